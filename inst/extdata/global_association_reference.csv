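dataset,metric,r,p,significant
HCP_day_1,global_efficiency,-0.01,0.846,0
HCP_day_1,global_clustering,0.02,0.503,0
HCP_day_1,small_world_propensity,0.02,0.548,0
HCP_day_1_ses_1,global_efficiency,-0.01,0.631,0
HCP_day_1_ses_1,global_clustering,0.07,0.023,1
HCP_day_1_ses_1,small_world_propensity,0.04,0.221,0
HCP_day_1_ses_2,global_efficiency,-0.03,0.370,0
HCP_day_1_ses_2,global_clustering,0.03,0.303,0
HCP_day_1_ses_2,small_world_propensity,0.02,0.614,0
HCP_day_2,global_efficiency,-0.03,0.284,0
HCP_day_2,global_clustering,0.01,0.799,0
HCP_day_2,small_world_propensity,0.01,0.720,0
HCP_day_1_day_2,global_efficiency,-0.02,0.543,0
HCP_day_1_day_2,global_clustering,0.01,0.768,0
HCP_day_1_day_2,small_world_propensity,0.01,0.835,0
NKI_TR645,global_efficiency,-0.05,0.353,0
NKI_TR645,global_clustering,0.11,0.030,1
NKI_TR645,small_world_propensity,-0.01,0.823,0
NKI_TR1400,global_efficiency,-0.00,0.972,0
NKI_TR1400,global_clustering,0.11,0.049,1
NKI_TR1400,small_world_propensity,0.00,0.940,0
NKI_TR2500,global_efficiency,-0.04,0.410,0
NKI_TR2500,global_clustering,0.05,0.373,0
NKI_TR2500,small_world_propensity,0.04,0.474,0
RUB,global_efficiency,0.00,0.962,0
RUB,global_clustering,0.07,0.068,0
RUB,small_world_propensity,0.02,0.707,0
UMN,global_efficiency,0.10,0.108,0
UMN,global_clustering,0.04,0.542,0
UMN,small_world_propensity,0.08,0.198,0
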