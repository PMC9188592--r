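patient,status,sbp_mmhg,dbp_mmhg,peak_gradient_mmhg,peak_gradient_digits,sac_ml_mmhg,sac_digits,total_sv_ml,branch_sv_ml,coa_sv_ml,graft_sv_ml,vmax_ms,graft_origin,graft_length_cm,graft_diameter_cm
1,pre,131,62,14.4,1,1.24,2,85,35.70,49.30,NA,1.90,NA,NA,NA
1,post,145,62,12.1,1,1.00,2,83,24.07,42.00,16.90,1.74,left_subclavian,8.1,1.6
2,pre,150,67,10.1,1,0.73,2,61,20.74,40.26,NA,1.59,NA,NA,NA
2,post,143,53,4.1,1,0.73,2,66.5,14.63,27.60,24.00,1.03,aortic_arch,6.9,1.7
3,pre,144,78,8.64,2,1.30,2,86,30.80,55.20,NA,1.47,NA,NA,NA
3,post,148,71,4.2,1,1.07,2,82.5,22.28,47.70,12.53,1.05,left_subclavian,8.3,1.5
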