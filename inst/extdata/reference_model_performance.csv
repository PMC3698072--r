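comparison,group_I,group_J,n_II,n_IJ,n_JI,n_JJ,accuracy,npv,ppv,specificity,sensitivity
mHC_vs_fHC_T0,male,female,19,2,2,7,0.87,0.90,0.78,0.90,0.78
mHC_vs_fHC_T0-T2,male,female,19,2,1,8,0.90,0.95,0.80,0.90,0.89
mCFS_vs_fCFS_T0,male,female,7,5,2,8,0.68,0.78,0.62,0.58,0.80
mCFS_vs_fCFS_T0-T2,male,female,8,4,1,9,0.77,0.89,0.69,0.67,0.90
mGWI_vs_fGWI_T0-T2,male,female,19,1,3,7,0.87,0.86,0.88,0.95,0.70
GWI_vs_HC_males_T0,HC,GWI,16,5,6,14,0.73,0.73,0.74,0.76,0.70
GWI_vs_HC_males_T2,HC,GWI,14,7,4,16,0.73,0.78,0.70,0.67,0.80
GWI_vs_HC_males_T0-T2,HC,GWI,17,4,3,17,0.83,0.85,0.81,0.81,0.85
CFS_vs_HC_males_T0,HC,CFS,16,5,3,9,0.76,0.84,0.64,0.76,0.75
CFS_vs_HC_males_T1,HC,CFS,16,5,1,11,0.82,0.94,0.69,0.76,0.92
CFS_vs_HC_males_T2,HC,CFS,16,5,4,8,0.73,0.80,0.62,0.76,0.67
CFS_vs_HC_males_T0-T2,HC,CFS,18,3,2,10,0.85,0.90,0.77,0.86,0.83
GWI_vs_HC_females_T1,HC,GWI,8,1,2,8,0.84,0.80,0.89,0.89,0.80
GWI_vs_HC_females_T2,HC,GWI,8,1,3,7,0.79,0.73,0.88,0.89,0.70
GWI_vs_HC_females_T0-T2,HC,GWI,8,1,2,8,0.84,0.80,0.89,0.89,0.80
CFS_vs_HC_females_T0,HC,CFS,5,4,1,9,0.74,0.83,0.69,0.56,0.90
CFS_vs_HC_females_T1,HC,CFS,4,5,2,8,0.63,0.67,0.62,0.44,0.80
CFS_vs_HC_females_T2,HC,CFS,3,6,0,10,0.68,1.00,0.63,0.33,1.00
CFS_vs_HC_females_T0-T2,HC,CFS,4,5,1,9,0.68,0.80,0.64,0.44,0.90
CFS_vs_HC_females_T0-T2_subsets,HC,CFS,8,1,3,7,0.79,0.73,0.88,0.89,0.70
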