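label,u_m_d,A_transfer_m2,C_MCCA_undiss_gCOD_L,V_L,C_MCC_broth_gCOD_L,HRT_d,observed_flux_gCOD_m2_d
synthetic_study_A,12,1.4,0.4,4.8,2,9,2.54
synthetic_study_B,60,1.4,0.3,4.8,1.5,9,4.22
synthetic_study_C,207,1.4,0.25,4.8,1,9.5,8.79
synthetic_study_D,480,8.1,0.1,60,3,15,12.16
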