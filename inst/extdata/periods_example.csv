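period_id,phase,t_start_d,t_end_d,V_L,HRT_d,OLR_gCOD_L_d,Q_feed_L_d,Q_effluent_L_d,Q_recycle_L_d,ethanol_cod_fraction,inner_diameter_m
2,II,17,38,4.8,9,6,0.5333333333333333,0.5333333333333333,9,0.4,0.12
3,II,38,58,4.8,9,6,0.5333333333333333,0.5333333333333333,86,0.4,0.12
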