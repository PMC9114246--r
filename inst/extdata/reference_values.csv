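quantity,unit,expected,tolerance
lab_power_W,W,0.257,0.01
lab_pv_working,W m^-3,85.709,0.01
lab_lambda_um,um,237.721,0.01
pilot_power_W,W,77.006,0.01
pilot_pv_working,W m^-3,770.069,0.01
pilot_lambda_um,um,120.874,0.01
pilot_scaled_speed,s^-1,1.069,0.005
pilot_scaled_power_W,W,2.545,0.01
industrial_scaled_speed,s^-1,0.295,0.005
industrial_power_2stage_W,W,9425.137,0.01
industrial_power_3stage_W,W,14137.705,0.01
industrial_pv_2stage,W m^-3,45.532,0.01
industrial_pv_3stage,W m^-3,68.29,0.01
industrial_lambda_2stage_um,um,245.125,0.01
industrial_lambda_3stage_um,um,221.495,0.01
rtb_80_power_kW,kW,862.54,0.01
rtb_80_torque_Nm,N m,76775.40,0.01
rtb_80_pv_total,kW m^-3,2.88,0.01
la315_150_power_kW,kW,853.49,0.01
la315_150_torque_Nm,N m,40517.41,0.01
la315_150_pv_total,kW m^-3,2.84,0.01
cbt_80_power_kW,kW,759.03,0.01
pbt_110_power_kW,kW,735.61,0.01
selection_torque_ratio,dimensionless,1.9,0.01
sweep_avg_pv_z86,kW m^-3,3.59,0.01
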