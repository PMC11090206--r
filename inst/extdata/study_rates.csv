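system,quantity,value,sd,unit
propane_coupled,r_alkane,0.35,0.11,mmol/L/d
propane_coupled,r_no3,2.34,0.30,mmol N/L/d
propane_alone,r_alkane,0.02,0.01,mmol/L/d
propane_alone,r_no3,0.11,0.04,mmol N/L/d
butane_coupled,r_alkane,0.24,0.10,mmol/L/d
butane_coupled,r_no3,2.06,0.33,mmol N/L/d
butane_alone,r_alkane,0.09,0.06,mmol/L/d
butane_alone,r_no3,0.58,0.30,mmol N/L/d
propane_coupled,n_consumed_total,4.04,0.28,mmol N/d
propane_coupled,n2_produced,4.23,0.36,mmol N/d
butane_coupled,n_consumed_total,3.62,0.41,mmol N/d
butane_coupled,n2_produced,3.62,0.31,mmol N/d
anammox_batch,no2_nh4_ratio,1.42,0.05,dimensionless
anammox_batch,no3_nh4_ratio,0.27,0.04,dimensionless
isotope_batch,denit_share,4,NA,percent of generated nitrite
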