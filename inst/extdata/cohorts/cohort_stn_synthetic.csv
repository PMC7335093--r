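stim_id,patient_id,cohort,amplitude,n_electrodes,baseline_ybocs,postop_ybocs
stn_s01,stn_p01,stn,2.5,2,27.65095039,29.87833703
stn_s02,stn_p02,stn,2.5,2,28.53541956,28.67171089
stn_s03,stn_p03,stn,2.5,2,29.41988873,27.33103904
stn_s04,stn_p04,stn,2.5,2,30.3043579,25.85632148
stn_s05,stn_p05,stn,2.5,2,31.18882707,24.2475582
stn_s06,stn_p06,stn,2.5,2,32.07329624,22.5047492
stn_s07,stn_p07,stn,2.5,2,32.95776541,20.6278945
stn_s08,stn_p08,stn,2.5,2,33.84223459,18.61699407
stn_s09,stn_p09,stn,2.5,2,34.72670376,16.47204794
stn_s10,stn_p10,stn,2.5,2,35.61117293,14.19305609
stn_s11,stn_p11,stn,2.5,2,36.4956421,11.78001852
stn_s12,stn_p12,stn,2.5,2,37.38011127,9.232935246
stn_s13,stn_p13,stn,2.5,2,38.26458044,6.551806253
stn_s14,stn_p14,stn,2.5,2,39.14904961,3.736631546
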