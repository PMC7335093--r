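stim_id,patient_id,cohort,amplitude,n_electrodes,baseline_ybocs,postop_ybocs
alic_s01,alic_p01,alic,4.5,2,24.18528775,24.70480978
alic_s02,alic_p02,alic,4.5,2,24.86287939,24.61204529
alic_s03,alic_p03,alic,4.5,2,25.54047103,24.47649819
alic_s04,alic_p04,alic,4.5,2,26.21806268,24.29816848
alic_s05,alic_p05,alic,4.5,2,26.89565432,24.07705616
alic_s06,alic_p06,alic,4.5,2,27.57324596,23.81316123
alic_s07,alic_p07,alic,4.5,2,28.25083761,23.50648369
alic_s08,alic_p08,alic,4.5,2,28.92842925,23.15702355
alic_s09,alic_p09,alic,4.5,2,29.60602089,22.7647808
alic_s10,alic_p10,alic,4.5,2,30.28361254,22.32975543
alic_s11,alic_p11,alic,4.5,2,30.96120418,21.85194746
alic_s12,alic_p12,alic,4.5,2,31.63879582,21.33135688
alic_s13,alic_p13,alic,4.5,2,32.31638746,20.7679837
alic_s14,alic_p14,alic,4.5,2,32.99397911,20.1618279
alic_s15,alic_p15,alic,4.5,2,33.67157075,19.51288949
alic_s16,alic_p16,alic,4.5,2,34.34916239,18.82116848
alic_s17,alic_p17,alic,4.5,2,35.02675404,18.08666486
alic_s18,alic_p18,alic,4.5,2,35.70434568,17.30937863
alic_s19,alic_p19,alic,4.5,2,36.38193732,16.48930978
alic_s20,alic_p20,alic,4.5,2,37.05952897,15.62645834
alic_s21,alic_p21,alic,4.5,2,37.73712061,14.72082428
alic_s22,alic_p22,alic,4.5,2,38.41471225,13.77240761
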