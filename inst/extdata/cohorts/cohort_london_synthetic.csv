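stim_id,patient_id,cohort,amplitude,n_electrodes,baseline_ybocs,postop_ybocs
london_s01,london_p01,london,3,4,33.79464882,22.58748429
london_s02,london_p02,london,3,4,34.75678929,20.88969058
london_s03,london_p03,london,3,4,35.71892976,19.06229686
london_s04,london_p04,london,3,4,36.68107024,17.10530314
london_s05,london_p05,london,3,4,37.64321071,15.01870942
london_s06,london_p06,london,3,4,38.60535118,12.80251571
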