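stim_id,patient_id,cohort,amplitude,n_electrodes,baseline_ybocs,postop_ybocs
nacc_s01,nacc_p01,nacc,4,2,18.92626512,17.07206417
nacc_s02,nacc_p01,nacc,4,2,18.92626512,16.60802844
nacc_s03,nacc_p01,nacc,4,2,18.92626512,16.14399271
nacc_s04,nacc_p01,nacc,4,2,18.92626512,15.67995699
nacc_s05,nacc_p02,nacc,4,2,22.09018937,17.7595833
nacc_s06,nacc_p02,nacc,4,2,22.09018937,17.21797422
nacc_s07,nacc_p02,nacc,4,2,22.09018937,16.67636514
nacc_s08,nacc_p02,nacc,4,2,22.09018937,16.13475606
nacc_s09,nacc_p03,nacc,4,2,25.25411362,17.8265156
nacc_s10,nacc_p03,nacc,4,2,25.25411362,17.20733316
nacc_s11,nacc_p03,nacc,4,2,25.25411362,16.58815072
nacc_s12,nacc_p03,nacc,4,2,25.25411362,15.96896828
nacc_s13,nacc_p04,nacc,4,2,28.41803787,17.27286105
nacc_s14,nacc_p04,nacc,4,2,28.41803787,16.57610525
nacc_s15,nacc_p04,nacc,4,2,28.41803787,15.87934946
nacc_s16,nacc_p04,nacc,4,2,28.41803787,15.18259367
nacc_s17,nacc_p05,nacc,4,2,31.58196213,16.09861965
nacc_s18,nacc_p05,nacc,4,2,31.58196213,15.32429051
nacc_s19,nacc_p05,nacc,4,2,31.58196213,14.54996136
nacc_s20,nacc_p05,nacc,4,2,31.58196213,13.77563221
nacc_s21,nacc_p06,nacc,4,2,34.74588638,14.30379142
nacc_s22,nacc_p06,nacc,4,2,34.74588638,13.45188891
nacc_s23,nacc_p06,nacc,4,2,34.74588638,12.59998641
nacc_s24,nacc_p06,nacc,4,2,34.74588638,11.7480839
nacc_s25,nacc_p07,nacc,4,2,37.90981063,11.88837634
nacc_s26,nacc_p07,nacc,4,2,37.90981063,10.95890048
nacc_s27,nacc_p07,nacc,4,2,37.90981063,10.02942462
nacc_s28,nacc_p07,nacc,4,2,37.90981063,9.099948758
nacc_s29,nacc_p08,nacc,4,2,41.07373488,8.852374414
nacc_s30,nacc_p08,nacc,4,2,41.07373488,7.845325198
nacc_s31,nacc_p08,nacc,4,2,41.07373488,6.838275983
nacc_s32,nacc_p08,nacc,4,2,41.07373488,5.831226767
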