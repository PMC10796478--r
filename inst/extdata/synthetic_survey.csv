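lake,date,fraction,taxon,reads
LakeA,2020-06-01,large,Gonyostomum_semen,2176
LakeA,2020-06-01,small,Urotricha_cf_pseudofurcata,5714
LakeA,2020-06-15,large,Gonyostomum_semen,2431
LakeA,2020-06-15,small,Urotricha_cf_pseudofurcata,3745
LakeA,2020-06-29,large,Gonyostomum_semen,4408
LakeA,2020-06-29,small,Urotricha_cf_pseudofurcata,8621
LakeA,2020-07-13,large,Gonyostomum_semen,48229
LakeA,2020-07-13,small,Urotricha_cf_pseudofurcata,488
LakeA,2020-07-27,large,Gonyostomum_semen,55968
LakeA,2020-07-27,small,Urotricha_cf_pseudofurcata,1113
LakeA,2020-08-10,large,Gonyostomum_semen,43058
LakeA,2020-08-10,small,Urotricha_cf_pseudofurcata,4420
LakeA,2020-08-24,large,Gonyostomum_semen,28234
LakeA,2020-08-24,small,Urotricha_cf_pseudofurcata,505
LakeA,2020-09-07,large,Gonyostomum_semen,3946
LakeA,2020-09-07,small,Urotricha_cf_pseudofurcata,2211
LakeA,2020-09-21,large,Gonyostomum_semen,2338
LakeA,2020-09-21,small,Urotricha_cf_pseudofurcata,10494
LakeB,2020-06-01,large,Gonyostomum_semen,8838
LakeB,2020-06-01,small,Urotricha_cf_pseudofurcata,11756
LakeB,2020-06-15,large,Gonyostomum_semen,2982
LakeB,2020-06-15,small,Urotricha_cf_pseudofurcata,5325
LakeB,2020-06-29,large,Gonyostomum_semen,856
LakeB,2020-06-29,small,Urotricha_cf_pseudofurcata,5280
LakeB,2020-07-13,large,Gonyostomum_semen,27976
LakeB,2020-07-13,small,Urotricha_cf_pseudofurcata,3002
LakeB,2020-07-27,large,Gonyostomum_semen,53038
LakeB,2020-07-27,small,Urotricha_cf_pseudofurcata,2068
LakeB,2020-08-10,large,Gonyostomum_semen,54044
LakeB,2020-08-10,small,Urotricha_cf_pseudofurcata,629
LakeB,2020-08-24,large,Gonyostomum_semen,53323
LakeB,2020-08-24,small,Urotricha_cf_pseudofurcata,4501
LakeB,2020-09-07,large,Gonyostomum_semen,3010
LakeB,2020-09-07,small,Urotricha_cf_pseudofurcata,12024
LakeB,2020-09-21,large,Gonyostomum_semen,2274
LakeB,2020-09-21,small,Urotricha_cf_pseudofurcata,13928
LakeC,2020-06-01,large,Gonyostomum_semen,4814
LakeC,2020-06-01,small,Urotricha_cf_pseudofurcata,15592
LakeC,2020-06-15,large,Gonyostomum_semen,4024
LakeC,2020-06-15,small,Urotricha_cf_pseudofurcata,9938
LakeC,2020-06-29,large,Gonyostomum_semen,3870
LakeC,2020-06-29,small,Urotricha_cf_pseudofurcata,12047
LakeC,2020-07-13,large,Gonyostomum_semen,35373
LakeC,2020-07-13,small,Urotricha_cf_pseudofurcata,3070
LakeC,2020-07-27,large,Gonyostomum_semen,67442
LakeC,2020-07-27,small,Urotricha_cf_pseudofurcata,2356
LakeC,2020-08-10,large,Gonyostomum_semen,50682
LakeC,2020-08-10,small,Urotricha_cf_pseudofurcata,3247
LakeC,2020-08-24,large,Gonyostomum_semen,41810
LakeC,2020-08-24,small,Urotricha_cf_pseudofurcata,2429
LakeC,2020-09-07,large,Gonyostomum_semen,3071
LakeC,2020-09-07,small,Urotricha_cf_pseudofurcata,18253
LakeC,2020-09-21,large,Gonyostomum_semen,2351
LakeC,2020-09-21,small,Urotricha_cf_pseudofurcata,19919
LakeD,2020-06-01,large,Gonyostomum_semen,3251
LakeD,2020-06-01,small,Urotricha_cf_pseudofurcata,10581
LakeD,2020-06-15,large,Gonyostomum_semen,11756
LakeD,2020-06-15,small,Urotricha_cf_pseudofurcata,10191
LakeD,2020-06-29,large,Gonyostomum_semen,3426
LakeD,2020-06-29,small,Urotricha_cf_pseudofurcata,11040
LakeD,2020-07-13,large,Gonyostomum_semen,39923
LakeD,2020-07-13,small,Urotricha_cf_pseudofurcata,2701
LakeD,2020-07-27,large,Gonyostomum_semen,22958
LakeD,2020-07-27,small,Urotricha_cf_pseudofurcata,2301
LakeD,2020-08-10,large,Gonyostomum_semen,26995
LakeD,2020-08-10,small,Urotricha_cf_pseudofurcata,2984
LakeD,2020-08-24,large,Gonyostomum_semen,38764
LakeD,2020-08-24,small,Urotricha_cf_pseudofurcata,1325
LakeD,2020-09-07,large,Gonyostomum_semen,2190
LakeD,2020-09-07,small,Urotricha_cf_pseudofurcata,4144
LakeD,2020-09-21,large,Gonyostomum_semen,719
LakeD,2020-09-21,small,Urotricha_cf_pseudofurcata,9831
LakeE,2020-06-01,large,Gonyostomum_semen,0
LakeE,2020-06-01,small,Urotricha_cf_pseudofurcata,16473
LakeE,2020-06-15,large,Gonyostomum_semen,0
LakeE,2020-06-15,small,Urotricha_cf_pseudofurcata,12021
LakeE,2020-06-29,large,Gonyostomum_semen,0
LakeE,2020-06-29,small,Urotricha_cf_pseudofurcata,4657
LakeE,2020-07-13,large,Gonyostomum_semen,0
LakeE,2020-07-13,small,Urotricha_cf_pseudofurcata,13525
LakeE,2020-07-27,large,Gonyostomum_semen,0
LakeE,2020-07-27,small,Urotricha_cf_pseudofurcata,8941
LakeE,2020-08-10,large,Gonyostomum_semen,0
LakeE,2020-08-10,small,Urotricha_cf_pseudofurcata,16819
LakeE,2020-08-24,large,Gonyostomum_semen,0
LakeE,2020-08-24,small,Urotricha_cf_pseudofurcata,2853
LakeE,2020-09-07,large,Gonyostomum_semen,0
LakeE,2020-09-07,small,Urotricha_cf_pseudofurcata,13023
LakeE,2020-09-21,large,Gonyostomum_semen,0
LakeE,2020-09-21,small,Urotricha_cf_pseudofurcata,6285
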