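genotype,n,n_female,age_mean,age_sd,n_hfd,n_hn
APOE2,58,30,16.12,1.8,15,25
APOE3,54,27,15.25,1.54,25,20
APOE4,57,28,15.84,1.76,15,30
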