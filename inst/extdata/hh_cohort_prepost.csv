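subject,volumes,pre_excitation,post_excitation,pre_inhibition,post_inhibition,obliterated,printed_soz_index,printed_pz_index,printed_bni
1,300,0.14,-0.59,-0.03,0.40,FALSE,512,1239,1751
2,300,0.28,0.08,-0.97,-0.26,FALSE,71,73,144
3,300,0.10,0.08,-0.84,-0.30,FALSE,22,64,86
4,600,0.50,-0.52,-0.91,0.47,FALSE,203,152,354
5,300,0.08,-0.51,-0.40,0.15,FALSE,768,138,906
6,300,0.41,-0.30,-0.96,-0.01,FALSE,172,99,271
7,600,0.21,-0.54,-1.18,0.02,FALSE,360,102,462
8,600,0.04,0.27,-0.20,-0.94,FALSE,-621,-359,-980
9,600,0.23,0.38,-1.09,-1.50,FALSE,-66,-38,-104
10,NA,NA,NA,NA,NA,TRUE,NA,NA,NA
11,NA,NA,NA,NA,NA,TRUE,NA,NA,NA
12,NA,NA,NA,NA,NA,TRUE,NA,NA,NA
13,NA,NA,NA,NA,NA,TRUE,NA,NA,NA
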