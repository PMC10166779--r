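organ,gene,n,n_deaths
colon,MLH1,241,26
colon,MSH2,165,20
colon,MSH6,22,3
colon,PMS2,3,1
endometrium,MLH1,93,11
endometrium,MSH2,82,11
endometrium,MSH6,36,2
endometrium,PMS2,5,0
rectum,MLH1,36,8
rectum,MSH2,59,15
rectum,MSH6,12,3
rectum,PMS2,1,0
ovary,MLH1,23,2
ovary,MSH2,25,5
ovary,MSH6,3,0
ovary,PMS2,1,0
ureter_kidney,MLH1,14,5
ureter_kidney,MSH2,64,11
ureter_kidney,MSH6,7,0
ureter_kidney,PMS2,0,0
urinary_bladder,MLH1,15,3
urinary_bladder,MSH2,32,8
urinary_bladder,MSH6,7,0
urinary_bladder,PMS2,0,0
prostate,MLH1,15,3
prostate,MSH2,30,6
prostate,MSH6,4,0
prostate,PMS2,1,0
stomach,MLH1,17,10
stomach,MSH2,21,5
stomach,MSH6,2,1
stomach,PMS2,1,0
small_intestine,MLH1,25,7
small_intestine,MSH2,24,5
small_intestine,MSH6,2,0
small_intestine,PMS2,2,0
bile_duct,MLH1,15,9
bile_duct,MSH2,6,2
bile_duct,MSH6,0,0
bile_duct,PMS2,0,0
pancreas,MLH1,11,10
pancreas,MSH2,8,4
pancreas,MSH6,1,0
pancreas,PMS2,0,0
brain,MLH1,4,2
brain,MSH2,13,9
brain,MSH6,3,1
brain,PMS2,1,1
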