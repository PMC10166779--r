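organ,gene,sex,s10_pct,q65_pct,m75_pct
colon,MLH1,M,87,48.4,6
colon,MLH1,F,87,36.3,5
colon,MSH2,M,87,41.5,5
colon,MSH2,F,87,29.8,4
colon,MSH6,M,87,12.7,2
colon,MSH6,F,87,10.1,1
colon,PMS2,M,87,9.5,1
colon,PMS2,F,87,2.8,0
rectum,MLH1,M,72,6.0,2
rectum,MLH1,F,72,4.6,1
rectum,MSH2,M,72,12.6,4
rectum,MSH2,F,72,7.6,2
rectum,MSH6,M,72,5.1,1
rectum,MSH6,F,72,3.9,1
rectum,PMS2,M,72,0,0
rectum,PMS2,F,72,2.2,1
endometrium,MLH1,F,92,31.7,3
endometrium,MSH2,F,92,37.6,3
endometrium,MSH6,F,92,32.1,3
endometrium,PMS2,F,92,12.7,1
ovary,MLH1,F,85,8.0,1
ovary,MSH2,F,85,10.6,2
ovary,MSH6,F,85,2.9,0
ovary,PMS2,F,85,2.5,0
stomach,MLH1,M,63,2.8,1
stomach,MLH1,F,63,2.0,1
stomach,MSH2,M,63,4.3,2
stomach,MSH2,F,63,2.6,1
stomach,MSH6,M,63,0.7,0
stomach,MSH6,F,63,0.7,0
stomach,PMS2,M,63,2.7,1
stomach,PMS2,F,63,0,0
small_intestine,MLH1,M,70,4.4,1
small_intestine,MLH1,F,70,2.5,1
small_intestine,MSH2,M,70,4.5,1
small_intestine,MSH2,F,70,3.2,1
small_intestine,MSH6,M,70,0.7,0
small_intestine,MSH6,F,70,0.6,0
small_intestine,PMS2,M,70,3.3,1
small_intestine,PMS2,F,70,2.1,1
bile_duct,MLH1,M,42,2.9,2
bile_duct,MLH1,F,42,1.5,1
bile_duct,MSH2,M,42,1.0,1
bile_duct,MSH2,F,42,0.8,0
bile_duct,MSH6,M,42,0,0
bile_duct,MSH6,F,42,0,0
bile_duct,PMS2,M,42,0,0
bile_duct,PMS2,F,42,0,0
pancreas,MLH1,M,17,1.1,1
pancreas,MLH1,F,17,1.9,2
pancreas,MSH2,M,17,1.4,1
pancreas,MSH2,F,17,1.2,1
pancreas,MSH6,M,17,0,0
pancreas,MSH6,F,17,0.7,1
pancreas,PMS2,M,17,0,0
pancreas,PMS2,F,17,0,0
ureter_kidney,MLH1,M,73,2.5,1
ureter_kidney,MLH1,F,73,1.7,0
ureter_kidney,MSH2,M,73,11.5,3
ureter_kidney,MSH2,F,73,9.7,3
ureter_kidney,MSH6,M,73,1.4,0
ureter_kidney,MSH6,F,73,3.2,1
ureter_kidney,PMS2,M,73,0,0
ureter_kidney,PMS2,F,73,0,0
urinary_bladder,MLH1,M,71,3.3,1
urinary_bladder,MLH1,F,71,1.3,0
urinary_bladder,MSH2,M,71,5.9,2
urinary_bladder,MSH2,F,71,4.7,1
urinary_bladder,MSH6,M,71,3.0,1
urinary_bladder,MSH6,F,71,1.8,1
urinary_bladder,PMS2,M,71,0,0
urinary_bladder,PMS2,F,71,0,0
prostate,MLH1,M,76,5.3,1
prostate,MSH2,M,76,10.6,3
prostate,MSH6,M,76,3.0,1
prostate,PMS2,M,76,3.3,1
brain,MLH1,M,34,0,0
brain,MLH1,F,34,0.9,1
brain,MSH2,M,34,3.3,2
brain,MSH2,F,34,1.4,1
brain,MSH6,M,34,0.8,1
brain,MSH6,F,34,1.2,1
brain,PMS2,M,34,0,0
brain,PMS2,F,34,7.3,5
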