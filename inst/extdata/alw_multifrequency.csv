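series,component,weight,band,frequency_GHz,alw_xx,alw_yy,alw_zz
exp,,1,X,9.7671,20,20,18
exp,,1,Q,33.6615,24,22,18
exp,,1,W,93.993,24,21,18
exp,,1,J,262.8436,52,28,25
qmmm,comp_2H,0.69,X,9.7671,18,16,21
qmmm,comp_2H,0.69,Q,33.6615,24,21,18
qmmm,comp_2H,0.69,W,93.993,40,23,19
qmmm,comp_2H,0.69,J,262.8436,102,45,20
qmmm,comp_3H,0.31,X,9.7671,18,17,20
qmmm,comp_3H,0.31,Q,33.6615,24,20,18
qmmm,comp_3H,0.31,W,93.993,37,24,21
qmmm,comp_3H,0.31,J,262.8436,97,47,19
ecrism,,1,X,9.7671,17,15,19
ecrism,,1,Q,33.6615,26,20,19
ecrism,,1,W,93.993,35,25,21
ecrism,,1,J,262.8436,90,40,19
vac,,1,W,93.993,53,NA,NA
vac,,1,J,262.8436,140,42,NA
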