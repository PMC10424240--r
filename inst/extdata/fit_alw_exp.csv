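band,frequency_GHz,alw_xx,alw_yy,alw_zz
X,9.7671,20,20,18
Q,33.6615,24,22,18
W,93.993,24,21,18
J,262.8436,52,28,25
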