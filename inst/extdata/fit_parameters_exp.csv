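component,weight,gxx,gyy,gzz,Axx_MHz,Ayy_MHz,Azz_MHz
Comp1,0.67,2.00834,2.00598,2.0023,14,14,100
Comp2,0.33,2.00795,2.00598,2.0023,14,14,100
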