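series,n_hbonds,weight,gxx,gyy,gzz,Axx_MHz,Ayy_MHz,Azz_MHz,Axx_ccsd_MHz,Ayy_ccsd_MHz,Azz_ccsd_MHz
qmmm,2,0.69,2.00791,2.00578,2.00214,7.3,7.5,95.2,11.6,12.0,99.0
qmmm,3,0.31,2.00767,2.00572,2.00214,7.4,7.7,98.1,11.0,11.5,101.0
ecrism,2,1.0,2.00796,2.00576,2.0021,7.4,7.6,96.1,12.3,12.8,102.8
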