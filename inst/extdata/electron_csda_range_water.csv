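# Electron CSDA range in liquid water (unit density), rounded from a
# published stopping-power/range compilation (ESTAR-style). range in g/cm2;
# divide by density (1 g/cm3) for cm. Interpolated log-log in between.
E_keV,range_g_cm2
10,2.515e-4
20,8.566e-4
30,1.756e-3
40,2.907e-3
50,4.320e-3
60,5.940e-3
70,7.726e-3
80,9.702e-3
100,1.431e-2
150,2.817e-2
200,4.490e-2
300,8.421e-2
400,1.285e-1
500,1.766e-1
600,2.260e-1
800,3.260e-1
1000,4.367e-1
2000,9.785e-1
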