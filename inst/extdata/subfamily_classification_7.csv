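true,n,Campopleginae,Cremastinae,Ctenopelmatinae,Metopiinae,Orthocentrinae,Pimplinae,Tryphoninae
Campopleginae,37,91.89,0.00,2.70,0.00,5.41,0.00,0.00
Cremastinae,23,0.00,86.96,8.70,0.00,0.00,4.35,0.00
Ctenopelmatinae,81,3.70,2.47,85.19,0.00,2.47,0.00,6.17
Metopiinae,28,3.57,0.00,0.00,89.29,0.00,0.00,7.14
Orthocentrinae,22,0.00,0.00,0.00,4.55,72.73,13.64,9.09
Pimplinae,52,0.00,0.00,1.92,0.00,3.85,86.5,7.69
Tryphoninae,38,0.00,2.63,26.32,0.00,0.00,5.26,65.79
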