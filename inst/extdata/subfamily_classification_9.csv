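true,n,Campopleginae,Cremastinae,Ctenopelmatinae,Metopiinae,Ophioninae,Orthocentrinae,Pimplinae,Tersilochinae,Tryphoninae
Campopleginae,37,94.59,5.41,0.00,0.00,0.00,0.00,0.00,0.00,0.00
Cremastinae,23,0.00,82.6,8.70,0.00,4.35,4.35,0.00,0.00,0.00
Ctenopelmatinae,81,4.94,0.00,87.65,0.00,0.00,2.47,0.00,0.00,4.94
Metopiinae,28,7.14,0.00,0.00,89.29,0.00,0.00,0.00,0.00,3.57
Ophioninae,36,0.00,0.00,0.00,0.00,100.00,0.00,0.00,0.00,0.00
Orthocentrinae,22,0.00,0.00,0.00,4.55,0.00,81.82,4.55,0.00,9.09
Pimplinae,52,0.00,0.00,0.00,0.00,0.00,3.85,90.38,0.00,5.77
Tersilochinae,16,0.00,6.25,0.00,0.00,0.00,0.00,0.00,93.75,0.00
Tryphoninae,38,0.00,2.63,21.05,0.00,0.00,0.00,5.26,0.00,71.05
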