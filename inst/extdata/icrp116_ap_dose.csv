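# Effective dose per unit photon fluence, pSv*cm2, anteroposterior (AP)
# irradiation geometry, versus photon energy in keV.
# Transcribed from ICRP Publication 116, Table A.1 (photons, AP column),
# 0.01-0.2 MeV rows.
energy_keV,pSv_cm2
10,0.0685
15,0.156
20,0.225
30,0.313
40,0.351
50,0.370
60,0.390
70,0.413
80,0.444
100,0.519
150,0.748
200,1.000
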