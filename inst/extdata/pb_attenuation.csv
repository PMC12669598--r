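# Linear attenuation coefficient of lead (density 11.35 g/cm3), 1/mm versus
# photon energy in keV; used for X-ray tube filtration in the pulse simulator.
# Transcribed from the NIST XCOM mass-attenuation table for Pb (total, with
# coherent scattering). The Pb K-edge at 88.00 keV is bracketed by the
# 88.00/88.01 keV rows.
energy_keV,mu_per_mm
10,148.2
15,126.7
20,98.02
30,34.41
40,16.30
50,9.127
60,5.699
70,3.870
80,2.746
88.00,2.168
88.01,8.720
100,6.298
120,3.995
150,2.286
200,1.133
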