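# Linear attenuation coefficient of LYSO (Lu1.8 Y0.2 Si O5, density 7.1 g/cm3),
# 1/mm versus photon energy in keV.
# Derived by the package authors from NIST XCOM elemental mass-attenuation
# coefficients (total, with coherent scattering) combined with the mixture rule;
# Lu values below/above its K-edge obtained by photoelectric Z-scaling from the
# NIST Pb table where no direct tabulation was at hand (~10-15% accuracy below
# 20 keV, better above).
# The Lu K-edge at 63.31 keV is bracketed by the 63.30/63.32 keV rows so that
# piecewise interpolation never bridges the discontinuity. The weak Y K-edge
# (17.04 keV, 4% mass fraction) is intentionally smoothed over.
energy_keV,mu_per_mm
10,156.8
12,105.2
15,58.74
20,29.51
25,16.29
30,10.35
35,6.937
40,4.899
45,3.607
50,2.755
55,2.158
60,1.725
63.30,1.512
63.32,4.949
70,3.784
80,2.641
90,1.967
100,1.576
120,1.030
150,0.660
200,0.355
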