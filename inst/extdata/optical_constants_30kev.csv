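# X-ray optical constants at 30 keV photon energy.
# delta: refractive index decrement, computed from the free-electron
#   approximation delta = r_e * lambda^2 * n_e / (2*pi) with tabulated bulk
#   densities (consistent with the standard Henke/CXRO tabulation far from
#   absorption edges at this energy).
# mu_per_um: linear attenuation coefficient, from NIST XCOM elemental
#   mass attenuation coefficients at 30 keV combined by mass fraction and
#   multiplied by the bulk density.
# density in g/cm^3; delta dimensionless; mu in 1/um.
material,formula,density_g_cm3,delta,mu_per_um
Al2O3,Al2O3,3.97,8.980e-07,3.077e-04
C6H10O5,C6H10O5,1.10,2.691e-07,3.548e-05
PMMA,C5H8O2,1.19,2.961e-07,3.608e-05
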