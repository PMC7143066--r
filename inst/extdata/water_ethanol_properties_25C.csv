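# Water-ethanol binary mixture properties at 25 C versus ethanol mass fraction.
# Representative values compiled from published measurements (density and
# viscosity after Khattab et al. 2012, Korean J. Chem. Eng. 29:812; mutual
# diffusion coefficient after Pratt & Wakeham 1974, Proc. R. Soc. Lond. A 336:393,
# converted from mole- to mass-fraction support). Values are smoothed,
# literature-derived approximations intended for order-5 polynomial fitting,
# not a primary data source.
# Columns: ethanol mass fraction (-), density (kg/m3), dynamic viscosity (mPa s),
# mutual diffusivity (1e-9 m2/s).
w_ethanol,density_kg_m3,viscosity_mpa_s,diffusivity_1e9_m2_s
0.00,997.0,0.890,1.24
0.10,980.4,1.320,0.91
0.20,966.4,1.800,0.66
0.30,950.1,2.190,0.48
0.40,931.5,2.350,0.41
0.50,909.9,2.400,0.43
0.60,887.5,2.240,0.52
0.70,864.7,1.960,0.65
0.80,841.6,1.620,0.79
0.90,817.7,1.320,0.96
1.00,785.1,1.080,1.13
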