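# Reference worked-example table: TET donor (emission maximum 539 nm, quantum
# yield 0.43) paired with metal nanospheres of commercially available sizes.
# Per row: Mie molar extinction at 539 nm (M^-1 cm^-1), size-corrected complex
# dielectric of the metal at 539 nm, its squared modulus, spectral overlap
# integral (M^-1 cm^-1 nm^4), and the NSET / FRET 50%-quenching distances (A).
# outlier_J = TRUE marks rows whose overlap integral is inconsistent with the
# consensus donor calibration (silver 10 nm: one-decade discrepancy; platinum:
# overlap integrals inconsistent in magnitude with every other row). These
# rows are excluded from calibration fits.
metal,diameter_nm,molar_extinction,eps_real,eps_imag,eps_mod2,overlap_integral,nset_d0_A,fret_d0_A,outlier_J
gold,40,9.46e9,-5.08,2.63,32.76,7.32e20,345.32,411.40,FALSE
gold,20,1.02e9,-4.98,3.05,34.11,6.56e19,234.89,275.89,FALSE
gold,10,1.01e8,-4.75,3.80,36.95,6.35e18,156.41,186.52,FALSE
silver,40,8.76e8,-12.09,0.55,146.42,6.51e19,120.59,274.89,FALSE
silver,20,2.46e7,-11.93,0.70,142.70,1.84e18,58.75,151.67,FALSE
silver,10,1.81e6,-11.50,0.97,133.23,1.37e18,36.57,98.43,TRUE
copper,8,1.99e7,-4.82,8.76,99.96,2.93e18,134.56,163.95,FALSE
copper,4,2.44e6,-3.91,10.49,125.39,3.32e17,92.32,114.07,FALSE
platinum,30,6.12e8,-8.93,18.05,405.53,2.37e10,292.65,266.17,TRUE
platinum,5,1.49e6,-8.10,29.22,919.0,1.93e10,101.48,97.71,TRUE
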