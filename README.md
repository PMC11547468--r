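# nsetr

Fluorescence quenching of a dye by a metal nanoparticle, modelled as
**nanometal surface energy transfer** (NSET) with its **FRET**
counterpart for comparison — for people building nanoparticle–dye
biosensors (plasmon rulers, DNA-hybridization probes) who need to turn
a metal, a sphere size and a dye into a quenching-versus-distance
curve, and to fit the model's two free parameters against measured
quenching data.

## The model

A donor dye held at separation *r* from a metal nanosphere surface is
quenched with efficiency

    E = 1 / (1 + (r/d0)^4)          (NSET)
    E = 1 / (1 + (r/R0)^6)          (FRET)

The Forster radius comes from the spectral overlap
`J = Σ F_D(λ) ε_A(λ) λ⁴ dλ`:

    R0 = 0.211 (κ² n⁻⁴ Q_D J)^(1/6)   [Å]

and the NSET 50%-quenching distance from the particle optics:

    d0 = α (λ_emis/n_p) (A Φ)^(1/4) [ (n_m/2n_p)(1 + ε₁²/|ε₂|²) ]^(1/4)

where ε₂ is the metal's complex dielectric at the emission wavelength —
size-corrected through a Drude surface-scattering damping term
Γ_r = Γ_∞ + C·ħv_f/r — n_m its refractive index, A the per-particle
absorptivity built from the Mie molar extinction and the skin depth
λ/(2πκ), and α ≈ 0.1159 the orientation-averaged prefactor. The
scattering constant **C** and the prefactor **α** are the model's free
parameters; `nset_fit()` estimates them by exhaustive coarse-to-fine
grid search (MRE/RMSE objectives) against a table of observed
quenching cases, and a Lasso/perceptron harness checks how much of the
quenching a regression can explain. A synthetic case-table generator
reproduces the 56-case DNA-ruler study design (52 gold / 4 silver
spheres of 10/20 nm, 20–80 bp duplex spacers, tilt 0–39°) so everything
is testable without measured data.

## Worked example

```r
library(nsetr)
transfer_system("gold", 10)       # 10 nm gold sphere, TET donor
```

    Transfer system: gold sphere, d = 10 nm; donor tet (539 nm, QY 0.43)
      dielectric at 539 nm: -4.750 +3.800i  (|eps|^2 = 37.00)
      n + i kappa = 0.816 + 2.327i,  skin depth = 36.9 nm
      molar extinction = 1e+08 M^-1 cm^-1,  J = 8.18e+18 M^-1 cm^-1 nm^4
      NSET d0 = 161.65 A,   FRET R0 = 194.34 A

Read: the size-corrected gold dielectric at the TET emission maximum,
the Mie extinction of the sphere (1.0×10⁸ M⁻¹cm⁻¹), and the two
50%-quenching distances — the NSET distance (~162 Å) is what a 1/r⁴
ruler experiment calibrates against. Fitting the two free parameters to
a synthetic 56-case table and validating the regressions:

```r
cases <- generate_cases(generator_config(seed = 1))
nset_fit(cases, mre_epsilon = 0.05, objective = "rmse")
```

    NSET quenching model, exhaustive grid-search fit
      56 cases; 3 stages, 1,680,000 evaluations
      C = 1.808, alpha = 0.1  (objective RMSE = 0.1047)

```r
run_validation_suite(cases, seed = 1)
```

    Validation R^2 (rows: learners; designs: split / 5-fold CV / 10% blind)
          run_train run_test cv_train cv_test blind_train blind_test blind_valid
    lasso   0.99911  0.99903  0.99908 0.99905     0.99902    0.99912     0.99901
    mlp     0.99992  0.99962  0.99994 0.99943     0.99994    0.99041     0.99932

The RMSE at the optimum (~0.10) sits just above the generator's 0.08
observation noise — the grid search recovers what is recoverable — and
the near-unity R² values reflect the schema's built-in complementarity
between observed fluorescence and quenching. A command-line front end
(`exec/nset`) exposes the same operations as subcommands
(`dielectric`, `extinction`, `d0`, `quench-curve`, `distance`,
`synth`, `gridsearch`, `ml`).

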