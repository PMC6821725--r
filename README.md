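# pentarho

Quantitative analysis pipeline for the pentameric viral rhodopsin
OLPVRII: photocycle kinetics from flash-photolysis spectroscopy, pKa
titrations, black-lipid-membrane (BLM) electrometry, pentamer structure
geometry, and free-energy profiles of the central pore.

## The scientific problem

OLPVRII is a viral rhodopsin that assembles into a C5-symmetric pentamer
with a water-filled pore along the symmetry axis — an architecture
resembling pentameric ligand-gated ion channels rather than classical
microbial proton pumps. Characterizing it quantitatively requires five
very different computations on five kinds of measurement:

1. **Photocycle kinetics.** After a laser flash, transient absorption
   ΔA(λ, t) is recorded from 330–730 nm over seven decades of time. The
   photocycle is a sequential chain of intermediates (K540 → M410 →
   N525/O550 → ground at 514 nm), so every trace shares the same
   lifetimes. A *global* multiexponential fit — variable projection over
   all wavelengths at once — determines how many kinetic steps there are
   and their time constants, and Bateman kinetics then converts amplitude
   spectra into absolute intermediate spectra.
2. **Titration.** Two protonation events shift the absorption spectrum:
   protonation of the proton acceptor in acid (λmax 514 → 548 nm) and
   deprotonation of the retinal Schiff base in base (the 514 nm band
   vanishes). Boltzmann-sigmoid fits of the right observable against pH
   give the two pKa values.
3. **Electrometry.** Flash-induced BLM currents decompose into signed
   exponential components; each component's lifetime is assigned to the
   photocycle transition nearest in log time, identifying which steps
   move charge.
4. **Structure geometry.** Kabsch superposition gives inter-protomer
   backbone RMSDs; ring geometry measures the axial water pentagon; a
   HOLE-style profiler maps the pore radius along the axis.
5. **Pore energetics.** Boltzmann inversion of axial particle densities,
   G(z) = −RT ln(n(z)/n_bulk), yields potentials of mean force for water
   and ions with block-bootstrap uncertainties, summarized as per-region
   ion selectivity.

All computation lives in the package (`R/`); the numbered scripts under
`analysis/` are thin drivers that chain the stages over files in
`results/`. A synthetic-data generator emulates every input, so the whole
pipeline runs offline and seeded.

## Worked example

Generate the flash-photolysis matrix at SNR 100 and recover the
photocycle (output from `analysis/01_simulate.R` + `02_photocycle_fit.R`):

```r
library(pentarho)
scheme <- olpvrii_photocycle_scheme()
ds0 <- gen_photocycle_dataset(scheme)                  # noiseless
ds <- gen_photocycle_dataset(scheme,
        noise = noise_spec(max(abs(ds0$delta_a)) / 100, seed = 1))

choose_num_exponentials(ds, n_max = 8)
#> [1] 7
fit <- fit_global_exponentials(ds, 7)
signif(fit$taus, 3)
#> [1] 9.80e-07 1.54e-05 6.04e-05 3.41e-04 9.90e-03 2.48e-02 7.30e-02
```

Seven exponentials, recovering the generating lifetimes 1, 16, 61,
340 µs and 10, 25, 73 ms. The reconstructed intermediate spectra give
λmax = 539.8, 540.0, 410.2, 410.1, 410.4, 536.9, 542.0 nm — a K-like
state rising into M410 and relaxing through late red-shifted mixtures.

Titration fits on synthetic spectra at SNR 50 (`03_titration.R`):

```text
acceptor pKa    = 3.242 +/- 0.120   (lambda_max 553 -> 515 nm)
Schiff-base pKa = 10.372 +/- 0.025  (A514 step 1.003)
```

BLM photocurrent decomposition and assignment (`04_photocurrents.R`):

```text
 amplitude        tau     charge    assigned
     1.012   24.26 us   2.45e-05    K540->M410
     0.797    5.82 ms   4.63e-03    M->N/O rise
    -0.780   87.31 ms  -6.81e-02    O550->ground
    -0.616  924.27 ms  -5.70e-01    membrane discharge
```

Structure geometry on the stand-in pentamer (`05_structure_geometry.R`):

```text
protomer backbone RMSD range (A): 0.176 0.189
water pentagon O-O: 2.60 +/- 0.00 A
```

Pore PMFs and selectivity (`06_pore_pmf.R`):

```text
         region  barrier_cation  barrier_anion  selective_for
    cytoplasmic           1.294          0.236          anion
   constriction           0.069          0.050           none
  extracellular           0.233          1.350         cation
```

## Reproduction

Run the pipeline stages in order from the repository root (each stage
reads the previous stage's files from `results/`):

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_photocycle_fit.R
Rscript analysis/03_titration.R
Rscript analysis/04_photocurrents.R
Rscript analysis/05_structure_geometry.R
Rscript analysis/06_pore_pmf.R
```

The headline quantities are recomputed from scratch by

```sh
Rscript scripts/acceptance.R --seed 1 --out acceptance.json
```

which reports the two titration midpoints (mean fitted pKa over 20
seeded replicates at SNR 50): with seed 1, `t4 = 10.366` (Schiff base)
and `t5 = 3.325` (proton acceptor).

The test suite (`testthat`, 350+ assertions including property tests and
a per-criterion acceptance file) runs with:

```sh
Rscript -e 'testthat::test_dir("tests/testthat")'
```

Methods, conventions and their rationale (noise/averaging convention,
coincident-lifetime guard, PMF bulk definition, selectivity threshold,
stand-in structure) are documented in
`vignettes/pentarho-methods.Rmd`.
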