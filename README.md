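# hsqcdecon

Isotopomer deconvolution of 2D ¹H,¹³C HSQC NMR multiplets for stable-isotope
tracer metabolomics.

## The problem

In a [U-¹³C]-glucose tracer experiment — here, hypothermic machine perfusion
of kidneys with labelled glucose in the perfusate — de novo glycolytic
products such as lactate and alanine appear uniformly ¹³C-labelled, while the
pre-existing metabolite pool carries ¹³C only at the 1.1% natural abundance.
In a ¹H,¹³C HSQC spectrum only protonated ¹³C carbons give signal, and the
only resolved coupling in the ¹³C dimension is the one-bond ¹³C–¹³C scalar
coupling: a ¹³C observed next to ¹²C neighbours gives a singlet, next to one
¹³C neighbour a doublet of splitting ¹J(CC), and next to two ¹³C neighbours a
doublet of doublets. A measured multiplet is therefore a mixture of the
2^k neighbour-labelling components (k = coupled neighbours), and the mixture
proportions encode the fraction of molecules carrying the tracer.

This package provides that analysis end to end:

1. **Multiplet simulation** — first-order stick spectra per labelling
   pattern, convolved with a Lorentzian/Gaussian lineshape, equal-area
   normalised (`build_basis()`, `simulate_component()`).
2. **Deconvolution** — non-negative least-squares fit of a measured
   cross-section as component mixture plus polynomial baseline
   (`fit_multiplet()`).
3. **Enrichment** — inversion of the singlet (A_s) and fully coupled (A_f)
   component areas to the tracer mole fraction X under the two-population
   model, with p the ¹³C natural abundance:

       r = (A_f / A_s) · p · (1 − p)^k,   X = r / (1 + r)

   (`enrichment_from_components()`; an exact switch subtracts the p² = 0.0121%
   natural pair term).
4. **Absolute amounts** — total concentrations from 1D ¹H spectra by ratio
   quantification against an internal standard, multiplied by X and the
   sample volume (`quantify_1d()`, `labelled_amount()`).
5. **Time-course statistics** — mean ± SD per time point and pooled
   two-tailed Student's t tests between time points
   (`summarize_timecourse()`, `ttest_from_summary()`, `run_timecourse()`).
6. **Synthetic cohort** — a generator emulating a 6-kidney, 6/12/18/24 h
   perfusion experiment with known ground truth (`generate_cohort()`), so the
   whole pipeline is testable without instrument data.

## Worked example

The `analysis/` scripts run the full study on a simulated cohort:

```sh
Rscript analysis/01_simulate.R     # cohort -> scratch/cohort/
Rscript analysis/02_deconvolve.R   # fits + enrichment -> results/records.csv
Rscript analysis/03_timecourse.R   # summaries + t tests -> results/
Rscript analysis/04_validation.R   # reported-summary t tests, inversion check
```

With the default seed the time-course stage prints:

```
Per-time-point summaries (results/summary.csv):
  alanine   6 h:  1.07% +/- 0.30 (n=6)
  alanine  24 h:  2.34% +/- 0.81 (n=6)
  lactate   6 h:  3.28% +/- 1.19 (n=6)
  lactate  24 h:  7.79% +/- 1.86 (n=6)

6 h vs 24 h comparisons (results/tests.csv):
  lactate  enrichment_pct t= -5.02 df=10 p=0.00052 *
  lactate  labelled_nmol  t= -3.90 df=10 p=0.003 *
```

The recovered lactate enrichment means (3.28% at 6 h, 7.79% at 24 h) track
the generating trajectory (3.25% → 7.74%), and the 6 vs 24 h rise is
significant — the behaviour the method is designed to detect. The validation
stage checks the closed-form inversion against a 10⁷-molecule brute-force
simulation (relative error well under 1%) and recomputes the reported
summary-level t tests.

A minimal in-R session:

```r
library(hsqcdecon)
sys   <- builtin_spin_systems()
basis <- build_basis(sys$lactate, observed = 2)   # 4 components: s, d, d, dd
xs    <- read_cross_section("scratch/cohort/K01_T06_lactate_xs.tsv")
fit   <- fit_multiplet(xs, basis)
enrichment_from_components(fit)                   # fraction of [U-13C] lactate
```

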