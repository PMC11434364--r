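# urinmr

Urinary ¹H-NMR metabolomics for obesity phenotyping: a reproducible R
pipeline from raw free induction decays to biomarker cutoff statistics.

Cross-sectional metabolomics studies of obesity ask whether urinary
metabolite concentrations separate patients by adiposity — in particular
whether visceral fat above 16 kg can be predicted from urine. Answering that
requires a long chain of steps which published studies usually run through a
mix of vendor software, spreadsheets and ad-hoc scripts: spectral
processing, untargeted profiling, internal-standard quantification,
nonparametric group statistics and ROC cutoff analysis. `urinmr` implements
that chain as one tested, seeded package, together with a synthetic-cohort
generator that reproduces the statistical structure such studies assume —
so every stage is verifiable without access to patient data.

## The model in brief

* **Signal.** A FID is $s(t) = \sum_\ell a_\ell e^{2\pi i f_\ell t - t/T_2^*}$
  over the resonance lines of a 27-signal urine panel plus a TSP reference
  singlet (0.00 ppm, 9 protons), a broad residual-water hump and white
  noise; amplitudes are concentration × protons. Default acquisition:
  500 MHz, 16 ppm window, 65,536 points, 0.5 Hz exponential apodization.
* **Processing.** Apodize → FFT → automatic phasing (per-line local phases
  + weighted circular regression) → asymmetric-least-squares baseline →
  chemical-shift calibration on TSP.
* **Profiling.** 0.05 ppm binning with the residual-water region
  (4.65–4.95 ppm) excluded as exactly six masked bins; PCA of the
  mean-centred bin matrix.
* **Quantification.** Per-signal alignment (normalized cross-correlation,
  ±0.03 ppm) and window integration with a local linear baseline;
  concentrations in mg/mL of neat urine via
  $c = \frac{I_{met}}{I_{TSP}}\cdot\frac{9}{n_H}\cdot 0.58\,\mathrm{mM}
  \cdot \frac{700}{630}\cdot \frac{M}{1000}$.
* **Statistics.** Mann–Whitney (2 groups), Kruskal–Wallis + Dunn
  (3 groups), chi-square/Fisher, Spearman; empirical ROC with trapezoidal
  AUC (= U/(n₁n₀)), DeLong confidence interval, Youden-optimal cutoff, and
  predictive values at the sample prevalence.

The default synthetic cohort mirrors the modeled study: 75 subjects
(23 with visceral fat 9–16 kg, 52 above 16 kg), log-normal concentration
variation (CV 0.5), and fold-changes of 2.1 / 2.5 / 2.0 for sarcosine,
trigonelline and phenylalanine in the high-visceral-fat group.

## Worked example

```r
library(urinmr)

design <- cohort_design(acq = acq_params(n_points = 16384L),
                        t2_s = 0.15, seed = 42)
cohort  <- simulate_cohort(design)
spectra <- lapply(cohort$fids, process_fid)
lib     <- generate_metabolite_library()
conc    <- quantify_panel(spectra, lib, quant_config())
conc
#> <concentration_table> 75 samples x 27 signals (mg/mL)

labeled <- assign_groups(cohort$subjects)
vf <- run_group_tables(conc, labeled)$vf
vf[vf$metabolite %in% c("Sarcosine", "Trigonelline", "Phenylalanine"),
   c("metabolite", "mean_<=16", "mean_>16", "p_value")]
#>       metabolite mean_<=16 mean_>16  p_value
#> 15     Sarcosine   0.00391  0.00848 1.37e-05
#> 24 Phenylalanine   0.01596  0.02954 6.49e-06
#> 27  Trigonelline   0.01433  0.03459 2.75e-09

roc_analysis(conc$matrix[, "Sarcosine"], labeled$vf_group == ">16")
#> <roc_result> AUC 0.817 (0.719, 0.915), cutoff 0.006499: sens 63%, spec 91%, PPV 94%, NPV 52%
```

The three injected markers separate the visceral-fat groups (all
p < 0.05 by Mann–Whitney) while the 24 null metabolites do not, and the ROC
stage reports the cutoff maximizing Youden's J with its operating
characteristics. Concentrations are in mg/mL of neat urine; the group means
above reflect the simulated 2–3× fold-changes. The predictive-value helper
reproduces published accuracy arithmetic exactly — for a marker with 65%
sensitivity and 69% specificity in a 52/23 cohort:

```r
ppv_npv_from_accuracy(65, 69, 52L, 23L)[c("ppv", "npv")]
#> $ppv  [1] 83
#> $npv  [1] 47
```

A command-line front end (`exec/urinmr`) exposes `all`, `simulate`,
`process` and `quantify` subcommands over the same functions, with YAML
configuration and JCAMP-DX file I/O.

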