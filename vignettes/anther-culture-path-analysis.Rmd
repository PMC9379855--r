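---
title: "From band codes and spectra to regeneration efficiency: the andropath methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From band codes and spectra to regeneration efficiency: the andropath methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(andropath)
```

`andropath` implements the quantitative chain that links in vitro
anther-culture conditions to green plant regeneration efficiency (GPRE) in
cereals: scoring of methylation-sensitive AFLP (metAFLP) band profiles into
(epi)genetic event rates, extraction of a glutathione proxy from ATR-FTIR
spectra, and a maximum-likelihood path analysis tying copper supplementation,
CHH-context methylation dynamics and the thiol signal to GPRE. This vignette
explains the models and conventions behind each stage, the choices made where
more than one convention is defensible, and what the synthetic-data
generators do and do not emulate.

## 1. metAFLP event coding

Two AFLP platforms are run on the same DNA with the isoschizomers Acc65I and
KpnI, which share a recognition site but differ in methylation sensitivity:
KpnI cuts regardless of cytosine methylation, Acc65I is blocked by it. Band
presence/absence for the donor (D) and a regenerant (R) on both platforms
gives a four-digit code per locus, in the fixed order (Acc65I-D, Acc65I-R,
KpnI-D, KpnI-R).

The 16 possible codes are classified by applying the two enzyme rules
literally:

* the KpnI band tracks the *sequence* — `kD != kR` means the restriction
  site itself changed (sequence variation, SV);
* the Acc65I band means "present **and** unmethylated" — with the sequence
  intact in both plants, losing the Acc65I band in the regenerant is de novo
  methylation (DNMV) and gaining it is demethylation (DMV);
* an Acc65I band without the KpnI band in the same plant is physically
  contradictory (`INCONSISTENT`), and a locus with no band anywhere is
  `UNINFORMATIVE`.

This reconstruction is a design decision, not a copy of any published
spreadsheet: the original scoring scheme circulates as supplementary material
we treat as unavailable, so `classify_code()` takes a `table` argument (and
`metaflp_truth_table(reassign = ...)`) through which users can mirror an
alternative assignment. Percentages are computed over *informative* sites
(everything but `UNINFORMATIVE`); inconsistent codes stay in the denominator
but in no event class by default, with `inconsistent_as_sv = TRUE` as the
alternative reading, because whether published rates folded them into SV is
not decidable from the literature. Tissue-culture-induced variation is the
aggregate TCIV = SV% + DMV% + DNMV%.

Methylation context is read off the selective primer's 3' end: a `C-H-G`
suffix (H = A, C, T) marks CHG, a `CG` suffix marks CG, and a suffix of two
bases from {A, T} marks the asymmetric CHH context. Where suffixes overlap
(e.g. `CCG`), the longest match wins, so CHG takes precedence over CG.
Technical replicates of one plant are merged by logical OR before coding
("band seen in either sample"), with a strict AND option.

## 2. FTIR preprocessing and the thiol band

Spectra are absorbance versus wavenumber (cm^-1). The processing chain is:

1. **Baseline correction.** Default is the rubberband method (subtracting
   the lower convex hull), because the instrument vendor's baseline
   algorithm is proprietary; a linear-endpoints method and asymmetric least
   squares (second-difference penalty, `lambda = 1e5`, asymmetry `p = 0.01`)
   are available. No attempt is made to match the vendor software
   bit-for-bit.
2. **Unit-area normalization** over the 900-1800 cm^-1 fingerprint region:
   one scale factor, applied to the whole spectrum, so the thiol band at
   2540-2550 cm^-1 is measured on the normalized spectrum. Whether published
   integrals used normalized or raw spectra is not stated anywhere we could
   check; the normalized convention is the package default and the raw
   alternative is just `gsh_band()` without the normalization step.
3. **Binning**: absorbance summarized in successive 10 cm^-1 intervals over
   600-1780 and 2450-3700 cm^-1. The 1780-2450 cm^-1 region is excluded from
   all statistics (atmospheric CO2 and water-vapour interference). Bins are
   half-open `[lo, hi)` with the last bin of each window closed — a
   deterministic, gap-free tiling. "Summarized" is ambiguous, so
   `bin_10cm(stat = )` offers `integral` (default, trapezoid, units
   absorbance·cm^-1 — consistent with calling the feature an *integrated*
   absorbance), `sum` and `mean`.
4. **The glutathione proxy** is the trapezoid integral over 2540-2550
   cm^-1, the S-H stretching band that distinguishes reduced glutathione;
   window endpoints are interpolated onto the grid, so the integral is exact
   for piecewise-linear spectra and second-order accurate for smooth bands.
5. **Trial dispersion profiles**: spectra of one trial are interpolated to a
   common 1 cm^-1 grid and the pointwise SD/mean ratio is taken over
   2450-2800 cm^-1. Zero means give `NA`, never infinities; the ratio is
   invariant to common rescaling of the trial's spectra.

## 3. The path model and its ML fit

The observation table (`load_table1()`) has 37 regenerants from eight trials
(A-H) varying Cu(II) (0.1, 5, 10 uM), Ag(I) (0, 10, 60 uM) and culture time
(35, 42, 49 days), with CHH-context SV and DNMV percentages, the glutathione
band integral and GPRE. The model (`gpre_path_model()`) is a five-variable
recursive (acyclic, uncorrelated-residual) path diagram with Cu(II) as the
sole exogenous variable:

```
cu -> chh_dnmv -> chh_sv -> gpre
cu -> chh_sv; cu -> gsh -> gpre; cu -> gpre; chh_dnmv -> gpre
```

Eight coefficients, four residual variances and one exogenous variance give
13 free parameters against 15 distinct moments: 2 degrees of freedom. The
accompanying prose in the source literature calls CHH_DNMV exogenous and the
relations "non-recursive"; the diagram and every coefficient table say
otherwise, so the engine follows the diagram (and rejects cyclic edge sets
outright — only recursive models are in scope).

**Estimation.** With sample covariance S (n-1 denominator, which reproduces
the published variances exactly) the fit minimizes the Wishart ML
discrepancy

F(theta) = ln|Sigma(theta)| + tr(S Sigma(theta)^-1) - ln|S| - p,

where Sigma(theta) = (I-A)^-1 Psi (I-A)^-T. For this model class the
likelihood factorizes equation by equation, so the per-equation
least-squares solution is the exact ML optimum; `fit_ml()` starts there and
polishes with a quasi-Newton iteration (analytic gradient, convergence
declared below gradient norm 1e-8), which protects the generic case while
making the recursive case effectively closed-form. Because the raw variable
scales span five orders of magnitude (the band integral is ~0.005 while a
raw coefficient on it is ~750), optimization always runs on internally
unit-variance-rescaled variables; the back-transform is an exact diagonal
scale map, which is also how standard errors are mapped back
(`SE_raw = SE_std * |scale|`).

**Inference.** Standard errors come from the inverse of the Hessian of F at
the optimum, `acov = (2/m) H^-1` with multiplier `m = n - 1` (the
convention of the major SEM software; `m = n` is available). The Hessian is
the symmetrized finite-difference Jacobian of the analytic gradient. A
useful closed-form consequence, used as a test oracle: every
residual-variance critical ratio equals `sqrt(m/2)` (4.2426 at n = 37).
P-values are two-sided normal; no multiplicity adjustment is applied.
Standardized coefficients use model-implied SDs,
`beta = b * SD(source)/SD(target)`.

**Fit indices.** The chi-square is `m * F_min`; the independence baseline
(zero covariances, free variances — its ML solution is exactly `diag(S)`)
has `df_b = p(p-1)/2`. GFI/AGFI follow the trace formulas, RMR is the RMS
of raw covariance residuals and SRMR of correlation-metric residuals, both
over the p(p+1)/2 distinct moments; NFI, RFI, IFI, CFI, PNFI, PCFI and
RMSEA use their standard definitions. At df = 0, RMSEA and RFI are reported
as `NA` rather than 0/1 conventions.

**Effects.** Total effects are `(I-A)^-1 - I` — the convergent sum of
coefficient products over all directed routes, valid for any acyclic A —
computed on both scales. The reported total is constructed as
direct + indirect so additivity is exact in floating point, not just to
tolerance.

## 4. Synthetic data: what it does and does not emulate

Each stage has a generator so the full pipeline is testable without any
external download.

* `gen_marker_tables()` draws per-locus event classes at configured rates
  (defaults: the CHH/CHG/CG event levels observed in the triticale
  anther-culture study, e.g. CHH SV 8.65% and DNMV 0.58%), then a code
  uniformly within the class. Rates are defined as fractions of informative
  sites so the scoring stage recovers them directly; the uninformative
  fraction (default 0.1) and the inconsistency rate (default 0) are separate
  knobs. With several regenerants the donor band state is shared, which
  makes some classes impossible at some loci (you cannot de novo methylate
  an already methylated donor site) — rates are then exact in expectation
  only for the first regenerant. The generator does not model PCR or
  electrophoresis artifacts, comigration, or locus dependence.
* `gen_spectra()` builds leaf-like spectra as sums of Gaussian bands (broad
  O-H/N-H near 3324 cm^-1, C-H near 2920, Amide I at 1645, the 1399
  complex, carbohydrate fingerprint near 1048) plus an S-H band at 2545
  cm^-1, sinusoidal baseline drift and white noise. The S-H amplitude is
  calibrated analytically against the noiseless leaf background so that the
  normalized 2540-2550 integral equals the configured `gsh_level`; defaults
  are the per-trial means of the packaged table, so simulated features fall
  in the observed 0.004-0.006 range by construction. Real ATR effects
  (penetration-depth dependence, detector noise colour, water-vapour lines)
  are not modelled, so passing tests show the *pipeline arithmetic* is
  right, not that the feature is robust on any given instrument.
* `gen_sem_data()` draws the exogenous Cu(II) from the empirical design
  levels {0.1, 5, 10} uM (with the study's trial multiplicities via
  `table1_sem_config()`) and builds endogenous variables in topological
  order with Gaussian residuals — the reference case the asymptotic theory
  assumes; a variance-matched uniform option stresses that assumption. Rows
  are generated independently even though GPRE is constant within a trial
  in the real table, mirroring how the published analysis treated the 37
  records as independent observations.

## 5. Numerical conventions and degenerate inputs

* Covariance denominator n-1 and chi-square multiplier n-1, both
  configurable; skewness/kurtosis use the bias-corrected (SPSS/SAS type 2)
  formulas.
* Non-positive-definite S is rejected before fitting; during optimization a
  non-PD Sigma(theta) returns a large penalty value rather than an error.
* Variance parameters are bounded below at 1e-12 on the standardized scale.
* `quantify_variation()` errors on a context with no informative sites;
  `sd_mean_ratio()` flags zero-mean points as `NA`; empty spectral bins are
  flagged missing rather than zeroed; spectra acquired in descending
  wavenumber order are reoriented on read.
* Ties in context assignment resolve by longest suffix; ambiguous or
  unmatched primer extensions either error or (in the table pipeline) drop
  the locus with a QC record.

## 6. Problem sizes used in the shipped checks

The test suite exercises the OLS-oracle identity on 100 random recursive
models (p <= 5, n = 200), parameter recovery on 50 replicates of n = 5,000
drawn from the model fitted to the packaged table, marker round-trips at
10,000 sites plus 20 runs of 200,000 CHH sites against the published
per-regenerant ranges, and spectral checks on 0.01-0.5 cm^-1 grids. These
sizes were chosen so each property is tested well inside its asymptotic
regime while the whole suite stays quick on a laptop.

## 7. Known limitations

* Only observed-variable recursive models: no latent variables, mean
  structures, missing-data estimation, bootstrap intervals or modification
  indices.
* The classification truth table is a principled reconstruction; scoring
  schemes that treat inconsistent codes differently will shift SV/TCIV by
  up to the inconsistency rate.
* The published residual-variance rows of the source analysis are
  internally inconsistent with its own descriptive table, and one printed
  correlation and one test-statistic sign conflict with the printed path
  coefficients; the package follows the data and the coefficient tables,
  and the affected quantities are compared in magnitude where relevant.
* FTIR band integration assumes a locally resolved S-H band; in real leaf
  spectra the 2550 cm^-1 region is overlapped by O-H combination bands, so
  the feature is a proxy that should be validated chemically (enzymatic or
  MS assays) before quantitative use on new material.
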