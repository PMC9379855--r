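# andropath

Quantitative tools for linking in vitro anther-culture conditions to green
plant regeneration efficiency (GPRE) in cereals. The package implements the
three analysis stages used in triticale doubled-haploid studies:

1. **metAFLP scoring** — donor/regenerant AFLP band profiles from a
   methylation-sensitive / -insensitive isoschizomer pair (Acc65I vs KpnI)
   are encoded as 4-digit codes, classified into sequence variation (SV),
   demethylation (DMV) and de novo methylation (DNMV) events, and summarized
   as percentages per cytosine context (CG, CHG, CHH).
2. **ATR-FTIR preprocessing** — baseline correction, unit-area
   normalization over 900-1800 cm⁻¹, 10 cm⁻¹ binning, and the integrated
   2540-2550 cm⁻¹ S-H band, a proxy for reduced glutathione (GSH).
3. **Path analysis** — maximum-likelihood fitting of recursive
   observed-variable path models on a sample covariance matrix: for the
   coefficient matrix *A* and diagonal variance matrix *Ψ*,

   Σ(θ) = (I − A)⁻¹ Ψ (I − A)⁻ᵀ,
   F_ML(θ) = ln|Σ(θ)| + tr(S Σ(θ)⁻¹) − ln|S| − p,

   with χ² = (n−1)·F_min, asymptotic standard errors from the inverse
   information matrix, a standardized solution (β = b·SD(source)/SD(target)),
   the fit-index suite (GFI, AGFI, RMR, SRMR, NFI, RFI, IFI, CFI, PNFI,
   PCFI, RMSEA) and exact direct/indirect/total effect decomposition via
   (I − A)⁻¹ − I.

The packaged 37-regenerant observation table (`load_table1()`) carries the
study design — Cu(II) at 0.1/5/10 µM, Ag(I) at 0/10/60 µM, culture time
35/42/49 days across trials A-H — together with CHH_SV, CHH_DNMV, the GSH
band integral and GPRE. Synthetic-data generators for all three stages make
every pipeline step testable without external data.

## Worked example

```r
library(andropath)

tab   <- load_table1()
model <- gpre_path_model()        # cu -> {chh_dnmv, chh_sv, gsh, gpre}, 8 paths
mom   <- sample_moments(tab, model$variables)
fit   <- fit_ml(model, mom)

fit_indices(fit)[c("chi2", "df", "p_value", "gfi", "srmr", "cfi", "rmsea")]
#>     chi2 df p_value    gfi   srmr cfi rmsea
#>   0.1101  2  0.9465 0.9988 0.0139   1     0
```

The model fits the 15 observed moments with 13 free parameters almost
perfectly: χ²(2) = 0.11, p = 0.95, SRMR = 0.014. The coefficients:

```r
standard_errors(fit)[1:8, ]
#>          parameter estimate       se critical_ratio p_value
#> 1     cu->chh_dnmv   0.0123   0.0060         2.0256  0.0428
#> 2 chh_dnmv->chh_sv   0.3457   0.1230         2.8115  0.0049
#> 3       cu->chh_sv  -0.0166   0.0047        -3.5252  0.0004
#> 4          cu->gsh   0.0000   0.0000         2.5029  0.0123
#> 5         cu->gpre   0.4247   0.0471         9.0086  0.0000
#> 6     chh_sv->gpre   2.4776   1.3684         1.8106  0.0702
#> 7   chh_dnmv->gpre  -4.3996   1.1164        -3.9410  0.0001
#> 8        gsh->gpre 752.0313 334.5606         2.2478  0.0246
```

Every microMolar of Cu(II) adds ~0.42 green regenerants per 100 anthers
directly (standardized β = 0.913), raises de novo CHH methylation and the
GSH signal, and lowers CHH sequence variation; the GSH band carries a large
raw coefficient only because the integral is ~0.005 in absolute units
(β = 0.19). Decomposing effects:

```r
eff <- decompose_effects(fit)
eff[eff$source == "cu" & eff$target == "gpre",
    c("direct_beta", "indirect_beta", "total_beta")]
#>   direct_beta indirect_beta total_beta
#>        0.9131       -0.1078     0.8053
```

so the net standardized effect of Cu(II) on regeneration efficiency is
0.805: a strong positive direct effect, slightly offset through the
methylation/GSH channels. `run_reproduction()` executes all stages
(descriptives, correlations, fit, indices, effects) in one call and can
write the full TSV/JSON report.

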