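# Synthetic-data generators for the three analysis stages: metAFLP marker
# tables, ATR-FTIR spectra, and multivariate observations drawn from a
# recursive path model. All generators are deterministic given the seed in
# their config.

.codes_by_class <- function() {
  tab <- metaflp_truth_table()
  split(names(tab), unname(tab))
}

#' Configuration for the marker-table generator
#'
#' Event rates are fractions of *informative* sites (the denominator used by
#' [quantify_variation()]), so a round-trip through the scoring stage
#' recovers them directly. Defaults are the per-context event levels
#' observed in triticale anther-culture regenerants (CHH: SV 8.65%, DNMV
#' 0.58%; CHG: SV 23.64%, DMV 2.90%, DNMV 1.82%; CG: SV 11.66%, DMV 1.42%,
#' DNMV 1.10%).
#'
#' @param seed integer seed.
#' @param n_sites named integer vector of loci per context.
#' @param rates named list per context, each with `sv`, `dmv`, `dnmv`.
#' @param inconsistent_rate fraction of informative sites drawn as
#'   physically inconsistent codes (default 0).
#' @param uninformative fraction of sites with no band anywhere (0000).
#' @param meth_fraction among no-change sites, the fraction scored as
#'   methylated (0011) rather than unmethylated (1111).
#' @param n_regenerants number of regenerant columns.
#' @return A `marker_config` list.
#' @export
marker_config <- function(seed = 1L,
                          n_sites = c(CG = 1000L, CHG = 1000L, CHH = 1000L),
                          rates = list(
                            CG  = c(sv = 0.1166, dmv = 0.0142, dnmv = 0.0110),
                            CHG = c(sv = 0.2364, dmv = 0.0290, dnmv = 0.0182),
                            CHH = c(sv = 0.0865, dmv = 0.0000, dnmv = 0.0058)),
                          inconsistent_rate = 0,
                          uninformative = 0.1,
                          meth_fraction = 0.3,
                          n_regenerants = 1L) {
  for (cc in names(rates)) {
    r <- rates[[cc]]
    if (any(r < 0) || any(r > 1) || sum(r) + inconsistent_rate > 1)
      stop("event rates must lie in [0,1] and sum to <= 1 per context",
           call. = FALSE)
  }
  if (uninformative < 0 || uninformative >= 1)
    stop("uninformative fraction must be in [0,1)", call. = FALSE)
  structure(list(seed = as.integer(seed), n_sites = n_sites, rates = rates,
                 inconsistent_rate = inconsistent_rate,
                 uninformative = uninformative,
                 meth_fraction = meth_fraction,
                 n_regenerants = as.integer(n_regenerants)),
            class = "marker_config")
}

.ext_for_context <- function(context, k, rng_ok = TRUE) {
  pool <- switch(context,
                 CHH = c("AA", "AT", "TA", "TT"),
                 CHG = c("CAG", "CTG", "CCG"),
                 CG  = c("ACG", "TCG", "GCG"))
  sample(pool, k, replace = TRUE)
}

#' Generate a donor/regenerant metAFLP marker table
#'
#' Each locus is assigned a context (via its selective-primer extension) and
#' a 4-digit donor/regenerant code drawn by event class from the
#' classification truth table. With several regenerants, the donor band
#' state fixed by the first regenerant's code constrains the codes available
#' to the others (e.g. de novo methylation requires an unmethylated donor
#' site), so configured rates are exact in expectation only for the first
#' regenerant.
#'
#' @param cfg a [marker_config()].
#' @return A `marker_table` (see [read_marker_table()]) with donor column
#'   `D` and regenerant columns `R1`, `R2`, ...; the drawn codes are kept in
#'   attribute `codes` (one matrix per context, sites x regenerants).
#' @export
gen_marker_tables <- function(cfg) {
  stopifnot(inherits(cfg, "marker_config"))
  set.seed(cfg$seed)
  by_class <- .codes_by_class()
  rows <- list(); code_store <- list()
  for (cc in names(cfg$n_sites)) {
    n <- cfg$n_sites[[cc]]
    r <- cfg$rates[[cc]]
    u <- cfg$uninformative
    p_nc <- (1 - u) * (1 - sum(r) - cfg$inconsistent_rate)
    probs <- c(UNINFORMATIVE = u,
               SV = (1 - u) * r[["sv"]],
               DMV = (1 - u) * r[["dmv"]],
               DNMV = (1 - u) * r[["dnmv"]],
               INCONSISTENT = (1 - u) * cfg$inconsistent_rate,
               NO_CHANGE_UNMETHYLATED = p_nc * (1 - cfg$meth_fraction),
               NO_CHANGE_METHYLATED = p_nc * cfg$meth_fraction)
    cls <- sample(names(probs), n, replace = TRUE, prob = probs)
    code1 <- character(n)
    for (k in unique(cls)) {
      idx <- cls == k
      pool <- by_class[[k]]
      code1[idx] <- if (length(pool) == 1L) pool
                    else sample(pool, sum(idx), replace = TRUE)
    }
    codes <- matrix("", n, cfg$n_regenerants)
    codes[, 1] <- code1
    if (cfg$n_regenerants > 1L) {
      donor_bits <- paste0(substr(code1, 1, 1), substr(code1, 3, 3))
      for (j in 2:cfg$n_regenerants) {
        cls_j <- sample(names(probs), n, replace = TRUE, prob = probs)
        codes[, j] <- vapply(seq_len(n), function(i) {
          pool <- by_class[[cls_j[i]]]
          ok <- pool[paste0(substr(pool, 1, 1), substr(pool, 3, 3)) ==
                       donor_bits[i]]
          if (!length(ok))   # class impossible for this donor state
            ok <- switch(donor_bits[i], "11" = "1111", "01" = "0011",
                         "00" = "0000", "10" = "1010")
          if (length(ok) == 1L) ok else sample(ok, 1L)
        }, character(1))
      }
    }
    code_store[[cc]] <- codes
    ext <- .ext_for_context(cc, n)
    ids <- sprintf("%s_%04d", cc, seq_len(n))
    bit <- function(m, pos) matrix(as.integer(substr(m, pos, pos)), nrow(m))
    acc <- data.frame(locus_id = ids, platform = "ACC",
                      primer_extension = ext,
                      D = bit(codes, 1)[, 1],
                      stringsAsFactors = FALSE)
    kpn <- data.frame(locus_id = ids, platform = "KPN",
                      primer_extension = ext,
                      D = bit(codes, 3)[, 1],
                      stringsAsFactors = FALSE)
    for (j in seq_len(cfg$n_regenerants)) {
      acc[[paste0("R", j)]] <- as.integer(substr(codes[, j], 2, 2))
      kpn[[paste0("R", j)]] <- as.integer(substr(codes[, j], 4, 4))
    }
    rows[[cc]] <- rbind(acc, kpn)
  }
  out <- as_marker_table(do.call(rbind, c(rows, make.row.names = FALSE)))
  attr(out, "codes") <- code_store
  out
}

#' Configuration for the FTIR spectrum generator
#'
#' Emulates leaf ATR-FTIR spectra as a sum of Gaussian bands (broad O-H/N-H
#' and C-H stretches around 3324 and 2920 cm^-1, Amide I at 1645 cm^-1, the
#' 1399 cm^-1 complex and the carbohydrate fingerprint peaking at
#' 1048 cm^-1) plus a thiol S-H band at 2545 cm^-1, slow baseline drift and
#' white noise. `gsh_level` is the target integrated absorbance of the
#' 2540-2550 cm^-1 band on the unit-area-normalized spectrum; the S-H
#' amplitude is calibrated analytically against the noiseless leaf spectrum
#' so that the extracted feature matches it. Default levels are the
#' per-trial means of the packaged observation table.
#'
#' @param seed integer seed.
#' @param gsh_level named numeric vector, one level per trial (defaults to
#'   the per-trial means of [load_table1()]).
#' @param n_per_trial named integer vector of spectra per trial (defaults to
#'   the study's trial multiplicities).
#' @param grid_range,grid_step wavenumber grid, cm^-1.
#' @param leaf_bands data frame `center`, `sigma`, `amplitude`.
#' @param sh_center,sh_sigma S-H band position and width, cm^-1.
#' @param noise_sd white-noise SD (raw absorbance units).
#' @param drift_amplitude amplitude of the slow sinusoidal baseline drift.
#' @param level_cv between-spectrum coefficient of variation of the trial's
#'   thiol level.
#' @return A `spectra_config` list.
#' @export
spectra_config <- function(seed = 1L,
                           gsh_level = NULL,
                           n_per_trial = NULL,
                           grid_range = c(600, 4000), grid_step = 1,
                           leaf_bands = data.frame(
                             center = c(3324, 2920, 1645, 1399, 1048, 1160),
                             sigma  = c(180, 60, 45, 40, 55, 30),
                             amplitude = c(0.45, 0.18, 0.45, 0.30, 0.60, 0.25)),
                           sh_center = 2545, sh_sigma = 6,
                           noise_sd = 1e-4, drift_amplitude = 0.002,
                           level_cv = 0.08) {
  tab <- load_table1()
  if (is.null(gsh_level))
    gsh_level <- tapply(tab$gsh, tab$trial, mean)
  if (is.null(n_per_trial))
    n_per_trial <- table(tab$trial)
  if (any(leaf_bands$sigma <= 0) || sh_sigma <= 0)
    stop("band widths must be positive", call. = FALSE)
  structure(list(seed = as.integer(seed),
                 gsh_level = gsh_level,
                 n_per_trial = as.integer(n_per_trial) |>
                   stats::setNames(names(n_per_trial)),
                 grid_range = grid_range, grid_step = grid_step,
                 leaf_bands = leaf_bands,
                 sh_center = sh_center, sh_sigma = sh_sigma,
                 noise_sd = noise_sd, drift_amplitude = drift_amplitude,
                 level_cv = level_cv),
            class = "spectra_config")
}

.gauss <- function(w, center, sigma, amplitude)
  amplitude * exp(-(w - center)^2 / (2 * sigma^2))

#' Generate per-trial ATR-FTIR spectra
#'
#' @param cfg a [spectra_config()].
#' @return Named list (one element per trial) of lists of [ftir_spectrum()]
#'   objects.
#' @export
gen_spectra <- function(cfg) {
  stopifnot(inherits(cfg, "spectra_config"))
  set.seed(cfg$seed)
  w <- seq(cfg$grid_range[1], cfg$grid_range[2], by = cfg$grid_step)
  leaf <- rowSums(mapply(.gauss, cfg$leaf_bands$center, cfg$leaf_bands$sigma,
                         cfg$leaf_bands$amplitude, MoreArgs = list(w = w)))
  # calibration: unit-amplitude S-H band integral over [2540, 2550] and the
  # fingerprint area of the noiseless leaf spectrum
  base_spec <- ftir_spectrum(w, leaf)
  area_f <- .trapz_window(base_spec, 900, 1800)
  sh_unit <- cfg$sh_sigma * sqrt(2 * pi) *
    (stats::pnorm((2550 - cfg$sh_center) / cfg$sh_sigma) -
     stats::pnorm((2540 - cfg$sh_center) / cfg$sh_sigma))
  out <- list()
  for (tr in names(cfg$n_per_trial)) {
    k <- cfg$n_per_trial[[tr]]
    lev <- cfg$gsh_level[[tr]]
    out[[tr]] <- lapply(seq_len(k), function(i) {
      lev_i <- lev * max(0, 1 + stats::rnorm(1, 0, cfg$level_cv))
      amp_sh <- lev_i * area_f / sh_unit
      drift <- cfg$drift_amplitude *
        sin(2 * pi * (w - cfg$grid_range[1]) /
              diff(cfg$grid_range) * stats::runif(1, 0.5, 1.5) +
            stats::runif(1, 0, 2 * pi))
      a <- leaf + .gauss(w, cfg$sh_center, cfg$sh_sigma, amp_sh) +
        drift + stats::rnorm(length(w), 0, cfg$noise_sd)
      ftir_spectrum(w, a, provenance = sprintf("sim:trial%s#%d", tr, i))
    })
    names(out[[tr]]) <- sprintf("%s_%02d", tr, seq_len(k))
  }
  out
}

#' Configuration for the path-model data generator
#'
#' @param seed integer seed.
#' @param model a [path_model()].
#' @param coefficients named numeric vector over the model's paths
#'   (`"source->target"`).
#' @param residual_vars named numeric vector over endogenous variables.
#' @param exogenous named list: for each exogenous variable, the pool of
#'   values sampled (with replacement) for each record.
#' @param intercepts optional named numeric vector (default all zero).
#' @param n number of records.
#' @param residual_dist `"normal"` (reference case) or `"uniform"`
#'   (variance-matched, to stress distributional robustness).
#' @return A `sem_config` list.
#' @export
sem_config <- function(seed = 1L, model, coefficients, residual_vars,
                       exogenous, intercepts = NULL, n = 200L,
                       residual_dist = c("normal", "uniform")) {
  stopifnot(inherits(model, "path_model"))
  residual_dist <- match.arg(residual_dist)
  path_names <- paste0(model$paths$source, "->", model$paths$target)
  if (!setequal(names(coefficients), path_names))
    stop("coefficients must be named by the model's paths", call. = FALSE)
  if (!setequal(names(residual_vars), model$endogenous))
    stop("residual_vars must be named by the endogenous variables",
         call. = FALSE)
  if (any(residual_vars <= 0)) stop("residual variances must be positive",
                                    call. = FALSE)
  if (!setequal(names(exogenous), model$exogenous))
    stop("exogenous pools must be named by the exogenous variables",
         call. = FALSE)
  if (is.null(intercepts))
    intercepts <- stats::setNames(numeric(length(model$endogenous)),
                                  model$endogenous)
  if (n < 2L) stop("n must be >= 2", call. = FALSE)
  structure(list(seed = as.integer(seed), model = model,
                 coefficients = coefficients, residual_vars = residual_vars,
                 exogenous = exogenous, intercepts = intercepts,
                 n = as.integer(n), residual_dist = residual_dist),
            class = "sem_config")
}

#' Generate observations from a recursive path model
#'
#' Exogenous variables are sampled from their configured value pools;
#' endogenous variables are built in topological order as linear
#' combinations of their parents plus independent residuals.
#'
#' @param cfg a [sem_config()].
#' @return Data frame with one column per model variable and `cfg$n` rows.
#' @export
gen_sem_data <- function(cfg) {
  stopifnot(inherits(cfg, "sem_config"))
  set.seed(cfg$seed)
  model <- cfg$model
  n <- cfg$n
  d <- as.data.frame(matrix(NA_real_, n, length(model$variables),
                            dimnames = list(NULL, model$variables)))
  for (x in model$exogenous)
    d[[x]] <- sample(cfg$exogenous[[x]], n, replace = TRUE)
  rres <- switch(cfg$residual_dist,
                 normal = function(k, v) stats::rnorm(k, 0, sqrt(v)),
                 uniform = function(k, v)
                   stats::runif(k, -sqrt(3 * v), sqrt(3 * v)))
  for (y in intersect(model$order, model$endogenous)) {
    parents <- model$paths$source[model$paths$target == y]
    b <- cfg$coefficients[paste0(parents, "->", y)]
    d[[y]] <- cfg$intercepts[[y]] +
      as.matrix(d[parents]) %*% b + rres(n, cfg$residual_vars[[y]])
  }
  d
}

#' Path-model generator config calibrated to the packaged study
#'
#' Fits the anther-culture model ([gpre_path_model()]) to the packaged
#' observation table and returns a [sem_config()] whose coefficients,
#' residual variances and exogenous Cu(II) pool reproduce the fitted model,
#' with intercepts chosen to match the observed means.
#'
#' @param seed integer seed.
#' @param n number of records to generate.
#' @return A `sem_config`.
#' @export
table1_sem_config <- function(seed = 1L, n = 5000L) {
  tab <- load_table1()
  model <- gpre_path_model()
  mom <- sample_moments(tab, model$variables)
  fit <- fit_ml(model, mom)
  path_names <- paste0(model$paths$source, "->", model$paths$target)
  coefs <- fit$theta[path_names]
  psis <- stats::setNames(fit$theta[paste0("psi:", model$endogenous)],
                          model$endogenous)
  # intercepts so that generated means match the observed means
  mu <- mom$means
  icpt <- vapply(model$endogenous, function(y) {
    parents <- model$paths$source[model$paths$target == y]
    b <- coefs[paste0(parents, "->", y)]
    unname(mu[y] - sum(b * mu[parents]))
  }, numeric(1))
  sem_config(seed = seed, model = model, coefficients = coefs,
             residual_vars = psis,
             exogenous = list(cu = tab$cu),
             intercepts = icpt, n = n)
}
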