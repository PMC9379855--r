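# ATR-FTIR spectral preprocessing and band quantification.

#' Construct a spectrum object
#'
#' @param wavenumber numeric vector, cm^-1; stored in increasing order.
#' @param absorbance numeric vector of the same length, finite.
#' @param provenance character vector of processing-step labels.
#' @return Object of class `spectrum`: list with `wavenumber`, `absorbance`,
#'   `provenance`.
#' @export
ftir_spectrum <- function(wavenumber, absorbance, provenance = character()) {
  if (length(wavenumber) != length(absorbance))
    stop("wavenumber and absorbance must have equal length", call. = FALSE)
  if (length(wavenumber) < 2L)
    stop("a spectrum needs at least 2 points", call. = FALSE)
  if (!all(is.finite(wavenumber)) || !all(is.finite(absorbance)))
    stop("spectrum values must be finite", call. = FALSE)
  o <- order(wavenumber)
  wavenumber <- wavenumber[o]; absorbance <- absorbance[o]
  if (any(diff(wavenumber) == 0))
    stop("duplicate wavenumbers", call. = FALSE)
  structure(list(wavenumber = wavenumber, absorbance = absorbance,
                 provenance = provenance),
            class = "spectrum")
}

#' @export
print.spectrum <- function(x, ...) {
  cat(sprintf("<spectrum> %d points, %.1f-%.1f cm-1\n",
              length(x$wavenumber), min(x$wavenumber), max(x$wavenumber)))
  if (length(x$provenance))
    cat("  processing:", paste(x$provenance, collapse = " -> "), "\n")
  invisible(x)
}

# Trapezoid integral of a spectrum over [lo, hi], interpolating the window
# endpoints onto the grid. Errors if the grid does not cover the window.
.trapz_window <- function(s, lo, hi) {
  w <- s$wavenumber; a <- s$absorbance
  if (lo < w[1] || hi > w[length(w)])
    stop(sprintf("grid (%.1f-%.1f) does not cover window [%g, %g]",
                 w[1], w[length(w)], lo, hi), call. = FALSE)
  inside <- w > lo & w < hi
  wi <- c(lo, w[inside], hi)
  ai <- c(stats::approx(w, a, lo)$y, a[inside], stats::approx(w, a, hi)$y)
  sum(diff(wi) * (ai[-1] + ai[-length(ai)]) / 2)
}

#' Read a spectrum from delimited text or JCAMP-DX
#'
#' Two-column delimited files (wavenumber, absorbance; comma, tab or
#' whitespace separated, optional header) and minimal JCAMP-DX
#' (`XYDATA=(X++(Y..Y))` in AFFN form, or `XYPOINTS`/`PEAK TABLE`
#' `(XY..XY)`) are supported. Wavenumbers are returned in increasing order
#' regardless of acquisition direction.
#'
#' @param path file path.
#' @param dialect `"auto"` (default; JCAMP detected from `##TITLE=`),
#'   `"delim"` or `"jcamp"`.
#' @return A [ftir_spectrum()] with provenance initialized to the file name.
#' @export
read_spectrum <- function(path, dialect = c("auto", "delim", "jcamp")) {
  dialect <- match.arg(dialect)
  lines <- readLines(path, warn = FALSE)
  if (dialect == "auto")
    dialect <- if (any(grepl("^##TITLE=", lines[seq_len(min(5, length(lines)))])))
      "jcamp" else "delim"
  xy <- if (dialect == "jcamp") .parse_jcamp(lines, path)
        else .parse_delim_spectrum(lines, path)
  ftir_spectrum(xy$x, xy$y, provenance = paste0("read:", basename(path)))
}

.parse_delim_spectrum <- function(lines, path) {
  lines <- lines[nzchar(trimws(lines))]
  split1 <- strsplit(trimws(lines), "[,;\t ]+")
  first <- suppressWarnings(as.numeric(split1[[1]]))
  if (anyNA(first)) { lines <- lines[-1]; split1 <- split1[-1] }  # header row
  x <- y <- numeric(length(split1))
  for (i in seq_along(split1)) {
    v <- suppressWarnings(as.numeric(split1[[i]]))
    if (length(v) < 2 || anyNA(v[1:2]))
      stop(sprintf("%s: non-numeric spectrum row at line %d", path, i),
           call. = FALSE)
    x[i] <- v[1]; y[i] <- v[2]
  }
  if (anyDuplicated(x))
    stop(sprintf("%s: duplicate wavenumber %g", path, x[anyDuplicated(x)]),
         call. = FALSE)
  list(x = x, y = y)
}

# Minimal JCAMP-DX reader: AFFN (plain numeric) tables only.
.parse_jcamp <- function(lines, path) {
  ldr <- function(key) {
    hit <- grep(paste0("^##", key, "="), lines, value = TRUE)
    if (!length(hit)) return(NA_character_)
    sub(paste0("^##", key, "="), "", hit[1])
  }
  num <- function(key) suppressWarnings(as.numeric(ldr(key)))
  start <- grep("^##(XYDATA|XYPOINTS|PEAK TABLE)=", lines)
  if (!length(start)) stop(path, ": no XYDATA/XYPOINTS block", call. = FALSE)
  kind <- sub("^##([A-Z ]+)=.*$", "\\1", lines[start[1]])
  body <- lines[(start[1] + 1):length(lines)]
  end <- grep("^##", body)
  if (length(end)) body <- body[seq_len(end[1] - 1)]
  body <- body[nzchar(trimws(body))]
  xf <- num("XFACTOR"); yf <- num("YFACTOR")
  if (is.na(xf)) xf <- 1; if (is.na(yf)) yf <- 1
  if (kind == "XYDATA") {
    # (X++(Y..Y)): each line starts with an X value, then Y values
    rows <- strsplit(trimws(body), "[,; \t]+")
    xs <- ys <- list()
    npts <- num("NPOINTS")
    deltax <- num("DELTAX")
    if (is.na(deltax) && !is.na(npts) && npts > 1)
      deltax <- (num("LASTX") - num("FIRSTX")) / (npts - 1)
    for (r in rows) {
      v <- suppressWarnings(as.numeric(r))
      if (anyNA(v)) stop(path, ": non-AFFN JCAMP data", call. = FALSE)
      yr <- v[-1]
      xs[[length(xs) + 1]] <- v[1] + deltax * (seq_along(yr) - 1)
      ys[[length(ys) + 1]] <- yr
    }
    list(x = unlist(xs) * xf, y = unlist(ys) * yf)
  } else {
    v <- suppressWarnings(as.numeric(unlist(strsplit(trimws(body), "[,; \t]+"))))
    if (anyNA(v) || length(v) %% 2 != 0)
      stop(path, ": malformed XY table", call. = FALSE)
    list(x = v[seq(1, length(v), 2)] * xf, y = v[seq(2, length(v), 2)] * yf)
  }
}

#' Write a spectrum as two-column CSV
#'
#' @param s a [ftir_spectrum()].
#' @param path output file.
#' @export
write_spectrum <- function(s, path) {
  stopifnot(inherits(s, "spectrum"))
  utils::write.table(
    data.frame(wavenumber = s$wavenumber, absorbance = s$absorbance),
    path, sep = ",", row.names = FALSE, col.names = TRUE, quote = FALSE)
  invisible(path)
}

#' Baseline-correct a spectrum
#'
#' @param s a [ftir_spectrum()].
#' @param method `"rubberband"` (default; subtracts the lower convex hull),
#'   `"linear"` (line through the first and last point) or `"asls"`
#'   (asymmetric least squares, Eilers-style second-difference penalty).
#' @param lambda,p,maxit asls smoothing penalty, asymmetry weight and
#'   iteration cap.
#' @return Corrected [ftir_spectrum()] with provenance appended.
#' @export
baseline_correct <- function(s, method = c("rubberband", "linear", "asls"),
                             lambda = 1e5, p = 0.01, maxit = 20) {
  stopifnot(inherits(s, "spectrum"))
  method <- match.arg(method)
  w <- s$wavenumber; a <- s$absorbance; n <- length(w)
  if (n < 3L) stop("baseline correction needs >= 3 points", call. = FALSE)
  base <- switch(method,
    linear = a[1] + (a[n] - a[1]) * (w - w[1]) / (w[n] - w[1]),
    rubberband = {
      hull <- .lower_hull(w, a)
      stats::approx(w[hull], a[hull], w)$y
    },
    asls = .asls_baseline(a, lambda = lambda, p = p, maxit = maxit)
  )
  ftir_spectrum(w, a - base,
           provenance = c(s$provenance, paste0("baseline:", method)))
}

# Andrew monotone-chain lower convex hull; x assumed strictly increasing.
.lower_hull <- function(x, y) {
  stack <- integer(0)
  for (i in seq_along(x)) {
    while (length(stack) >= 2) {
      j <- stack[length(stack)]; k <- stack[length(stack) - 1]
      # pop j if it lies on or above the chord k -> i
      if ((x[j] - x[k]) * (y[i] - y[k]) - (y[j] - y[k]) * (x[i] - x[k]) <= 0)
        stack <- stack[-length(stack)]
      else break
    }
    stack <- c(stack, i)
  }
  stack
}

.asls_baseline <- function(y, lambda, p, maxit) {
  n <- length(y)
  D <- Matrix::bandSparse(n - 2, n, k = 0:2,
                          diagonals = list(rep(1, n - 2), rep(-2, n - 2),
                                           rep(1, n - 2)))
  P <- lambda * Matrix::crossprod(D)
  wgt <- rep(1, n)
  z <- y
  for (i in seq_len(maxit)) {
    W <- Matrix::Diagonal(n, wgt)
    z <- as.numeric(Matrix::solve(W + P, wgt * y))
    wnew <- ifelse(y > z, p, 1 - p)
    if (all(wnew == wgt)) break
    wgt <- wnew
  }
  z
}

#' Normalize a spectrum to unit area over a window
#'
#' Scales the whole spectrum by one factor so that the trapezoid area over
#' the given window (default the 900-1800 cm^-1 fingerprint region) equals 1.
#' Idempotent and invariant to multiplicative rescaling of the input.
#'
#' @param s a [ftir_spectrum()].
#' @param window numeric length-2, cm^-1.
#' @return Normalized [ftir_spectrum()].
#' @export
normalize_unit_area <- function(s, window = c(900, 1800)) {
  stopifnot(inherits(s, "spectrum"), length(window) == 2)
  window <- sort(window)
  area <- .trapz_window(s, window[1], window[2])
  if (!is.finite(area) || area <= 0)
    stop("non-positive area over normalization window", call. = FALSE)
  ftir_spectrum(s$wavenumber, s$absorbance / area,
           provenance = c(s$provenance,
                          sprintf("normalize:unit-area[%g,%g]",
                                  window[1], window[2])))
}

#' Summarize a spectrum in successive 10 cm^-1 bins
#'
#' Bins cover 600-1780 and 2450-3700 cm^-1 by default; the 1780-2450 cm^-1
#' region (atmospheric CO2 / water-vapour interference) carries no bins.
#' Bins are half-open `[lo, hi)` with the final bin of each window closed.
#'
#' @param s a [ftir_spectrum()].
#' @param windows list of length-2 numeric windows to tile.
#' @param width bin width in cm^-1.
#' @param stat summarization rule: `"integral"` (trapezoid over the bin,
#'   default), `"sum"` or `"mean"` of the points falling in the bin.
#' @return A `binned_spectrum` data frame with columns `lo`, `hi`, `value`,
#'   `n_points`. Bins not covered by the grid have `value = NA` and are
#'   listed in the `missing_bins` attribute.
#' @export
bin_10cm <- function(s, windows = list(c(600, 1780), c(2450, 3700)),
                     width = 10, stat = c("integral", "sum", "mean")) {
  stopifnot(inherits(s, "spectrum"))
  stat <- match.arg(stat)
  w <- s$wavenumber; a <- s$absorbance
  out <- do.call(rbind, lapply(windows, function(win) {
    lo <- seq(win[1], win[2] - width, by = width)
    data.frame(lo = lo, hi = lo + width)
  }))
  out$value <- NA_real_
  out$n_points <- 0L
  last_hi <- vapply(windows, function(win) win[2], numeric(1))
  for (i in seq_len(nrow(out))) {
    closed <- out$hi[i] %in% last_hi
    inbin <- w >= out$lo[i] & (if (closed) w <= out$hi[i] else w < out$hi[i])
    out$n_points[i] <- sum(inbin)
    covered <- out$lo[i] >= w[1] && out$hi[i] <= w[length(w)]
    if (!covered) next
    out$value[i] <- switch(stat,
      integral = .trapz_window(s, out$lo[i], out$hi[i]),
      sum = sum(a[inbin]),
      mean = if (any(inbin)) mean(a[inbin]) else NA_real_)
  }
  attr(out, "missing_bins") <- which(is.na(out$value))
  attr(out, "stat") <- stat
  class(out) <- c("binned_spectrum", class(out))
  out
}

#' Integrated thiol (glutathione) band
#'
#' Trapezoid integral of the absorbance over the 2540-2550 cm^-1 range, the
#' S-H stretching band that distinguishes reduced glutathione. Conventionally
#' computed on the area-normalized spectrum (see [normalize_unit_area()]).
#'
#' @param s a [ftir_spectrum()].
#' @param band numeric length-2 integration limits, cm^-1.
#' @return Scalar integrated absorbance (absorbance * cm^-1).
#' @export
gsh_band <- function(s, band = c(2540, 2550)) {
  stopifnot(inherits(s, "spectrum"), length(band) == 2)
  band <- sort(band)
  .trapz_window(s, band[1], band[2])
}

#' Pointwise SD/mean ratio across the spectra of a trial
#'
#' Spectra are interpolated to a common grid (default 1 cm^-1) over the
#' window, then the pointwise standard deviation (n-1 denominator) is divided
#' by the pointwise mean. Points with zero mean are returned as `NA`.
#'
#' @param spectra list of [ftir_spectrum()] objects (>= 2), e.g. one trial's
#'   regenerants.
#' @param window numeric length-2 window, cm^-1 (default 2450-2800, the
#'   thiol region).
#' @param grid_step common-grid spacing, cm^-1.
#' @return Data frame with columns `wavenumber`, `mean`, `sd`, `ratio`.
#' @export
sd_mean_ratio <- function(spectra, window = c(2450, 2800), grid_step = 1) {
  if (!is.list(spectra) || length(spectra) < 2L ||
      !all(vapply(spectra, inherits, logical(1), "spectrum")))
    stop("need a list of >= 2 spectrum objects", call. = FALSE)
  window <- sort(window)
  lo <- max(window[1], max(vapply(spectra, function(s) s$wavenumber[1], 1)))
  hi <- min(window[2],
            min(vapply(spectra, function(s) max(s$wavenumber), 1)))
  if (hi <= lo) stop("window not covered by all spectra", call. = FALSE)
  grid <- seq(lo, hi, by = grid_step)
  M <- vapply(spectra,
              function(s) stats::approx(s$wavenumber, s$absorbance, grid)$y,
              numeric(length(grid)))
  mu <- rowMeans(M)
  sdv <- apply(M, 1, stats::sd)
  ratio <- ifelse(mu == 0, NA_real_, sdv / mu)
  data.frame(wavenumber = grid, mean = mu, sd = sdv, ratio = ratio)
}
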