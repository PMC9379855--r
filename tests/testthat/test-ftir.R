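make_gauss_spectrum <- function(center = 2545, sigma = 6, amp = 1,
                                from = 2400, to = 2700, step = 0.01,
                                baseline = function(w) 0) {
  w <- seq(from, to, by = step)
  ftir_spectrum(w, amp * exp(-(w - center)^2 / (2 * sigma^2)) + baseline(w))
}

test_that("spectra read/write round-trips and normalizes orientation", {
  w <- seq(600, 700, by = 0.5)
  s <- ftir_spectrum(w, sin(w / 30) + 2)
  f <- withr::local_tempfile(fileext = ".csv")
  write_spectrum(s, f)
  back <- read_spectrum(f)
  expect_equal(back$wavenumber, s$wavenumber, tolerance = 1e-9)
  expect_equal(back$absorbance, s$absorbance, tolerance = 1e-9)

  # descending acquisition order reads identically to ascending
  fd <- withr::local_tempfile(fileext = ".csv")
  writeLines(paste(rev(w), rev(s$absorbance), sep = ","), fd)
  expect_equal(read_spectrum(fd)$absorbance, s$absorbance, tolerance = 1e-12)

  f2 <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("600,0.1", "601,0.2"), f2)
  expect_length(read_spectrum(f2)$wavenumber, 2L)

  fbad <- withr::local_tempfile()
  writeLines(c("600,0.1", "601,oops"), fbad)
  expect_error(read_spectrum(fbad), "line 2")
  fdup <- withr::local_tempfile()
  writeLines(c("600,0.1", "600,0.2"), fdup)
  expect_error(read_spectrum(fdup), "duplicate")
})

test_that("JCAMP-DX spectra parse to the same values as their delimited twin", {
  w <- seq(1000, 1009, by = 1)
  a <- round(sin(w / 7) + 1.5, 6)
  fj <- withr::local_tempfile(fileext = ".jdx")
  writeLines(c(
    "##TITLE=synthetic test block",
    "##JCAMP-DX=4.24",
    "##XUNITS=1/CM", "##YUNITS=ABSORBANCE",
    "##FIRSTX=1000", "##LASTX=1009", "##NPOINTS=10",
    "##XFACTOR=1", "##YFACTOR=1",
    "##XYDATA=(X++(Y..Y))",
    paste(1000, paste(a[1:5], collapse = " ")),
    paste(1005, paste(a[6:10], collapse = " ")),
    "##END="), fj)
  s <- read_spectrum(fj)
  expect_equal(s$wavenumber, w)
  expect_equal(s$absorbance, a, tolerance = 1e-12)

  # (XY..XY) point table
  fp <- withr::local_tempfile(fileext = ".jdx")
  writeLines(c("##TITLE=points", "##XYPOINTS=(XY..XY)",
               paste(w, a, sep = ",", collapse = " "), "##END="), fp)
  sp <- read_spectrum(fp)
  expect_equal(sp$absorbance, a, tolerance = 1e-12)
})

test_that("baseline correction recovers a band sitting on a linear ramp", {
  ramp <- function(w) 0.002 * (w - 2400) + 0.05
  s <- make_gauss_spectrum(amp = 0.8, baseline = ramp)
  corr <- baseline_correct(s, method = "linear")
  at <- which.min(abs(corr$wavenumber - 2545))
  # the Gaussian's own tails at the window edges are ~0 for sigma = 6
  expect_equal(corr$absorbance[at], 0.8, tolerance = 1e-6)
  expect_match(corr$provenance[length(corr$provenance)], "baseline:linear")

  # rubberband: lower convex hull also strips the ramp
  rb <- baseline_correct(s, method = "rubberband")
  expect_equal(rb$absorbance[at], 0.8, tolerance = 1e-3)
  expect_gte(min(rb$absorbance), -1e-9)

  # flat baseline: output equals input; constant offset removed
  flat <- make_gauss_spectrum(amp = 0.5)
  expect_equal(baseline_correct(flat, "linear")$absorbance, flat$absorbance,
               tolerance = 1e-9)
  off <- ftir_spectrum(flat$wavenumber, flat$absorbance + 3)
  expect_equal(baseline_correct(off, "linear")$absorbance, flat$absorbance,
               tolerance = 1e-9)

  # asls strips a slowly varying baseline to first order
  as <- baseline_correct(s, method = "asls", lambda = 1e6)
  expect_lt(abs(median(as$absorbance[abs(s$wavenumber - 2545) > 50])), 0.01)
  expect_error(baseline_correct(s, method = "omnic"))
})

test_that("unit-area normalization is exact, idempotent and scale-invariant", {
  w <- seq(600, 2000, by = 1)
  s <- ftir_spectrum(w, rep(0.7, length(w)))
  nrm <- normalize_unit_area(s)
  # constant c over a 900-wide window -> every value 1/900
  expect_equal(nrm$absorbance, rep(1 / 900, length(w)), tolerance = 1e-12)
  area <- function(x) {
    keep <- x$wavenumber >= 900 & x$wavenumber <= 1800
    sum(diff(x$wavenumber[keep]) *
          (x$absorbance[keep][-1] + x$absorbance[keep][-sum(keep)]) / 2)
  }
  expect_equal(area(nrm), 1, tolerance = 1e-9)
  expect_equal(normalize_unit_area(nrm)$absorbance, nrm$absorbance,
               tolerance = 1e-12)
  s7 <- ftir_spectrum(w, 7 * s$absorbance)
  expect_equal(normalize_unit_area(s7)$absorbance, nrm$absorbance,
               tolerance = 1e-12)
  zero <- ftir_spectrum(w, rep(0, length(w)))
  expect_error(normalize_unit_area(zero), "non-positive")
})

test_that("10 cm-1 binning tiles the two windows and conserves absorbance", {
  w <- seq(550, 3750, by = 0.5)
  s <- ftir_spectrum(w, rep(2, length(w)))
  b <- bin_10cm(s)
  expect_equal(nrow(b), 118 + 125)
  expect_equal(unique(round(b$value, 9)), 20)   # constant: integral 2 * 10
  expect_false(any(b$hi > 1780 & b$lo < 2450))  # interference gap unbinned

  # conservation: bins over a window sum to the window's direct integral
  sg <- make_gauss_spectrum(center = 3000, sigma = 40, amp = 1,
                            from = 2450, to = 3700, step = 0.25)
  bg <- bin_10cm(sg, windows = list(c(2450, 3700)))
  expect_equal(sum(bg$value), gsh_band(sg, c(2450, 3700)), tolerance = 1e-9)

  # a narrow band inside one bin puts its whole integral there
  sn <- make_gauss_spectrum(center = 2545, sigma = 1, amp = 1,
                            from = 2450, to = 3700, step = 0.05)
  bn <- bin_10cm(sn, windows = list(c(2450, 3700)))
  hit <- bn[bn$lo == 2540, ]
  expect_equal(hit$value, gauss_integral(2540, 2550, 2545, 1, 1),
               tolerance = 1e-4)
  expect_lt(max(abs(bn$value[bn$lo %in% c(2500, 2600)])), 1e-8)

  # partial grid coverage flags missing bins instead of zeroing them
  part <- ftir_spectrum(seq(600, 1000, 1), rep(1, 401))
  bp <- bin_10cm(part, windows = list(c(600, 1780)))
  expect_true(anyNA(bp$value))
  expect_true(length(attr(bp, "missing_bins")) > 0)
})

test_that("the thiol band integral matches the erf closed form", {
  expect_equal(gsh_band(ftir_spectrum(seq(2500, 2600, 1), rep(0, 101))), 0)
  s <- make_gauss_spectrum(center = 2545, sigma = 6, amp = 0.37)
  expect_equal(gsh_band(s), gauss_integral(2540, 2550, 2545, 6, 0.37),
               tolerance = 1e-6)
  # grid-refinement stability: halving the spacing moves the integral < 1e-4
  s2 <- make_gauss_spectrum(center = 2545, sigma = 6, amp = 0.37,
                            step = 0.005)
  expect_lt(abs(gsh_band(s) - gsh_band(s2)) / gsh_band(s), 1e-4)
  short <- ftir_spectrum(seq(2544, 2548, 0.5), rep(1, 9))
  expect_error(gsh_band(short), "does not cover")
})

test_that("SD/mean ratio behaves as a relative-dispersion profile", {
  w <- seq(2400, 2900, by = 1)
  c1 <- ftir_spectrum(w, rep(0.2, length(w)))
  expect_equal(unique(sd_mean_ratio(list(c1, c1))$ratio), 0)

  c3 <- ftir_spectrum(w, 3 * c1$absorbance)
  r <- sd_mean_ratio(list(c1, c3))
  expect_equal(unique(round(r$ratio, 6)), round(sqrt(2) / 2, 6))
  expect_true(all(r$wavenumber >= 2450 & r$wavenumber <= 2800))

  # common multiplicative scaling leaves the ratio unchanged
  k <- 17
  rk <- sd_mean_ratio(list(ftir_spectrum(w, k * c1$absorbance),
                           ftir_spectrum(w, k * c3$absorbance)))
  expect_equal(rk$ratio, r$ratio, tolerance = 1e-12)

  # zero mean -> undefined, not infinite
  z1 <- ftir_spectrum(w, rep(-1, length(w)))
  z2 <- ftir_spectrum(w, rep(1, length(w)))
  expect_true(all(is.na(sd_mean_ratio(list(z1, z2))$ratio)))
  expect_error(sd_mean_ratio(list(c1)), ">= 2")
})
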