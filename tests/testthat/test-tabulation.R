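# synthetic table rows from the analytic reference: cheap, noise-controlled
rosenfeld_curve <- function(phi, q = seq(0, 10, 0.01), noise = 0) {
  s <- rosenfeld_sq(phi, q)
  if (noise > 0) s <- s + rnorm(length(q), sd = noise)
  structure(list(q = q, s = s, phi = phi, r_max = NA_real_, nu = phi / pi),
            class = "sf_curve")
}

test_that("Savitzky-Golay smoothing is exact on polynomials, reduces noise", {
  q <- seq(0, 10, 0.01)
  cubic <- 1 + 0.3 * q - 0.05 * q^2 + 0.002 * q^3
  expect_equal(smooth_curve(cubic), cubic, tolerance = 1e-10)
  expect_equal(smooth_curve(rep(2.5, 500)), rep(2.5, 500))
  expect_error(smooth_curve(cubic, window = 28), "odd")
  expect_error(smooth_curve(q[1:20]), "shorter")

  set.seed(9)
  clean <- sin(q)
  noisy <- clean + rnorm(length(q), sd = 0.05)
  sm <- smooth_curve(noisy)
  expect_lt(sqrt(mean((sm - clean)^2)), sqrt(mean((noisy - clean)^2)) / 2)
})

test_that("bivariate spline table reproduces its rows and interpolates phi", {
  set.seed(41)
  phis <- seq(0.05, 0.65, 0.05)
  curves <- lapply(phis, rosenfeld_curve, noise = 0.002)
  tab <- fit_sf_table(curves)
  expect_identical(tab$phi_grid, phis)

  # node self-consistency within the smoothing budget
  worst <- max(vapply(seq_along(phis), function(i)
    max(abs(sf_eval(tab, phis[i], tab$q_grid) - tab$values[i, ])),
    numeric(1)))
  expect_lt(worst, 0.05)

  # mid-phi evaluation lies between locally ordered neighbor rows
  qs <- c(1, 2.5, 4, 7)
  for (i in c(3, 6, 9)) {
    mid <- sf_eval(tab, (phis[i] + phis[i + 1]) / 2, qs)
    lo <- pmin(tab$values[i, match(qs, tab$q_grid)],
               tab$values[i + 1, match(qs, tab$q_grid)])
    hi <- pmax(tab$values[i, match(qs, tab$q_grid)],
               tab$values[i + 1, match(qs, tab$q_grid)])
    expect_true(all(mid > lo - 0.02 & mid < hi + 0.02))
  }

  # the most dilute row stays within 1% of the analytic reference
  sel <- tab$q_grid >= 0.6
  expect_lt(max(abs(sf_eval(tab, 0.05, tab$q_grid[sel]) /
                    rosenfeld_sq(0.05, tab$q_grid[sel]) - 1)), 0.01)

  expect_error(fit_sf_table(curves[1:3]), "at least 4")
  expect_error(fit_sf_table(curves[1:6]), "0.65")
  expect_s3_class(fit_sf_table(curves[1:6], require_coverage = FALSE),
                  "sf_table")

  # evaluation refuses to extrapolate
  expect_error(sf_eval(tab, 0.71, 1), "outside tabulated range")
  expect_error(sf_eval(tab, 0.3, 11), "outside tabulated range")
  expect_true(is.finite(sf_eval(tab, 0.3, 0)) && sf_eval(tab, 0.3, 0) > 0)
})

test_that("peak location refines quadratically and filters ripple", {
  q <- seq(0, 10, 0.01)
  bump <- 1 + exp(-((q - 3.217) / 0.4)^2)
  pk <- locate_peaks(bump, q = q)
  expect_identical(nrow(pk), 1L)
  expect_lt(abs(pk$q - 3.217), 0.001)          # grid/10 refinement

  expect_identical(nrow(locate_peaks(exp(-q), q = q)), 0L)

  # parabola apex recovered essentially exactly
  par <- 5 - (q - 4.238)^2
  expect_lt(abs(locate_peaks(par, q = q)$q - 4.238), 1e-6)

  # a sidelobe hugging a tall peak is absorbed by the separation rule
  two <- 1 + 5 * exp(-((q - 3.2) / 0.05)^2) + 0.4 * exp(-((q - 3.45) / 0.05)^2) +
    0.8 * exp(-((q - 5.6) / 0.3)^2)
  all_pk <- locate_peaks(two, q = q, min_prominence = 0.05)
  expect_gte(nrow(all_pk), 3L)
  sep_pk <- locate_peaks(two, q = q, min_prominence = 0.05,
                         min_separation = 0.5)
  expect_identical(nrow(sep_pk), 2L)
  expect_equal(sep_pk$q, c(3.2, 5.6), tolerance = 0.01)
})

test_that("table serialization round-trips bit-exactly with a TSV mirror", {
  set.seed(17)
  phis <- seq(0.05, 0.65, 0.05)
  tab <- fit_sf_table(lapply(phis, rosenfeld_curve, noise = 0.001))
  bin <- tempfile(fileext = ".bin"); tsv <- tempfile(fileext = ".tsv")
  write_sf_table(tab, bin, tsv = tsv)
  back <- read_sf_table(bin)
  expect_identical(back$phi_grid, tab$phi_grid)
  expect_identical(back$q_grid, tab$q_grid)
  expect_identical(back$values, tab$values)
  expect_identical(back$spline$coef, tab$spline$coef)
  expect_identical(back$spline$rss, tab$spline$rss)
  expect_identical(back$lower_confidence, tab$lower_confidence)

  # TSV mirror has one row per (phi, q) node
  df <- read.table(tsv, sep = "\t", comment.char = "#", skip = 3)
  expect_identical(nrow(df), length(phis) * length(tab$q_grid))

  # corrupted inputs fail loudly, not with partial data
  raw <- readBin(bin, "raw", file.size(bin))
  trunc <- tempfile()
  writeBin(raw[1:200], trunc)
  expect_error(read_sf_table(trunc), "truncated")
  notmine <- tempfile()
  writeBin(charToRaw("GARBAGEFILE-------"), notmine)
  expect_error(read_sf_table(notmine), "magic")
  unlink(c(bin, tsv, trunc, notmine))
})

test_that("table rows grow a monotone contact peak and a flat high-q tail", {
  phis <- seq(0.05, 0.65, 0.05)
  tab <- fit_sf_table(lapply(phis, rosenfeld_curve))
  peak_heights <- apply(tab$values[, tab$q_grid > 1], 1, max)
  expect_true(all(diff(peak_heights) > -1e-6))
  # diffraction features fade at high q (the reference's own third
  # oscillation keeps the densest row just above 1.1)
  tail_mean <- rowMeans(tab$values[, tab$q_grid >= 9])
  expect_true(all(abs(tail_mean - 1) < 0.12))
  expect_true(all(abs(tail_mean[phis <= 0.6] - 1) < 0.1))
})
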