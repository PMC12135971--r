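#' Taper the correlation function toward the box edge
#'
#' Multiplies \eqn{h(r) = g(r) - 1} by a window that is 1 up to `l/4`, falls
#' linearly to 0 at `l/2` and is 0 beyond, suppressing the noisy large-r
#' part of the estimate that would otherwise leak into low Q.  Tapering h
#' (rather than g itself) is the convention that preserves the
#' \eqn{S \to 1} high-Q limit.
#'
#' @param pdf A `pair_distribution`.
#' @param l Box side; defaults to `pdf$l`.
#' @return Numeric vector `h` on the PDF's r grid.
#' @export
taper_correlation <- function(pdf, l = pdf$l) {
  if (max(pdf$r) < l / 2 - 1e-9)
    stop("r grid must extend to at least l/2")
  r <- pdf$r
  w <- ifelse(r <= l / 4, 1, pmax(0, (l / 2 - r) / (l / 4)))
  (pdf$g - 1) * w
}

#' Zero-order Hankel kernel matrix
#'
#' Matrix with elements \eqn{A_{ij} = r_j J_0(Q_i r_j)}, precomputable once
#' for fixed grids and reused across samples so the transform is a single
#' matrix product.
#'
#' @param q_grid Scattering-vector magnitudes (QR scale).
#' @param r_grid Distances (radii).
#' @return A `length(q_grid)` x `length(r_grid)` matrix.
#' @export
hankel_matrix <- function(q_grid, r_grid) {
  outer(q_grid, r_grid, function(q, r) r * besselJ(q * r, 0))
}

#' Structure factor from a pair distribution function
#'
#' Discrete zero-order Hankel transform of the tapered correlation function:
#' \deqn{S(Q) = 1 + 2\pi\nu \sum_{r_j \le r_{max}} h(r_j)\,J_0(Q r_j)\,
#'   r_j\,\Delta r,}
#' with number density \eqn{\nu = \phi/\pi} for unit-radius disks.  The sum
#' runs over histogram bin centers up to `r_max` (truncating the kernel
#' matrix columns and the tail of h); `r_max` defaults to `l/2`, the radius
#' of the inscribed sampling circle.
#'
#' @param pdf A `pair_distribution`.
#' @param q_grid Q grid, default `seq(0, 10, 0.01)`.
#' @param r_max Integration limit in radii (at most `l/2`).
#' @param phi Area fraction; defaults to `pdf$phi`.
#' @param taper Apply the [taper_correlation()] window (default `TRUE`).
#' @return An `sf_curve`: `q`, `s`, `phi`, `r_max`, `nu`.
#' @examples
#' # ideal gas: g == 1 gives S == 1
#' pdf <- structure(list(r = seq(0.05, 50, 0.1), g = rep(1, 500),
#'                       phi = 0.2, l = 100, n_samples = 1L),
#'                  class = "pair_distribution")
#' s <- structure_factor(pdf)
#' range(s$s)
#' @export
structure_factor <- function(pdf, q_grid = seq(0, 10, 0.01), r_max = pdf$l / 2,
                             phi = pdf$phi, taper = TRUE) {
  if (r_max > pdf$l / 2 + 1e-9)
    stop("r_max may not exceed l/2 = ", pdf$l / 2,
         " (no pair data beyond the inscribed-circle radius)")
  h <- if (taper) taper_correlation(pdf) else pdf$g - 1
  keep <- pdf$r <= r_max
  r <- pdf$r[keep]
  h <- h[keep]
  dr <- pdf$r[2] - pdf$r[1]
  nu <- phi / pi
  A <- hankel_matrix(q_grid, r)
  s <- as.vector(1 + 2 * pi * nu * dr * (A %*% h))
  structure(list(q = q_grid, s = s, phi = phi, r_max = r_max, nu = nu),
            class = "sf_curve")
}

#' Replace the low-Q region of a structure factor by a parabolic fit
#'
#' The transform oscillates at very low Q (finite-box truncation); values at
#' `q <= q_cut` are replaced by a least-squares parabola
#' \eqn{s = c_0 + c_1 q + c_2 q^2} fitted on `(0, q_cut]` with weights
#' proportional to \eqn{q^2}, so the noisiest points near Q = 0 carry no
#' weight.  Values above `q_cut` are untouched.
#'
#' @param curve An `sf_curve` covering `[0, q_cut]`.
#' @param q_cut Replacement boundary (default 0.6).
#' @return The curve with the low-Q region replaced; coefficients in
#'   attribute `parabola`.
#' @export
low_q_parabola_replace <- function(curve, q_cut = 0.6) {
  sel <- curve$q > 0 & curve$q <= q_cut
  if (sum(sel) < 10) stop("fewer than 10 points below q_cut = ", q_cut)
  q <- curve$q[sel]; s <- curve$s[sel]
  fit <- lm(s ~ q + I(q^2), weights = q^2)
  cf <- unname(coef(fit))
  rep_sel <- curve$q <= q_cut
  curve$s[rep_sel] <- cf[1] + cf[2] * curve$q[rep_sel] + cf[3] * curve$q[rep_sel]^2
  attr(curve, "parabola") <- cf
  curve
}

#' @export
print.sf_curve <- function(x, ...) {
  cat("Structure factor S(Q): ", length(x$q), " points on Q in [",
      format(min(x$q)), ", ", format(max(x$q)), "], phi = ",
      format(x$phi, digits = 4), ", r_max = ", format(x$r_max), " radii\n",
      sep = "")
  pk <- locate_peaks(x)
  if (nrow(pk))
    cat("  main peak at Q =", format(pk$q[which.max(pk$s)], digits = 4),
        "with S =", format(max(pk$s), digits = 4), "\n")
  invisible(x)
}

#' @export
plot.sf_curve <- function(x, ...) {
  plot(x$q, x$s, type = "l", xlab = "QR", ylab = "S", ...)
  abline(h = 1, lty = 3)
  invisible(x)
}

#' Simulate a structure factor at one area fraction
#'
#' Full pipeline: Monte Carlo run, averaged pair distribution, Hankel
#' transform, low-Q parabola replacement and Savitzky-Golay smoothing.
#'
#' @inheritParams simulate_gr
#' @param q_grid Q grid (default `seq(0, 10, 0.01)`).
#' @param r_max Integration limit; `NULL` for `l/2`.
#' @param smooth Apply [smooth_curve()] (default `TRUE`).
#' @param q_cut Parabola replacement boundary (default 0.6).
#' @return An `sf_curve` with the averaged `pair_distribution` in attribute
#'   `pdf` and run metadata in attribute `run`.
#' @export
simulate_sq <- function(phi0, l, n_samples, sample_interval = 50,
                        burn_in = NULL, seed = NULL, w_b = 0.1,
                        q_grid = seq(0, 10, 0.01), r_max = NULL,
                        smooth = TRUE, q_cut = 0.6) {
  pdf <- simulate_gr(phi0, l, n_samples, sample_interval, burn_in, seed, w_b)
  if (is.null(r_max)) r_max <- l / 2
  curve <- structure_factor(pdf, q_grid, r_max)
  curve <- low_q_parabola_replace(curve, q_cut)
  if (smooth) curve <- smooth_curve(curve)
  attr(curve, "pdf") <- pdf
  attr(curve, "run") <- attr(pdf, "run")
  curve
}
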