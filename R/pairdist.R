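#' Pair-distance histogram inside the inscribed circle
#'
#' Selects the disks whose centers lie strictly inside the circle of
#' diameter `l` centered in the box and histograms all pairwise direct
#' Euclidean distances (no minimum image: the circle geometry replaces the
#' periodic one) into bins of width `w_b` covering `[0, l]`.
#'
#' @param packing A `disk_packing` (or any object with `positions` and `l`).
#' @param w_b Bin width in radii (default 0.1).
#' @return A `distance_histogram`: `counts`, `w_b`, `n_bins`, `n0` (disks in
#'   the circle), `n_pairs`, `l`, `n_disks` (in the whole box) and
#'   `n_samples` (1; histograms from consecutive samples may be added with
#'   [add_histograms()]).
#' @export
pair_histogram <- function(packing, w_b = 0.1) {
  l <- packing$l
  n_bins <- round(l / w_b)
  h <- cpp_pair_hist(packing$positions, l, w_b, n_bins)
  if (h$n0 < 2) stop("fewer than 2 disks inside the inscribed circle")
  structure(list(counts = h$counts, w_b = w_b, n_bins = n_bins, n0 = h$n0,
                 n_pairs = h$n0 * (h$n0 - 1) / 2, l = l,
                 n_disks = nrow(packing$positions), n_samples = 1L),
            class = "distance_histogram")
}

#' Accumulate distance histograms from consecutive samples
#'
#' Adds per-bin counts of histograms taken on the same box and binning;
#' normalizing the sum is equivalent to averaging the individually
#' normalized pair distributions, since the normalization uses the fixed
#' theoretical pair count rather than the fluctuating `n0`.
#'
#' @param hists List of `distance_histogram` objects.
#' @return A single `distance_histogram` with summed counts and `n_samples`.
#' @export
add_histograms <- function(hists) {
  h <- hists[[1]]
  for (x in hists[-1]) {
    stopifnot(x$n_bins == h$n_bins, x$l == h$l, x$w_b == h$w_b)
    h$counts <- h$counts + x$counts
    h$n0 <- h$n0 + x$n0
    h$n_pairs <- h$n_pairs + x$n_pairs
    h$n_samples <- h$n_samples + x$n_samples
  }
  h
}

#' Distance density of two random points in a circle
#'
#' Probability density of the normalized distance \eqn{x = r/(2R)} between
#' two independent uniform points in a disk of radius \eqn{R}:
#' \deqn{\rho(x) = \frac{16x}{\pi}\left(\arccos x - x\sqrt{1 - x^2}\right),
#'   \quad 0 \le x \le 1,}
#' which integrates to 1 on `[0, 1]` and vanishes at both ends.  This is the
#' finite-geometry normalization used to turn raw pair counts into g(r).
#'
#' @param x Normalized distances in `[0, 1]`.
#' @return Density values.
#' @export
circle_distance_density <- function(x) {
  if (any(x < 0 | x > 1)) stop("normalized distance x must lie in [0, 1]")
  16 * x / pi * (acos(x) - x * sqrt(pmax(0, 1 - x^2)))
}

#' Expected per-bin pair fractions for uniform points in a circle
#'
#' For `n_bins` bins of normalized width `1/n_bins`, the expected fraction of
#' pairs in bin i is the density at the bin center times the bin width:
#' \eqn{n_i = \rho(x_i)\,\delta_r}.  The fractions sum to 1 up to
#' discretization error.
#'
#' @param n_bins Number of bins (at least 10).
#' @return Numeric vector of expected fractions.
#' @export
expected_bin_fractions <- function(n_bins) {
  if (n_bins < 10) stop("need at least 10 bins")
  delta <- 1 / n_bins
  x <- (seq_len(n_bins) - 0.5) * delta
  circle_distance_density(x) * delta
}

#' Normalize a distance histogram to a pair distribution function
#'
#' Divides per-bin counts by the theoretical pair count
#' \eqn{\bar N(\bar N - 1)/2} with \eqn{\bar N = \nu \pi (l/2)^2} (the
#' expected number of centers in the circle, used instead of the fluctuating
#' observed count) and by the expected ideal-gas bin fractions from
#' [expected_bin_fractions()], yielding \eqn{g_i = p_i / n_i}.  Bins whose
#' expected fraction is below `1e-12` are set to 0 and flagged unreliable.
#'
#' @param hist A `distance_histogram` (possibly accumulated over samples).
#' @param nu Number density; default `n_disks / l^2` from the histogram.
#' @return A `pair_distribution`: `r` (bin centers, radii), `g`, `phi`
#'   (`nu * pi`), `l`, `n_samples`, and logical `unreliable`.
#' @export
normalize_to_pdf <- function(hist, nu = hist$n_disks / hist$l^2) {
  nbar <- nu * pi * (hist$l / 2)^2
  pairs_theory <- nbar * (nbar - 1) / 2 * hist$n_samples
  p <- hist$counts / pairs_theory
  n_i <- expected_bin_fractions(hist$n_bins)
  bad <- n_i < 1e-12
  g <- ifelse(bad, 0, p / pmax(n_i, 1e-300))
  structure(list(r = (seq_len(hist$n_bins) - 0.5) * hist$w_b, g = g,
                 phi = nu * pi, l = hist$l, n_samples = hist$n_samples,
                 unreliable = bad),
            class = "pair_distribution")
}

#' Average pair distribution functions
#'
#' Pointwise arithmetic mean of PDFs on identical r grids and area fraction;
#' sample counts are summed.
#'
#' @param pdfs List of `pair_distribution` objects.
#' @return A `pair_distribution`.
#' @export
average_pdfs <- function(pdfs) {
  p <- pdfs[[1]]
  if (length(pdfs) == 1L) return(p)
  for (x in pdfs[-1])
    if (length(x$r) != length(p$r) || any(x$r != p$r))
      stop("pair distributions are on different r grids")
  g <- Reduce(`+`, lapply(pdfs, `[[`, "g")) / length(pdfs)
  p$g <- g
  p$n_samples <- sum(vapply(pdfs, `[[`, integer(1), "n_samples"))
  p
}

#' @export
print.pair_distribution <- function(x, ...) {
  cat("Pair distribution g(r): ", length(x$r), " bins of width ",
      format(x$r[2] - x$r[1]), " radii, phi = ", format(x$phi, digits = 4),
      ", averaged over ", x$n_samples, " sample(s)\n", sep = "")
  invisible(x)
}

#' @export
plot.pair_distribution <- function(x, xlim = c(0, min(30, max(x$r))), ...) {
  plot(x$r, x$g, type = "l", xlim = xlim, xlab = "r (radii)",
       ylab = "g(r)", ...)
  abline(h = 1, lty = 3)
  invisible(x)
}

#' Simulate and estimate an averaged pair distribution function
#'
#' End-to-end helper: runs [run_packing()] with a histogram sampler and
#' returns the pair distribution averaged over all samples, with run
#' metadata attached.
#'
#' @param phi0 Target area fraction.
#' @param l Box side in radii.
#' @param n_samples Number of sampled PDFs to average.
#' @param sample_interval Sweeps between samples (default 50).
#' @param burn_in Burn-in sweeps; `NULL` for the density-dependent default.
#' @param seed RNG seed.
#' @param w_b Histogram bin width (default 0.1).
#' @return A `pair_distribution` with attributes `run` (acceptance rate,
#'   sigma, realized phi) attached.
#' @examples
#' g <- simulate_gr(0.3, l = 40, n_samples = 3, sample_interval = 5,
#'                  burn_in = 5, seed = 1)
#' @export
simulate_gr <- function(phi0, l, n_samples, sample_interval = 50,
                        burn_in = NULL, seed = NULL, w_b = 0.1) {
  spec <- packing_spec(phi0, l, seed)
  if (is.null(burn_in)) burn_in <- if (phi0 > 0.6) 1000 else 100
  run <- run_packing(spec, n_sweeps = burn_in + n_samples * sample_interval,
                     burn_in = burn_in, sample_interval = sample_interval,
                     sampler = function(p) pair_histogram(p, w_b))
  hist <- add_histograms(run$samples)
  pdf <- normalize_to_pdf(hist, nu = run$packing$phi_actual / pi)
  attr(pdf, "run") <- list(phi_actual = run$packing$phi_actual,
                           acceptance_rate = run$acceptance_rate,
                           sigma = run$sigma, l = l, seed = seed,
                           burn_in = burn_in, n_samples = n_samples,
                           sample_interval = sample_interval)
  pdf
}
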