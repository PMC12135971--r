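#' Deterministic test fixtures
#'
#' Small inputs with analytically known behavior, used by the test suite
#' and handy for experimentation:
#' \describe{
#'   \item{`lattice`}{A perfect hexagonal `disk_packing` at spacing given by
#'     `phi0` (first g(r) support at r = a).}
#'   \item{`uniform_points`}{`n` uniform random points in the box as a
#'     `disk_packing`-shaped object with no hard core (g = 1 oracle).}
#'   \item{`dilute`}{An equilibrated dilute hard-disk sample at `phi0`
#'     (virial-limit oracle).}
#'   \item{`two_disk`}{Exactly two disks inside the sampling circle at a
#'     prescribed `distance` (single-bin histogram).}
#'   \item{`saxs_profile`}{A synthetic two-column (Q, I) scattering profile
#'     from the analytic cylinder product model plus seeded Gaussian noise.}
#' }
#'
#' @param kind One of `"lattice"`, `"uniform_points"`, `"dilute"`,
#'   `"two_disk"`, `"saxs_profile"`.
#' @param l Box side (radii).
#' @param phi0 Area fraction where applicable.
#' @param n Point count for `uniform_points`.
#' @param distance Pair separation for `two_disk`.
#' @param seed RNG seed.
#' @param ... Passed to [saxs_intensity()] for `saxs_profile`
#'   (`radius`, `phi`, `noise_sd`, `q_grid`).
#' @return A `disk_packing` or, for `saxs_profile`, a data frame `(q, intensity)`.
#' @export
make_fixture <- function(kind, l = 50, phi0 = 0.3, n = 200, distance = 5.03,
                         seed = 1, ...) {
  set.seed(seed)
  as_packing <- function(pos, phi) {
    structure(list(positions = pos, l = l, a = NA_real_, n_x = NA_integer_,
                   n_y = NA_integer_, phi0 = phi,
                   phi_actual = nrow(pos) * pi / l^2, seed = seed,
                   sigma = NA_real_, sweeps_done = 0),
              class = "disk_packing")
  }
  switch(kind,
    lattice = hexagonal_init(packing_spec(phi0, l, seed)),
    uniform_points = as_packing(cbind(x = runif(n, 0, l), y = runif(n, 0, l)),
                                NA_real_),
    dilute = {
      run <- run_packing(packing_spec(phi0, l, seed), n_sweeps = 220,
                         burn_in = 200, sample_interval = 20)
      run$samples[[1]]
    },
    two_disk = {
      c0 <- l / 2
      as_packing(cbind(x = c(c0 - distance / 2, c0 + distance / 2),
                       y = c(c0, c0)), NA_real_)
    },
    saxs_profile = {
      args <- list(...)
      radius <- args$radius %||% 13
      phi <- args$phi %||% 0.4
      noise_sd <- args$noise_sd %||% 0.01
      q_grid <- args$q_grid %||% seq(0.005, 0.5, 0.005)
      prof <- saxs_intensity(q_grid, cylinder_model(radius, phi))
      prof$intensity <- prof$intensity + rnorm(length(q_grid), sd = noise_sd)
      prof
    },
    stop("unknown fixture kind: ", kind))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
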