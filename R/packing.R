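#' Specify a hard-disk packing simulation
#'
#' Collects the parameters of a Metropolis Monte Carlo run for unit-radius
#' hard disks in a square periodic box: the target area fraction, the box
#' side (in disk radii) and the RNG seed.  All lengths in the package are in
#' units of the disk radius, so scattering vectors are on the dimensionless
#' \eqn{QR} scale.
#'
#' @param phi0 Target area fraction, strictly between 0 and the hexagonal
#'   close-packing bound \eqn{\pi/(2\sqrt{3}) \approx 0.9069}.
#' @param l Box side in disk radii (default 500). Must exceed 4 (two
#'   diameters).
#' @param seed Integer RNG seed, recorded in all outputs. `NULL` leaves the
#'   RNG state untouched.
#' @return An object of class `packing_spec`.
#' @examples
#' packing_spec(0.6, l = 100, seed = 1)
#' @export
packing_spec <- function(phi0, l = 500, seed = NULL) {
  if (!is.numeric(phi0) || length(phi0) != 1L || !is.finite(phi0) ||
      phi0 <= 0 || phi0 >= .phi_max)
    stop("phi0 must lie in (0, ", format(.phi_max, digits = 6),
         "), the hexagonal close-packing bound pi/(2*sqrt(3))")
  if (!is.numeric(l) || length(l) != 1L || l <= 4)
    stop("box side l must exceed 4 (two disk diameters)")
  structure(list(phi0 = phi0, l = as.numeric(l),
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "packing_spec")
}

#' Hexagonal lattice spacing for a given area fraction
#'
#' Center-to-center distance \eqn{a} of unit-radius disks on a hexagonal
#' lattice with area fraction `phi0`:
#' \eqn{a = \sqrt{2\pi/(\sqrt{3}\,\phi_0)}}.  At close packing
#' (\eqn{\phi_0 = \pi/(2\sqrt 3)}) the spacing is exactly 2 and disks touch.
#'
#' @param phi0 Area fraction in `(0, pi/(2*sqrt(3)))`.
#' @return Spacing in disk radii, always greater than 2.
#' @examples
#' hexagonal_spacing(0.6)  # about 2.4589
#' @export
hexagonal_spacing <- function(phi0) {
  if (any(phi0 <= 0) || any(phi0 > .phi_max))
    stop("phi0 must lie in (0, ", format(.phi_max, digits = 6),
         "], the close-packing bound pi/(2*sqrt(3))")
  sqrt(2 * pi / (sqrt(3) * phi0))
}

#' Initialize disks on a hexagonal lattice in a periodic box
#'
#' Places `n_x = floor(l/a)` columns at spacing `a` and
#' `n_y = floor(l / (a*sqrt(3)/2))` rows at spacing `a*sqrt(3)/2`, alternate
#' rows offset by `a/2`, giving a realized area fraction
#' \eqn{\phi = N\pi/l^2} slightly below the target.  When the row count is
#' odd and the target is dense enough that the two rows meeting across the
#' periodic seam would sit closer than one diameter, the last row is dropped;
#' the constructed configuration is always overlap-free.
#'
#' @param spec A [packing_spec()].
#' @return A `disk_packing` object: a list with `positions` (N x 2 matrix in
#'   `[0, l)`), `l`, `a`, `n_x`, `n_y`, `phi0`, `phi_actual`, `seed`, `sigma`
#'   (current step sd, initialized to `a/2 - 1`) and `sweeps_done`.
#' @examples
#' p <- hexagonal_init(packing_spec(0.6, l = 50))
#' p$phi_actual
#' @export
hexagonal_init <- function(spec) {
  stopifnot(inherits(spec, "packing_spec"))
  a <- hexagonal_spacing(spec$phi0)
  l <- spec$l
  dy <- a * sqrt(3) / 2
  n_x <- as.integer(floor(l / a))
  n_y <- as.integer(floor(l / dy))
  if (n_x < 2 || n_y < 2)
    stop("box side ", l, " too small for spacing ", format(a, digits = 5),
         ": need at least 2 columns and 2 rows")
  build <- function(n_y) {
    row <- seq_len(n_x) - 1
    xs <- as.vector(outer(row * a, (seq_len(n_y) - 1) %% 2 * a / 2, `+`)) %% l
    ys <- rep((seq_len(n_y) - 1) * dy, each = n_x)
    cbind(x = xs, y = ys)
  }
  ## dense + odd row count: rows across the seam align vertically; drop one
  ## row if the seam gap falls below one diameter
  seam_gap <- l - (n_y - 1) * dy
  if (n_y %% 2L == 1L && seam_gap < 2) n_y <- n_y - 1L
  pos <- build(n_y)
  n <- nrow(pos)
  structure(list(positions = pos, l = l, a = a, n_x = n_x, n_y = n_y,
                 phi0 = spec$phi0, phi_actual = n * pi / l^2,
                 seed = spec$seed, sigma = a / 2 - 1, sweeps_done = 0),
            class = "disk_packing")
}

#' @export
print.disk_packing <- function(x, ...) {
  cat("Hard-disk packing:", nrow(x$positions), "unit disks in a periodic box of side",
      format(x$l), "radii\n")
  cat("  target area fraction ", format(x$phi0, digits = 4),
      ", realized ", format(x$phi_actual, digits = 4), "\n", sep = "")
  cat("  lattice ", x$n_x, " x ", x$n_y, " (a = ", format(x$a, digits = 5),
      "), sigma = ", format(x$sigma, digits = 4),
      ", sweeps done = ", x$sweeps_done, "\n", sep = "")
  invisible(x)
}

#' @export
plot.disk_packing <- function(x, ...) {
  sym <- seq(0, 2 * pi, length.out = 33)
  plot(NA, xlim = c(0, x$l), ylim = c(0, x$l), asp = 1,
       xlab = "x (radii)", ylab = "y (radii)",
       main = sprintf("phi = %.3f", x$phi_actual), ...)
  for (i in seq_len(nrow(x$positions)))
    lines(x$positions[i, 1] + cos(sym), x$positions[i, 2] + sin(sym), col = "grey40")
  invisible(x)
}

#' Minimum-image distance in a periodic square box
#'
#' Euclidean distance between two points using the nearest periodic image
#' along each axis.
#'
#' @param p,q Numeric length-2 coordinates in `[0, l)`.
#' @param l Box side.
#' @return Distance in the same units as `l`, at most `l/sqrt(2)`.
#' @examples
#' min_image_distance(c(0.5, 0.5), c(499.5, 0.5), 500)  # 1
#' @export
min_image_distance <- function(p, q, l) {
  cpp_min_image_distance(as.numeric(p), as.numeric(q), l)
}

#' Build the tile occupancy grid of a packing
#'
#' The box is divided into `ceil(l/sqrt(2))` tiles per side so each tile
#' (side at most \eqn{\sqrt 2}) can hold at most one center of a
#' non-overlapping unit-disk configuration.  The grid stores `-1` for an
#' empty tile and the disk's serial number (1-based) otherwise, and makes
#' collision candidates an O(1) lookup.
#'
#' @param packing A `disk_packing`.
#' @return A `tile_grid`: integer matrix with attributes `n_tiles`,
#'   `tile_side` and `l`.
#' @export
build_tile_grid <- function(packing) {
  stopifnot(inherits(packing, "disk_packing"))
  n_tiles <- ceiling(packing$l / sqrt(2))
  g <- cpp_build_tile_grid(packing$positions, packing$l, n_tiles)
  g[g >= 0L] <- g[g >= 0L] + 1L   # 1-based serials on the R side
  g[g < 0L] <- -1L
  structure(g, n_tiles = n_tiles, tile_side = packing$l / n_tiles,
            l = packing$l, class = "tile_grid")
}

.grid0 <- function(grid) {
  ## 0-based copy for the C++ kernels
  g <- unclass(grid)
  attributes(g) <- list(dim = dim(g))
  g[g > 0L] <- g[g > 0L] - 1L
  g
}

#' Tile-based collision check for a proposed move
#'
#' Tests whether any disk other than `disk_id` lies within one diameter
#' (strictly less than 2 radii) of the proposed center, scanning only the
#' 20-tile neighborhood of the proposal (the 5 x 5 block minus its four
#' corners, with periodic index wrap) plus a corner-sliver guard.  A contact
#' at exactly 2 is not a collision.  The result matches a brute-force
#' all-pairs check.
#'
#' @param grid A `tile_grid` consistent with `packing`.
#' @param packing The `disk_packing`.
#' @param disk_id 1-based serial of the disk being moved.
#' @param proposed Length-2 proposed center, wrapped into `[0, l)`.
#' @return `TRUE` if the move would collide.
#' @export
collision_check <- function(grid, packing, disk_id, proposed) {
  cpp_collision_check(.grid0(grid), packing$positions, packing$l,
                      as.integer(disk_id) - 1L,
                      proposed[1] %% packing$l, proposed[2] %% packing$l)
}

#' Step-size policy for Metropolis moves
#'
#' Displacements are drawn per axis from a normal distribution with standard
#' deviation `sigma`.  During tuning the rejection rate is measured over
#' windows of `rejection_window` attempted moves (default `10 N`) and `sigma`
#' is multiplied by `shrink_factor` until the rate drops to
#' `target_rejection` or below.
#'
#' @param sigma Step standard deviation in radii (> 0).
#' @param rejection_window Attempts per tuning window; `NULL` means `10 N`.
#' @param shrink_factor Multiplier applied when rejection is too high.
#' @param target_rejection Highest acceptable rejection rate.
#' @return A `step_policy` list.
#' @export
step_policy <- function(sigma, rejection_window = NULL, shrink_factor = 0.8,
                        target_rejection = 0.5) {
  stopifnot(sigma > 0, shrink_factor > 0, shrink_factor < 1)
  structure(list(sigma = sigma, rejection_window = rejection_window,
                 shrink_factor = shrink_factor,
                 target_rejection = target_rejection),
            class = "step_policy")
}

#' Attempt a Metropolis move of one disk
#'
#' Draws a normal step `(v_x, v_y)` with sd `sigma`, wraps the proposal into
#' the box and accepts it unless it brings the disk strictly closer than one
#' diameter to another.  On rejection the configuration is unchanged.
#'
#' @param packing A `disk_packing`.
#' @param grid Its `tile_grid`.
#' @param disk_id 1-based disk serial.
#' @param sigma Step standard deviation; defaults to `packing$sigma`.
#' @return A list `(packing, grid, accepted)` with state updated atomically
#'   on acceptance.
#' @export
attempt_move <- function(packing, grid, disk_id, sigma = packing$sigma) {
  i <- as.integer(disk_id)
  stopifnot(i >= 1L, i <= nrow(packing$positions))
  l <- packing$l
  prop <- (packing$positions[i, ] + rnorm(2, sd = sigma)) %% l
  if (collision_check(grid, packing, i, prop))
    return(list(packing = packing, grid = grid, accepted = FALSE))
  ts <- attr(grid, "tile_side"); nt <- attr(grid, "n_tiles")
  idx <- function(p) pmin(floor(p / ts), nt - 1) + 1
  old <- idx(packing$positions[i, ]); new <- idx(prop)
  grid[old[1], old[2]] <- -1L
  grid[new[1], new[2]] <- i
  packing$positions[i, ] <- prop
  list(packing = packing, grid = grid, accepted = TRUE)
}

#' Tune the Metropolis step size
#'
#' Starting from `sigma = a/2 - 1`, runs windows of `10 N` attempted moves
#' and multiplies `sigma` by 0.8 whenever more than half of the window was
#' rejected, until the measured rejection rate is at or below one half.
#' Tuning moves advance the configuration (they are counted toward burn-in
#' by [run_packing()]).
#'
#' @param packing A `disk_packing`.
#' @param policy Optional [step_policy()]; defaults to the packing's current
#'   `sigma` with a `10 N` window.
#' @return A list `(packing, sigma, rejection_rate, windows)`.
#' @export
tune_step_size <- function(packing, policy = NULL) {
  n <- nrow(packing$positions)
  if (is.null(policy)) policy <- step_policy(packing$sigma)
  window <- if (is.null(policy$rejection_window)) 10 * n else policy$rejection_window
  sigma <- policy$sigma
  grid <- .grid0(build_tile_grid(packing))
  pos <- packing$positions + 0        # force a private copy
  windows <- 0L
  repeat {
    if (sigma < 1e-6)
      stop("step-size tuning failed: sigma underflow (jammed or invalid state)")
    acc <- cpp_mc_run(pos, grid, packing$l, sigma, window)
    windows <- windows + 1L
    rate <- 1 - acc / window
    if (rate <= policy$target_rejection) break
    sigma <- sigma * policy$shrink_factor
  }
  packing$positions <- pos
  packing$sigma <- sigma
  packing$sweeps_done <- packing$sweeps_done + windows * window / n
  list(packing = packing, sigma = sigma, rejection_rate = rate,
       windows = windows)
}

#' Run a hard-disk Monte Carlo simulation
#'
#' Initializes a hexagonal lattice, tunes the step size, runs `burn_in`
#' sweeps (one sweep = N attempted single-disk moves) and then samples the
#' configuration every `sample_interval` sweeps for `n_sweeps - burn_in`
#' further sweeps.  The `sampler` callback receives the current
#' `disk_packing` and its results are collected; with the default `NULL`
#' sampler the configurations themselves are returned.
#'
#' @param spec A [packing_spec()].
#' @param n_sweeps Total sweeps after tuning, including burn-in.
#' @param burn_in Sweeps discarded before sampling. Default 100 for
#'   `phi0 <= 0.6`, 1000 above (dense states evolve slowly).
#' @param sample_interval Sweeps between samples (default 50).
#' @param sampler Function of one argument (the packing) or `NULL`.
#' @param policy Optional [step_policy()] overriding `sigma = a/2 - 1`.
#' @return A list with `packing` (final state), `samples` (list of sampler
#'   results), `acceptance_rate` over the sampling phase, `sigma`, and the
#'   run parameters.
#' @examples
#' run <- run_packing(packing_spec(0.3, l = 40, seed = 1),
#'                    n_sweeps = 30, burn_in = 10, sample_interval = 10)
#' length(run$samples)
#' @export
run_packing <- function(spec, n_sweeps, burn_in = NULL, sample_interval = 50,
                        sampler = NULL, policy = NULL) {
  stopifnot(inherits(spec, "packing_spec"), n_sweeps >= 0)
  if (is.null(burn_in)) burn_in <- if (spec$phi0 > 0.6) 1000 else 100
  if (!is.null(spec$seed)) set.seed(spec$seed)
  packing <- hexagonal_init(spec)
  n <- nrow(packing$positions)
  tuned <- tune_step_size(packing, policy)
  packing <- tuned$packing
  grid <- .grid0(build_tile_grid(packing))
  pos <- packing$positions + 0
  run_sweeps <- function(k) {
    if (k <= 0) return(0)
    cpp_mc_run(pos, grid, packing$l, packing$sigma, k * n)
  }
  run_sweeps(burn_in)
  samples <- list()
  accepted <- 0
  sampling_sweeps <- n_sweeps - burn_in
  n_samples <- if (sampling_sweeps > 0) floor(sampling_sweeps / sample_interval) else 0
  for (s in seq_len(n_samples)) {
    accepted <- accepted + run_sweeps(sample_interval)
    packing$positions <- pos + 0   # snapshot copy: pos is updated in place
    packing$sweeps_done <- burn_in + s * sample_interval
    samples[[s]] <- if (is.null(sampler)) packing else sampler(packing)
  }
  leftover <- sampling_sweeps - n_samples * sample_interval
  accepted <- accepted + run_sweeps(leftover)
  packing$positions <- pos
  packing$sweeps_done <- 0 + n_sweeps   # sweeps after tuning
  list(packing = packing, samples = samples,
       acceptance_rate = if (sampling_sweeps > 0) accepted / (sampling_sweeps * n) else NA_real_,
       sigma = packing$sigma, tuning = tuned[c("rejection_rate", "windows")],
       spec = spec, n_sweeps = n_sweeps, burn_in = burn_in,
       sample_interval = sample_interval)
}

#' Write a configuration snapshot as plain text
#'
#' Header lines beginning with `#` record the box side, target and realized
#' area fractions, seed and sweep index; then one `x y` pair per line at 17
#' significant digits, in units of the disk radius.  [read_snapshot()]
#' round-trips bit-identically.
#'
#' @param packing A `disk_packing`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_snapshot <- function(packing, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# harddisk2d snapshot"),
    sprintf("# l = %.17g", packing$l),
    sprintf("# phi0 = %.17g", packing$phi0),
    sprintf("# phi_actual = %.17g", packing$phi_actual),
    sprintf("# seed = %s", if (is.null(packing$seed)) "NA" else packing$seed),
    sprintf("# sweep = %s", format(packing$sweeps_done)),
    sprintf("# a = %.17g", packing$a),
    sprintf("# n_x = %d", packing$n_x),
    sprintf("# n_y = %d", packing$n_y)), con)
  writeLines(sprintf("%.17g %.17g", packing$positions[, 1],
                     packing$positions[, 2]), con)
  invisible(path)
}

#' Read a configuration snapshot
#'
#' @param path File written by [write_snapshot()].
#' @return A `disk_packing`.
#' @export
read_snapshot <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  get <- function(key) {
    ln <- grep(paste0("^# ", key, " = "), hdr, value = TRUE)
    if (!length(ln)) return(NA)
    sub(paste0("^# ", key, " = "), "", ln[1])
  }
  body <- lines[!grepl("^#", lines) & nzchar(lines)]
  xy <- do.call(rbind, lapply(strsplit(body, " +"), as.numeric))
  colnames(xy) <- c("x", "y")
  seed <- get("seed")
  structure(list(positions = xy, l = as.numeric(get("l")),
                 a = as.numeric(get("a")),
                 n_x = as.integer(get("n_x")), n_y = as.integer(get("n_y")),
                 phi0 = as.numeric(get("phi0")),
                 phi_actual = as.numeric(get("phi_actual")),
                 seed = if (identical(seed, "NA")) NULL else as.integer(seed),
                 sigma = NA_real_,
                 sweeps_done = as.numeric(get("sweep"))),
            class = "disk_packing")
}
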