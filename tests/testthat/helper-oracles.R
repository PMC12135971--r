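# Independent brute-force oracles, kept free of the package's C++ kernels.

r_min_image_dist <- function(p, q, l) {
  d <- abs(p - q)
  d <- pmin(d, l - d)
  sqrt(sum(d^2))
}

# minimum pairwise minimum-image distance, plain R
r_brute_min_dist <- function(pos, l) {
  n <- nrow(pos)
  best <- Inf
  for (i in seq_len(n - 1)) {
    dx <- abs(pos[(i + 1):n, 1] - pos[i, 1]); dx <- pmin(dx, l - dx)
    dy <- abs(pos[(i + 1):n, 2] - pos[i, 2]); dy <- pmin(dy, l - dy)
    best <- min(best, min(dx^2 + dy^2))
  }
  sqrt(best)
}

# does a proposed center for disk `id` collide with any other disk?
r_brute_collision <- function(pos, l, id, p) {
  other <- pos[-id, , drop = FALSE]
  if (!nrow(other)) return(FALSE)
  dx <- abs(other[, 1] - p[1]); dx <- pmin(dx, l - dx)
  dy <- abs(other[, 2] - p[2]); dy <- pmin(dy, l - dy)
  any(dx^2 + dy^2 < 4)
}

# all-pairs distance histogram inside the inscribed circle, plain R
r_brute_pair_hist <- function(pos, l, w_b = 0.1) {
  c0 <- l / 2
  keep <- (pos[, 1] - c0)^2 + (pos[, 2] - c0)^2 < (l / 2)^2
  pts <- pos[keep, , drop = FALSE]
  d <- as.vector(dist(pts))
  n_bins <- round(l / w_b)
  counts <- tabulate(pmin(floor(d / w_b) + 1L, n_bins + 1L), n_bins + 1L)
  counts[seq_len(n_bins)]
}

# session-level cache for runs shared between test blocks
.test_cache <- new.env(parent = emptyenv())
cached <- function(name, expr) {
  if (!exists(name, envir = .test_cache))
    assign(name, force(expr), envir = .test_cache)
  get(name, envir = .test_cache)
}

# an equilibrated small dilute run used by several blocks
dilute_run <- function() cached("dilute_run", {
  simulate_gr(0.05, l = 100, n_samples = 60, sample_interval = 10,
              burn_in = 50, seed = 19)
})
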