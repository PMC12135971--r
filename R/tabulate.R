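#' Savitzky-Golay smoothing of a structure-factor curve
#'
#' Local least-squares polynomial smoothing over the full Q range via
#' [signal::sgolayfilt()].  A polynomial of degree at most `polyorder`
#' passes through unchanged.
#'
#' @param curve An `sf_curve` (or plain numeric vector).
#' @param window Odd window width in samples (default 29).
#' @param polyorder Local polynomial order (default 3).
#' @return The smoothed curve (same class as the input).
#' @export
smooth_curve <- function(curve, window = 29, polyorder = 3) {
  if (window %% 2 == 0) stop("Savitzky-Golay window must be odd")
  if (window <= polyorder) stop("window must exceed the polynomial order")
  y <- if (inherits(curve, "sf_curve")) curve$s else curve
  if (length(y) <= window) stop("curve shorter than the smoothing window")
  sm <- signal::sgolayfilt(y, p = polyorder, n = window)
  if (inherits(curve, "sf_curve")) {
    curve$s <- sm
    curve
  } else sm
}

## quadratic B-spline design matrix on [lo, hi] with nseg equal segments
.bspline_basis <- function(x, lo, hi, nseg, degree = 2) {
  dx <- (hi - lo) / nseg
  knots <- seq(lo - degree * dx, hi + degree * dx, by = dx)
  splines::splineDesign(knots, x, ord = degree + 1, outer.ok = TRUE)
}

## second-difference penalty matrix for k coefficients
.diff_penalty <- function(k) {
  d <- diff(diag(k), differences = 2)
  crossprod(d)
}

#' Fit the bivariate structure-factor table
#'
#' Assembles smoothed per-area-fraction S(Q) curves into a matrix over the
#' (phi, Q) plane and fits a tensor-product B-spline of degree 2 in both
#' variables with unit weights.  Smoothing follows the penalized-spline
#' formulation: a second-difference coefficient penalty whose weight is
#' chosen (by bisection) as the largest value keeping the residual sum of
#' squares at or below `smoothing` (default 0.1), so the fit is as smooth as
#' that residual budget allows.
#'
#' @param curves List of `sf_curve` objects, one per area fraction, on a
#'   common Q grid.
#' @param phi_grid Area fractions of the rows; defaults to the curves' `phi`.
#' @param smoothing Residual-sum-of-squares budget (default 0.1).
#' @param nseg_q Number of B-spline segments along Q (default 120, fine
#'   enough to resolve the sharpest tabulated peaks).
#' @param max_node_dev Largest tolerated absolute deviation between the
#'   spline and the input values at any grid node (default 0.045); caps how
#'   much of the residual budget may concentrate on one feature.
#' @param require_coverage Enforce the canonical 0.05-0.65 coverage
#'   (default `TRUE`); rows above 0.65 are flagged lower-confidence.
#' @param provenance Optional list of per-row metadata (box side, sweeps,
#'   seed), stored verbatim.
#' @return An `sf_table`: `phi_grid`, `q_grid`, `values` (rows = phi),
#'   `spline` (knots + coefficient matrix), `lower_confidence` flags,
#'   `provenance`.
#' @export
fit_sf_table <- function(curves, phi_grid = NULL, smoothing = 0.1,
                         nseg_q = 120, max_node_dev = 0.045,
                         require_coverage = TRUE, provenance = NULL) {
  if (length(curves) < 4) stop("need at least 4 area-fraction rows")
  q_grid <- curves[[1]]$q
  for (cv in curves)
    if (length(cv$q) != length(q_grid) || any(cv$q != q_grid))
      stop("curves are on different Q grids")
  if (is.null(phi_grid))
    phi_grid <- vapply(curves, `[[`, numeric(1), "phi")
  o <- order(phi_grid)
  phi_grid <- phi_grid[o]; curves <- curves[o]
  if (require_coverage && (min(phi_grid) > 0.051 || max(phi_grid) < 0.649))
    stop("table must cover area fractions 0.05 to 0.65; got [",
         min(phi_grid), ", ", max(phi_grid), "]")
  values <- do.call(rbind, lapply(curves, `[[`, "s"))
  np <- length(phi_grid)
  nseg_phi <- max(2L, np - 2L)   # one basis function per row
  Bp <- .bspline_basis(phi_grid, min(phi_grid), max(phi_grid), nseg_phi)
  Bq <- .bspline_basis(q_grid, min(q_grid), max(q_grid), nseg_q)
  Pp <- .diff_penalty(ncol(Bp)); Pq <- .diff_penalty(ncol(Bq))
  K0 <- kronecker(crossprod(Bq), crossprod(Bp))
  K1 <- kronecker(diag(ncol(Bq)), Pp) + kronecker(Pq, diag(ncol(Bp)))
  rhs <- as.vector(crossprod(Bp, values %*% Bq))
  ridge <- 1e-9 * diag(nrow(K0))
  solve_lam <- function(lam) {
    C <- matrix(solve(K0 + lam * K1 + ridge, rhs), ncol(Bp), ncol(Bq))
    dev <- values - Bp %*% C %*% t(Bq)
    list(C = C, rss = sum(dev^2), maxdev = max(abs(dev)))
  }
  ok <- function(f) f$rss <= smoothing && f$maxdev <= max_node_dev
  f <- solve_lam(0)
  lam <- 0
  if (ok(f)) {
    lo <- 1e-8
    cand <- solve_lam(lo)
    if (ok(cand)) {
      hi <- lo
      while (hi < 1e8) {
        nxt <- solve_lam(hi * 10)
        if (!ok(nxt)) break
        hi <- hi * 10; cand <- nxt
      }
      lo <- hi; hi <- hi * 10
      for (it in 1:12) {
        mid <- sqrt(lo * hi)
        trial <- solve_lam(mid)
        if (ok(trial)) { lo <- mid; cand <- trial } else hi <- mid
      }
      f <- cand; lam <- lo
    }
  }
  structure(list(phi_grid = phi_grid, q_grid = q_grid, values = values,
                 spline = list(coef = f$C,
                               phi_range = range(phi_grid),
                               q_range = range(q_grid),
                               nseg_phi = nseg_phi, nseg_q = nseg_q,
                               degree = 2L, rss = f$rss, lambda = lam),
                 lower_confidence = phi_grid > 0.651,
                 provenance = provenance),
            class = "sf_table")
}

#' Evaluate the tabulated structure factor
#'
#' Spline evaluation of S at arbitrary (phi, q) within the tabulated
#' ranges; out-of-range requests are rejected rather than extrapolated.
#'
#' @param table An `sf_table`.
#' @param phi Single area fraction within the tabulated range.
#' @param q Q values within the tabulated range.
#' @return S values.
#' @export
sf_eval <- function(table, phi, q) {
  sp <- table$spline
  if (length(phi) != 1L || phi < sp$phi_range[1] - 1e-9 ||
      phi > sp$phi_range[2] + 1e-9)
    stop("phi = ", phi, " outside tabulated range [", sp$phi_range[1], ", ",
         sp$phi_range[2], "]")
  if (any(q < sp$q_range[1] - 1e-9) || any(q > sp$q_range[2] + 1e-9))
    stop("q outside tabulated range [", sp$q_range[1], ", ", sp$q_range[2], "]")
  phi <- min(max(phi, sp$phi_range[1]), sp$phi_range[2])
  q <- pmin(pmax(q, sp$q_range[1]), sp$q_range[2])
  Bp <- .bspline_basis(phi, sp$phi_range[1], sp$phi_range[2], sp$nseg_phi,
                       sp$degree)
  Bq <- .bspline_basis(q, sp$q_range[1], sp$q_range[2], sp$nseg_q, sp$degree)
  as.vector(Bp %*% sp$coef %*% t(Bq))
}

#' @export
print.sf_table <- function(x, ...) {
  cat("Structure-factor table: ", length(x$phi_grid), " area fractions in [",
      format(min(x$phi_grid)), ", ", format(max(x$phi_grid)), "], ",
      length(x$q_grid), " Q points in [", format(min(x$q_grid)), ", ",
      format(max(x$q_grid)), "]\n", sep = "")
  cat("  spline RSS = ", format(x$spline$rss, digits = 4), "\n", sep = "")
  invisible(x)
}

#' @export
plot.sf_table <- function(x, ...) {
  cols <- grDevices::hcl.colors(length(x$phi_grid), "viridis")
  plot(NA, xlim = range(x$q_grid), ylim = range(x$values),
       xlab = "QR", ylab = "S", ...)
  for (i in seq_along(x$phi_grid))
    lines(x$q_grid, x$values[i, ], col = cols[i])
  legend("topright", legend = format(x$phi_grid), col = cols, lty = 1,
         cex = 0.6, title = "phi")
  invisible(x)
}

#' Locate peaks of a structure-factor curve
#'
#' Local maxima by three-point comparison, refined by quadratic
#' interpolation through the three bracketing samples; returned in
#' ascending Q.  Maxima with prominence (height above the higher of the two
#' flanking minima) below `min_prominence` are discarded as ripple.
#'
#' @param curve An `sf_curve`, or a numeric vector of S values with `q`
#'   supplied.
#' @param q Q grid when `curve` is a plain vector.
#' @param q_window Optional `c(lo, hi)` restriction of the search range.
#' @param min_prominence Smallest prominence kept (default 0.01).
#' @param min_separation Minimum Q distance between reported peaks (default
#'   0, off).  When two maxima fall closer than this, only the higher is
#'   kept.  Truncating a sharp diffraction-like peak at finite `r_max`
#'   surrounds it with window sidelobes at spacing of order `4*pi/r_max`;
#'   a separation threshold between that scale and the physical inter-peak
#'   spacing suppresses them.
#' @return A data frame with columns `q` and `s`, one row per peak.
#' @export
locate_peaks <- function(curve, q = NULL, q_window = NULL,
                         min_prominence = 0.01, min_separation = 0) {
  if (inherits(curve, "sf_curve")) { s <- curve$s; q <- curve$q } else s <- curve
  stopifnot(length(q) == length(s))
  if (!is.null(q_window)) {
    keep <- q >= q_window[1] & q <= q_window[2]
    q <- q[keep]; s <- s[keep]
  }
  n <- length(s)
  if (n < 3) return(data.frame(q = numeric(0), s = numeric(0)))
  i <- which(s[2:(n - 1)] > s[1:(n - 2)] & s[2:(n - 1)] >= s[3:n]) + 1L
  if (!length(i)) return(data.frame(q = numeric(0), s = numeric(0)))
  ## topographic prominence: lowest descent before the curve rises above the
  ## peak again (or reaches the window edge) on either side
  keep <- logical(length(i))
  qp <- sp <- numeric(length(i))
  for (k in seq_along(i)) {
    j <- i[k]
    higher_l <- which(s[seq_len(j - 1)] > s[j])
    left_min <- min(s[(if (length(higher_l)) max(higher_l) else 1L):j])
    higher_r <- which(s[(j + 1):n] > s[j]) + j
    right_min <- min(s[j:(if (length(higher_r)) min(higher_r) else n)])
    keep[k] <- (s[j] - max(left_min, right_min)) >= min_prominence
    denom <- s[j - 1] - 2 * s[j] + s[j + 1]
    off <- if (abs(denom) > 0) 0.5 * (s[j - 1] - s[j + 1]) / denom else 0
    dq <- q[2] - q[1]
    qp[k] <- q[j] + off * dq
    sp[k] <- s[j] - 0.25 * (s[j - 1] - s[j + 1]) * off
  }
  out <- data.frame(q = qp[keep], s = sp[keep])
  if (min_separation > 0 && nrow(out) > 1) {
    keep2 <- rep(TRUE, nrow(out))
    for (a in order(out$s, decreasing = TRUE)) {
      if (!keep2[a]) next
      close <- abs(out$q - out$q[a]) < min_separation & seq_len(nrow(out)) != a
      keep2[close & out$s <= out$s[a]] <- FALSE
    }
    out <- out[keep2, , drop = FALSE]
    rownames(out) <- NULL
  }
  out
}

.sft_magic <- "HD2DSFT"
.sft_version <- 1L

#' Write a structure-factor table
#'
#' Serializes the table to a documented little-endian binary file (magic
#' string, version, grid sizes, grids, value matrix, spline segment counts
#' and coefficients) and, optionally, a TSV mirror with one `(phi, q, S)`
#' row per grid node.  [read_sf_table()] round-trips bit-exactly.
#'
#' @param table An `sf_table`.
#' @param path Binary file path.
#' @param tsv Optional TSV mirror path.
#' @return `path`, invisibly.
#' @export
write_sf_table <- function(table, path, tsv = NULL) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(.sft_magic), con)
  writeBin(.sft_version, con, size = 4, endian = "little")
  sp <- table$spline
  writeBin(as.integer(c(length(table$phi_grid), length(table$q_grid),
                        sp$nseg_phi, sp$nseg_q, sp$degree,
                        table$lower_confidence)), con,
           size = 4, endian = "little")
  writeBin(c(table$phi_grid, table$q_grid, as.vector(table$values),
             sp$phi_range, sp$q_range, sp$rss, as.vector(sp$coef)), con,
           size = 8, endian = "little")
  if (!is.null(tsv)) {
    grid <- expand.grid(q = table$q_grid, phi = table$phi_grid)
    df <- data.frame(phi = grid$phi, q = grid$q,
                     S = as.vector(t(table$values)))
    hdr <- c("# harddisk2d structure-factor table",
             paste0("# phi grid: ", paste(format(table$phi_grid), collapse = " ")),
             "phi\tq\tS")
    writeLines(hdr, tsv)
    write.table(df, tsv, sep = "\t", row.names = FALSE, col.names = FALSE,
                quote = FALSE, append = TRUE)
  }
  invisible(path)
}

#' Read a structure-factor table
#'
#' @param path File written by [write_sf_table()].
#' @return An `sf_table`.
#' @export
read_sf_table <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- rawToChar(readBin(con, "raw", nchar(.sft_magic)))
  if (!identical(magic, .sft_magic))
    stop("not a harddisk2d table file (bad magic)")
  ver <- readBin(con, "integer", 1, size = 4, endian = "little")
  if (!identical(ver, .sft_version))
    stop("unsupported table format version ", ver)
  ints <- readBin(con, "integer", 5, size = 4, endian = "little")
  if (length(ints) < 5) stop("truncated table file")
  np <- ints[1]; nq <- ints[2]
  lc <- readBin(con, "integer", np, size = 4, endian = "little")
  need <- np + nq + np * nq + 5 +
    (ints[3] + ints[5]) * (ints[4] + ints[5])
  dbl <- readBin(con, "double", need, size = 8, endian = "little")
  if (length(dbl) < need) stop("truncated table file")
  phi_grid <- dbl[seq_len(np)]
  q_grid <- dbl[np + seq_len(nq)]
  values <- matrix(dbl[np + nq + seq_len(np * nq)], np, nq)
  rest <- dbl[-seq_len(np + nq + np * nq)]
  structure(list(phi_grid = phi_grid, q_grid = q_grid, values = values,
                 spline = list(coef = matrix(rest[-(1:5)], ints[3] + ints[5],
                                             ints[4] + ints[5]),
                               phi_range = rest[1:2], q_range = rest[3:4],
                               nseg_phi = ints[3], nseg_q = ints[4],
                               degree = ints[5], rss = rest[5]),
                 lower_confidence = as.logical(lc),
                 provenance = NULL),
            class = "sf_table")
}
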