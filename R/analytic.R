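#' Rosenfeld analytic structure factor of the hard-disk fluid
#'
#' Closed-form S(Q) from Rosenfeld's scaled-particle (fundamental-measure)
#' theory for a one-component fluid of hard disks of diameter
#' \eqn{\sigma = 2} (unit radius), \eqn{S(Q) = 1/(1 - \nu\,\tilde c(Q))}
#' with the direct correlation function
#' \deqn{\tilde c(Q) = \frac{\pi}{6(1-\phi)^3 Q^2}\Big[
#'   -\tfrac54 (1-\phi)^2 Q^2 \sigma^2 J_0^2(Q\sigma/2)
#'   + \big(4((\phi-20)\phi+7) + \tfrac54 (1-\phi)^2 Q^2\sigma^2\big)
#'     J_1^2(Q\sigma/2)
#'   + 2(\phi-13)(1-\phi)\,Q\sigma\,J_1(Q\sigma/2) J_0(Q\sigma/2)\Big]}
#' and number density \eqn{\nu = \phi/\pi}.  It reproduces the
#' Percus-Yevick-level structure at low density and is used here as the
#' analytic reference for the simulated tables; it deviates from simulation
#' at high area fraction.  The Q = 0 value is taken by the small-Q limit of
#' the expression (evaluated just off zero, where it is smooth).
#'
#' @param phi Area fraction in `[0, 0.9)`.
#' @param q Scattering-vector magnitudes on the QR scale, `>= 0`.
#' @return S values, positive, tending to 1 at large Q and as `phi -> 0`.
#' @examples
#' rosenfeld_sq(0.6, c(1, 3.07, 10))
#' @export
rosenfeld_sq <- function(phi, q) {
  if (length(phi) != 1L || phi < 0 || phi >= 0.9)
    stop("phi must be a single value in [0, 0.9)")
  if (any(q < 0)) stop("q must be nonnegative")
  if (phi == 0) return(rep(1, length(q)))
  sgm <- 2
  qq <- ifelse(q < 1e-3, 1e-3, q)  # Q -> 0 by limit; avoids 1/Q^2 cancellation
  x <- qq * sgm / 2
  J0 <- besselJ(x, 0)
  J1 <- besselJ(x, 1)
  cq <- pi / (6 * (1 - phi)^3 * qq^2) * (
    -5 / 4 * (1 - phi)^2 * qq^2 * sgm^2 * J0^2 +
      (4 * ((phi - 20) * phi + 7) + 5 / 4 * (1 - phi)^2 * qq^2 * sgm^2) * J1^2 +
      2 * (phi - 13) * (1 - phi) * qq * sgm * J1 * J0)
  nu <- phi / pi
  1 / (1 - nu * cq)
}

#' Dilute-limit hard-disk structure factor
#'
#' Leading-order virial expression \eqn{S(Q) = 1 - (4\phi/Q) J_1(2Q)},
#' exact as \eqn{\phi \to 0}; used as an independent oracle for both the
#' simulation pipeline and the Rosenfeld transcription.
#'
#' @param phi Area fraction (small).
#' @param q Q values (> 0; the Q = 0 limit is `1 - 4 phi`).
#' @return S values.
#' @export
dilute_sq <- function(phi, q) {
  qq <- ifelse(q < 1e-8, 1e-8, q)
  1 - 4 * phi / qq * besselJ(2 * qq, 1)
}

#' Infinite-cylinder form factor
#'
#' Cross-section form factor of an infinitely long circular cylinder of
#' radius R in the fiber-perpendicular direction,
#' \eqn{P(x) = (2 J_1(x)/x)^2} with \eqn{x = QR}, normalized to
#' \eqn{P(0) = 1}.  Zeros coincide with the roots of \eqn{J_1}
#' (the first at \eqn{x \approx 3.8317}).
#'
#' @param x Dimensionless QR values, `>= 0`.
#' @return Form-factor values in `[0, 1]`.
#' @examples
#' cylinder_form_factor(c(0, 3.8317))
#' @export
cylinder_form_factor <- function(x) {
  if (any(x < 0)) stop("x must be nonnegative")
  out <- rep(1, length(x))
  nz <- x > 1e-8
  out[nz] <- (2 * besselJ(x[nz], 1) / x[nz])^2
  out
}

#' Cylinder scattering model
#'
#' Bundles the parameters of the form-factor x structure-factor intensity
#' model for densely packed parallel cylinders: radius (in physical length
#' units, e.g. angstroms), area fraction of the packing, an intensity scale
#' and an additive background.
#'
#' @param radius Cylinder radius R > 0 (e.g. 13 for 1.3 nm microfibrils).
#' @param phi Area fraction in `(0, 0.7]`.
#' @param scale Intensity multiplier (default 1).
#' @param background Additive constant (default 0).
#' @return A `cylinder_model` list.
#' @export
cylinder_model <- function(radius, phi, scale = 1, background = 0) {
  stopifnot(radius > 0, phi > 0, phi <= 0.7)
  structure(list(radius = radius, phi = phi, scale = scale,
                 background = background), class = "cylinder_model")
}

#' Small-angle scattering intensity of packed parallel cylinders
#'
#' Intensity product model
#' \eqn{I(Q) = \mathrm{scale} \cdot S(QR;\phi)\,P(QR) + \mathrm{background}}
#' on a physical Q grid (inverse length): the hard-disk structure factor is
#' evaluated on the dimensionless QR scale and multiplied by the cylinder
#' form factor.  With `q_weighted = TRUE` the returned intensity is
#' \eqn{Q I(Q)}, the orientation correction used when comparing a perfectly
#' aligned line trace with azimuthally averaged fiber data.
#'
#' @param q_grid Physical scattering vectors (same inverse-length units as
#'   `1/model$radius`).
#' @param model A [cylinder_model()].
#' @param sq_source Either `"rosenfeld"` (analytic S) or an `sf_table` from
#'   [fit_sf_table()], evaluated at `model$phi`.
#' @param q_weighted Return `q * I(q)` (default `FALSE`).
#' @return A data frame with columns `q` and `intensity`.
#' @examples
#' m <- cylinder_model(radius = 13, phi = 0.4)
#' head(saxs_intensity(seq(0.01, 0.5, 0.01), m))
#' @export
saxs_intensity <- function(q_grid, model, sq_source = "rosenfeld",
                           q_weighted = FALSE) {
  stopifnot(inherits(model, "cylinder_model"))
  x <- q_grid * model$radius
  if (identical(sq_source, "rosenfeld")) {
    s <- rosenfeld_sq(model$phi, x)
  } else if (identical(sq_source, "unity")) {
    s <- rep(1, length(x))
  } else if (inherits(sq_source, "sf_table")) {
    if (any(x > max(sq_source$q_grid)) || any(x < min(sq_source$q_grid)))
      stop("q * R outside tabulated range [", min(sq_source$q_grid), ", ",
           max(sq_source$q_grid), "] on the QR scale")
    s <- sf_eval(sq_source, model$phi, x)
  } else stop("sq_source must be 'rosenfeld', 'unity' or an sf_table")
  i <- model$scale * s * cylinder_form_factor(x) + model$background
  if (q_weighted) i <- q_grid * i
  data.frame(q = q_grid, intensity = i)
}
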