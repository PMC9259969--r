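#' Optical and solvent conditions of a DLS measurement
#'
#' Bundles everything needed to turn decay rates into hydrodynamic radii:
#' laser wavelength, detection angle, solvent refractive index, and the
#' temperature and viscosity entering the Stokes–Einstein relation.
#' Defaults describe a typical red-laser instrument measuring aqueous
#' samples at 25 °C (water viscosity 8.872e-4 Pa·s).
#'
#' @param wavelength laser wavelength in m (default 658 nm).
#' @param angle scattering angle in degrees, in (0, 180).
#' @param ri solvent refractive index.
#' @param temperature absolute temperature in K.
#' @param viscosity solvent viscosity in Pa·s.
#' @return A list of class `dls_conditions`.
#' @export
dls_conditions <- function(wavelength = 658e-9, angle = 90, ri = 1.330,
                           temperature = 298.15, viscosity = 8.872e-4) {
  stop_if_not_scalar_pos(wavelength, "wavelength")
  stop_if_not_scalar_pos(ri, "ri")
  stop_if_not_scalar_pos(temperature, "temperature")
  stop_if_not_scalar_pos(viscosity, "viscosity")
  if (angle <= 0 || angle >= 180)
    stop("scattering angle must lie in (0, 180) degrees", call. = FALSE)
  structure(list(wavelength = wavelength, angle = angle, ri = ri,
                 temperature = temperature, viscosity = viscosity),
            class = "dls_conditions")
}

#' Scattering vector magnitude
#'
#' \eqn{q = (4\pi n / \lambda) \sin(\theta/2)}; the decay rate of a
#' diffusing species is \eqn{\Gamma = q^2 D}.
#'
#' @param conditions a [dls_conditions] object.
#' @return q in m^-1.
#' @examples
#' scattering_vector(dls_conditions())  # ~1.796e7 for 658 nm / 90 deg
#' @export
scattering_vector <- function(conditions = dls_conditions()) {
  stopifnot(inherits(conditions, "dls_conditions"))
  4 * pi * conditions$ri / conditions$wavelength *
    sin(conditions$angle * pi / 180 / 2)
}

#' Hydrodynamic radius from a diffusion coefficient (Stokes–Einstein)
#'
#' \eqn{R_h = k_B T / (6 \pi \eta D)}, the radius of the sphere diffusing
#' at the measured rate.
#'
#' @param D diffusion coefficient in m^2/s (> 0); vectorized.
#' @param temperature absolute temperature in K.
#' @param viscosity solvent viscosity in Pa·s.
#' @return Radius in m.
#' @examples
#' stokes_einstein_radius(2.4615e-10, 298.15, 8.872e-4)  # ~1 nm
#' @export
stokes_einstein_radius <- function(D, temperature = 298.15,
                                   viscosity = 8.872e-4) {
  if (any(D <= 0) || temperature <= 0 || viscosity <= 0)
    stop("D, temperature and viscosity must be positive", call. = FALSE)
  .kB * temperature / (6 * pi * viscosity * D)
}

#' Diffusion coefficient of a sphere of given hydrodynamic radius
#'
#' Exact inverse of [stokes_einstein_radius()].
#'
#' @param rh radius in m (> 0); vectorized.
#' @inheritParams stokes_einstein_radius
#' @return D in m^2/s.
#' @export
diffusion_from_radius <- function(rh, temperature = 298.15,
                                  viscosity = 8.872e-4) {
  if (any(rh <= 0) || temperature <= 0 || viscosity <= 0)
    stop("rh, temperature and viscosity must be positive", call. = FALSE)
  .kB * temperature / (6 * pi * viscosity * rh)
}

#' DLS correlograms
#'
#' Holds one intensity autocorrelation measurement \eqn{g_2(\tau)} with
#' the conditions needed for its interpretation.
#'
#' @param tau lag times in s, strictly increasing, positive, length >= 20.
#' @param g2 intensity autocorrelation values.
#' @param conditions a [dls_conditions] object.
#' @param label measurement name.
#' @return An object of class `correlogram`.
#' @export
correlogram <- function(tau, g2, conditions = dls_conditions(),
                        label = "sample") {
  tau <- as.numeric(tau); g2 <- as.numeric(g2)
  if (length(tau) < 20L || length(g2) != length(tau))
    stop("tau and g2 must have equal length >= 20", call. = FALSE)
  if (any(tau <= 0) || any(diff(tau) <= 0))
    stop("tau must be positive and strictly increasing", call. = FALSE)
  stopifnot(inherits(conditions, "dls_conditions"))
  structure(list(tau = tau, g2 = g2, conditions = conditions,
                 label = label),
            class = "correlogram")
}

#' @export
print.correlogram <- function(x, ...) {
  cat(sprintf(
    "DLS correlogram '%s': %d lags, %.3g-%.3g s, g2 in [%.4f, %.4f]\n",
    x$label, length(x$tau), min(x$tau), max(x$tau), min(x$g2), max(x$g2)))
  invisible(x)
}

#' Read / write a DLS correlogram as CSV
#'
#' Two-column CSV (`tau_s`, `g2`).  Some instruments export
#' \eqn{g_2 - 1}; pass `dialect = "g2minus1"` to shift such files onto the
#' `B = 1` convention — the dialect is never guessed from the values.
#'
#' @param path CSV file path.
#' @param conditions a [dls_conditions] attached to the result.
#' @param dialect `"g2"` (default) or `"g2minus1"`.
#' @param label measurement name.
#' @return A [correlogram].
#' @export
read_correlogram <- function(path, conditions = dls_conditions(),
                             dialect = c("g2", "g2minus1"),
                             label = basename(path)) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- utils::read.csv(path)
  if (ncol(tab) < 2L)
    stop("correlogram CSV needs lag-time and g2 columns", call. = FALSE)
  tau <- tab[[1L]]; g2 <- tab[[2L]]
  if (dialect == "g2minus1") g2 <- g2 + 1
  correlogram(tau, g2, conditions, label = label)
}

#' @rdname read_correlogram
#' @param corr a [correlogram] to write (`g2` convention).
#' @export
write_correlogram <- function(corr, path) {
  stopifnot(inherits(corr, "correlogram"))
  utils::write.csv(data.frame(tau_s = corr$tau, g2 = corr$g2), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Forward model of the intensity autocorrelation of a mixture
#'
#' Siegert-relation model shared by the fitting routines and the synthetic
#' generator: \eqn{g_2(\tau) = B + \beta\,[\sum_i w_i e^{-q^2 D(r_i)\tau}]^2}
#' with intensity weights `w` (normalized internally) over hydrodynamic
#' radii `rh`.
#'
#' @param tau lag times in s.
#' @param rh hydrodynamic radii in nm.
#' @param weights intensity weights (any positive scale).
#' @param conditions a [dls_conditions].
#' @param B baseline; `beta` intercept.
#' @param beta coherence (intercept) factor.
#' @return g2 values at `tau`.
#' @export
dls_g2_model <- function(tau, rh, weights, conditions = dls_conditions(),
                         B = 1, beta = 0.9) {
  w <- weights / sum(weights)
  gamma <- scattering_vector(conditions)^2 *
    diffusion_from_radius(rh * 1e-9, conditions$temperature,
                          conditions$viscosity)
  g1 <- as.vector(exp(-outer(tau, gamma)) %*% w)
  B + beta * g1^2
}
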