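# Seeded generators producing synthetic data with known ground truth for
# every analysis module: mass-photometry event sets, nanoDSF thermal ramps
# and DLS correlograms.  Each generator is deterministic for a given seed
# and writes/reads through the same formats the analysis readers accept.

#' Generate synthetic mass-photometry events
#'
#' Draws landing events from a mixture of Gaussian mass populations with a
#' hard lower detection cutoff: values below `detection_limit` are redrawn
#' (rejection sampling), which keeps each component's event count exact
#' while producing exactly the left-truncated distributions the analysis
#' fits.  Optionally adds a uniform background over the window and
#' unbinding events (negated draws from the same mixture).
#'
#' @param components data frame with columns `mu` (kDa), `sigma` (kDa,
#'   > 0) and `count` (events >= 0), one row per population.
#' @param detection_limit hard lower cutoff `t` in kDa (default 30).
#' @param background_count uniform background events over `window`.
#' @param window range of the uniform background, kDa.
#' @param unbinding_fraction fraction of the signal count added as
#'   negative-signed unbinding events.
#' @param seed integer seed; the output is bit-identical per seed.
#' @return An [mp_events] object (`kind = "mass"`, `source =
#'   "synthetic"`); the generating spec is kept in `$meta$truth`.
#' @examples
#' ev <- gen_mp_events(data.frame(mu = 480, sigma = 38.4, count = 5000),
#'                     detection_limit = 30, seed = 42)
#' min(ev$values) >= 30
#' @export
gen_mp_events <- function(components, detection_limit = 30,
                          background_count = 0, window = c(0, 2000),
                          unbinding_fraction = 0, seed = NULL) {
  if (!is.data.frame(components) ||
      !all(c("mu", "sigma", "count") %in% names(components)))
    stop("`components` needs columns mu, sigma, count", call. = FALSE)
  if (any(components$sigma <= 0) || any(components$count < 0))
    stop("sigma must be > 0 and count >= 0", call. = FALSE)
  if (detection_limit < 0)
    stop("detection_limit must be >= 0", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)

  draw_component <- function(mu, sigma, n) {
    if (n == 0) return(numeric(0))
    if (stats::pnorm(detection_limit, mu, sigma, lower.tail = FALSE) < 1e-6)
      stop("component at ", mu,
           " kDa is essentially entirely below the detection limit",
           call. = FALSE)
    x <- stats::rnorm(n, mu, sigma)
    while (any(bad <- x < detection_limit))
      x[bad] <- stats::rnorm(sum(bad), mu, sigma)
    x
  }
  values <- unlist(lapply(seq_len(nrow(components)), function(k)
    draw_component(components$mu[k], components$sigma[k],
                   components$count[k])))
  if (background_count > 0)
    values <- c(values, stats::runif(background_count, window[1L],
                                     window[2L]))
  if (unbinding_fraction > 0 && length(values)) {
    n_unbind <- round(unbinding_fraction * length(values))
    if (n_unbind > 0)
      values <- c(values,
                  -sample(values, n_unbind, replace = TRUE))
  }
  mp_events(values, kind = "mass", source = "synthetic",
            meta = list(truth = list(components = components,
                                     detection_limit = detection_limit,
                                     background_count = background_count,
                                     unbinding_fraction = unbinding_fraction,
                                     seed = seed)))
}

#' Generate synthetic calibration standards
#'
#' Produces per-standard mean contrasts lying on a known contrast-to-mass
#' line `mass = slope * contrast + intercept`, optionally perturbed by
#' multiplicative Gaussian noise, so [fit_calibration()] can be exercised
#' against exact ground truth.  The default panel is the three
#' regular-field-of-view native-marker masses (66, 146, 480 kDa).
#'
#' @param slope,intercept true line coefficients (kDa per contrast unit,
#'   kDa); `slope` must be nonzero.
#' @param masses known standard masses in kDa.
#' @param labels standard names.
#' @param noise relative (multiplicative) contrast noise s.d.
#' @param seed integer seed.
#' @return A data frame `label`, `known_mass`, `mean_contrast`, ready for
#'   [fit_calibration()].
#' @export
gen_calibration_events <- function(slope = -20000, intercept = 0,
                                   masses = c(66, 146, 480),
                                   labels = paste0("NM", seq_along(masses)),
                                   noise = 0, seed = NULL) {
  if (slope == 0) stop("slope must be nonzero", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  contrasts <- (masses - intercept) / slope
  if (noise > 0)
    contrasts <- contrasts * (1 + stats::rnorm(length(masses), 0, noise))
  data.frame(label = labels, known_mass = masses,
             mean_contrast = contrasts)
}

#' Generate a synthetic nanoDSF thermal ramp
#'
#' Simulates a two-state (van 't Hoff) thermal unfolding read out as a
#' fluorescence ratio with linear native and unfolded baselines, plus an
#' optional logistic backscattering transition.  The unfolded fraction is
#' \deqn{f(T) = K/(1+K),\quad K = \exp[-(\Delta H/R)(1/T - 1/T_m)]}
#' (temperatures in kelvin), the noiseless ratio is
#' \eqn{(1-f)\,r_N(T) + f\,r_U(T)}, and F330 is a flat channel at
#' `f330_level` so that F350 = ratio × F330.  Relative Gaussian noise is
#' applied independently to both fluorescence channels; scattering noise
#' is additive.
#'
#' @param tm van 't Hoff midpoint in °C.
#' @param delta_h van 't Hoff enthalpy in kJ/mol (> 0; default 400).
#' @param ratio_native,ratio_unfolded `c(value, slope_per_degC)` of the
#'   linear ratio baselines, anchored at the grid start.
#' @param f330_level mean F330 counts (default 8000, inside the
#'   recommended 2000–15000 acquisition window).
#' @param grid `c(start, end, step)` in °C; default 20–90 at 0.1.
#' @param noise relative fluorescence noise s.d. (default 0.001).
#' @param scattering_mid logistic midpoint in °C, or `NULL` for no
#'   scattering channel.
#' @param scattering_steepness logistic rate in 1/°C (default 0.5).
#' @param scattering_baseline,scattering_amplitude logistic offset and
#'   amplitude.
#' @param scattering_noise additive scattering noise s.d.
#' @param label capillary name.
#' @param seed integer seed.
#' @return A [thermal_ramp]; the generating parameters sit in attribute
#'   `truth`.
#' @examples
#' ramp <- gen_dsf_ramp(tm = 84, noise = 0, seed = 1)
#' length(ramp$temperature)  # 701
#' @export
gen_dsf_ramp <- function(tm = 70, delta_h = 400,
                         ratio_native = c(0.8, 0),
                         ratio_unfolded = c(1.0, 0),
                         f330_level = 8000,
                         grid = c(20, 90, 0.1), noise = 0.001,
                         scattering_mid = NULL,
                         scattering_steepness = 0.5,
                         scattering_baseline = 0,
                         scattering_amplitude = 1,
                         scattering_noise = 0,
                         label = "synthetic", seed = NULL) {
  if (grid[1L] >= grid[2L] || grid[3L] <= 0)
    stop("grid must be c(start, end, step) with start < end, step > 0",
         call. = FALSE)
  stop_if_not_scalar_pos(delta_h, "delta_h")
  if (!is.null(seed)) set.seed(seed)
  temperature <- seq(grid[1L], grid[2L], by = grid[3L])
  R_kJ <- 8.314462618e-3
  t_k <- temperature + 273.15
  K <- exp(-(delta_h / R_kJ) * (1 / t_k - 1 / (tm + 273.15)))
  f <- K / (1 + K)
  r_n <- ratio_native[1L] + ratio_native[2L] * (temperature - grid[1L])
  r_u <- ratio_unfolded[1L] + ratio_unfolded[2L] * (temperature - grid[1L])
  ratio <- (1 - f) * r_n + f * r_u

  n <- length(temperature)
  jitter <- function(x) if (noise > 0)
    x * (1 + stats::rnorm(n, 0, noise)) else x
  f330 <- jitter(rep(f330_level, n))
  f350 <- jitter(ratio * f330_level)

  scattering <- NULL
  if (!is.null(scattering_mid)) {
    scattering <- scattering_baseline + scattering_amplitude /
      (1 + exp(-scattering_steepness * (temperature - scattering_mid)))
    if (scattering_noise > 0)
      scattering <- scattering + stats::rnorm(n, 0, scattering_noise)
  }
  ramp <- thermal_ramp(temperature, pmax(f330, 0), pmax(f350, 0),
                       scattering, label = label)
  attr(ramp, "truth") <- list(tm = tm, delta_h = delta_h,
                              ratio = ratio, fraction_unfolded = f,
                              scattering_mid = scattering_mid,
                              scattering_steepness = scattering_steepness,
                              seed = seed)
  ramp
}

#' Generate a synthetic DLS correlogram
#'
#' Builds the intensity autocorrelation of a mixture of diffusing species
#' through the package's own forward model ([dls_g2_model()]): intensity
#' weights proportional to mass_fraction × Rh^3 (compact-sphere Rayleigh
#' convention), \eqn{g_1(\tau) = \sum_i w_i e^{-q^2 D_i \tau}},
#' \eqn{g_2 = B + \beta g_1^2}, plus additive Gaussian noise.
#'
#' @param components data frame with columns `rh` (nm, > 0) and
#'   `mass_fraction` (>= 0, summing to > 0).
#' @param conditions a [dls_conditions].
#' @param B baseline (default 1); `beta` intercept (default 0.9).
#' @param beta coherence factor.
#' @param tau lag-time grid in s; default 200 log-spaced points over
#'   1e-7–1 s.
#' @param noise additive g2 noise s.d.
#' @param label measurement name.
#' @param seed integer seed.
#' @return A [correlogram]; generating weights and parameters in attribute
#'   `truth`.
#' @examples
#' corr <- gen_correlogram(data.frame(rh = c(5, 21.5),
#'                                    mass_fraction = c(72, 27)),
#'                         noise = 0, seed = 1)
#' attr(corr, "truth")$intensity_weights
#' @export
gen_correlogram <- function(components, conditions = dls_conditions(),
                            B = 1, beta = 0.9,
                            tau = 10^seq(-7, 0, length.out = 200),
                            noise = 0, label = "synthetic", seed = NULL) {
  if (!is.data.frame(components) ||
      !all(c("rh", "mass_fraction") %in% names(components)))
    stop("`components` needs columns rh and mass_fraction", call. = FALSE)
  if (any(components$rh <= 0) || any(components$mass_fraction < 0) ||
      sum(components$mass_fraction) <= 0)
    stop("rh must be > 0 and mass fractions >= 0 with positive sum",
         call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  w_int <- components$mass_fraction * components$rh^3
  w_int <- w_int / sum(w_int)
  g2 <- dls_g2_model(tau, components$rh, w_int, conditions, B, beta)
  if (noise > 0) g2 <- g2 + stats::rnorm(length(tau), 0, noise)
  corr <- correlogram(tau, g2, conditions, label = label)
  attr(corr, "truth") <- list(components = components,
                              intensity_weights = w_int,
                              B = B, beta = beta, noise = noise,
                              seed = seed)
  corr
}
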