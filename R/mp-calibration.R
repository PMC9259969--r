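#' Contrast-to-mass calibration
#'
#' A mass photometer measures interferometric contrast; a linear calibration
#' against protein standards of known mass converts contrast to kDa.  The
#' usual protocol runs an unstained native marker whose species at 66, 146
#' and 480 kDa are visible in the regular field of view, fits Gaussians to
#' the three contrast peaks, and regresses known mass on mean contrast.  A
#' calibration is considered valid when the largest per-standard relative
#' error stays below 5%.
#'
#' @param standards data frame with columns `label`, `known_mass` (kDa,
#'   positive) and `mean_contrast` (dimensionless, nonzero); one row per
#'   standard, at least two rows with distinct contrasts (three
#'   recommended).
#' @param force_origin fit `mass = a * contrast` through the origin instead
#'   of the default free-intercept line `mass = a * contrast + b`.
#' @param max_rel_error_pct validity bound on the largest per-standard
#'   relative error, in percent.
#'
#' @return An object of class `mp_calibration`: `slope` (kDa per contrast
#'   unit), `intercept` (kDa), `standards` (input plus `predicted_mass` and
#'   `rel_error_pct`), `max_rel_error`, `is_valid`.
#' @examples
#' std <- data.frame(label = c("NM1", "NM2", "NM3"),
#'                   known_mass = c(66, 146, 480),
#'                   mean_contrast = -c(66, 146, 480) / 20000)
#' cal <- fit_calibration(std)
#' cal$slope         # -20000
#' cal$max_rel_error # 0
#' @export
fit_calibration <- function(standards, force_origin = FALSE,
                            max_rel_error_pct = 5) {
  req <- c("known_mass", "mean_contrast")
  if (!is.data.frame(standards) || !all(req %in% names(standards)))
    stop("`standards` needs columns known_mass and mean_contrast",
         call. = FALSE)
  if (nrow(standards) < 2L)
    stop("at least two calibration standards are required", call. = FALSE)
  if (any(standards$known_mass <= 0))
    stop("known masses must be positive", call. = FALSE)
  if (anyDuplicated(standards$mean_contrast) ||
      diff(range(standards$mean_contrast)) == 0)
    stop("calibration standards must have distinct contrasts", call. = FALSE)
  if (is.null(standards$label))
    standards$label <- paste0("std", seq_len(nrow(standards)))

  fit <- if (force_origin) {
    stats::lm(known_mass ~ mean_contrast + 0, data = standards)
  } else {
    stats::lm(known_mass ~ mean_contrast, data = standards)
  }
  a <- unname(stats::coef(fit)[["mean_contrast"]])
  b <- if (force_origin) 0 else unname(stats::coef(fit)[["(Intercept)"]])

  standards$predicted_mass <- a * standards$mean_contrast + b
  standards$rel_error_pct <-
    100 * abs(standards$predicted_mass - standards$known_mass) /
    standards$known_mass
  max_err <- max(standards$rel_error_pct)
  is_valid <- max_err < max_rel_error_pct
  if (!is_valid)
    warning(sprintf(
      "calibration max relative error %.2f%% exceeds the %.0f%% bound",
      max_err, max_rel_error_pct), call. = FALSE)

  structure(
    list(slope = a, intercept = b, standards = standards,
         max_rel_error = max_err, is_valid = is_valid,
         force_origin = force_origin),
    class = "mp_calibration"
  )
}

#' @export
print.mp_calibration <- function(x, ...) {
  cat(sprintf("Contrast-to-mass calibration: mass = %.6g * contrast %+.6g\n",
              x$slope, x$intercept))
  cat(sprintf("  max relative error %.3f%% -> %s\n", x$max_rel_error,
              if (x$is_valid) "valid" else "INVALID"))
  print(x$standards, row.names = FALSE)
  invisible(x)
}

#' Convert contrast events to masses with a fitted calibration
#'
#' Maps every event contrast `c` to mass `a * c + b`.  Refuses event sets
#' already expressed in mass units so a calibration can never be applied
#' twice.
#'
#' @param events an [mp_events] object with `kind = "contrast"`.
#' @param model an `mp_calibration` from [fit_calibration()].
#' @return An [mp_events] object with `kind = "mass"` and the same number
#'   of events.
#' @export
apply_calibration <- function(events, model) {
  stopifnot(inherits(events, "mp_events"), inherits(model, "mp_calibration"))
  if (events$kind != "contrast")
    stop("events are already in mass units; refusing to calibrate twice",
         call. = FALSE)
  if (!is.finite(model$slope) || !is.finite(model$intercept))
    stop("calibration model has non-finite coefficients", call. = FALSE)
  mp_events(model$slope * events$values + model$intercept,
            kind = "mass", source = events$source,
            meta = c(events$meta,
                     list(calibration = c(slope = model$slope,
                                          intercept = model$intercept))))
}
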