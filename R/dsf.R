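#' Thermal ramps from nanoDSF experiments
#'
#' A `thermal_ramp` holds one capillary's record of a thermal denaturation
#' experiment: intrinsic tryptophan/tyrosine fluorescence at 330 and 350 nm
#' and (optionally) backscattering, sampled along a strictly increasing
#' temperature grid (the standard protocol ramps 20–90 °C at 1 °C/min).
#'
#' @param temperature temperatures in °C, strictly increasing, length >= 10.
#' @param f330,f350 fluorescence counts at 330 / 350 nm, non-negative.
#' @param scattering optional backscattering counts.
#' @param label capillary / condition name.
#' @return An object of class `thermal_ramp`.
#' @export
thermal_ramp <- function(temperature, f330, f350, scattering = NULL,
                         label = "capillary") {
  temperature <- as.numeric(temperature)
  f330 <- as.numeric(f330); f350 <- as.numeric(f350)
  n <- length(temperature)
  if (n < 10L) stop("a thermal ramp needs at least 10 points", call. = FALSE)
  if (length(f330) != n || length(f350) != n ||
      (!is.null(scattering) && length(scattering) != n))
    stop("ramp channels must all have the same length", call. = FALSE)
  if (any(diff(temperature) <= 0))
    stop("temperature grid must be strictly increasing", call. = FALSE)
  if (any(f330 < 0) || any(f350 < 0))
    stop("fluorescence counts must be non-negative", call. = FALSE)
  structure(
    list(temperature = temperature, f330 = f330, f350 = f350,
         scattering = if (is.null(scattering)) NULL else
           as.numeric(scattering),
         label = label),
    class = "thermal_ramp"
  )
}

#' @export
print.thermal_ramp <- function(x, ...) {
  cat(sprintf(
    "Thermal ramp '%s': %d points, %.1f-%.1f degC%s\n", x$label,
    length(x$temperature), min(x$temperature), max(x$temperature),
    if (is.null(x$scattering)) "" else ", with scattering"))
  invisible(x)
}

#' Read processed nanoDSF curve exports
#'
#' Parses the per-capillary CSV export of processed curves.  Two layouts
#' are auto-detected: *wide* — a temperature column plus
#' `<label>:F330`, `<label>:F350` and optional `<label>:Scattering` columns
#' per capillary (`:` or `_` separator) — and *long* — columns
#' `label`, `temperature`, `f330`, `f350`, optional `scattering`.  Rows are
#' sorted by ascending temperature (with a warning if the file was not).
#'
#' @param path CSV file path.
#' @return A named list of [thermal_ramp] objects, one per capillary.
#' @export
read_thermal_ramps <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- utils::read.csv(path, check.names = FALSE)
  nm <- names(tab)
  low <- tolower(nm)
  if (all(c("label", "f330", "f350") %in% low)) {
    names(tab) <- low
    ramps <- lapply(split(tab, tab$label), function(d) {
      d <- sort_ramp_rows(d, path)
      thermal_ramp(d$temperature, d$f330, d$f350, d$scattering,
                   label = d$label[1L])
    })
    return(ramps[unique(tab$label)])
  }
  t_col <- which(low %in% c("temperature", "temp", "t", "temperature_c"))
  if (!length(t_col))
    stop("no temperature column found in ", path, call. = FALSE)
  t_col <- t_col[1L]
  tab <- sort_ramp_rows_wide(tab, t_col, path)
  channel <- sub("^.*[:_]", "", nm)
  cap <- sub("[:_][^:_]*$", "", nm)
  is_chan <- tolower(channel) %in% c("f330", "f350", "scattering") &
    seq_along(nm) != t_col
  labels <- unique(cap[is_chan])
  if (!length(labels))
    stop("no <capillary>:F330/F350 columns found in ", path, call. = FALSE)
  ramps <- lapply(labels, function(lb) {
    pick <- function(ch) {
      j <- which(cap == lb & tolower(channel) == ch)
      if (length(j)) tab[[j[1L]]] else NULL
    }
    f330 <- pick("f330"); f350 <- pick("f350")
    if (is.null(f330) || is.null(f350))
      stop("capillary '", lb, "' is missing an F330 or F350 column",
           call. = FALSE)
    thermal_ramp(tab[[t_col]], f330, f350, pick("scattering"), label = lb)
  })
  stats::setNames(ramps, labels)
}

sort_ramp_rows <- function(d, path) {
  if (is.unsorted(d$temperature, strictly = TRUE)) {
    warning("temperatures in ", path, " were not ascending; rows sorted",
            call. = FALSE)
    d <- d[order(d$temperature), , drop = FALSE]
  }
  d
}

sort_ramp_rows_wide <- function(tab, t_col, path) {
  if (is.unsorted(tab[[t_col]], strictly = TRUE)) {
    warning("temperatures in ", path, " were not ascending; rows sorted",
            call. = FALSE)
    tab <- tab[order(tab[[t_col]]), , drop = FALSE]
  }
  tab
}

#' Write thermal ramps to a wide-format CSV
#'
#' Inverse of [read_thermal_ramps()] (wide layout).  All ramps must share
#' one temperature grid.
#'
#' @param ramps a [thermal_ramp] or list of them.
#' @param path destination CSV path.
#' @return `path`, invisibly.
#' @export
write_thermal_ramps <- function(ramps, path) {
  if (inherits(ramps, "thermal_ramp")) ramps <- list(ramps)
  out <- data.frame(temperature = ramps[[1L]]$temperature)
  for (r in ramps) {
    stopifnot(inherits(r, "thermal_ramp"))
    if (!isTRUE(all.equal(r$temperature, out$temperature)))
      stop("all ramps must share one temperature grid", call. = FALSE)
    out[[paste0(r$label, ":F330")]] <- r$f330
    out[[paste0(r$label, ":F350")]] <- r$f350
    if (!is.null(r$scattering))
      out[[paste0(r$label, ":Scattering")]] <- r$scattering
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Fluorescence ratio curve (F350/F330)
#'
#' The 350/330 nm ratio tracks the solvent exposure of tryptophan residues
#' and is the standard unfolding readout of nanoDSF.  Points with zero
#' F330 are masked (dropped) and counted.
#'
#' @param ramp a [thermal_ramp].
#' @return A data frame with columns `temperature` and `ratio`; the number
#'   of masked points is attached as attribute `n_masked`.
#' @export
compute_ratio <- function(ramp) {
  stopifnot(inherits(ramp, "thermal_ramp"))
  ok <- ramp$f330 > 0
  if (!any(ok)) stop("all F330 values are zero; no ratio defined",
                     call. = FALSE)
  out <- data.frame(temperature = ramp$temperature[ok],
                    ratio = ramp$f350[ok] / ramp$f330[ok])
  attr(out, "n_masked") <- sum(!ok)
  out
}

## smoothed first derivative dy/dx on a (near-)uniform grid;
## Savitzky-Golay when the grid is uniform, central differences otherwise
smoothed_derivative <- function(x, y, window = 11L, order = 3L) {
  n <- length(x)
  window <- min(as.integer(window), if (n %% 2L) n else n - 1L)
  window <- max(window, order + 1L)
  if (window %% 2L == 0L) window <- window + 1L
  dx <- diff(x)
  uniform <- diff(range(dx)) < 1e-8 * mean(dx)
  if (uniform) {
    d <- signal::sgolayfilt(y, p = order, n = window, m = 1L) / mean(dx)
    ys <- signal::sgolayfilt(y, p = order, n = window, m = 0L)
  } else {
    ys <- moving_average(y, window)
    d <- c(diff(ys)[1L] / dx[1L],
           (ys[-(1:2)] - ys[1:(n - 2L)]) / (x[-(1:2)] - x[1:(n - 2L)]),
           diff(ys)[n - 1L] / dx[n - 1L])
  }
  list(smoothed = ys, derivative = d)
}

#' Locate thermal transitions from the first-derivative extremum
#'
#' Melting temperatures are read off as extrema of the first derivative of
#' the (smoothed) signal with respect to temperature — the conventional
#' "minimum of the first derivative" for transitions where the ratio
#' falls, and the mirror maximum where it rises.  The same machinery
#' locates the midpoint of a scattering transition (aggregation midpoint).
#' Extrema are kept when their prominence in |dy/dT| exceeds
#' `min_prominence`; the reported temperature is the centroid of the
#' derivative peak above its half height, which averages grid noise
#' instead of pinning the transition to the noisiest single point.  The
#' leading and trailing half-window of the smoothing filter is excluded
#' from peak detection (filter edge artifacts).
#'
#' @param temperature,y the curve; at least 20 points, e.g. from
#'   [compute_ratio()].
#' @param smooth_window,smooth_order Savitzky–Golay window (points, odd)
#'   and polynomial order used for the derivative estimate.  The default
#'   21-point cubic window spans ~2 °C on the usual 0.1 °C grid — narrow
#'   against the >5 °C width of a protein unfolding transition, wide
#'   enough to suppress counting noise.
#' @param min_prominence prominence floor on `|dy/dT|`; default
#'   (`NULL`) is the larger of 10% of the biggest derivative magnitude
#'   and twelve times the derivative's noise level (estimated from the
#'   median absolute point-to-point difference), which keeps any genuine
#'   transition and discards smoothing ripple and noise maxima.
#' @return A data frame with columns `tm` (°C), `prominence`
#'   (°C^-1 units of the signal), `sign` (+1 rising, -1 falling),
#'   sorted ascending by `tm`; zero rows when the curve has no transition
#'   (e.g. a straight line).
#' @examples
#' ramp <- gen_dsf_ramp(tm = 84, noise = 0, seed = 1)
#' rt <- compute_ratio(ramp)
#' find_transitions(rt$temperature, rt$ratio)
#' @export
find_transitions <- function(temperature, y, smooth_window = 21,
                             smooth_order = 3, min_prominence = NULL) {
  if (is.data.frame(temperature)) {
    y <- temperature[[2L]]
    temperature <- temperature[[1L]]
  }
  n <- length(temperature)
  if (n < 20L)
    stop("at least 20 points are required", call. = FALSE)
  sd_ <- smoothed_derivative(temperature, y, smooth_window, smooth_order)
  d <- sd_$derivative
  trim <- min(smooth_window %/% 2L, (n - 4L) %/% 4L)
  core <- (trim + 1L):(n - trim)
  sigma_d <- 1.4826 * stats::mad(diff(d[core]), center = 0) / sqrt(2)
  min_prominence <- min_prominence %||%
    max(0.1 * max(abs(d[core])), 12 * sigma_d)

  ## half-height centroid of the derivative peak at index i
  locate <- function(v, i) {
    thr <- 0.5 * v[i]
    lo <- i; while (lo > 1L && v[lo - 1L] >= thr) lo <- lo - 1L
    hi <- i; while (hi < n && v[hi + 1L] >= thr) hi <- hi + 1L
    idx <- lo:hi
    sum((v[idx] - thr) * temperature[idx]) / sum(v[idx] - thr)
  }

  collect <- function(sgn) {
    v <- sgn * d
    at <- local_maxima(v)
    at <- at[at %in% core & v[at] > 0]
    if (!length(at)) return(NULL)
    prom <- vapply(at, function(i) peak_prominence(v, i), numeric(1))
    keep <- prom > min_prominence
    if (!any(keep)) return(NULL)
    data.frame(
      tm = vapply(at[keep], function(i) locate(v, i), numeric(1)),
      prominence = prom[keep], sign = sgn)
  }
  out <- rbind(collect(+1), collect(-1))
  if (is.null(out))
    return(data.frame(tm = numeric(0), prominence = numeric(0),
                      sign = numeric(0)))
  out <- out[order(out$tm), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Aggregation onset from backscattering (1% rule)
#'
#' The onset of thermally induced aggregation is taken as the temperature
#' where the backscattering signal first rises past a small fraction
#' (default 1%) of its transition amplitude — interpretable as the
#' temperature at which ~1% of the protein has aggregated.  The baseline
#' is the median of the first `baseline_frac` of points, the plateau the
#' maximum of the smoothed trace, and the crossing is located on the
#' smoothed, baseline-normalized trace by linear interpolation between
#' grid points.  When the total rise is smaller than `noise_mult` standard
#' deviations of the baseline window, no aggregation is reported.
#'
#' @param temperature,scattering the scattering trace; >= 20 points.
#' @param fraction amplitude fraction defining the onset (default 0.01).
#' @param baseline_frac fraction of leading points used for the baseline
#'   and its noise estimate (default 0.1).
#' @param smooth_window,smooth_order smoothing of the trace before the
#'   plateau and crossing search.
#' @param noise_mult rise-versus-noise multiple below which the curve is
#'   called flat.
#' @return Onset temperature in °C, or `NA_real_` when no aggregation is
#'   detected.
#' @export
find_aggregation_onset <- function(temperature, scattering,
                                   fraction = 0.01, baseline_frac = 0.1,
                                   smooth_window = 11, smooth_order = 3,
                                   noise_mult = 5) {
  if (is.data.frame(temperature)) {
    scattering <- temperature[[2L]]
    temperature <- temperature[[1L]]
  }
  n <- length(temperature)
  if (n < 20L) stop("at least 20 points are required", call. = FALSE)
  nb <- max(3L, floor(baseline_frac * n))
  baseline <- stats::median(scattering[seq_len(nb)])
  noise <- stats::sd(scattering[seq_len(nb)])
  sm <- smoothed_derivative(temperature, scattering,
                            smooth_window, smooth_order)$smoothed
  plateau <- max(sm)
  amplitude <- plateau - baseline
  if (!is.finite(amplitude) || amplitude <= 0 ||
      amplitude < noise_mult * noise)
    return(NA_real_)
  z <- (sm - baseline) / amplitude
  above <- which(z >= fraction)
  if (!length(above)) return(NA_real_)
  i <- above[1L]
  if (i == 1L) return(temperature[1L])
  ## linear interpolation between the straddling grid points
  t0 <- temperature[i - 1L]; t1 <- temperature[i]
  z0 <- z[i - 1L]; z1 <- z[i]
  if (z1 == z0) return(t1)
  t0 + (fraction - z0) / (z1 - z0) * (t1 - t0)
}

#' Full nanoDSF analysis of one capillary
#'
#' Convenience wrapper running the standard analysis: fluorescence-ratio
#' transitions (melting temperatures), scattering-based aggregation onset
#' and midpoint, and the initial-fluorescence acquisition check.
#'
#' @param ramp a [thermal_ramp].
#' @param blank optional buffer-control [thermal_ramp] on the same grid;
#'   its fluorescence (and scattering, if present) is subtracted
#'   point-by-point before analysis.
#' @param onset_fraction passed to [find_aggregation_onset()].
#' @param ... passed to [find_transitions()].
#' @return An object of class `dsf_result`: `label`, `tm_values` (data
#'   frame from [find_transitions()]), `tm` (highest-prominence melting
#'   temperature or `NA`), `t_onset_agg`, `t_agg_mid`,
#'   `initial_fluorescence_ok`, `ratio` (the ratio curve).
#' @export
analyze_dsf <- function(ramp, blank = NULL, onset_fraction = 0.01, ...) {
  stopifnot(inherits(ramp, "thermal_ramp"))
  if (!is.null(blank)) ramp <- subtract_blank(ramp, blank)
  rt <- compute_ratio(ramp)
  trans <- find_transitions(rt$temperature, rt$ratio, ...)
  tm <- if (nrow(trans)) trans$tm[which.max(trans$prominence)] else NA_real_
  t_onset <- NA_real_; t_mid <- NA_real_
  if (!is.null(ramp$scattering)) {
    t_onset <- find_aggregation_onset(ramp$temperature, ramp$scattering,
                                      fraction = onset_fraction)
    strans <- find_transitions(ramp$temperature, ramp$scattering, ...)
    if (nrow(strans))
      t_mid <- strans$tm[which.max(strans$prominence)]
  }
  structure(
    list(label = ramp$label, tm_values = trans, tm = tm,
         t_onset_agg = t_onset, t_agg_mid = t_mid,
         initial_fluorescence_ok = check_initial_fluorescence(ramp)$ok,
         ratio = rt),
    class = "dsf_result"
  )
}

#' @export
print.dsf_result <- function(x, ...) {
  cat(sprintf("nanoDSF analysis '%s'\n", x$label))
  cat(sprintf("  Tm (dominant): %s degC; %d transition(s)\n",
              if (is.na(x$tm)) "none" else sprintf("%.2f", x$tm),
              nrow(x$tm_values)))
  cat(sprintf("  aggregation onset: %s; midpoint: %s\n",
              if (is.na(x$t_onset_agg)) "none" else
                sprintf("%.2f degC", x$t_onset_agg),
              if (is.na(x$t_agg_mid)) "none" else
                sprintf("%.2f degC", x$t_agg_mid)))
  cat(sprintf("  initial fluorescence in range: %s\n",
              x$initial_fluorescence_ok))
  invisible(x)
}

#' Subtract a buffer-control ramp
#'
#' Point-by-point subtraction of a blank (buffer-only) capillary measured
#' on the same temperature grid; negative results are clipped at zero.
#'
#' @param ramp,blank [thermal_ramp] objects sharing one grid.
#' @return A corrected [thermal_ramp].
#' @export
subtract_blank <- function(ramp, blank) {
  stopifnot(inherits(ramp, "thermal_ramp"), inherits(blank, "thermal_ramp"))
  if (!isTRUE(all.equal(ramp$temperature, blank$temperature)))
    stop("ramp and blank must share one temperature grid", call. = FALSE)
  sc <- ramp$scattering
  if (!is.null(sc) && !is.null(blank$scattering))
    sc <- sc - blank$scattering
  thermal_ramp(ramp$temperature,
               pmax(ramp$f330 - blank$f330, 0),
               pmax(ramp$f350 - blank$f350, 0),
               sc, label = ramp$label)
}

#' Rank screening conditions by melting temperature
#'
#' Detergent / buffer screens are summarized by the dominant melting
#' temperature of each condition, sorted most stable first, with the shift
#' relative to a reference condition (typically the solubilization
#' detergent).  Ties are broken alphabetically by label.
#'
#' @param results named list of `dsf_result` objects (see [analyze_dsf()]),
#'   or a data frame with columns `label` and `tm`.
#' @param reference_label label of the reference condition.
#' @return A data frame `label`, `tm`, `delta_tm` sorted descending by
#'   `tm` (ties by label).
#' @export
rank_conditions <- function(results, reference_label) {
  if (is.data.frame(results)) {
    tab <- results[, c("label", "tm")]
  } else {
    tab <- data.frame(
      label = vapply(results, function(r) r$label, character(1)),
      tm = vapply(results, function(r) r$tm, numeric(1)))
  }
  if (any(is.na(tab$tm)))
    stop("every condition must have at least one melting temperature",
         call. = FALSE)
  if (!reference_label %in% tab$label)
    stop("reference label '", reference_label, "' not among the results",
         call. = FALSE)
  ref_tm <- tab$tm[tab$label == reference_label][1L]
  tab$delta_tm <- tab$tm - ref_tm
  tab <- tab[order(-tab$tm, tab$label), , drop = FALSE]
  rownames(tab) <- NULL
  tab
}

#' Initial-fluorescence acquisition check
#'
#' Instrument guidance puts usable initial fluorescence between 2000 and
#' 15000 counts in both channels; outside that range the excitation power
#' or concentration should be adjusted before the ramp.
#'
#' @param ramp a [thermal_ramp].
#' @param range acceptable initial count range.
#' @return A list with `ok` (logical) and `message`.
#' @export
check_initial_fluorescence <- function(ramp, range = c(2000, 15000)) {
  stopifnot(inherits(ramp, "thermal_ramp"))
  f0 <- c(f330 = ramp$f330[1L], f350 = ramp$f350[1L])
  ok <- all(f0 >= range[1L] & f0 <= range[2L])
  msg <- if (ok) {
    sprintf("initial counts %.0f / %.0f within [%d, %d]",
            f0[1L], f0[2L], range[1L], range[2L])
  } else {
    sprintf("initial counts %.0f / %.0f outside [%d, %d]; adjust excitation or concentration",
            f0[1L], f0[2L], range[1L], range[2L])
  }
  list(ok = ok, message = msg)
}
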