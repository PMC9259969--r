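#' Bin mass-photometry events into a mass histogram
#'
#' Builds a uniform histogram of event masses over a half-open window
#' `[lo, hi)`.  Events outside the window (including negative-valued
#' unbinding events when `lo >= 0`) are excluded from the counts but their
#' number is recorded, so the decomposition downstream only ever sees the
#' observable mass range.
#'
#' @param events an [mp_events] object with `kind = "mass"`.
#' @param bin_width bin width in kDa (> 0).  Default 10 kDa.
#' @param window numeric length-2, `c(lo, hi)` in kDa with `hi > lo`; the
#'   histogram covers `[lo, hi)`.  Default `c(0, 2000)`.  If `hi - lo` is
#'   not a multiple of `bin_width` the last bin is clipped at `hi`.
#' @return An object of class `mass_histogram`: `bin_edges` (ascending),
#'   `counts` (integer, one fewer than edges), `mids`, `bin_width`,
#'   `window`, `n_excluded`.
#' @examples
#' h <- build_histogram(mp_events(c(50, 50, 70)), bin_width = 20,
#'                      window = c(40, 80))
#' h$counts  # 2 1
#' @export
build_histogram <- function(events, bin_width = 10, window = c(0, 2000)) {
  stopifnot(inherits(events, "mp_events"))
  if (events$kind != "mass")
    stop("histograms are built from mass events; calibrate contrasts first",
         call. = FALSE)
  stop_if_not_scalar_pos(bin_width, "bin_width")
  if (length(window) != 2L || window[2] <= window[1])
    stop("`window` must be c(lo, hi) with hi > lo", call. = FALSE)
  lo <- window[1]; hi <- window[2]

  edges <- seq(lo, hi, by = bin_width)
  if (edges[length(edges)] < hi) edges <- c(edges, hi)
  nbin <- length(edges) - 1L

  v <- events$values
  inside <- v >= lo & v < hi
  n_excluded <- sum(!inside)
  idx <- pmin(nbin, 1L + floor((v[inside] - lo) / bin_width))
  counts <- tabulate(idx, nbins = nbin)
  if (sum(counts) == 0L)
    warning("0 events in window [", lo, ", ", hi, ")", call. = FALSE)

  structure(
    list(bin_edges = edges, counts = as.integer(counts),
         mids = (edges[-1L] + edges[-length(edges)]) / 2,
         bin_width = bin_width, window = c(lo, hi),
         n_excluded = n_excluded),
    class = "mass_histogram"
  )
}

#' @export
print.mass_histogram <- function(x, ...) {
  cat(sprintf(
    "Mass histogram: %d bins of %.4g kDa over [%.4g, %.4g); %d events (%d excluded)\n",
    length(x$counts), x$bin_width, x$window[1], x$window[2],
    sum(x$counts), x$n_excluded))
  invisible(x)
}

#' Detect candidate mass peaks to seed the mixture fit
#'
#' Smooths the histogram counts with a centered moving average and reports
#' local maxima above a count floor, enforcing a minimum separation between
#' peaks (when two maxima are closer, the taller one wins).  Each peak
#' yields an initial guess for one truncated-Gaussian component: the mean
#' at the bin center, a width of `max(sigma_floor, sigma_rel * mu)` —
#' reflecting the roughly mass-proportional resolution of the instrument —
#' and a count from the local histogram area within two widths of the peak.
#' These guesses seed [fit_truncated_mixture()] and, as with any automatic
#' peak picker, should be reviewed (and overridden) by the user when the
#' histogram is crowded.
#'
#' @param hist a [build_histogram()] result.
#' @param min_count smallest smoothed bin count accepted as a peak.
#' @param min_separation minimum distance between reported peaks in kDa;
#'   default four bin widths.
#' @param smooth_window moving-average window in bins (odd; default 5).
#' @param sigma_floor,sigma_rel width-guess parameters (kDa and relative).
#' @return A data frame with columns `mu`, `sigma`, `n` (one row per
#'   guess), sorted ascending by `mu`; zero rows when nothing qualifies.
#' @export
detect_peaks <- function(hist, min_count = 5, min_separation = NULL,
                         smooth_window = 5, sigma_floor = 15,
                         sigma_rel = 0.08) {
  stopifnot(inherits(hist, "mass_histogram"))
  if (!length(hist$counts)) stop("empty histogram", call. = FALSE)
  min_separation <- min_separation %||% (4 * hist$bin_width)

  sm <- moving_average(as.numeric(hist$counts), smooth_window)
  cand <- local_maxima(sm)
  cand <- cand[sm[cand] >= min_count]
  if (!length(cand))
    return(data.frame(mu = numeric(0), sigma = numeric(0), n = numeric(0)))

  ## greedy separation filter, tallest first
  cand <- cand[order(sm[cand], decreasing = TRUE)]
  kept <- integer(0)
  for (i in cand) {
    if (!length(kept) ||
        all(abs(hist$mids[i] - hist$mids[kept]) >= min_separation))
      kept <- c(kept, i)
  }
  kept <- sort(kept)

  mu0 <- hist$mids[kept]
  sigma0 <- pmax(sigma_floor, sigma_rel * mu0)
  n0 <- vapply(seq_along(kept), function(j) {
    lo <- mu0[j] - 2 * sigma0[j]
    hi <- mu0[j] + 2 * sigma0[j]
    sum(hist$counts[hist$mids >= lo & hist$mids <= hi])
  }, numeric(1))
  data.frame(mu = mu0, sigma = sigma0, n = pmax(n0, 1))
}
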