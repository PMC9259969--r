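#' Hydrodynamic-radius weight distributions
#'
#' A `size_distribution` is a discrete weight distribution over a grid of
#' hydrodynamic radii, in one of three weightings: `intensity` (what DLS
#' measures), `mass`, or `number`.  Inversion results live on a log-spaced
#' grid; constructed distributions (e.g. a pair of delta peaks) may use
#' any positive ascending grid.
#'
#' @param rh radii in nm, positive, strictly increasing.
#' @param weights non-negative weights; normalized to sum 1.
#' @param weighting `"intensity"`, `"mass"` or `"number"`.
#' @return An object of class `size_distribution`.
#' @export
size_distribution <- function(rh, weights,
                              weighting = c("intensity", "mass", "number")) {
  weighting <- match.arg(weighting)
  rh <- as.numeric(rh); weights <- as.numeric(weights)
  if (length(rh) != length(weights))
    stop("rh and weights must have equal length", call. = FALSE)
  if (any(rh <= 0) || any(diff(rh) <= 0))
    stop("rh grid must be positive and strictly increasing", call. = FALSE)
  if (any(weights < 0)) stop("weights must be non-negative", call. = FALSE)
  s <- sum(weights)
  if (s <= 0) stop("weights must not all be zero", call. = FALSE)
  structure(list(rh = rh, weights = weights / s, weighting = weighting),
            class = "size_distribution")
}

#' @export
print.size_distribution <- function(x, ...) {
  cat(sprintf("Size distribution (%s-weighted): %d grid points, %.3g-%.3g nm\n",
              x$weighting, length(x$rh), min(x$rh), max(x$rh)))
  pk <- extract_peaks(x, min_percent = 1)
  if (nrow(pk)) {
    for (i in seq_len(nrow(pk)))
      cat(sprintf("  peak %d: Rh = %.2f nm (%.1f%% of %s)\n",
                  i, pk$rh_mean[i], pk$percent[i], x$weighting))
  }
  invisible(x)
}

#' Invert a correlogram into a smooth radius distribution
#'
#' Regularized inversion of the Laplace-like problem behind DLS: find
#' non-negative intensity weights `w` on a log-spaced radius grid
#' minimizing
#' \deqn{\| K w - g_1 \|^2 + \alpha' \| L w \|^2,\quad
#'   K_{ij} = e^{-q^2 D(r_j) \tau_i},}
#' where \eqn{L} is the second-difference operator enforcing smoothness and
#' \eqn{g_1} is obtained from the Siegert relation with baseline `B` and
#' intercept `beta`, themselves refined by alternating linear fits.  The
#' non-negative least squares subproblem is solved exactly
#' ([pracma::lsqnonneg()]); the penalty scale is
#' `alpha^2 * ||K||_F^2 / ||L||_F^2`, so `alpha` is relative to the data
#' scale.  Species whose radii differ by a factor of ~3 or more are
#' resolved at typical noise; closer pairs merge into one broadened peak —
#' an intrinsic limit of the ill-posed inversion, not of the solver.
#'
#' @param corr a [correlogram].
#' @param grid `c(min_nm, max_nm, n_points)`; default 100 log-spaced
#'   points spanning 0.1–1000 nm.
#' @param alpha smoothness regularization (default 0.01, relative to the
#'   data scale).  The default is the largest value that still resolves
#'   species whose radii differ by a factor of 3 at 1e-3 noise; larger
#'   values merge such pairs into one broad peak.
#' @param n_outer alternations between the weight solve and the (B, beta)
#'   refresh.
#' @return A [size_distribution] (`weighting = "intensity"`) with
#'   attributes `B`, `beta`, `residual_norm`, and `chi2_dof` when the fit
#'   succeeded.
#' @export
fit_size_distribution <- function(corr, grid = c(0.1, 1000, 100),
                                  alpha = 0.01, n_outer = 3L) {
  stopifnot(inherits(corr, "correlogram"))
  if (length(grid) != 3L || grid[1L] <= 0 || grid[2L] <= grid[1L] ||
      grid[3L] < 10)
    stop("`grid` must be c(min_nm, max_nm, n_points >= 10)", call. = FALSE)
  tau <- corr$tau; g2 <- corr$g2
  rh <- 10^seq(log10(grid[1L]), log10(grid[2L]), length.out = grid[3L])
  m <- length(rh)
  gamma <- scattering_vector(corr$conditions)^2 *
    diffusion_from_radius(rh * 1e-9, corr$conditions$temperature,
                          corr$conditions$viscosity)
  K <- exp(-outer(tau, gamma))

  ## second-difference penalty
  L <- matrix(0, m - 2L, m)
  for (i in seq_len(m - 2L)) L[i, i:(i + 2L)] <- c(1, -2, 1)
  lam <- alpha^2 * sum(K^2) / sum(L^2)

  ntail <- max(3L, ceiling(length(tau) * 0.1))
  B <- mean(utils::tail(g2, ntail))
  beta <- max(max(g2) - B, 1e-6)
  w <- NULL
  for (it in seq_len(n_outer)) {
    ## signed square root: plain sqrt(pmax(.,0)) would rectify baseline
    ## noise into a spurious slow tail; the signed form averages it out.
    ## Rows are weighted by sqrt(|z|) (inverse std of the transformed
    ## noise), which makes the solve first-order equivalent to least
    ## squares on g2 itself.
    z <- (g2 - B) / beta
    y <- sign(z) * sqrt(abs(z))
    r <- sqrt(pmax(abs(z), 1e-3 * max(abs(z))))
    A <- rbind(r * K, sqrt(lam * mean(r^2)) * L)
    w <- pracma::lsqnonneg(A, c(r * y, numeric(m - 2L)))$x
    if (sum(w) <= 0) break
    g1 <- as.vector(K %*% (w / sum(w)))
    lf <- stats::lm(g2 ~ I(g1^2))
    B_new <- unname(stats::coef(lf)[1L])
    beta_new <- unname(stats::coef(lf)[2L])
    if (is.finite(beta_new) && beta_new > 0) {
      B <- B_new; beta <- beta_new
    }
  }
  if (is.null(w) || sum(w) <= 0)
    stop("no decay detected: inversion returned an all-zero distribution",
         call. = FALSE)

  dist <- size_distribution(rh, w, weighting = "intensity")
  g2_hat <- dls_g2_model(tau, rh, dist$weights, corr$conditions, B, beta)
  rss <- sum((g2 - g2_hat)^2)
  attr(dist, "B") <- B
  attr(dist, "beta") <- beta
  attr(dist, "residual_norm") <- rss
  attr(dist, "chi2_dof") <- rss / max(1L, length(tau) - 2L)
  dist
}

#' Convert a size distribution between weightings
#'
#' Under the compact-sphere Rayleigh convention the scattered intensity of
#' a particle scales as mass × R^3 and mass as number × R^3, so
#' mass weights are intensity / R^3 and number weights intensity / R^6
#' (renormalized).  The maps are exact inverses of each other on any grid
#' with positive weights.
#'
#' @param dist a [size_distribution].
#' @param target `"intensity"`, `"mass"` or `"number"`.
#' @return A [size_distribution] in the target weighting.
#' @examples
#' d <- size_distribution(c(5, 21.5), c(0.5, 0.5), "intensity")
#' reweight_distribution(d, "mass")$weights
#' @export
reweight_distribution <- function(dist,
                                  target = c("intensity", "mass", "number")) {
  stopifnot(inherits(dist, "size_distribution"))
  target <- match.arg(target)
  ## exponent of R in the weight relative to number weighting:
  ## intensity = number * R^6, mass = number * R^3
  expo <- c(intensity = 6, mass = 3, number = 0)
  shift <- expo[[target]] - expo[[dist$weighting]]
  w <- dist$weights * dist$rh^shift
  size_distribution(dist$rh, w, weighting = target)
}

#' Extract peaks from a size distribution
#'
#' Splits the support of the distribution into contiguous regions of
#' positive weight — divided at interior local minima and wherever
#' neighbouring grid points are further apart than `gap_factor` (so
#' isolated delta components on a sparse grid count as separate peaks) —
#' and reports for each region its weight-averaged radius and its percent
#' of the current weighting.  Regions below `min_percent` are dropped.
#'
#' @param dist a [size_distribution].
#' @param min_percent smallest region percent reported (default 1).
#' @param gap_factor radius ratio between consecutive grid points above
#'   which a run of positive weight is split (default 1.5; the standard
#'   100-point inversion grid has a neighbour ratio of ~1.1 and is never
#'   split by this rule).
#' @return A data frame `rh_mean` (nm), `percent`, `idx_lo`, `idx_hi`,
#'   sorted ascending by `rh_mean`; zero rows when nothing qualifies.
#' @export
extract_peaks <- function(dist, min_percent = 1, gap_factor = 1.5) {
  stopifnot(inherits(dist, "size_distribution"))
  w <- dist$weights
  pos <- w > 1e-12 * max(w)
  if (!any(pos))
    return(data.frame(rh_mean = numeric(0), percent = numeric(0),
                      idx_lo = integer(0), idx_hi = integer(0)))
  runs <- rle(pos)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  segments <- list()
  for (r in which(runs$values)) {
    lo <- starts[r]; hi <- ends[r]
    ## split the run at interior local minima and at wide grid gaps
    cuts <- integer(0)
    if (hi - lo >= 2L) {
      interior <- (lo + 1L):(hi - 1L)
      cuts <- interior[w[interior] < w[interior - 1L] &
                         w[interior] < w[interior + 1L]]
    }
    if (hi > lo) {
      gaps <- which(dist$rh[(lo + 1L):hi] / dist$rh[lo:(hi - 1L)] >
                      gap_factor) + lo - 1L
      cuts <- sort(unique(c(cuts, gaps)))
    }
    ## the minimum bin itself goes to the left-hand region
    bounds <- c(lo - 1L, cuts, hi)
    for (j in seq_len(length(bounds) - 1L)) {
      segments[[length(segments) + 1L]] <-
        c(bounds[j] + 1L, bounds[j + 1L])
    }
  }
  out <- do.call(rbind, lapply(segments, function(s) {
    i <- s[1L]:s[2L]
    tot <- sum(w[i])
    data.frame(rh_mean = sum(w[i] * dist$rh[i]) / tot,
               percent = 100 * tot, idx_lo = s[1L], idx_hi = s[2L])
  }))
  out <- out[out$percent >= min_percent, , drop = FALSE]
  out <- out[order(out$rh_mean), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Detect large aggregates
#'
#' A sample is flagged as containing macromolecular aggregates when more
#' than `max_percent` of the scattered intensity sits above
#' `cutoff_radius`.  Given a correlogram the distribution is first
#' obtained by [fit_size_distribution()]; a secondary slow-decay check
#' (two-exponential fit reducing the single-decay residual sum of squares
#' by at least `rss_improvement` with a slow radius above the cutoff)
#' corroborates the call.
#'
#' @param x a [size_distribution] or a [correlogram].
#' @param cutoff_radius radius threshold in nm (default 100).
#' @param max_percent flagged when the intensity percent above the cutoff
#'   exceeds this (default 5).
#' @param ... passed on to [fit_size_distribution()] for correlograms.
#' @return A list with `flagged`, `percent_above_cutoff`, `message`, and
#'   for correlograms `rss_two_component_ratio`.
#' @export
detect_aggregation <- function(x, cutoff_radius = 100, max_percent = 5,
                               ...) {
  UseMethod("detect_aggregation")
}

#' @export
detect_aggregation.size_distribution <- function(x, cutoff_radius = 100,
                                                 max_percent = 5, ...) {
  d <- if (x$weighting == "intensity") x else
    reweight_distribution(x, "intensity")
  pct <- 100 * sum(d$weights[d$rh > cutoff_radius])
  flagged <- pct > max_percent
  list(flagged = flagged, percent_above_cutoff = pct,
       message = sprintf(
         "%.1f%% of scattered intensity above %g nm (threshold %g%%): %s",
         pct, cutoff_radius, max_percent,
         if (flagged) "aggregates detected" else "clean"))
}

#' @rdname detect_aggregation
#' @param rss_improvement fractional residual-sum-of-squares reduction the
#'   two-exponential fit must achieve (default 0.2) for the slow decay to
#'   count as a real second species.
#' @export
detect_aggregation.correlogram <- function(x, cutoff_radius = 100,
                                           max_percent = 5,
                                           rss_improvement = 0.2, ...) {
  dist <- fit_size_distribution(x, ...)
  out <- detect_aggregation(dist, cutoff_radius, max_percent)

  ## corroborating slow-decay test on the raw correlogram
  single <- fit_cumulants(x)
  tau <- x$tau; g2 <- x$g2
  resid2 <- function(p) {
    B <- p[1L]; beta <- p[2L]; g_f <- p[3L]; g_s <- p[4L]; wf <- p[5L]
    g1 <- wf * exp(-g_f * tau) + (1 - wf) * exp(-g_s * tau)
    g2 - (B + beta * g1^2)
  }
  q <- scattering_vector(x$conditions)
  gamma_cut <- q^2 * diffusion_from_radius(cutoff_radius * 1e-9,
                                           x$conditions$temperature,
                                           x$conditions$viscosity)
  two <- minpack.lm::nls.lm(
    par = c(single$B, single$beta, single$gamma * 2, single$gamma / 10,
            0.9),
    lower = c(-Inf, 1e-12, 1e-12, 1e-12, 0),
    upper = c(Inf, Inf, Inf, Inf, 1),
    fn = resid2,
    control = minpack.lm::nls.lm.control(maxiter = 300))
  rss_ratio <- sum(two$fvec^2) / single$residual_norm
  slow_gamma <- min(two$par[3:4])
  slow_is_aggregate <- slow_gamma < gamma_cut &&
    rss_ratio <= (1 - rss_improvement)
  out$rss_two_component_ratio <- rss_ratio
  out$flagged <- out$flagged || slow_is_aggregate
  if (slow_is_aggregate && out$percent_above_cutoff <= max_percent)
    out$message <- paste0(out$message,
                          "; slow secondary decay confirms aggregates")
  out
}
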