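#' Expected bin counts of a left-truncated Gaussian mixture
#'
#' Forward model of the histogram decomposition.  Each component is a
#' normal distribution in mass, truncated on the left at the instrument's
#' detection limit `t`: landing events lighter than `t` produce no
#' detectable contrast, so the model places exactly zero expectation in any
#' bin that lies entirely below `t`, and a clipped probability mass in the
#' bin that straddles it.  The expected count in bin `[l, u)` is
#'
#' \deqn{E = \sum_k N_k \frac{\Phi((u-\mu_k)/\sigma_k) -
#'   \Phi((\max(l,t)-\mu_k)/\sigma_k)}{1 - \Phi((t-\mu_k)/\sigma_k)}}
#'
#' with \eqn{\Phi} the standard normal CDF.  With `renormalize = TRUE`
#' (default) the division by the visible tail makes `N_k` the expected
#' number of *observable* events of component `k`; with `FALSE` the model
#' is simply zeroed below `t` and `N_k` counts the full (partly invisible)
#' population.
#'
#' @param bin_edges ascending bin edges (kDa).
#' @param mu,sigma,n component means (kDa), widths (kDa, > 0) and counts.
#' @param truncation_limit detection limit `t` in kDa.
#' @param renormalize renormalize each component on `[t, Inf)`.
#' @return Numeric vector of expected counts, one per bin.
#' @export
truncated_mixture_expected <- function(bin_edges, mu, sigma, n,
                                       truncation_limit,
                                       renormalize = TRUE) {
  l <- bin_edges[-length(bin_edges)]
  u <- bin_edges[-1L]
  lp <- pmax(l, truncation_limit)
  expected <- numeric(length(l))
  for (k in seq_along(mu)) {
    cell <- stats::pnorm((u - mu[k]) / sigma[k]) -
      stats::pnorm((lp - mu[k]) / sigma[k])
    cell[u <= truncation_limit] <- 0
    if (renormalize) {
      visible <- 1 - stats::pnorm((truncation_limit - mu[k]) / sigma[k])
      cell <- if (visible < 1e-12) cell * 0 else cell / visible
    }
    expected <- expected + n[k] * pmax(cell, 0)
  }
  expected
}

#' Fit a left-truncated multi-Gaussian to a mass histogram
#'
#' Decomposes a mass histogram into Gaussian populations truncated at the
#' instrument's lower detection limit, by bounded least squares on the bin
#' counts: minimize \eqn{\sum_i (c_i - E_i)^2} over all component means,
#' widths and counts, with \eqn{E_i} given by
#' [truncated_mixture_expected()].  Truncation matters whenever a
#' population sits close to the detection limit (~30 kDa for typical
#' instruments): an untruncated Gaussian would be biased high in mean and
#' low in width there.
#'
#' @param hist a [build_histogram()] result.
#' @param guesses data frame of initial guesses with columns `mu`, `sigma`,
#'   `n` (one row per component), e.g. from [detect_peaks()]; at least one
#'   row.
#' @param truncation_limit detection limit `t` in kDa (default 30).
#' @param renormalize see [truncated_mixture_expected()].
#' @param control passed to [minpack.lm::nls.lm.control()]; defaults run a
#'   tight trust-region Levenberg–Marquardt (`ftol = 1e-10`).
#' @return An object of class `mp_mixture_fit`: `components` (data frame
#'   `mu`, `sigma`, `n`, `fraction`, sorted ascending by `mu`),
#'   `truncation_limit`, `histogram`, `fitted` (expected counts),
#'   `residual_norm`, `r_squared`, `converged`.  Components whose fitted
#'   means collapse onto one another (closer than one bin width) are merged
#'   with a warning.
#' @examples
#' ev <- gen_mp_events(data.frame(mu = 480, sigma = 38, count = 3000),
#'                     detection_limit = 30, seed = 1)
#' h <- build_histogram(ev, 10, c(0, 800))
#' fit <- fit_truncated_mixture(h, detect_peaks(h), truncation_limit = 30)
#' fit$components
#' @export
fit_truncated_mixture <- function(hist, guesses, truncation_limit = 30,
                                  renormalize = TRUE, control = NULL) {
  stopifnot(inherits(hist, "mass_histogram"))
  if (!is.data.frame(guesses) || nrow(guesses) < 1L ||
      !all(c("mu", "sigma", "n") %in% names(guesses)))
    stop("`guesses` must be a data frame with columns mu, sigma, n and >= 1 row",
         call. = FALSE)
  if (truncation_limit > hist$window[2])
    stop("truncation limit lies above the histogram window", call. = FALSE)

  K <- nrow(guesses)
  counts <- as.numeric(hist$counts)
  edges <- hist$bin_edges
  sigma_lb <- 1e-3
  lower <- c(rep(-Inf, K), rep(sigma_lb, K), rep(0, K))

  resid_fn <- function(p) {
    counts - truncated_mixture_expected(
      edges, p[1:K], p[(K + 1):(2 * K)], p[(2 * K + 1):(3 * K)],
      truncation_limit, renormalize)
  }
  control <- control %||%
    minpack.lm::nls.lm.control(ftol = 1e-10, ptol = 1e-10, maxiter = 500)

  ## deterministic multi-start: the supplied widths, local-moment widths
  ## estimated from the histogram around each guess, and halved widths --
  ## narrow populations sitting in a couple of bins otherwise risk a
  ## degenerate (delta-like) local minimum
  sigma0 <- pmax(guesses$sigma, sigma_lb)
  sigma_mom <- vapply(seq_len(K), function(k) {
    sel <- abs(hist$mids - guesses$mu[k]) <= 3 * sigma0[k]
    if (sum(hist$counts[sel]) < 2) return(sigma0[k])
    m <- sum(hist$counts[sel] * hist$mids[sel]) / sum(hist$counts[sel])
    v <- sum(hist$counts[sel] * (hist$mids[sel] - m)^2) /
      sum(hist$counts[sel]) - hist$bin_width^2 / 12
    if (v <= 0) sigma0[k] else min(sigma0[k], sqrt(v))
  }, numeric(1))
  starts <- unique(list(sigma0, sigma_mom, sigma0 / 2))

  best <- NULL
  for (s in starts) {
    par0 <- c(guesses$mu, pmax(s, sigma_lb), pmax(guesses$n, 0))
    fit <- tryCatch(
      minpack.lm::nls.lm(par = par0, lower = lower, fn = resid_fn,
                         control = control),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || sum(fit$fvec^2) < sum(best$fvec^2)) best <- fit
  }
  if (is.null(best))
    stop("truncated-mixture fit failed from every starting point",
         call. = FALSE)
  fit <- best
  converged <- fit$info %in% 1:4
  if (!converged)
    warning("truncated-mixture fit did not converge: ", fit$message,
            call. = FALSE)

  p <- fit$par
  comp <- data.frame(mu = p[1:K], sigma = p[(K + 1):(2 * K)],
                     n = p[(2 * K + 1):(3 * K)])
  if (any(comp$sigma <= sigma_lb * 1.0001))
    warning("one or more component widths hit the lower bound",
            call. = FALSE)
  comp <- merge_close_components(comp, hist$bin_width)
  comp <- comp[order(comp$mu), , drop = FALSE]
  rownames(comp) <- NULL
  total <- sum(comp$n)
  comp$fraction <- if (total > 0) comp$n / total else rep(0, nrow(comp))

  fitted <- truncated_mixture_expected(edges, comp$mu, comp$sigma, comp$n,
                                       truncation_limit, renormalize)
  ss_res <- sum((counts - fitted)^2)
  ss_tot <- sum((counts - mean(counts))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_

  structure(
    list(components = comp, truncation_limit = truncation_limit,
         histogram = hist, fitted = fitted, residual_norm = ss_res,
         r_squared = r2, converged = converged,
         renormalize = renormalize),
    class = "mp_mixture_fit"
  )
}

## components closer than one bin width are indistinguishable on this
## histogram: merge them (count-weighted) rather than report a split peak
merge_close_components <- function(comp, bin_width) {
  comp <- comp[order(comp$mu), , drop = FALSE]
  repeat {
    if (nrow(comp) < 2L) return(comp)
    gaps <- diff(comp$mu)
    j <- which(gaps < bin_width)
    if (!length(j)) return(comp)
    j <- j[1L]
    w <- comp$n[j] + comp$n[j + 1L]
    wts <- if (w > 0) comp$n[j:(j + 1L)] / w else c(0.5, 0.5)
    merged <- data.frame(
      mu = sum(wts * comp$mu[j:(j + 1L)]),
      sigma = sum(wts * comp$sigma[j:(j + 1L)]),
      n = w)
    warning(sprintf(
      "merged two components converging at %.1f kDa (closer than one bin width)",
      merged$mu), call. = FALSE)
    comp <- rbind(comp[seq_len(j - 1L), ], merged,
                  comp[setdiff(seq_len(nrow(comp)), seq_len(j + 1L)), ])
    comp <- comp[order(comp$mu), , drop = FALSE]
  }
}

#' @export
print.mp_mixture_fit <- function(x, ...) {
  cat(sprintf(
    "Left-truncated Gaussian mixture fit (t = %.4g kDa, %s)\n",
    x$truncation_limit,
    if (x$converged) "converged" else "NOT converged"))
  comp <- x$components
  comp$percent <- 100 * comp$fraction
  print(format(comp, digits = 4), row.names = FALSE)
  cat(sprintf("  residual norm %.4g, R^2 = %.5f\n",
              x$residual_norm, x$r_squared))
  invisible(x)
}

#' Assign an oligomeric state to a fitted mass peak
#'
#' Finds the integer number of monomers whose total mass best matches a
#' fitted peak and reports the relative deviation.  A peak at 108 kDa with
#' an 18.5 kDa monomer, for example, is a hexamer at 2.7% deviation.  Note
#' that detergent-solubilized membrane proteins carry micelle mass, so
#' deviations well above tolerance may still be a protein–micelle complex
#' rather than a wrong assignment.
#'
#' @param peak_mass fitted peak mass in kDa (> 0).
#' @param monomer_mass monomer mass in kDa (> 0).
#' @param tolerance relative deviation accepted for the assignment
#'   (default 0.10).
#' @param n_max largest stoichiometry considered.
#' @return A list with `n` (integer >= 1), `rel_deviation`, `accepted`.
#' @examples
#' assign_stoichiometry(108, 18.5)  # hexamer
#' @export
assign_stoichiometry <- function(peak_mass, monomer_mass, tolerance = 0.10,
                                 n_max = 50L) {
  stop_if_not_scalar_pos(peak_mass, "peak_mass")
  stop_if_not_scalar_pos(monomer_mass, "monomer_mass")
  n <- max(1L, as.integer(round(peak_mass / monomer_mass)))
  n <- min(n, as.integer(n_max))
  rel <- abs(peak_mass - n * monomer_mass) / (n * monomer_mass)
  list(n = n, rel_deviation = rel, accepted = rel <= tolerance)
}
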