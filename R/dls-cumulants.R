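#' Cumulant analysis of a DLS correlogram
#'
#' Fits the standard second-order cumulant expansion
#' \deqn{g_2(\tau) = B + \beta e^{-2\Gamma\tau}
#'   \left(1 + \frac{\mu_2}{2}\tau^2\right)^2}
#' by nonlinear least squares, giving the mean decay rate \eqn{\Gamma},
#' the second cumulant \eqn{\mu_2} and the polydispersity index
#' \eqn{PDI = \mu_2/\Gamma^2}.  The diffusion coefficient follows as
#' \eqn{D = \Gamma/q^2} and the z-average hydrodynamic radius from the
#' Stokes–Einstein relation.  Cumulant analysis is the fastest route to a
#' size but is famously derailed by traces of aggregate; inspect the PDI
#' and prefer [fit_size_distribution()] when it exceeds ~0.3.
#'
#' @param corr a [correlogram].
#' @param noise_floor minimum dynamic range (max g2 - min g2) accepted.
#' @return An object of class `cumulant_fit`: `B`, `beta`, `gamma` (s^-1),
#'   `mu2` (s^-2, possibly clipped), `pdi`, `D` (m^2/s), `rh` (m),
#'   `residual_norm`, `converged`.
#' @examples
#' corr <- gen_correlogram(data.frame(rh = 5, mass_fraction = 1),
#'                         noise = 0, seed = 1)
#' fit_cumulants(corr)$rh * 1e9  # ~5 nm
#' @export
fit_cumulants <- function(corr, noise_floor = 1e-4) {
  stopifnot(inherits(corr, "correlogram"))
  tau <- corr$tau; g2 <- corr$g2
  if (diff(range(g2)) <= noise_floor)
    stop("correlogram has no usable dynamic range (no decay detected)",
         call. = FALSE)

  ## starting values: baseline from the tail, decay from the early slope
  ntail <- max(3L, ceiling(length(tau) * 0.1))
  B0 <- mean(utils::tail(g2, ntail))
  beta0 <- max(max(g2) - B0, noise_floor)
  early <- which((g2 - B0) > 0.2 * beta0)
  gamma0 <- if (length(early) >= 3L) {
    sl <- stats::coef(stats::lm(log(g2[early] - B0) ~ tau[early]))[[2L]]
    max(-sl / 2, 1 / max(tau))
  } else 1 / stats::median(tau)

  resid_fn <- function(p) {
    B <- p[1L]; beta <- p[2L]; gam <- p[3L]; mu2 <- p[4L]
    g2 - (B + beta * exp(-2 * gam * tau) * (1 + (mu2 / 2) * tau^2)^2)
  }
  fit <- minpack.lm::nls.lm(
    par = c(B0, beta0, gamma0, 0),
    lower = c(-Inf, 1e-12, 1e-12, -Inf),
    fn = resid_fn,
    control = minpack.lm::nls.lm.control(ftol = 1e-12, ptol = 1e-12,
                                         maxiter = 500))
  converged <- fit$info %in% 1:4
  if (!converged)
    warning("cumulant fit did not converge: ", fit$message, call. = FALSE)
  p <- fit$par
  mu2 <- p[4L]
  if (mu2 < 0) {
    warning("negative second cumulant clipped to 0 (pdi set to 0)",
            call. = FALSE)
    mu2 <- 0
  }
  gamma <- p[3L]
  q <- scattering_vector(corr$conditions)
  D <- gamma / q^2
  rh <- stokes_einstein_radius(D, corr$conditions$temperature,
                               corr$conditions$viscosity)
  structure(
    list(B = p[1L], beta = p[2L], gamma = gamma, mu2 = mu2,
         pdi = if (gamma > 0) mu2 / gamma^2 else NA_real_,
         D = D, rh = rh,
         residual_norm = sum(fit$fvec^2), converged = converged),
    class = "cumulant_fit"
  )
}

#' @export
print.cumulant_fit <- function(x, ...) {
  cat(sprintf(
    "Cumulant fit: Gamma = %.5g /s, PDI = %.4f, D = %.4g m^2/s, Rh = %.3f nm\n",
    x$gamma, x$pdi, x$D, x$rh * 1e9))
  cat(sprintf("  B = %.5f, beta = %.4f, residual norm %.3g (%s)\n",
              x$B, x$beta, x$residual_norm,
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}
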