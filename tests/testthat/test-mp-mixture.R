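test_that("model expectation is exactly zero below the truncation limit", {
  edges <- seq(0, 200, by = 10)
  for (t in c(30, 55, 95)) {
    e <- truncated_mixture_expected(edges, mu = 60, sigma = 30, n = 1000,
                                    truncation_limit = t)
    below <- which(edges[-1] <= t)
    expect_true(all(e[below] == 0))
    expect_true(all(e[-below] >= 0))
  }
})

test_that("renormalized components integrate to their observable count", {
  ## fine bins over a wide range approximate the [t, Inf) integral
  edges <- seq(40, 5000, by = 1)
  e <- truncated_mixture_expected(edges, mu = c(60, 300),
                                  sigma = c(25, 30), n = c(800, 200),
                                  truncation_limit = 40)
  expect_equal(sum(e), 1000, tolerance = 1e-6)
})

test_that("a noiseless model histogram is refit to its own parameters", {
  edges <- seq(0, 300, by = 10)
  truth <- list(mu = 100, sigma = 10, n = 1000)
  counts <- truncated_mixture_expected(edges, truth$mu, truth$sigma,
                                       truth$n, 30)
  h <- structure(list(bin_edges = edges, counts = counts,
                      mids = (edges[-1] + edges[-length(edges)]) / 2,
                      bin_width = 10, window = c(0, 300), n_excluded = 0L),
                 class = "mass_histogram")
  fit <- fit_truncated_mixture(
    h, data.frame(mu = 90, sigma = 15, n = 800), truncation_limit = 30)
  expect_true(fit$converged)
  expect_equal(fit$components$mu, truth$mu, tolerance = 1e-6)
  expect_equal(fit$components$sigma, truth$sigma, tolerance = 1e-6)
  expect_equal(fit$components$n, truth$n, tolerance = 1e-6)
  expect_lt(fit$residual_norm, 1e-10)
  expect_equal(fit$components$fraction, 1)
})

test_that("with the truncation far below the window the fit is plain Gaussian", {
  ev <- gen_mp_events(data.frame(mu = 200, sigma = 25, count = 4000),
                      detection_limit = 0, seed = 9)
  h <- build_histogram(ev, 10, c(50, 400))
  t_off <- 50 - 10 * 25
  fit <- fit_truncated_mixture(h, data.frame(mu = 190, sigma = 20, n = 4000),
                               truncation_limit = t_off)

  ## independent untruncated least squares on the same histogram
  l <- h$bin_edges[-length(h$bin_edges)]
  u <- h$bin_edges[-1]
  obj <- function(p) {
    e <- p[3] * (pnorm((u - p[1]) / p[2]) - pnorm((l - p[1]) / p[2]))
    sum((h$counts - e)^2)
  }
  plain <- stats::nlminb(c(190, 20, 4000), obj,
                         control = list(rel.tol = 1e-14,
                                        iter.max = 1000))$par
  expect_equal(fit$components$mu, plain[1], tolerance = 1e-6)
  expect_equal(fit$components$sigma, plain[2], tolerance = 1e-6)
  expect_equal(fit$components$n, plain[3], tolerance = 1e-6)

  ## and the model itself reduces to the untruncated formula exactly
  e_trunc <- truncated_mixture_expected(h$bin_edges, 200, 25, 1000, t_off)
  e_plain <- 1000 * (pnorm((u - 200) / 25) - pnorm((l - 200) / 25))
  expect_equal(e_trunc, e_plain, tolerance = 1e-12)
})

test_that("three seeded populations are recovered within 1.5% in mean", {
  ev <- gen_mp_events(micelle_complex_panel, detection_limit = 40, seed = 7)
  h <- build_histogram(ev, 10, c(0, 700))
  fit <- fit_truncated_mixture(h, detect_peaks(h), truncation_limit = 40)
  expect_true(fit$converged)
  expect_equal(nrow(fit$components), 3L)
  rel <- abs(fit$components$mu - micelle_complex_panel$mu) / micelle_complex_panel$mu
  expect_true(all(rel < 0.015))
  ## component counts within 5% of generated counts
  rel_n <- abs(fit$components$n - micelle_complex_panel$count) / micelle_complex_panel$count
  expect_true(all(rel_n < 0.05))
  ## fractions are a partition of unity
  expect_equal(sum(fit$components$fraction), 1, tolerance = 1e-9)
  expect_lte(fit$r_squared, 1)
})

test_that("fit results are invariant under event permutation", {
  ev <- gen_mp_events(data.frame(mu = c(147, 278), sigma = c(12, 22),
                                 count = c(2000, 2000)),
                      detection_limit = 40, seed = 3)
  set.seed(1)
  shuffled <- mp_events(sample(ev$values), kind = "mass")
  h1 <- build_histogram(ev, 10, c(0, 600))
  h2 <- build_histogram(shuffled, 10, c(0, 600))
  expect_identical(h1$counts, h2$counts)
  f1 <- fit_truncated_mixture(h1, detect_peaks(h1), 40)
  f2 <- fit_truncated_mixture(h2, detect_peaks(h2), 40)
  expect_equal(f1$components, f2$components)
})

test_that("components collapsing onto one mean are merged with a warning", {
  ## a noiseless single-population histogram leaves two identical guesses
  ## nothing to separate on: they converge onto one mean and are merged
  edges <- seq(0, 500, by = 10)
  counts <- truncated_mixture_expected(edges, 200, 20, 3000, 30)
  h <- structure(list(bin_edges = edges, counts = counts,
                      mids = (edges[-1] + edges[-length(edges)]) / 2,
                      bin_width = 10, window = c(0, 500), n_excluded = 0L),
                 class = "mass_histogram")
  guesses <- data.frame(mu = c(195, 205), sigma = c(20, 20),
                        n = c(1500, 1500))
  expect_warning(fit <- fit_truncated_mixture(h, guesses, 30), "merged")
  expect_equal(nrow(fit$components), 1L)
  expect_equal(fit$components$mu, 200, tolerance = 1e-3)
  expect_equal(fit$components$n, 3000, tolerance = 1e-3)
})

test_that("stoichiometry assignment matches exhaustive search", {
  hexamer <- assign_stoichiometry(108, 18.5)
  expect_equal(hexamer$n, 6L)
  expect_equal(hexamer$rel_deviation, abs(108 - 6 * 18.5) / (6 * 18.5))
  expect_true(hexamer$accepted)

  expect_equal(assign_stoichiometry(100, 100)$n, 1L)
  expect_equal(assign_stoichiometry(100, 100)$rel_deviation, 0)

  set.seed(4)
  for (i in 1:200) {
    m <- runif(1, 10, 100)
    peak <- runif(1, m, 20 * m)
    got <- assign_stoichiometry(peak, m)$n
    best <- which.min(abs(peak - (1:50) * m))
    expect_equal(got, best)
  }
  expect_error(assign_stoichiometry(-1, 10), "positive")
})
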