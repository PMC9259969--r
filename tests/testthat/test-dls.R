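test_that("scattering vector follows the optics formula", {
  q <- scattering_vector(dls_conditions())
  expect_equal(q, 4 * pi * 1.330 / 658e-9 * sin(pi / 4), tolerance = 1e-12)
  expect_equal(q / 1e7, 1.796, tolerance = 1e-3)
  ## monotone in angle; maximum at backscatter
  angles <- seq(10, 170, by = 10)
  qs <- vapply(angles, function(a)
    scattering_vector(dls_conditions(angle = a)), numeric(1))
  expect_true(all(diff(qs) > 0))
  expect_lt(max(qs), 4 * pi * 1.330 / 658e-9)
})

test_that("Stokes-Einstein conversion and its inverse are exact", {
  expect_equal(stokes_einstein_radius(2.4615e-10, 298.15, 8.872e-4),
               1.000e-9, tolerance = 1e-4)
  expect_equal(stokes_einstein_radius(2 * 2.4615e-10),
               stokes_einstein_radius(2.4615e-10) / 2)
  d0 <- 5e-11
  expect_equal(diffusion_from_radius(stokes_einstein_radius(d0)), d0,
               tolerance = 1e-12)
  ## Rh decreasing in D, increasing in T at fixed D*eta
  expect_gt(stokes_einstein_radius(1e-10, 308.15),
            stokes_einstein_radius(1e-10, 298.15))
})

test_that("correlogram CSV round trip and the g2-1 dialect shift", {
  corr <- gen_correlogram(data.frame(rh = 8, mass_fraction = 1),
                          noise = 1e-4, seed = 6)
  path <- withr::local_tempfile(fileext = ".csv")
  write_correlogram(corr, path)
  back <- read_correlogram(path)
  expect_equal(back$tau, corr$tau, tolerance = 1e-12)
  expect_equal(back$g2, corr$g2, tolerance = 1e-12)

  shifted <- data.frame(tau_s = corr$tau, g2minus1 = corr$g2 - 1)
  utils::write.csv(shifted, path, row.names = FALSE)
  back2 <- read_correlogram(path, dialect = "g2minus1")
  expect_equal(back2$g2, corr$g2, tolerance = 1e-12)
})

test_that("cumulant fit recovers a noiseless single exponential exactly", {
  corr <- gen_correlogram(data.frame(rh = 5, mass_fraction = 1),
                          B = 1, beta = 0.9, noise = 0, seed = 1)
  cf <- fit_cumulants(corr)
  gamma_true <- scattering_vector(corr$conditions)^2 *
    diffusion_from_radius(5e-9)
  expect_true(cf$converged)
  expect_equal(cf$gamma, gamma_true, tolerance = 1e-6)
  expect_lt(cf$pdi, 1e-6)
  expect_equal(cf$B, 1, tolerance = 1e-8)
  expect_equal(cf$beta, 0.9, tolerance = 1e-6)
  expect_equal(cf$rh, 5e-9, tolerance = 1e-6)
})

test_that("mixture cumulant decay matches the exact initial slope of g1", {
  comp <- data.frame(rh = c(5, 8), mass_fraction = c(0.6, 0.4))
  corr <- gen_correlogram(comp, noise = 0, seed = 1)
  cf <- fit_cumulants(corr)
  ## numeric derivative of the exact field correlation at tau -> 0
  truth <- attr(corr, "truth")
  gam <- scattering_vector(corr$conditions)^2 *
    diffusion_from_radius(comp$rh * 1e-9)
  g1 <- function(t) sum(truth$intensity_weights * exp(-gam * t))
  h <- 1e-9
  gamma_init <- -(log(g1(h)) - log(g1(0))) / h
  expect_equal(cf$gamma, gamma_init, tolerance = 0.05)
  expect_gt(cf$pdi, 0)
})

test_that("the generator's output is the module's own forward model", {
  comp <- data.frame(rh = c(5, 21.5), mass_fraction = c(72, 27))
  corr <- gen_correlogram(comp, noise = 0, seed = 1)
  truth <- attr(corr, "truth")
  expect_equal(truth$intensity_weights, c(0.0324, 0.9676), tolerance = 1e-3)
  g2 <- dls_g2_model(corr$tau, comp$rh, truth$intensity_weights,
                     corr$conditions, B = 1, beta = 0.9)
  expect_identical(corr$g2, g2)
  ## single exponential sanity: intercept 1.9, log-linear decay
  single <- gen_correlogram(data.frame(rh = 5, mass_fraction = 1),
                            noise = 0, seed = 1)
  ## intercept B + beta, up to the decay over the first (1e-7 s) lag
  expect_equal(max(single$g2), 1.9, tolerance = 5e-3)
  early <- single$tau < 1e-5
  slope <- ols_line(single$tau[early],
                    log(single$g2[early] - 1))[["slope"]]
  gamma_true <- scattering_vector(single$conditions)^2 *
    diffusion_from_radius(5e-9)
  expect_equal(slope, -2 * gamma_true, tolerance = 1e-3)
})

test_that("inversion recovers a single species within one grid cell", {
  corr <- gen_correlogram(data.frame(rh = 10, mass_fraction = 1),
                          noise = 0, seed = 1)
  dist <- fit_size_distribution(corr)
  pk <- extract_peaks(dist)
  expect_equal(nrow(pk), 1L)
  ## one grid cell on the default 100-point log grid is a factor 1.098
  expect_lt(abs(log(pk$rh_mean / 10)), log(10^(4 / 99)))
  expect_equal(pk$percent, 100, tolerance = 1e-6)
  expect_true(all(dist$weights >= 0))
})

test_that("species with radius ratio >= 3 are resolved at 1e-3 noise", {
  for (s in 1:3) {
    corr <- gen_correlogram(
      data.frame(rh = c(5, 15), mass_fraction = c(27, 1)),
      noise = 1e-3, seed = s)
    dist <- fit_size_distribution(corr)
    pk <- extract_peaks(dist, min_percent = 5)
    expect_gte(nrow(pk), 2L)
    expect_lt(abs(log(pk$rh_mean[1] / 5)), log(1.5))
    expect_lt(abs(log(pk$rh_mean[nrow(pk)] / 15)), log(1.5))
    ## residual consistent with the injected noise level
    expect_lt(attr(dist, "chi2_dof"), 4e-6)
  }
})

test_that("the printed LMNG-like pair is resolved from the correlogram", {
  corr <- gen_correlogram(
    data.frame(rh = c(5, 21.5), mass_fraction = c(72, 27)),
    noise = 1e-3, seed = 4)
  pk <- extract_peaks(fit_size_distribution(corr), min_percent = 1)
  expect_equal(nrow(pk), 2L)
})

test_that("reweighting follows the compact-sphere convention exactly", {
  ## equal intensity at R and 2R puts mass 8:1 in favor of R
  d <- size_distribution(c(10, 20), c(0.5, 0.5), "intensity")
  expect_equal(reweight_distribution(d, "mass")$weights, c(8, 1) / 9)
  ## single radius is 100% in every weighting
  s <- size_distribution(5, 1, "intensity")
  for (wt in c("mass", "number", "intensity"))
    expect_equal(reweight_distribution(s, wt)$weights, 1)
})

test_that("reweighting round trips are the identity", {
  set.seed(11)
  rh <- sort(10^runif(40, -1, 3))
  w <- runif(40); w <- w / sum(w)
  d <- size_distribution(rh, w, "intensity")
  for (path in list(c("mass", "intensity"),
                    c("number", "intensity"),
                    c("mass", "number", "intensity"))) {
    out <- d
    for (target in path) out <- reweight_distribution(out, target)
    expect_equal(out$weights, d$weights, tolerance = 1e-12)
  }
})

test_that("peak extraction reports constructed delta peaks exactly", {
  d <- size_distribution(c(5, 21.5), c(0.727, 0.273), "mass")
  pk <- extract_peaks(d)
  expect_equal(pk$rh_mean, c(5, 21.5))
  expect_equal(pk$percent, c(72.7, 27.3), tolerance = 1e-9)
  ## threshold above every region -> empty
  expect_equal(nrow(extract_peaks(d, min_percent = 80)), 0L)
})

test_that("radius-mass power law reproduces its anchor pairs", {
  model <- default_radius_mass_model()
  expect_equal(model$mass_exponent, 2.32, tolerance = 0.01)
  expect_equal(model$mass_prefactor, 3.56, tolerance = 0.01)
  anchors <- data.frame(rh = c(11.0, 5, 21.5, 0.9, 9.7),
                        mass = c(921.0, 147.6, 4394.2, 2.8, 683.1))
  pred <- radius_mass_convert(anchors$rh, "radius_to_mass", model)
  expect_true(all(abs(pred - anchors$mass) / anchors$mass < 0.03))
  ## round trip identity
  m <- c(2.8, 147.6, 4394.2)
  expect_equal(radius_mass_convert(
    radius_mass_convert(m, "mass_to_radius", model),
    "radius_to_mass", model), m, tolerance = 1e-9)
  expect_error(radius_mass_fit(data.frame(rh = 5, mass = 100)),
               "at least two")
})

test_that("the four-pair fit predicts the held-out pair within 2%", {
  four <- radius_mass_fit(data.frame(rh = c(5, 21.5, 0.9, 9.7),
                                     mass = c(147.6, 4394.2, 2.8, 683.1)))
  expect_equal(radius_mass_convert(11.0, "radius_to_mass", four), 921.0,
               tolerance = 0.02)
})

test_that("aggregate detection flags 10% intensity at 300 nm and not a clean sample", {
  dirty <- gen_correlogram(
    data.frame(rh = c(5, 300), mass_fraction = c(0.9 * 300^3, 0.1 * 5^3)),
    noise = 1e-3, seed = 2)
  res <- detect_aggregation(dirty)
  expect_true(res$flagged)
  expect_equal(res$percent_above_cutoff, 10, tolerance = 3)

  clean <- gen_correlogram(data.frame(rh = 5, mass_fraction = 1),
                           noise = 1e-3, seed = 2)
  expect_false(detect_aggregation(clean)$flagged)

  ## flag decision equals direct recomputation from the distribution
  dist <- fit_size_distribution(dirty)
  pct <- 100 * sum(dist$weights[dist$rh > 100])
  expect_equal(detect_aggregation(dist)$flagged, pct > 5)
})
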