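test_that("wide-format exports round-trip through the reader", {
  r1 <- gen_dsf_ramp(tm = 60, noise = 0.001, scattering_mid = 55,
                     label = "DDM", seed = 1)
  r2 <- gen_dsf_ramp(tm = 70, noise = 0.001, label = "LMNG", seed = 2)
  path <- withr::local_tempfile(fileext = ".csv")
  write_thermal_ramps(list(r1, r2), path)
  ramps <- read_thermal_ramps(path)
  expect_named(ramps, c("DDM", "LMNG"))
  expect_equal(ramps$DDM$f330, r1$f330, tolerance = 1e-8)
  expect_equal(ramps$DDM$scattering, r1$scattering, tolerance = 1e-8)
  expect_null(ramps$LMNG$scattering)
})

test_that("rows in descending temperature order are sorted with a warning", {
  r <- gen_dsf_ramp(tm = 60, noise = 0, seed = 1)
  path <- withr::local_tempfile(fileext = ".csv")
  write_thermal_ramps(r, path)
  tab <- utils::read.csv(path, check.names = FALSE)
  utils::write.csv(tab[rev(seq_len(nrow(tab))), ], path, row.names = FALSE)
  expect_warning(ramps <- read_thermal_ramps(path), "sorted")
  expect_equal(ramps[[1]]$temperature, r$temperature)
})

test_that("ratio computation masks zero-F330 points", {
  r <- thermal_ramp(1:20, c(0, rep(100, 19)), rep(150, 20))
  rt <- compute_ratio(r)
  expect_equal(nrow(rt), 19L)
  expect_equal(attr(rt, "n_masked"), 1L)
  r2 <- thermal_ramp(1:20, rep(100, 20), rep(100, 20))
  expect_equal(compute_ratio(r2)$ratio, rep(1, 20))
  expect_error(compute_ratio(thermal_ramp(1:20, rep(0, 20), rep(1, 20))),
               "all F330")
})

test_that("noiseless ratio equals the generator's analytic two-state curve", {
  r <- gen_dsf_ramp(tm = 65, noise = 0, seed = 1)
  rt <- compute_ratio(r)
  expect_equal(rt$ratio, attr(r, "truth")$ratio, tolerance = 1e-12)
  ## at the midpoint the unfolded fraction is exactly one half
  at_tm <- which.min(abs(r$temperature - 65))
  expect_equal(attr(r, "truth")$fraction_unfolded[at_tm], 0.5,
               tolerance = 1e-9)
  expect_equal(rt$ratio[at_tm], (0.8 + 1.0) / 2, tolerance = 1e-9)
})

test_that("a noiseless two-state transition is located at its midpoint", {
  r <- gen_dsf_ramp(tm = 84, noise = 0, seed = 1)
  rt <- compute_ratio(r)
  tr <- find_transitions(rt$temperature, rt$ratio)
  expect_equal(nrow(tr), 1L)
  expect_equal(tr$tm, 84, tolerance = 0.1)
  expect_equal(tr$sign, 1)
})

test_that("a straight line yields no transitions", {
  x <- seq(20, 90, 0.1)
  expect_equal(nrow(find_transitions(x, 0.8 + 0.001 * x)), 0L)
})

test_that("two well-separated transitions are reported in ascending order", {
  x <- seq(20, 90, 0.1)
  y1 <- compute_ratio(gen_dsf_ramp(tm = 50, noise = 0))$ratio
  y2 <- compute_ratio(gen_dsf_ramp(tm = 80, noise = 0))$ratio
  tr <- find_transitions(x, y1 + y2)
  expect_equal(nrow(tr), 2L)
  expect_equal(tr$tm, c(50, 80), tolerance = 0.15)
})

test_that("smoothing windows 5-21 do not shift a noiseless transition", {
  r <- gen_dsf_ramp(tm = 70, noise = 0, seed = 1)
  rt <- compute_ratio(r)
  for (w in c(5, 9, 11, 15, 21)) {
    tr <- find_transitions(rt$temperature, rt$ratio, smooth_window = w)
    expect_lt(abs(tr$tm[which.max(tr$prominence)] - 70), 0.1)
  }
})

test_that("aggregation onset matches the logistic closed form", {
  ## 1% crossing of a logistic with rate k sits at Tmid - ln(99)/k
  k <- 0.5
  onset_true <- 62
  tmid <- onset_true + log(99) / k
  r <- gen_dsf_ramp(tm = 75, noise = 0, scattering_mid = tmid,
                    scattering_steepness = k, scattering_noise = 0.002,
                    seed = 5)
  onset <- find_aggregation_onset(r$temperature, r$scattering)
  expect_equal(onset, onset_true, tolerance = 0.5)

  ## noiseless crossing is essentially exact
  r0 <- gen_dsf_ramp(tm = 75, noise = 0, scattering_mid = tmid,
                     scattering_steepness = k, seed = 5)
  expect_equal(find_aggregation_onset(r0$temperature, r0$scattering),
               onset_true, tolerance = 0.1)
})

test_that("flat scattering yields no onset and affine transforms cancel", {
  x <- seq(20, 90, 0.1)
  set.seed(2)
  flat <- 5 + rnorm(length(x), 0, 0.01)
  expect_true(is.na(find_aggregation_onset(x, flat)))

  r <- gen_dsf_ramp(tm = 75, noise = 0, scattering_mid = 70,
                    scattering_steepness = 0.5, seed = 1)
  o1 <- find_aggregation_onset(r$temperature, r$scattering)
  o2 <- find_aggregation_onset(r$temperature, 3 * r$scattering + 100)
  expect_equal(o1, o2, tolerance = 1e-9)
})

test_that("onset never exceeds the scattering transition midpoint", {
  for (k in c(0.3, 0.5, 1)) {
    r <- gen_dsf_ramp(tm = 75, noise = 0, scattering_mid = 70,
                      scattering_steepness = k, seed = 1)
    onset <- find_aggregation_onset(r$temperature, r$scattering)
    mid <- find_transitions(r$temperature, r$scattering)
    expect_lte(onset, mid$tm[which.max(mid$prominence)])
  }
})

test_that("condition ranking orders by Tm with stable tie-breaks", {
  tab <- data.frame(label = c("DDM", "OGNG", "DaM", "DDaM", "LMNG"),
                    tm = c(60, 62, 63, 65, 69.5))
  rk <- rank_conditions(tab, "DDM")
  expect_equal(rk$label[1], "LMNG")
  expect_equal(rk$delta_tm[1], 9.5)
  expect_equal(rk$delta_tm[rk$label == "DDM"], 0)

  ties <- data.frame(label = c("zeta", "alpha"), tm = c(60, 60))
  expect_equal(rank_conditions(ties, "zeta")$label, c("alpha", "zeta"))
  expect_error(rank_conditions(tab, "nope"), "reference")
})

test_that("initial fluorescence check enforces the 2000-15000 window", {
  mk <- function(f330, f350) thermal_ramp(1:20, rep(f330, 20),
                                          rep(f350, 20))
  expect_true(check_initial_fluorescence(mk(5000, 6000))$ok)
  expect_false(check_initial_fluorescence(mk(1000, 6000))$ok)
  expect_false(check_initial_fluorescence(mk(5000, 15001))$ok)
  expect_true(check_initial_fluorescence(mk(2000, 15000))$ok)
})

test_that("blank subtraction removes an additive buffer signal", {
  r <- gen_dsf_ramp(tm = 65, noise = 0, seed = 1)
  blank <- thermal_ramp(r$temperature, rep(500, length(r$temperature)),
                        rep(300, length(r$temperature)), label = "buffer")
  spiked <- thermal_ramp(r$temperature, r$f330 + 500, r$f350 + 300,
                         label = r$label)
  corrected <- subtract_blank(spiked, blank)
  expect_equal(corrected$f330, r$f330, tolerance = 1e-12)
  expect_equal(corrected$f350, r$f350, tolerance = 1e-12)
})
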