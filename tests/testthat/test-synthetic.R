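test_that("truth construction honors density, spectral radius, and seed", {
  tr0 <- make_truth(5, temporal_density = 0, contemporaneous_density = 0,
                    between_density = 0, seed = 42)
  expect_true(all(tr0$beta[row(tr0$beta) != col(tr0$beta)] == 0))
  expect_true(all(tr0$kappa_zeta[row(tr0$beta) != col(tr0$beta)] == 0))

  tr <- make_truth(6, target_spectral_radius = 0.45, seed = 43)
  expect_equal(panelgvar:::spectral_radius(tr$beta), 0.45, tolerance = 1e-6)
  expect_identical(make_truth(6, target_spectral_radius = 0.45, seed = 43)$beta, tr$beta)
  expect_false(identical(make_truth(6, seed = 44)$beta, tr$beta))

  # PD by construction
  expect_silent(chol(tr$kappa_zeta))
  expect_silent(chol(tr$kappa_between))
})

test_that("simulated panels are stationary and respect independence limits", {
  # near-zero between variance and B = 0: waves behave as independent draws
  tr <- gvar_parameters(matrix(0, 2, 2), diag(2), diag(2) * 1e6, n_waves = 3)
  ds <- simulate_panel(tr, 50000, seed = 45)
  lag_cov <- cov(ds$scores[, 1, 1], ds$scores[, 2, 1])
  expect_lt(abs(lag_cov), 0.02)

  # per-wave means and SDs are wave-invariant within Monte-Carlo error
  tr2 <- make_truth(3, seed = 46)
  ds2 <- simulate_panel(tr2, 50000, seed = 47)
  for (j in 1:3) {
    mns <- apply(ds2$scores[, , j], 2, mean)
    sds <- apply(ds2$scores[, , j], 2, sd)
    expect_lt(max(mns) - min(mns), 0.04)
    expect_lt(max(sds) - min(sds), 0.04)
  }
})

test_that("ordinalization counts thresholds below the latent value", {
  ds <- tiny_continuous(n = 1, k = 1)
  ds$scores[1, , 1] <- c(1.5, -0.2, 2.5)
  out <- ordinalize(ds, matrix(c(0, 1, 2), 1))
  expect_equal(unname(out$scores[1, , 1]), c(2, 0, 3))

  # effectively infinite thresholds give all zeros
  out0 <- ordinalize(ds, matrix(c(1e6, 2e6, 3e6), 1))
  expect_true(all(out0$scores == 0))

  expect_error(ordinalize(ds, matrix(c(1, 1, 2), 1)), "ascending")

  # category proportions follow the normal CDF arithmetic
  big <- tiny_continuous(n = 60000, k = 1, seed = 48)
  big$scores[, , 1] <- rnorm(180000)
  th <- qnorm(c(0.55, 0.93, 0.99))
  ob <- ordinalize(big, matrix(th, 1))
  props <- as.vector(table(ob$scores)) / length(ob$scores)
  expect_equal(props, c(0.55, 0.38, 0.06, 0.01), tolerance = 0.01)

  # missing cells stay missing
  dm <- tiny_continuous(n = 5, k = 2)
  dm$scores[2, 3, ] <- NA
  om <- ordinalize(dm, matrix(rep(c(-1, 0, 1), each = 2), 2))
  expect_identical(missing_mask(om), missing_mask(dm))
})

test_that("threshold calibration hits target categorical moments", {
  # published wave-1 target for a skewed item: mean .532, SD .720
  th <- calibrate_thresholds(0.532, 0.720, latent_sd = 1.3)
  set.seed(49)
  lat <- rnorm(100000, 0, 1.3)
  cat <- findInterval(lat, th)
  expect_equal(mean(cat), 0.532, tolerance = 0.02)
  expect_equal(sd(cat), 0.720, tolerance = 0.02)

  # near-constant item: ~98.7% zeros
  th10 <- calibrate_thresholds(0.012, 0.135, latent_sd = 1)
  expect_equal(mean(findInterval(rnorm(100000), th10) == 0), 0.987,
               tolerance = 0.005)

  # maximal-SD boundary forces a {0, 3} mixture
  thb <- calibrate_thresholds(1.5, sqrt(1.5 * 3 - 1.5^2) - 0.01)
  pr <- diff(c(0, pnorm(thb), 1))
  expect_equal(pr[1], pr[4], tolerance = 0.05)
  expect_lt(pr[2] + pr[3], 0.05)

  # infeasible targets
  expect_error(calibrate_thresholds(0, 0.5), "infeasible")
  expect_error(calibrate_thresholds(0.5, 2.0), "feasible interval")
})

test_that("attrition is monotone, score-dependent, and seed-stable", {
  tr <- make_truth(4, seed = 50)
  base <- simulate_panel(tr, 4000, seed = 51)
  base$scores <- abs(base$scores)  # totals positive, like symptom scores

  # no dropout configured
  none <- apply_attrition(base, 0, 0, seed = 52)
  expect_no_missing(none)

  # slope 0: ~ base rate per transition, independent of scores
  flat <- apply_attrition(base, 0.1, 0, seed = 53)
  part <- panelgvar:::participation_matrix(flat)
  r12 <- 1 - sum(part[, 2]) / sum(part[, 1])
  r23 <- 1 - sum(part[, 3]) / sum(part[, 2])
  expect_lt(abs(r12 - 0.1), 0.02)
  expect_lt(abs(r23 - 0.1), 0.02)

  # positive slope: dropouts have higher wave-1 totals (negative t)
  dep <- apply_attrition(base, 0.08, 0.8, seed = 54)
  at <- attrition_comparison(dep)
  expect_lt(at$t, 0)
  expect_gt(at$mean_dropouts, at$mean_completers)

  # monotone: once out, always out
  pm <- panelgvar:::participation_matrix(dep)
  expect_true(all(pm[, 2] >= pm[, 3]))
  expect_true(all(pm[, 1] >= pm[, 2]))

  # reproducible
  expect_identical(apply_attrition(base, 0.1, 0.3, seed = 55)$scores,
                   apply_attrition(base, 0.1, 0.3, seed = 55)$scores)
})

test_that("the calibrated preset reproduces the published study regime", {
  sim <- simulate_lin_like("mothers", n = 869, seed = 56)
  ds <- sim$data
  expect_equal(n_persons(ds), 869)
  expect_equal(n_items(ds), 10)
  expect_true(all(ds$scores[!is.na(ds$scores)] %in% 0:3))

  # item means at wave 1 track the published calibration targets
  mom <- epds_reference_moments()
  target <- mom[mom$group == "mothers" & mom$wave == "T1", ]
  got <- colMeans(ds$scores[, 1, ], na.rm = TRUE)
  expect_lt(max(abs(got - target$mean[match(names(got), target$item)])), 0.08)

  # strongly right-skewed items, like the published tables
  m1 <- item_moments(ds)
  expect_gt(min(m1$skewness[m1$item == "EPDS1"]), 1)

  # screening removes exactly the near-constant item
  expect_identical(screen_variance(ds)$excluded, "EPDS10")

  # attrition in the published 5-15% per-wave band, dropouts more symptomatic
  mp <- missingness_profile(ds)
  expect_gt(mp$dropout_pct[2], 5); expect_lt(mp$dropout_pct[2], 18)
  expect_lt(attrition_comparison(ds)$t, 0)

  # fathers preset differs in size and calibration
  simf <- simulate_lin_like("fathers", seed = 57)
  expect_equal(n_persons(simf$data), 579)
})
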