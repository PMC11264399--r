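test_that("stationary covariance solves the Lyapunov equation", {
  # B = 0: the stationary covariance is the innovation covariance
  Sz <- matrix(c(1, 0.3, 0.3, 1), 2)
  expect_equal(stationary_covariance(matrix(0, 2, 2), Sz), Sz)

  # scalar closed form: 0.75 / (1 - 0.25) = 1
  expect_equal(stationary_covariance(matrix(0.5), matrix(0.75)),
               matrix(1), tolerance = 1e-12)

  # random stable 3x3 against the truncated 200-term series oracle
  set.seed(14)
  B <- matrix(rnorm(9, 0, 0.25), 3)
  B <- B * (0.6 / panelgvar:::spectral_radius(B))
  Sz3 <- crossprod(matrix(rnorm(9), 3)) + diag(3)
  S <- stationary_covariance(B, Sz3)
  expect_lt(max(abs(S - series_stationary(B, Sz3))), 1e-8)
  # residual of the defining equation
  expect_lt(max(abs(S - B %*% S %*% t(B) - Sz3)), 1e-10)
  expect_identical(S, t(S))

  # explosive process errors
  expect_error(stationary_covariance(matrix(1.01), matrix(1)), "spectral radius")
})

test_that("implied stacked covariance has the VAR(1) + random-intercept form", {
  p <- 2
  par0 <- gvar_parameters(matrix(0, p, p), diag(p), diag(p), n_waves = 3)
  imp <- implied_covariance(par0, 3)
  expect_equal(dim(imp$sigma), c(6, 6))
  for (t in 1:3) for (s in 1:3) {
    blk <- imp$sigma[(t - 1) * 2 + 1:2, (s - 1) * 2 + 1:2]
    expect_equal(unname(blk), if (t == s) 2 * diag(2) else diag(2))
  }

  # univariate arithmetic: b=.5, var_zeta=.75, var_between=.5
  par1 <- gvar_parameters(matrix(0.5), matrix(1 / 0.75), matrix(1 / 0.5),
                          n_waves = 3)
  imp1 <- implied_covariance(par1, 3)
  expect_equal(unname(diag(imp1$sigma)), rep(1.5, 3), tolerance = 1e-12)
  expect_equal(unname(imp1$sigma[1, 2]), 1.0, tolerance = 1e-12)
  expect_equal(unname(imp1$sigma[1, 3]), 0.25 * 1 + 0.5, tolerance = 1e-12)

  # exact symmetry is enforced structurally
  tr <- make_truth(4, seed = 15)
  S <- implied_covariance(tr, 3)$sigma
  expect_identical(S, t(S))
})

test_that("implied covariance matches the empirical covariance of simulations", {
  tr <- gvar_parameters(matrix(c(0.4, 0.15, 0, 0.3), 2, byrow = TRUE),
                        matrix(c(1.2, -0.4, -0.4, 1.1), 2),
                        matrix(c(1.5, -0.3, -0.3, 1.4), 2), n_waves = 3)
  ds <- simulate_panel(tr, 200000, seed = 16)
  Y <- panelgvar:::flatten_scores(ds)
  emp <- cov(Y)
  imp <- implied_covariance(tr, 3)$sigma
  expect_lt(max(abs(emp - imp)), 0.012)
  expect_lt(max(abs(colMeans(Y))), 0.02)
})

test_that("FIML log-likelihood handles missingness patterns correctly", {
  # single observed cell with implied mean 0, variance 1
  par1 <- gvar_parameters(matrix(0), matrix(2), matrix(2), n_waves = 3)
  # var = 0.5/(1) ... univariate: sigma* = 0.5/(1-0) = 0.5; + between 0.5 = 1
  ds1 <- tiny_continuous(n = 1, k = 1)
  ds1$scores[1, , 1] <- c(0, NA, NA)
  expect_equal(fiml_loglik(par1, ds1), -0.5 * log(2 * pi), tolerance = 1e-12)

  # complete data: equals the dense oracle with no pattern logic
  tr <- make_truth(3, seed = 17)
  ds <- simulate_panel(tr, 20, seed = 18)
  imp <- implied_covariance(tr, 3)
  expect_equal(fiml_loglik(tr, ds),
               dense_mvn_loglik(panelgvar:::flatten_scores(ds), imp$mu, imp$sigma),
               tolerance = 1e-8)

  # a fully-missing person contributes nothing
  ds2 <- ds
  ds2$scores <- array(NA_real_, c(21, 3, 3))
  ds2$scores[1:20, , ] <- ds$scores
  ds2$person_ids <- 1:21
  expect_equal(fiml_loglik(tr, ds2), fiml_loglik(tr, ds))

  # invariance to person order (and hence to pattern grouping)
  ds3 <- ds
  ds3$scores[c(2, 5, 9), 3, ] <- NA
  ds3$scores[c(4, 7), 2, 1] <- NA
  perm <- sample(20)
  dsp <- panel_dataset(ds3$scores[perm, , ], ds3$schema, person_ids = perm)
  expect_equal(fiml_loglik(tr, dsp), fiml_loglik(tr, ds3), tolerance = 1e-10)

  # the compiled objective agrees with the R implementation
  pat <- saturated_pattern(3)
  prob <- panelgvar:::build_prob(ds3, pat)
  th <- panelgvar:::pack_theta(tr, pat)
  expect_equal(-panelgvar:::cpp_gvar_negll(th, prob) * prob$n_total,
               fiml_loglik(tr, ds3), tolerance = 1e-8)
})

test_that("likelihood at the truth beats perturbed parameters on average", {
  tr <- make_truth(3, seed = 19)
  ds <- simulate_panel(tr, 4000, seed = 20)
  ll_true <- fiml_loglik(tr, ds)
  set.seed(21)
  worse <- replicate(5, {
    pert <- tr
    pert$beta <- pert$beta + matrix(rnorm(9, 0, 0.08), 3)
    if (panelgvar:::spectral_radius(pert$beta) < 0.95)
      fiml_loglik(pert, ds) < ll_true
    else TRUE
  })
  expect_true(mean(worse) >= 0.8)
})

test_that("vanishing between-variance degenerates to a plain panel VAR(1)", {
  B <- matrix(c(0.5, 0.2, 0, 0.4), 2, byrow = TRUE)
  Kz <- diag(2)
  tr <- gvar_parameters(B, Kz, diag(2) * 1e8, n_waves = 3)  # Sigma_B ~ 0
  imp <- implied_covariance(tr, 3)$sigma
  Sstar <- stationary_covariance(B, diag(2))
  for (t in 1:3) for (s in 1:t) {
    blk <- imp[(t - 1) * 2 + 1:2, (s - 1) * 2 + 1:2]
    Bp <- diag(2); if (t > s) for (k in seq_len(t - s)) Bp <- B %*% Bp
    expect_equal(unname(blk), Bp %*% Sstar, tolerance = 1e-7)
  }
})

test_that("parameter JSON round-trips labels and orientation", {
  tr <- make_truth(3, seed = 22)
  js <- gvar_parameters_json(tr)
  doc <- jsonlite::fromJSON(js)
  expect_equal(doc$orientation, "beta[receiver, predictor]")
  expect_equal(doc$beta, unname(tr$beta), tolerance = 1e-12)
})
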