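test_that("fitting recovers known sparse parameters from large samples", {
  tr <- make_truth(4, temporal_density = 0.2, seed = 23)
  ds <- simulate_panel(tr, 2000, seed = 24)
  fit <- fit_gvar(ds, pattern_from_parameters(tr))
  expect_true(fit$converged)
  fit <- standard_errors(fit, ds)
  free <- which(fit$pattern$beta)
  err <- abs(fit$params$beta[free] - tr$beta[free])
  expect_true(all(err < 3 * pmax(fit$se$beta[free], 0.02)))

  # refit from the solution reconverges immediately at the same optimum
  fit2 <- fit_gvar(ds, fit$pattern, init = fit$params)
  expect_equal(fit2$loglik, fit$loglik, tolerance = 1e-8)
  expect_lte(fit2$n_iterations, 5)
})

test_that("a null temporal matrix is estimated near zero", {
  tr <- gvar_parameters(matrix(0, 4, 4), diag(4), diag(4), n_waves = 3)
  ds <- simulate_panel(tr, 2000, seed = 25)
  fit <- fit_gvar(ds)
  expect_true(fit$converged)
  expect_lt(max(abs(fit$params$beta)), 0.08)
})

test_that("standard errors shrink like information accumulates", {
  tr <- make_truth(3, seed = 26)
  ds <- simulate_panel(tr, 400, seed = 27)
  fit <- standard_errors(fit_gvar(ds), ds)
  # duplicate every person: information doubles, SEs shrink by ~1/sqrt(2)
  ds2 <- panel_dataset(ds$scores[rep(1:400, 2), , ], ds$schema,
                       person_ids = 1:800)
  fit2 <- standard_errors(fit_gvar(ds2, init = fit$params), ds2)
  ratio <- fit2$se$beta / fit$se$beta
  expect_equal(mean(ratio, na.rm = TRUE), 1 / sqrt(2), tolerance = 0.02)
})

test_that("observed-information SEs agree with a parametric bootstrap", {
  tr <- gvar_parameters(matrix(c(0.4, 0.2, 0, 0.35), 2, byrow = TRUE),
                        matrix(c(1.3, -0.4, -0.4, 1.2), 2),
                        matrix(c(2, -0.5, -0.5, 2), 2), n_waves = 3)
  ds <- simulate_panel(tr, 500, seed = 28)
  fit <- standard_errors(fit_gvar(ds), ds)
  boots <- vapply(1:200, function(b) {
    db <- simulate_panel(fit$params, 500, seed = 1000 + b)
    fit_gvar(db)$params$beta[1, 1]
  }, numeric(1))
  expect_equal(fit$se$beta[1, 1], sd(boots), tolerance = 0.1)
})

test_that("Wald pruning removes null edges and keeps real ones", {
  p <- 4
  B <- matrix(0, p, p); B[2, 1] <- 0.4
  tr <- gvar_parameters(B, diag(p), diag(p), n_waves = 3)
  ds <- simulate_panel(tr, 2000, seed = 29)
  fit <- standard_errors(fit_gvar(ds), ds)

  # alpha = 1 removes nothing
  pr1 <- prune_gvar(fit, ds, alpha = 1)
  expect_equal(pr1$n_params, fit$n_params)

  pr <- prune_gvar(fit, ds, alpha = 0.01)
  expect_true(pr$converged)
  expect_true(pr$pattern$beta[2, 1])            # true edge retained
  null_beta <- which(tr$beta == 0)
  expect_gte(mean(!pr$pattern$beta[null_beta]), 0.9)
  null_kz <- which(tr$kappa_zeta == 0 & lower.tri(tr$kappa_zeta))
  expect_gte(mean(!pr$pattern$kappa_zeta[null_kz]), 0.8)
  # nested pattern
  expect_true(all(pr$pattern$beta <= fit$pattern$beta))

  # Wald arithmetic: z = 2 gives p ~ 0.0455, retained at alpha = .05
  wt <- panelgvar:::edge_wald_table(fit)
  expect_equal(wt$p, 2 * pnorm(-abs(wt$estimate / wt$se)), tolerance = 1e-12)
  expect_equal(2 * pnorm(-2), 0.0455, tolerance = 2e-4)

  # alpha = 0 removes every off-diagonal edge and BIC stays finite
  pr0 <- prune_gvar(fit, ds, alpha = 0, prune_auto = FALSE)
  expect_true(all(!pr0$pattern$beta[row(B) != col(B)]))
  expect_true(is.finite(panelgvar:::model_bic(pr0)))
})

test_that("BIC search only accepts improvements and is deterministic", {
  p <- 3
  B <- matrix(0, p, p); diag(B) <- 0.35; B[2, 1] <- 0.4
  Kz <- diag(p); Kz[1, 2] <- Kz[2, 1] <- -0.35
  tr <- gvar_parameters(B, Kz, diag(p), n_waves = 3)
  ds <- simulate_panel(tr, 1500, seed = 30)
  sat <- standard_errors(fit_gvar(ds), ds)
  pruned <- prune_gvar(sat, ds, alpha = 0.01)
  searched <- search_gvar(pruned, ds, alpha = 0.01)
  expect_lte(panelgvar:::model_bic(searched), panelgvar:::model_bic(pruned) + 1e-6)
  # deterministic: same inputs, same result
  searched2 <- search_gvar(pruned, ds, alpha = 0.01)
  expect_equal(searched$params$beta, searched2$params$beta, tolerance = 1e-10)
  expect_identical(searched$pattern, searched2$pattern)

  # likelihood ordering across the nested fits
  expect_gte(sat$loglik + 1e-6, searched$loglik)
  expect_gte(searched$loglik + 1e-6, pruned$loglik)

  # candidate enumeration follows the documented lexical order
  pat <- pruned$pattern
  cand <- panelgvar:::candidate_edges(pat)
  expect_true(all(cand$mat == sort(cand$mat)) ||
                identical(unique(cand$mat),
                          intersect(c("beta", "kappa_zeta", "kappa_between"),
                                    unique(cand$mat))))
})

test_that("fit indices implement the stated formulas", {
  f <- panelgvar:::fit_index_formulas(50, 40, 500, 60, N = 500,
                                      loglik = -100, n_params = 5)
  expect_equal(f$cfi, 1 - 10 / 440, tolerance = 1e-12)
  expect_equal(f$rmsea, sqrt(10 / (40 * 499)), tolerance = 1e-12)
  expect_equal(f$bic, 200 + 5 * log(100 / 100 * 500))  # -2LL + k ln N
  expect_equal(panelgvar:::fit_index_formulas(50, 40, 500, 60, N = 100,
                                              loglik = -100, n_params = 5)$bic,
               200 + 5 * log(100), tolerance = 1e-12)

  # the saturated comparison model itself: chi2 0, CFI 1, TLI truncated, RMSEA 0
  f0 <- panelgvar:::fit_index_formulas(0, 10, 500, 60, N = 500,
                                       loglik = -100, n_params = 5)
  expect_equal(f0$cfi, 1)
  expect_equal(f0$tli, 1)
  expect_equal(f0$rmsea, 0)

  # df = 0 flags RMSEA as undefined
  fdf0 <- panelgvar:::fit_index_formulas(0, 0, 500, 60, N = 500,
                                         loglik = -100, n_params = 5)
  expect_true(fdf0$rmsea_undefined)
  expect_equal(fdf0$rmsea, 0)
})

test_that("model fit indices are good when the model is true", {
  tr <- make_truth(3, seed = 31)
  ds <- simulate_panel(tr, 1200, seed = 32)
  fit <- fit_gvar(ds)
  fi <- fit_indices(fit, ds)
  expect_gt(fi$cfi, 0.99)
  expect_lt(fi$rmsea, 0.02)
  expect_gte(fi$df, 0)

  # saturated EM equals the closed-form MLE on complete data
  sat <- panelgvar:::fit_saturated(ds)
  Y <- panelgvar:::flatten_scores(ds)
  n <- nrow(Y)
  expect_equal(sat$mu, colMeans(Y), tolerance = 1e-8)
  expect_equal(sat$sigma, cov(Y) * (n - 1) / n, tolerance = 1e-6)
  expect_equal(sat$loglik,
               dense_mvn_loglik(Y, colMeans(Y), cov(Y) * (n - 1) / n),
               tolerance = 1e-6)
  # the saturated likelihood dominates the structured model's
  expect_gte(sat$loglik + 1e-6, fit$loglik)
})

test_that("BIC comparison reports signed differences and the favored model", {
  tr <- make_truth(3, seed = 33)
  ds <- simulate_panel(tr, 300, seed = 34)
  fit <- fit_gvar(ds)
  expect_equal(as.numeric(compare_bic(fit, fit)), 0)

  # one parameter difference at equal likelihood: |delta| = ln(n)
  m1 <- fit; m2 <- fit
  m2$n_params <- fit$n_params - 1L
  m1$n_persons <- m2$n_persons <- 869
  expect_equal(as.numeric(compare_bic(m1, m2)), log(869), tolerance = 1e-12)
  expect_equal(attr(compare_bic(m1, m2), "favored"), "m2")
})

test_that("non-convergence is reported, never thrown", {
  # two persons cannot identify a saturated 3-item panel model
  ds <- tiny_continuous(n = 2, k = 3, seed = 35)
  fit <- fit_gvar(ds, control = list(maxit = 30, restarts = 0))
  expect_s3_class(fit, "gvar_fit")
  expect_false(fit$converged)
})
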