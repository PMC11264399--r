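#' Fit a panel GVAR model by full-information maximum likelihood
#'
#' Maximizes the FIML log-likelihood over the free parameters of `pattern`
#' with a quasi-Newton (BFGS) optimizer and central-difference numeric
#' gradients; stationarity and positive-definiteness are maintained by
#' rejecting invalid proposals during line search. The objective is the
#' per-person mean negative log-likelihood, which keeps the gradient
#' convergence criterion comparable across sample sizes.
#'
#' Non-convergence never raises an error: the returned model carries
#' `converged = FALSE` (the stability module relies on this contract).
#'
#' @param ds A preprocessed (continuous) [panel_dataset()] with at least
#'   3 waves.
#' @param pattern An [edge_pattern()]; default saturated.
#' @param init Optional [gvar_parameters()] starting values (e.g. a previous
#'   fit); defaults to zero temporal matrix, identity precisions, and the
#'   observed wave means.
#' @param control List of optimizer settings: `maxit` (BFGS iterations per
#'   restart, default 2000), `restarts` (default 4), `grad_tol` (max-norm of
#'   the mean-scale gradient, default 1e-5), `reltol` (relative objective
#'   change, default 1e-9).
#'
#' @return An object of class `gvar_fit`: `params`, `pattern`, `loglik`
#'   (total), `n_params`, `n_persons`, `se` (filled by [standard_errors()]),
#'   `converged`, `n_iterations`.
#' @export
fit_gvar <- function(ds, pattern = NULL, init = NULL, control = list()) {
  if (n_waves(ds) < 3) stop("panel GVAR fitting requires at least 3 waves")
  p <- n_items(ds)
  if (is.null(pattern)) pattern <- saturated_pattern(p)
  ctrl <- modifyList(list(maxit = 2000, restarts = 4,
                          grad_tol = 1e-5, reltol = 1e-9), control)
  prob <- build_prob(ds, pattern)
  if (is.null(init)) init <- moment_init(ds)
  fn <- function(th) cpp_gvar_negll(th, prob)
  gr <- function(th) cpp_gvar_grad(th, prob)
  # a warm start can be invalid under a new pattern (e.g. a near-singular
  # precision loses the off-diagonals that kept it positive-definite);
  # fall back to progressively simpler valid starts
  starts <- list(init, moment_init(ds),
                 gvar_parameters(matrix(0, p, p), diag(p), diag(p),
                                 matrix(0, n_waves(ds), p),
                                 items = ds$schema$items))
  theta <- NULL
  for (s in starts) {
    cand <- tryCatch(pack_theta(s, pattern), error = function(e) NULL)
    if (!is.null(cand) && fn(cand) < 1e9) { theta <- cand; break }
  }
  if (is.null(theta)) theta <- pack_theta(starts[[3]], pattern)

  total_iter <- 0L
  converged <- FALSE
  f_prev <- fn(theta)
  ok <- TRUE
  for (r in seq_len(ctrl$restarts + 1)) {
    opt <- tryCatch(
      optim(theta, fn, gr, method = "BFGS",
            control = list(maxit = ctrl$maxit, reltol = 1e-12)),
      error = function(e) NULL)
    if (is.null(opt)) { ok <- FALSE; break }
    total_iter <- total_iter + opt$counts[["gradient"]]
    theta <- opt$par
    g <- gr(theta)
    rel <- abs(f_prev - opt$value) / (abs(opt$value) + 1e-12)
    f_prev <- opt$value
    if (max(abs(g)) < ctrl$grad_tol && rel < ctrl$reltol) {
      converged <- TRUE
      break
    }
  }
  # damped-Newton polish: BFGS can stall just above the gradient tolerance
  # where the objective is ill-conditioned (between covariance near its
  # singularity boundary); a few curvature-aware steps finish the job
  if (ok && !converged) {
    g <- gr(theta)
    f0 <- fn(theta)
    for (it in seq_len(40)) {
      if (max(abs(g)) < ctrl$grad_tol && rel < ctrl$reltol) break
      H <- tryCatch(cpp_gvar_hessian(theta, prob), error = function(e) NULL)
      if (is.null(H) || any(!is.finite(H))) break
      ei <- eigen((H + t(H)) / 2, symmetric = TRUE)
      if (max(ei$values) <= 0) break
      flo <- 1e-6 * max(ei$values)          # flat-direction flooring
      step <- -ei$vectors %*% ((crossprod(ei$vectors, g)) /
                                 pmax(ei$values, flo))
      nrm <- sqrt(sum(step^2))
      if (nrm > 1) step <- step / nrm       # trust-region style cap
      s <- 1
      repeat {
        f1 <- fn(theta + s * step)
        if (f1 <= f0 || s < 1e-8) break
        s <- s / 2
      }
      if (f1 > f0) {                        # flat to machine precision
        rel <- 0
        break
      }
      rel <- abs(f0 - f1) / (abs(f1) + 1e-12)
      theta <- theta + s * step
      f0 <- f1
      g <- gr(theta)
      total_iter <- total_iter + 1L
    }
    converged <- max(abs(g)) < ctrl$grad_tol && rel < ctrl$reltol
    f_prev <- f0
  }
  value <- fn(theta)
  params <- tryCatch(
    unpack_theta(theta, pattern, n_waves(ds), ds$schema$items),
    error = function(e) NULL)
  if (is.null(params) || !is.finite(value) || value >= 1e9) {
    ok <- FALSE
    params <- init
    converged <- FALSE
  }
  structure(list(
    params = params, pattern = pattern,
    loglik = if (ok) -value * prob$n_total else NA_real_,
    n_params = pattern_n_params(pattern, n_waves(ds)),
    n_persons = prob$n_total,
    theta = theta, se = NULL, vcov = NULL,
    converged = converged && ok, n_iterations = total_iter
  ), class = "gvar_fit")
}

# crude moment-based starting values: observed wave means, zero temporal
# matrix, and the pooled within-wave covariance split evenly between the
# innovation and between-person components (halves the optimizer's path
# compared to identity precisions)
moment_init <- function(ds) {
  p <- n_items(ds)
  Tn <- n_waves(ds)
  nu0 <- t(vapply(seq_len(Tn), function(t)
    colMeans(ds$scores[, t, , drop = FALSE], na.rm = TRUE), numeric(p)))
  K0 <- tryCatch({
    S <- matrix(0, p, p)
    for (t in seq_len(Tn)) {
      m <- ds$scores[, t, , drop = TRUE]
      if (is.null(dim(m))) m <- matrix(m, ncol = p)
      m <- m[stats::complete.cases(m), , drop = FALSE]
      S <- S + stats::cov(m) / Tn
    }
    2 * chol_inv(S + diag(0.05 * mean(diag(S)) + 1e-8, p))
  }, error = function(e) diag(p))
  gvar_parameters(matrix(0, p, p), K0, K0, nu0, items = ds$schema$items)
}

#' @export
print.gvar_fit <- function(x, ...) {
  cat("<gvar_fit> p =", length(x$params$items), "items;",
      x$n_params, "free parameters;",
      "logLik =", format(x$loglik, digits = 8),
      "; converged:", x$converged, "\n")
  invisible(x)
}

#' Standard errors from the observed information
#'
#' Numerically differentiates the negative log-likelihood at the optimum
#' (central differences) and inverts the observed information matrix. The
#' result populates `se` with matrices shaped like the parameters (`NA`
#' where an entry is fixed to zero) and `vcov` with the full covariance of
#' the free-parameter vector.
#'
#' @param model A converged [fit_gvar()] model.
#' @param ds The dataset the model was fitted to.
#' @return The model with `se` and `vcov` filled in.
#' @export
standard_errors <- function(model, ds) {
  if (!model$converged) stop("standard errors require a converged model")
  prob <- build_prob(ds, model$pattern)
  H <- cpp_gvar_hessian(model$theta, prob) * prob$n_total  # total-scale information
  H <- (H + t(H)) / 2
  if (any(!is.finite(H)))
    stop("observed information is not finite; the model is likely not identified")
  # spectral inversion with an eigenvalue floor: when the between-person
  # covariance estimate approaches singularity the information has flat
  # directions; flooring gives those parameters very large standard errors
  # (so Wald pruning drops them) instead of failing outright
  ei <- eigen(H, symmetric = TRUE)
  if (max(ei$values) <= 0)
    stop("observed information is not invertible; the model is likely not identified")
  floor_ev <- 1e-8 * max(ei$values)
  V <- ei$vectors %*% (t(ei$vectors) / pmax(ei$values, floor_ev))
  model$se_regularized <- any(ei$values < floor_ev)
  se_vec <- sqrt(pmax(diag(V), 0))
  p <- length(model$params$items)
  Tn <- nrow(model$params$nu)
  se <- list(beta = matrix(NA_real_, p, p),
             kappa_zeta = matrix(NA_real_, p, p),
             kappa_between = matrix(NA_real_, p, p),
             nu = matrix(NA_real_, Tn, p))
  ix <- theta_index(model$pattern, Tn)
  for (k in seq_along(ix)) {
    e <- ix[[k]]
    se[[e$mat]][e$i, e$j] <- se_vec[k]
    if (e$mat %in% c("kappa_zeta", "kappa_between"))
      se[[e$mat]][e$j, e$i] <- se_vec[k]
  }
  model$se <- se
  model$vcov <- V
  model
}

# Wald z and two-sided p for every free edge parameter; returns a data frame
edge_wald_table <- function(model) {
  if (is.null(model$se)) stop("run standard_errors() first")
  ix <- theta_index(model$pattern, nrow(model$params$nu))
  rows <- list()
  for (e in ix) {
    if (e$mat == "nu") next                              # means are never pruned
    if (e$mat != "beta" && e$i == e$j) next              # precision diagonals kept
    est <- model$params[[e$mat]][e$i, e$j]
    se <- model$se[[e$mat]][e$i, e$j]
    z <- est / se
    rows[[length(rows) + 1]] <- data.frame(
      mat = e$mat, i = e$i, j = e$j, estimate = est, se = se,
      z = z, p = 2 * pnorm(-abs(z)), stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Prune non-significant edges
#'
#' Fixes to zero, simultaneously, all free edge parameters (entries of
#' `beta` -- including the autoregressive diagonal unless
#' `prune_auto = FALSE` -- and off-diagonals of both precisions) whose
#' two-sided Wald p exceeds `alpha`, then refits under the sparser pattern,
#' warm-started from the pruned estimates. By default the step is repeated
#' on the refitted model until the pattern stabilizes (recursive pruning,
#' the convention in network psychometrics). Recursion matters at three
#' waves: the saturated between-person covariance estimate can sit near
#' singularity, which inflates its precision entries and their Wald z; the
#' first refit moves off that boundary and the re-test then removes the
#' spurious edges.
#'
#' @param model A converged [fit_gvar()] model (standard errors are computed
#'   if absent).
#' @param ds The dataset.
#' @param alpha Significance level to retain an edge (default 0.01, the
#'   conventional pruning level in network psychometrics).
#' @param prune_auto Should autoregressive self-loops be prunable too?
#' @param recursive Repeat the prune-and-refit step until no further edge
#'   is removed (default) or run a single pass.
#' @return The refitted sparser `gvar_fit`; its pattern is nested in the
#'   input pattern.
#' @export
prune_gvar <- function(model, ds, alpha = 0.01, prune_auto = TRUE,
                       recursive = TRUE) {
  repeat {
    if (is.null(model$se))
      model <- tryCatch(standard_errors(model, ds), error = function(e) model)
    if (is.null(model$se)) return(model)
    wt <- edge_wald_table(model)
    pat <- model$pattern
    removed <- FALSE
    for (r in seq_len(nrow(wt))) {
      e <- wt[r, ]
      if (!prune_auto && e$mat == "beta" && e$i == e$j) next
      if (e$p > alpha) {
        if (pat[[e$mat]][e$i, e$j]) removed <- TRUE
        pat[[e$mat]][e$i, e$j] <- FALSE
        if (e$mat != "beta") pat[[e$mat]][e$j, e$i] <- FALSE
      }
    }
    if (!removed) return(model)
    init <- model$params
    init$beta[!pat$beta] <- 0
    init$kappa_zeta[!pat$kappa_zeta] <- 0
    init$kappa_between[!pat$kappa_between] <- 0
    refit <- fit_gvar(ds, pat, init = init)
    if (!recursive || !refit$converged) return(refit)
    model <- refit
  }
}

# BIC of a fitted model: -2 logLik + k log(N), N = persons
model_bic <- function(model) {
  -2 * model$loglik + model$n_params * log(model$n_persons)
}

#' Signed BIC difference between two fitted models
#'
#' @param m1,m2 Fitted models on the same dataset.
#' @return `BIC(m1) - BIC(m2)` with attribute `favored` naming the model
#'   with the lower BIC (`"m1"`, `"m2"`, or `"tie"`).
#' @export
compare_bic <- function(m1, m2) {
  d <- model_bic(m1) - model_bic(m2)
  structure(d, favored = if (d < 0) "m1" else if (d > 0) "m2" else "tie")
}

#' Greedy BIC model search
#'
#' Starting from a pruned model, repeatedly frees the single fixed-to-zero
#' edge whose reintroduction most decreases the BIC, re-prunes, and stops
#' when no addition decreases the BIC. Ties are broken deterministically by
#' (matrix, column, row) order. Each candidate refit is warm-started from
#' the current solution.
#'
#' @param model A pruned, converged [fit_gvar()] model.
#' @param ds The dataset.
#' @param alpha Pruning level used in the re-prune step.
#' @param prune_auto Passed to [prune_gvar()].
#' @param max_steps Safety cap on accepted additions.
#' @return The searched `gvar_fit` (BIC never above the input's).
#' @export
search_gvar <- function(model, ds, alpha = 0.01, prune_auto = TRUE,
                        max_steps = 50L) {
  best <- model
  best_bic <- model_bic(best)
  for (step in seq_len(max_steps)) {
    cand <- candidate_edges(best$pattern)
    if (!nrow(cand)) break
    improved <- FALSE
    for (r in seq_len(nrow(cand))) {         # lexical order = tie-break
      pat <- best$pattern
      pat[[cand$mat[r]]][cand$i[r], cand$j[r]] <- TRUE
      if (cand$mat[r] != "beta")
        pat[[cand$mat[r]]][cand$j[r], cand$i[r]] <- TRUE
      fit <- fit_gvar(ds, pat, init = best$params)
      if (!fit$converged) next
      b <- model_bic(fit)
      if (b < best_bic - 1e-8 && !improved) {
        # first strictly better candidate this sweep is provisional...
        prov <- fit; prov_bic <- b; improved <- TRUE
      } else if (improved && b < prov_bic - 1e-8) {
        prov <- fit; prov_bic <- b
      }
    }
    if (!improved) break
    pruned <- prune_gvar(prov, ds, alpha = alpha, prune_auto = prune_auto)
    pb <- model_bic(pruned)
    nxt <- if (pruned$converged && pb <= prov_bic) pruned else prov
    nb <- model_bic(nxt)
    if (nb < best_bic - 1e-8) {
      best <- nxt; best_bic <- nb
    } else break
  }
  best
}

# fixed-to-zero prunable edges, in deterministic (matrix, column, row) order
candidate_edges <- function(pattern) {
  p <- nrow(pattern$beta)
  rows <- list()
  for (j in seq_len(p)) for (i in seq_len(p))
    if (!pattern$beta[i, j])
      rows[[length(rows) + 1]] <- data.frame(mat = "beta", i = i, j = j)
  for (nm in c("kappa_zeta", "kappa_between"))
    for (j in seq_len(p)) for (i in j:p)
      if (i != j && !pattern[[nm]][i, j])
        rows[[length(rows) + 1]] <- data.frame(mat = nm, i = i, j = j)
  if (!length(rows)) return(data.frame(mat = character(), i = integer(), j = integer()))
  out <- do.call(rbind, rows)
  out$mat <- as.character(out$mat)
  out
}

# ---- saturated and baseline comparison models ----

# Unstructured MVN mean/covariance by FIML (EM algorithm). Complete data
# converges in one step to the closed-form MLE.
fit_saturated <- function(ds, tol = 1e-8, maxit = 2000L) {
  Y <- flatten_scores(ds)
  d <- ncol(Y)
  groups <- pattern_groups(Y)
  n <- sum(vapply(groups, `[[`, numeric(1), "n"))
  mu <- colMeans(Y, na.rm = TRUE)
  v <- apply(Y, 2, var, na.rm = TRUE)
  v[!is.finite(v) | v <= 0] <- 1
  Sig <- diag(v, d)
  ll_old <- -Inf
  for (it in seq_len(maxit)) {
    sum_y <- numeric(d)
    sum_yy <- matrix(0, d, d)
    ll <- 0
    for (g in groups) {
      o <- g$idx; m <- setdiff(seq_len(d), o)
      Soo <- Sig[o, o, drop = FALSE]
      L <- chol(Soo)
      Soo_inv <- chol2inv(L)
      dev <- g$ybar - mu[o]
      dg <- length(o)
      ll <- ll - 0.5 * g$n * (dg * log(2 * pi) + 2 * sum(log(diag(L))) +
                              sum(Soo_inv * g$scatter) +
                              drop(dev %*% Soo_inv %*% dev))
      # E-step sufficient statistics for this pattern; scatter is around
      # ybar, so the second moment about zero is scatter + ybar ybar'
      M2_oo <- g$scatter + tcrossprod(g$ybar)
      sy <- numeric(d); syy <- matrix(0, d, d)
      sy[o] <- g$ybar
      syy[o, o] <- M2_oo
      if (length(m)) {
        A <- Sig[m, o, drop = FALSE] %*% Soo_inv   # regression of missing on observed
        mu_m_bar <- mu[m] + drop(A %*% (g$ybar - mu[o]))
        Cmm <- Sig[m, m, drop = FALSE] - A %*% Sig[o, m, drop = FALSE]
        # E[y_m] averaged over the group
        sy[m] <- mu_m_bar
        # E[y_m y_o'] = A %*% (M2_oo - mu_o ybar') ... derive via per-person:
        # y_m_hat_i = mu_m + A (y_o_i - mu_o); average of y_m_hat y_o':
        Emo <- tcrossprod(mu[m], g$ybar) +
          A %*% (M2_oo - tcrossprod(mu[o], g$ybar))
        syy[m, o] <- Emo
        syy[o, m] <- t(Emo)
        # E[y_m y_m'] = Cmm + average of y_m_hat y_m_hat'
        dev_o <- g$scatter  # covariance of y_o within group
        Vhat <- A %*% dev_o %*% t(A)               # covariance of y_m_hat
        syy[m, m] <- Cmm + Vhat + tcrossprod(mu_m_bar)
      }
      sum_y <- sum_y + g$n * sy
      sum_yy <- sum_yy + g$n * syy
    }
    mu_new <- sum_y / n
    Sig_new <- sum_yy / n - tcrossprod(mu_new)
    Sig_new <- (Sig_new + t(Sig_new)) / 2
    mu <- mu_new; Sig <- Sig_new
    if (abs(ll - ll_old) < tol * (abs(ll) + 1)) { ll_old <- ll; break }
    ll_old <- ll
  }
  # final log-likelihood at the converged estimates
  ll <- 0
  for (g in groups) {
    o <- g$idx
    L <- chol(Sig[o, o, drop = FALSE])
    Soo_inv <- chol2inv(L)
    dev <- g$ybar - mu[o]
    ll <- ll - 0.5 * g$n * (length(o) * log(2 * pi) + 2 * sum(log(diag(L))) +
                            sum(Soo_inv * g$scatter) +
                            drop(dev %*% Soo_inv %*% dev))
  }
  list(loglik = ll, mu = mu, sigma = Sig, n_params = d + d * (d + 1) / 2,
       n_persons = n)
}

# independence baseline: free means and variances, all covariances zero.
# With a diagonal covariance the cells are independent, so the per-column
# observed-data MLEs are exact.
fit_baseline <- function(ds) {
  Y <- flatten_scores(ds)
  d <- ncol(Y)
  ll <- 0
  for (j in seq_len(d)) {
    y <- Y[, j]; y <- y[!is.na(y)]
    m <- mean(y); v <- mean((y - m)^2)
    ll <- ll + sum(dnorm(y, m, sqrt(v), log = TRUE))
  }
  n <- nrow(Y[rowSums(!is.na(Y)) > 0, , drop = FALSE])
  list(loglik = ll, n_params = 2 * d, n_persons = n)
}

# pure formula layer, exposed for direct verification
fit_index_formulas <- function(chi2_m, df_m, chi2_b, df_b, N,
                               loglik, n_params) {
  cfi <- 1 - max(chi2_m - df_m, 0) / max(chi2_b - df_b, chi2_m - df_m, 0)
  tli <- if (df_m > 0)
    ((chi2_b / df_b) - (chi2_m / df_m)) / ((chi2_b / df_b) - 1)
  else 1
  tli <- min(tli, 1)
  rmsea_flag <- df_m == 0
  rmsea <- if (rmsea_flag) 0 else sqrt(max(chi2_m - df_m, 0) / (df_m * (N - 1)))
  list(chi2 = chi2_m, df = df_m, cfi = cfi, tli = tli, rmsea = rmsea,
       rmsea_undefined = rmsea_flag,
       bic = -2 * loglik + n_params * log(N),
       aic = -2 * loglik + 2 * n_params)
}

#' SEM fit indices for a fitted panel GVAR
#'
#' Computes chi-square against the FIML-saturated model (unrestricted stacked
#' mean and covariance), CFI and TLI against the independence baseline (free
#' means and variances, all covariances zero), RMSEA, BIC and AIC. N is the
#' number of persons; RMSEA uses N - 1.
#'
#' @param model A converged [fit_gvar()] model.
#' @param ds The dataset.
#' @param saturated Optional precomputed result of the internal saturated
#'   fit, to avoid repeating the EM when evaluating several models on the
#'   same data.
#' @return A list of class `gvar_fit_indices` with `chi2`, `df`, `cfi`,
#'   `tli`, `rmsea`, `bic`, `aic` (and `rmsea_undefined` flag when df = 0).
#' @export
fit_indices <- function(model, ds, saturated = NULL) {
  if (is.null(saturated)) saturated <- fit_saturated(ds)
  base <- fit_baseline(ds)
  chi2_m <- 2 * (saturated$loglik - model$loglik)
  df_m <- saturated$n_params - model$n_params
  chi2_b <- 2 * (saturated$loglik - base$loglik)
  df_b <- saturated$n_params - base$n_params
  out <- fit_index_formulas(chi2_m, df_m, chi2_b, df_b,
                            N = model$n_persons,
                            loglik = model$loglik, n_params = model$n_params)
  structure(out, class = "gvar_fit_indices")
}

#' @export
print.gvar_fit_indices <- function(x, ...) {
  cat(sprintf("chi2 = %.2f (df = %d), CFI = %.3f, TLI = %.3f, RMSEA = %.3f, BIC = %.2f\n",
              x$chi2, as.integer(x$df), x$cfi, x$tli, x$rmsea, x$bic))
  invisible(x)
}
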