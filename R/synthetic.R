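#' Build a sparse ground-truth parameter set
#'
#' Constructs random sparse GVAR parameters for recovery studies: a sparse
#' temporal matrix rescaled to a target spectral radius, and sparse
#' symmetric precisions made positive-definite by diagonal dominance.
#' Reproducible from `seed`.
#'
#' @param p Number of items.
#' @param temporal_density,contemporaneous_density,between_density Fraction
#'   of non-zero off-diagonal entries in `beta` and in the two precisions.
#' @param weight_range Absolute-magnitude interval for sampled weights.
#' @param target_spectral_radius Spectral radius `beta` is rescaled to
#'   (must be in (0, 1)).
#' @param ar Include autoregressive self-loops on the `beta` diagonal?
#' @param prob_positive Probability a sampled edge is positive (symptom
#'   networks are predominantly positive).
#' @param seed Integer seed.
#'
#' @return A [gvar_parameters()] object (3-wave zero means).
#' @export
make_truth <- function(p, temporal_density = 0.15,
                       contemporaneous_density = 0.15,
                       between_density = 0.10,
                       weight_range = c(0.25, 0.45),
                       target_spectral_radius = 0.5,
                       ar = TRUE, prob_positive = 0.8, seed = 1L) {
  stopifnot(target_spectral_radius > 0, target_spectral_radius < 1,
            temporal_density >= 0, temporal_density <= 1,
            contemporaneous_density >= 0, contemporaneous_density <= 1,
            between_density >= 0, between_density <= 1)
  set.seed(seed)
  rw <- function(k) stats::runif(k, weight_range[1], weight_range[2]) *
    ifelse(stats::runif(k) < prob_positive, 1, -1)
  B <- matrix(0, p, p)
  if (ar) diag(B) <- stats::runif(p, weight_range[1], weight_range[2])
  off <- which(row(B) != col(B))
  nz <- off[stats::runif(length(off)) < temporal_density]
  B[nz] <- rw(length(nz))
  sr <- spectral_radius(B)
  if (sr > 0) B <- B * (target_spectral_radius / sr)

  sparse_precision <- function(density, scale = 1) {
    K <- matrix(0, p, p)
    pairs <- which(lower.tri(K))
    nz <- pairs[stats::runif(length(pairs)) < density]
    K[nz] <- -abs(rw(length(nz))) * ifelse(stats::runif(length(nz)) < 0.85, 1, -1)
    K <- K + t(K)
    diag(K) <- 1 + rowSums(abs(K))   # diagonal dominance guarantees PD
    K * scale
  }
  Kz <- sparse_precision(contemporaneous_density)
  Kb <- sparse_precision(between_density, scale = 2)
  check_symmetric_pd(Kz, "kappa_zeta")
  check_symmetric_pd(Kb, "kappa_between")
  gvar_parameters(B, Kz, Kb, n_waves = 3L)
}

#' Simulate a continuous panel from GVAR parameters
#'
#' Per person: a random intercept from the between distribution, a wave-1
#' within-person deviation from the stationary distribution, then the lag-1
#' recursion with innovations from the contemporaneous covariance. The
#' observed score is wave mean + intercept + deviation.
#'
#' @param params A stationary [gvar_parameters()] object.
#' @param n_persons Number of persons.
#' @param n_waves Number of waves.
#' @param seed Integer seed.
#' @param group Group label for the dataset.
#' @return A continuous [panel_dataset()] (4-category schema retained for
#'   downstream ordinalization).
#' @export
simulate_panel <- function(params, n_persons, n_waves = 3L, seed = 1L,
                           group = "synthetic") {
  set.seed(seed)
  p <- length(params$items)
  B <- params$beta
  Sz <- chol_inv(params$kappa_zeta)
  Sb <- chol_inv(params$kappa_between)
  Sstar <- stationary_covariance(B, Sz)
  rmvn <- function(n, S) {
    L <- chol(S)
    matrix(rnorm(n * nrow(S)), n) %*% L
  }
  intercepts <- rmvn(n_persons, Sb)
  dev <- rmvn(n_persons, Sstar)
  nu <- params$nu
  if (nrow(nu) < n_waves)
    nu <- matrix(nu[1, ], n_waves, p, byrow = TRUE)
  sc <- array(NA_real_, c(n_persons, n_waves, p))
  for (t in seq_len(n_waves)) {
    if (t > 1) dev <- dev %*% t(B) + rmvn(n_persons, Sz)
    sc[, t, ] <- sweep(intercepts + dev, 2, nu[t, ], `+`)
  }
  schema <- panel_schema(params$items, n_categories = 4L,
                         waves = paste0("T", seq_len(n_waves)))
  panel_dataset(sc, schema, group = group)
}

#' Discretize latent continuous scores into ordinal categories
#'
#' The observed category is the number of thresholds lying below the latent
#' value, giving scores in `0..n_categories-1`.
#'
#' @param ds A continuous [panel_dataset()].
#' @param thresholds A p x (n_categories - 1) matrix (or list of length-p
#'   vectors) of strictly ascending per-item thresholds on the latent scale.
#' @return An ordinal `panel_dataset`.
#' @export
ordinalize <- function(ds, thresholds) {
  p <- n_items(ds)
  if (is.list(thresholds)) thresholds <- do.call(rbind, thresholds)
  if (is.null(dim(thresholds))) thresholds <- matrix(thresholds, nrow = p,
                                                     ncol = length(thresholds),
                                                     byrow = TRUE)
  stopifnot(nrow(thresholds) == p)
  if (any(apply(thresholds, 1, function(t) any(diff(t) <= 0))))
    stop("thresholds must be strictly ascending per item")
  sc <- ds$scores
  for (j in seq_len(p)) {
    lat <- matrix(ds$scores[, , j], n_persons(ds), n_waves(ds))
    cat <- matrix(0, nrow(lat), ncol(lat))
    for (t in thresholds[j, ]) cat <- cat + (lat > t)
    cat[is.na(lat)] <- NA
    sc[, , j] <- cat
  }
  ds$scores <- sc
  ds
}

# feasible SD interval for a categorical mean on support 0..K-1:
# lower bound from the two adjacent-integer mixture, upper from the
# extreme {0, K-1} two-point mixture
feasible_sd_range <- function(target_mean, n_categories) {
  K <- n_categories - 1
  lo <- sqrt((target_mean - floor(target_mean)) *
             (ceiling(target_mean) - target_mean))
  hi <- sqrt(target_mean * K - target_mean^2)
  c(lo, hi)
}

#' Solve thresholds matching a target categorical mean and SD
#'
#' Finds `n_categories - 1` ascending thresholds for a zero-mean normal
#' latent with SD `latent_sd` such that the implied categorical
#' (population) mean and SD match the targets within 0.01. When the SD
#' target is unattainable by threshold placement the function falls back to
#' matching the mean only (with a warning); infeasible targets raise an
#' error stating the feasible SD interval for that mean.
#'
#' @param target_mean,target_sd Target moments on the 0..n_categories-1 scale.
#' @param latent_sd SD of the latent normal variable.
#' @param n_categories Number of ordinal categories.
#' @return Numeric vector of ascending thresholds (latent scale).
#' @export
calibrate_thresholds <- function(target_mean, target_sd, latent_sd = 1,
                                 n_categories = 4L) {
  K <- n_categories - 1
  if (target_mean <= 0 || target_mean >= K)
    stop("target mean ", target_mean, " with positive SD is infeasible on 0..", K)
  rng <- feasible_sd_range(target_mean, n_categories)
  if (target_sd < rng[1] - 1e-9 || target_sd > rng[2] + 1e-9)
    stop(sprintf("target SD %.3f infeasible for mean %.3f; feasible interval [%.3f, %.3f]",
                 target_sd, target_mean, rng[1], rng[2]))
  moments <- function(z) {           # z: standard-scale thresholds
    pr <- diff(c(0, pnorm(z), 1))
    m <- sum((0:K) * pr)
    s <- sqrt(max(sum((0:K)^2 * pr) - m^2, 0))
    c(m, s)
  }
  obj <- function(par) {
    z <- cumsum(c(par[1], exp(par[-1])))
    ms <- moments(z)
    (ms[1] - target_mean)^2 + (ms[2] - target_sd)^2
  }
  starts <- list(c(0, log(0.8), log(0.8)),
                 c(qnorm(max(1 - target_mean / K, 1e-4)), log(0.4), log(0.4)),
                 c(1, log(1.2), log(1.2)))
  if (n_categories != 4)
    starts <- lapply(starts, function(s) c(s[1], rep(log(0.8), K - 1)))
  best <- NULL
  for (s0 in starts) {
    o <- tryCatch(optim(s0, obj, method = "Nelder-Mead",
                        control = list(maxit = 3000, reltol = 1e-14)),
                  error = function(e) NULL)
    if (!is.null(o) && (is.null(best) || o$value < best$value)) best <- o
  }
  z <- cumsum(c(best$par[1], exp(best$par[-1])))
  ms <- moments(z)
  if (abs(ms[1] - target_mean) > 0.01 || abs(ms[2] - target_sd) > 0.01) {
    warning("SD target unattainable to 0.01; falling back to mean-only matching")
    f <- function(z1) moments(cumsum(c(z1, rep(0.8, K - 1))))[1] - target_mean
    z1 <- stats::uniroot(f, c(-8, 8), tol = 1e-12)$root
    z <- cumsum(c(z1, rep(0.8, K - 1)))
  }
  z * latent_sd
}

#' Impose score-dependent monotone attrition
#'
#' For each wave transition, a still-participating person drops out with
#' probability `plogis(qlogis(base_rate) + slope * total)` where `total` is
#' their previous-wave symptom total; once dropped, all later waves are
#' missing. Because dropout depends only on observed history, the mechanism
#' is missing at random.
#'
#' @param ds A [panel_dataset()].
#' @param base_rate Dropout probability at total 0; scalar or one value per
#'   transition.
#' @param slope Log-odds increase in dropout per unit of previous-wave total.
#' @param seed Integer seed.
#' @return A `panel_dataset` with monotone wave-level missingness.
#' @export
apply_attrition <- function(ds, base_rate, slope = 0, seed = 1L) {
  Tn <- n_waves(ds)
  stopifnot(all(base_rate >= 0), all(base_rate < 1))
  if (length(base_rate) == 1) base_rate <- rep(base_rate, Tn - 1)
  stopifnot(length(base_rate) == Tn - 1)
  set.seed(seed)
  sc <- ds$scores
  active <- rep(TRUE, n_persons(ds))
  for (t in 2:Tn) {
    if (base_rate[t - 1] == 0 && slope == 0) next
    prev_total <- rowSums(sc[, t - 1, , drop = TRUE], na.rm = TRUE)
    pr <- plogis(qlogis(max(base_rate[t - 1], 1e-12)) + slope * prev_total)
    if (base_rate[t - 1] == 0) pr <- rep(0, length(pr))
    drop <- active & (stats::runif(length(pr)) < pr)
    sc[drop, t:Tn, ] <- NA_real_
    active <- active & !drop
  }
  ds$scores <- sc
  ds
}

#' Printed descriptive item moments shipped with the package
#'
#' Per-group, per-wave, per-item N, mean, SD, skewness and kurtosis for the
#' ten EPDS items in a three-wave postnatal community panel (mothers n = 869,
#' fathers n = 579 at wave 1). These published summary statistics are the
#' calibration targets of the synthetic generator and the inputs of the
#' in-package arithmetic checks.
#'
#' @return A data frame with columns `group`, `wave`, `item`, `n`, `mean`,
#'   `sd`, `skewness`, `kurtosis`.
#' @export
epds_reference_moments <- function() {
  path <- system.file("extdata", "epds_item_moments.csv", package = "panelgvar")
  read.csv(path, stringsAsFactors = FALSE)
}

# Deterministic ground-truth network for the calibrated preset: sadness
# (EPDS8) and anxiety (EPDS4) act as temporal hubs, mirroring the dominant
# qualitative pattern in postnatal symptom panels; the suicidal-ideation
# item (EPDS10) is kept unconnected and near-constant to exercise variance
# screening.
preset_truth <- function() {
  p <- 10
  items <- paste0("EPDS", 1:p)
  B <- matrix(0, p, p, dimnames = list(items, items))
  # B[receiver, predictor]
  B[8, 8] <- 0.32; B[4, 4] <- 0.30          # autoregressive self-loops
  B[7, 8] <- 0.32; B[9, 8] <- 0.34          # sadness -> sleep, crying (strong)
  B[1, 8] <- 0.18; B[2, 8] <- 0.15
  B[3, 8] <- 0.15; B[6, 8] <- 0.15
  B[8, 9] <- 0.25                           # crying -> sadness
  B[3, 4] <- 0.32                           # anxious -> self-blame (strong)
  B[4, 3] <- 0.22; B[6, 4] <- 0.18; B[5, 4] <- 0.20
  Kz <- diag(p)
  set_pc <- function(K, i, j, w) { K[i, j] <- K[j, i] <- -w; K }
  Kz <- set_pc(Kz, 1, 2, 0.30); Kz <- set_pc(Kz, 8, 9, 0.32)
  Kz <- set_pc(Kz, 7, 9, 0.25); Kz <- set_pc(Kz, 6, 8, 0.22)
  Kz <- set_pc(Kz, 7, 8, 0.20); Kz <- set_pc(Kz, 3, 4, 0.20)
  Kz <- set_pc(Kz, 1, 8, 0.18); Kz <- set_pc(Kz, 4, 5, 0.18)
  Kz <- set_pc(Kz, 2, 3, 0.15)
  Kb <- diag(p) * 2
  Kb <- set_pc(Kb, 1, 2, 0.5); Kb <- set_pc(Kb, 8, 9, 0.5)
  Kb <- set_pc(Kb, 4, 5, 0.5)
  dimnames(Kz) <- dimnames(Kb) <- list(items, items)
  gvar_parameters(B, Kz, Kb, n_waves = 3L)
}

#' Simulate a calibrated ordinal three-wave panel
#'
#' The default synthetic scenario: 9 inter-connected EPDS items plus the
#' near-constant suicidal-ideation item, 3 waves, latent-Gaussian
#' ordinalization with thresholds calibrated to the shipped published item
#' moments (wave-1 rows), and score-dependent monotone attrition whose base
#' rates echo the published per-transition dropout and whose positive slope
#' makes dropouts more symptomatic (missing at random given observed
#' history).
#'
#' @param group `"mothers"` (n = 869) or `"fathers"` (n = 579); sets the
#'   default sample size, the calibration targets, and the attrition base
#'   rates.
#' @param n Number of persons (default: the group's published wave-1 n).
#' @param seed Integer seed driving simulation and attrition.
#' @param ordinal Apply calibrated ordinalization? (`FALSE` returns the
#'   latent continuous panel.)
#' @param attrition Apply score-dependent monotone attrition?
#' @param slope Attrition log-odds slope per unit of previous-wave total.
#' @return A list with `data` (the [panel_dataset()]), `truth` (the
#'   generating [gvar_parameters()]), and `thresholds` (p x 3 matrix, or
#'   `NULL` when `ordinal = FALSE`).
#' @export
simulate_lin_like <- function(group = c("mothers", "fathers"), n = NULL,
                              seed = 1L, ordinal = TRUE, attrition = TRUE,
                              slope = 0.2) {
  group <- match.arg(group)
  if (is.null(n)) n <- if (group == "mothers") 869L else 579L
  truth <- preset_truth()
  ds <- simulate_panel(truth, n, n_waves = 3L, seed = seed, group = group)
  thresholds <- NULL
  if (ordinal) {
    imp <- implied_covariance(truth, 1)      # wave-1 marginal variances
    lat_sd <- sqrt(diag(imp$sigma))
    mom <- epds_reference_moments()
    mom <- mom[mom$group == group & mom$wave == "T1", ]
    mom <- mom[match(truth$items, mom$item), ]
    thresholds <- t(vapply(seq_along(truth$items), function(j)
      calibrate_thresholds(mom$mean[j], mom$sd[j], latent_sd = lat_sd[j]),
      numeric(3)))
    rownames(thresholds) <- truth$items
    ds <- ordinalize(ds, thresholds)
  }
  if (attrition) {
    base <- if (group == "mothers") c(0.065, 0.022) else c(0.030, 0.036)
    ds <- apply_attrition(ds, base, slope = slope, seed = seed + 1L)
  }
  list(data = ds, truth = truth, thresholds = thresholds)
}
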