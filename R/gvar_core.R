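#' Panel GVAR parameters
#'
#' The estimand of the random-intercept graphical vector autoregression:
#' a lag-1 temporal coefficient matrix `beta` (row = effect receiver, column
#' = predictor, so `beta[j, i]` is the effect of item i at wave t-1 on item j
#' at wave t), the contemporaneous innovation precision `kappa_zeta`, the
#' between-person (random intercept) precision `kappa_between`, and
#' wave-specific mean vectors `nu`.
#'
#' @param beta p x p temporal coefficient matrix; spectral radius must be
#'   below 1 (stationarity).
#' @param kappa_zeta p x p symmetric positive-definite innovation precision.
#' @param kappa_between p x p symmetric positive-definite between precision.
#' @param nu Wave means: an `n_waves` x p matrix (or a single length-p vector
#'   recycled over `n_waves` waves).
#' @param items Optional item labels.
#' @param n_waves Number of waves (needed only when `nu` is a vector).
#'
#' @return An object of class `gvar_parameters`.
#' @export
gvar_parameters <- function(beta, kappa_zeta, kappa_between, nu = NULL,
                            items = NULL, n_waves = 3L) {
  p <- nrow(beta)
  if (is.null(nu)) nu <- matrix(0, n_waves, p)
  if (is.null(dim(nu))) nu <- matrix(nu, n_waves, p, byrow = TRUE)
  if (is.null(items)) items <- colnames(beta)
  if (is.null(items)) items <- paste0("V", seq_len(p))
  stopifnot(ncol(beta) == p, all(dim(kappa_zeta) == p),
            all(dim(kappa_between) == p), ncol(nu) == p)
  check_symmetric_pd(kappa_zeta, "kappa_zeta")
  check_symmetric_pd(kappa_between, "kappa_between")
  if (spectral_radius(beta) >= 1)
    stop("beta has spectral radius >= 1; the process is not stationary")
  dimnames(beta) <- dimnames(kappa_zeta) <- dimnames(kappa_between) <-
    list(items, items)
  colnames(nu) <- items
  structure(list(beta = beta, kappa_zeta = kappa_zeta,
                 kappa_between = kappa_between, nu = nu, items = items),
            class = "gvar_parameters")
}

#' @export
print.gvar_parameters <- function(x, ...) {
  cat("<gvar_parameters> p =", length(x$items), "items,", nrow(x$nu), "waves;",
      "spectral radius(beta) =", round(spectral_radius(x$beta), 3), "\n")
  invisible(x)
}

spectral_radius <- function(B) max(Mod(eigen(B, only.values = TRUE)$values))

check_symmetric_pd <- function(K, name) {
  if (max(abs(K - t(K))) > 1e-10) stop(name, " is not symmetric")
  ok <- tryCatch({ chol(K); TRUE }, error = function(e) FALSE)
  if (!ok) stop(name, " is not positive-definite")
  invisible(TRUE)
}

# Cholesky-based inverse of a symmetric PD matrix
chol_inv <- function(K) chol2inv(chol(K))

#' Free/fixed edge pattern
#'
#' Boolean matrices marking which entries of `beta` and which off-diagonal
#' entries of the two precisions are free parameters; fixed entries are
#' constrained to zero. Precision diagonals are always free, and the
#' precision patterns must be symmetric.
#'
#' @param beta Logical p x p matrix (temporal edges, including the diagonal
#'   autoregressive self-loops).
#' @param kappa_zeta,kappa_between Logical symmetric p x p matrices; the
#'   diagonal is forced to `TRUE`.
#' @return An object of class `edge_pattern`.
#' @export
edge_pattern <- function(beta, kappa_zeta, kappa_between) {
  p <- nrow(beta)
  stopifnot(all(dim(kappa_zeta) == p), all(dim(kappa_between) == p))
  if (!identical(kappa_zeta, t(kappa_zeta)) ||
      !identical(kappa_between, t(kappa_between)))
    stop("precision patterns must be symmetric")
  diag(kappa_zeta) <- TRUE
  diag(kappa_between) <- TRUE
  structure(list(beta = beta, kappa_zeta = kappa_zeta,
                 kappa_between = kappa_between),
            class = "edge_pattern")
}

#' @rdname edge_pattern
#' @param p Number of items.
#' @export
saturated_pattern <- function(p) {
  m <- matrix(TRUE, p, p)
  edge_pattern(m, m, m)
}

#' @rdname edge_pattern
#' @param params A [gvar_parameters()] object; its non-zero entries define
#'   the free pattern.
#' @export
pattern_from_parameters <- function(params) {
  edge_pattern(params$beta != 0,
               params$kappa_zeta != 0 | t(params$kappa_zeta != 0),
               params$kappa_between != 0 | t(params$kappa_between != 0))
}

# number of free parameters under a pattern (wave means always free)
pattern_n_params <- function(pattern, n_waves) {
  p <- nrow(pattern$beta)
  sum(pattern$beta) +
    sum(pattern$kappa_zeta[lower.tri(pattern$kappa_zeta, diag = TRUE)]) +
    sum(pattern$kappa_between[lower.tri(pattern$kappa_between, diag = TRUE)]) +
    n_waves * p
}

#' Stationary covariance of the lag-1 process
#'
#' Solves the discrete Lyapunov equation
#' \eqn{\Sigma^* = B \Sigma^* B^\top + \Sigma_\zeta} via the Kronecker
#' linearization \eqn{(I - B \otimes B)\,\mathrm{vec}(\Sigma^*) =
#' \mathrm{vec}(\Sigma_\zeta)}.
#'
#' @param B Temporal coefficient matrix with spectral radius below 1.
#' @param Sigma_zeta Innovation covariance (symmetric positive-definite).
#' @return The stationary covariance, exactly symmetrized.
#' @export
stationary_covariance <- function(B, Sigma_zeta) {
  p <- nrow(B)
  if (spectral_radius(B) >= 1)
    stop("spectral radius of B is >= 1; no stationary covariance exists")
  A <- diag(p * p) - kronecker(B, B)
  S <- matrix(solve(A, as.vector(Sigma_zeta)), p, p)
  (S + t(S)) / 2
}

#' Implied stacked covariance and mean
#'
#' The model-implied moments of the stacked observation vector
#' (wave-major: all items at wave 1, then wave 2, ...). Block (t, s) with
#' t >= s equals \eqn{B^{t-s}\Sigma^* + \Sigma_B}: the within-person VAR(1)
#' block-Toeplitz structure plus the between-person covariance added to
#' every block by the random intercepts.
#'
#' @param params A [gvar_parameters()] object.
#' @param n_waves Number of waves to stack (default: waves of `nu`).
#' @return A list with `sigma` ((p n_waves) square, symmetric PD) and `mu`
#'   (stacked wave means).
#' @export
implied_covariance <- function(params, n_waves = nrow(params$nu)) {
  p <- length(params$items)
  B <- params$beta
  Sz <- chol_inv(params$kappa_zeta)
  Sb <- chol_inv(params$kappa_between)
  Sstar <- stationary_covariance(B, Sz)
  d <- p * n_waves
  Sig <- matrix(0, d, d)
  Bp <- vector("list", n_waves)
  Bp[[1]] <- diag(p)
  if (n_waves > 1)
    for (t in 2:n_waves) Bp[[t]] <- B %*% Bp[[t - 1]]
  for (t in seq_len(n_waves)) for (s in seq_len(t)) {
    blk <- Bp[[t - s + 1]] %*% Sstar + Sb
    ri <- (t - 1) * p + seq_len(p); ci <- (s - 1) * p + seq_len(p)
    Sig[ri, ci] <- blk
    if (t != s) Sig[ci, ri] <- t(blk)
  }
  if (nrow(params$nu) < n_waves)
    stop("params$nu has fewer waves than requested")
  mu <- as.vector(t(params$nu[seq_len(n_waves), , drop = FALSE]))
  ok <- tryCatch({ chol(Sig); TRUE }, error = function(e) FALSE)
  if (!ok) stop("implied covariance is not positive-definite")
  labs <- as.vector(outer(params$items, seq_len(n_waves),
                          function(i, t) paste0(i, ".w", t)))
  dimnames(Sig) <- list(labs, labs)
  names(mu) <- labs
  list(sigma = Sig, mu = mu)
}

# persons x (p * n_waves) matrix, wave-major stacking, NA = missing
flatten_scores <- function(ds) {
  sc <- ds$scores
  n <- dim(sc)[1]; Tn <- dim(sc)[2]; p <- dim(sc)[3]
  Y <- matrix(NA_real_, n, Tn * p)
  for (t in seq_len(Tn))
    Y[, (t - 1) * p + seq_len(p)] <- sc[, t, ]
  Y
}

# group rows of Y by missingness pattern; persons with zero observed cells
# are dropped (they contribute nothing to the likelihood)
pattern_groups <- function(Y) {
  obs <- !is.na(Y)
  key <- apply(obs, 1, function(r) paste(as.integer(r), collapse = ""))
  out <- list()
  for (k in unique(key)) {
    rows <- which(key == k)
    o <- which(obs[rows[1], ])
    if (!length(o)) next
    Yo <- Y[rows, o, drop = FALSE]
    ybar <- colMeans(Yo)
    ctr <- sweep(Yo, 2, ybar)
    out[[length(out) + 1]] <- list(
      idx = o, n = length(rows), ybar = ybar,
      scatter = crossprod(ctr) / length(rows)
    )
  }
  out
}

#' Full-information maximum-likelihood log-likelihood
#'
#' Sum over persons of the multivariate-normal log-density of each person's
#' observed cells, with mean and covariance sub-blocks selected by the
#' person's missingness pattern (persons are grouped by pattern; the result
#' is invariant to grouping). Unbiased under missing-at-random data.
#'
#' @param params A [gvar_parameters()] object.
#' @param ds A preprocessed (continuous) [panel_dataset()].
#' @return The scalar log-likelihood.
#' @export
fiml_loglik <- function(params, ds) {
  imp <- implied_covariance(params, n_waves(ds))
  Y <- flatten_scores(ds)
  groups <- pattern_groups(Y)
  ll <- 0
  for (g in groups) {
    Sg <- imp$sigma[g$idx, g$idx, drop = FALSE]
    L <- tryCatch(chol(Sg), error = function(e)
      stop("singular implied covariance for missingness pattern with cells ",
           paste(g$idx, collapse = ",")))
    logdet <- 2 * sum(log(diag(L)))
    Sinv <- chol2inv(L)
    dev <- g$ybar - imp$mu[g$idx]
    dg <- length(g$idx)
    ll <- ll - 0.5 * g$n * (dg * log(2 * pi) + logdet +
                            sum(Sinv * g$scatter) +
                            drop(dev %*% Sinv %*% dev))
  }
  ll
}

# ---- parameter vector packing (must mirror the C++ layout) ----

pack_theta <- function(params, pattern) {
  p <- length(params$items)
  lt <- lower.tri(matrix(0, p, p), diag = TRUE)
  c(params$beta[pattern$beta],
    params$kappa_zeta[lt & pattern$kappa_zeta],
    params$kappa_between[lt & pattern$kappa_between],
    as.vector(t(params$nu)))
}

unpack_theta <- function(theta, pattern, n_waves, items) {
  p <- nrow(pattern$beta)
  B <- matrix(0, p, p); Kz <- matrix(0, p, p); Kb <- matrix(0, p, p)
  pos <- sum(pattern$beta)
  B[pattern$beta] <- theta[seq_len(pos)]
  lt <- lower.tri(Kz, diag = TRUE)
  nz <- sum(lt & pattern$kappa_zeta)
  Kz[lt & pattern$kappa_zeta] <- theta[pos + seq_len(nz)]
  Kz <- Kz + t(Kz) - diag(diag(Kz))
  pos <- pos + nz
  nb <- sum(lt & pattern$kappa_between)
  Kb[lt & pattern$kappa_between] <- theta[pos + seq_len(nb)]
  Kb <- Kb + t(Kb) - diag(diag(Kb))
  pos <- pos + nb
  nu <- matrix(theta[pos + seq_len(n_waves * p)], n_waves, p, byrow = TRUE)
  gvar_parameters(B, Kz, Kb, nu, items = items)
}

# same layout, but returns the location of each theta element for reporting:
# matrix name and (row, col) indices
theta_index <- function(pattern, n_waves) {
  p <- nrow(pattern$beta)
  ix <- list()
  for (j in seq_len(p)) for (i in seq_len(p))
    if (pattern$beta[i, j])
      ix[[length(ix) + 1]] <- list(mat = "beta", i = i, j = j)
  for (j in seq_len(p)) for (i in j:p)
    if (pattern$kappa_zeta[i, j])
      ix[[length(ix) + 1]] <- list(mat = "kappa_zeta", i = i, j = j)
  for (j in seq_len(p)) for (i in j:p)
    if (pattern$kappa_between[i, j])
      ix[[length(ix) + 1]] <- list(mat = "kappa_between", i = i, j = j)
  for (t in seq_len(n_waves)) for (j in seq_len(p))
    ix[[length(ix) + 1]] <- list(mat = "nu", i = t, j = j)
  ix
}

# problem list consumed by the C++ objective
build_prob <- function(ds, pattern, scale = NULL) {
  Y <- flatten_scores(ds)
  groups <- pattern_groups(Y)
  n_tot <- sum(vapply(groups, `[[`, numeric(1), "n"))
  if (is.null(scale)) scale <- 1 / n_tot
  list(
    p = n_items(ds), n_waves = n_waves(ds),
    pat_beta = matrix(as.integer(pattern$beta), n_items(ds)),
    pat_kz = matrix(as.integer(pattern$kappa_zeta), n_items(ds)),
    pat_kb = matrix(as.integer(pattern$kappa_between), n_items(ds)),
    pat_idx = lapply(groups, function(g) as.integer(g$idx - 1L)),
    pat_n = vapply(groups, `[[`, numeric(1), "n"),
    pat_ybar = lapply(groups, `[[`, "ybar"),
    pat_scatter = lapply(groups, `[[`, "scatter"),
    scale = scale, n_total = n_tot
  )
}

#' Serialize GVAR parameters to JSON
#'
#' Matrices are written row-major with explicit item row/column labels so the
#' receiver-row / predictor-column orientation of `beta` survives export.
#'
#' @param params A [gvar_parameters()] object.
#' @param path Optional output path; if `NULL` the JSON string is returned.
#' @return `path` (invisibly) or a JSON string.
#' @export
gvar_parameters_json <- function(params, path = NULL) {
  doc <- list(
    items = params$items,
    orientation = "beta[receiver, predictor]",
    beta = params$beta, kappa_zeta = params$kappa_zeta,
    kappa_between = params$kappa_between, nu = params$nu
  )
  js <- jsonlite::toJSON(doc, matrix = "rowmajor", digits = NA, auto_unbox = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(path)
}
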