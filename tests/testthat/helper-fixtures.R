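# Shared fixtures, built in code at test time.

# tiny complete ordinal panel: n persons x 3 waves x k items, seeded
tiny_panel <- function(n = 6, k = 3, seed = 1, n_categories = 4) {
  set.seed(seed)
  sc <- array(as.numeric(sample(0:(n_categories - 1), n * 3 * k,
                                replace = TRUE)), c(n, 3, k))
  panel_dataset(sc, panel_schema(paste0("I", seq_len(k)), n_categories),
                person_ids = paste0("p", seq_len(n)))
}

# continuous panel with arbitrary values (validation-free round trips)
tiny_continuous <- function(n = 8, k = 3, seed = 2) {
  set.seed(seed)
  sc <- array(rnorm(n * 3 * k), c(n, 3, k))
  panel_dataset(sc, panel_schema(paste0("I", seq_len(k))),
                person_ids = seq_len(n))
}

# monotone-attrition fixture reproducing given per-wave participation counts:
# persons beyond the wave-k count are missing from wave k onwards
participation_fixture <- function(counts, k = 2) {
  n <- counts[1]
  sc <- array(0, c(n, length(counts), k))
  set.seed(99)
  sc[, , 1] <- sample(0:3, n * length(counts), replace = TRUE)
  for (w in seq_along(counts)[-1])
    if (counts[w] < n) sc[(counts[w] + 1):n, w, ] <- NA
  panel_dataset(sc, panel_schema(paste0("I", seq_len(k)),
                                 waves = paste0("T", seq_along(counts))))
}

# write a long CSV and return its path
write_long_csv <- function(df, dir = tempdir()) {
  path <- tempfile("panel", tmpdir = dir, fileext = ".csv")
  write.csv(df, path, row.names = FALSE, na = "")
  path
}

# dense multivariate-normal log-likelihood oracle (no missingness logic)
dense_mvn_loglik <- function(Y, mu, Sigma) {
  L <- chol(Sigma)
  Sinv <- chol2inv(L)
  ld <- 2 * sum(log(diag(L)))
  d <- ncol(Y)
  sum(apply(Y, 1, function(y) {
    dev <- y - mu
    -0.5 * (d * log(2 * pi) + ld + drop(dev %*% Sinv %*% dev))
  }))
}

# truncated-series oracle for the stationary covariance
series_stationary <- function(B, Sz, terms = 200) {
  S <- matrix(0, nrow(B), ncol(B))
  Bk <- diag(nrow(B))
  for (k in 0:terms) {
    S <- S + Bk %*% Sz %*% t(Bk)
    Bk <- Bk %*% B
  }
  S
}

expect_no_missing <- function(ds) expect_false(anyNA(ds$scores))
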