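#' Per-item, per-wave descriptive moments
#'
#' Computes, over non-missing values: n, sample mean, sample SD (n-1),
#' skewness, and excess kurtosis. By default the small-sample-adjusted
#' estimators are used (adjusted Fisher--Pearson skewness
#' \eqn{G_1 = g_1 \sqrt{n(n-1)}/(n-2)} and adjusted excess kurtosis
#' \eqn{G_2 = ((n+1) g_2 + 6)(n-1)/((n-2)(n-3))}), the convention of common
#' statistical software descriptive tables; `type = "raw"` gives the plain
#' moment ratios \eqn{g_1, g_2}.
#'
#' @param ds A [panel_dataset()].
#' @param type `"adjusted"` (default) or `"raw"`.
#' @return A data frame with columns `item`, `wave`, `n`, `mean`, `sd`,
#'   `skewness`, `kurtosis`. Skewness needs n >= 3 and kurtosis n >= 4 (and
#'   non-zero variance); otherwise `NA`.
#' @export
item_moments <- function(ds, type = c("adjusted", "raw")) {
  type <- match.arg(type)
  rows <- expand.grid(wave = seq_len(n_waves(ds)), item = seq_len(n_items(ds)))
  out <- do.call(rbind, lapply(seq_len(nrow(rows)), function(r) {
    w <- rows$wave[r]; j <- rows$item[r]
    v <- ds$scores[, w, j]
    v <- v[!is.na(v)]
    n <- length(v)
    m <- if (n) mean(v) else NA_real_
    s <- if (n > 1) sd(v) else NA_real_
    sk <- ku <- NA_real_
    if (n >= 3 && isTRUE(s > 0)) {
      m2 <- mean((v - m)^2)
      g1 <- mean((v - m)^3) / m2^1.5
      sk <- if (type == "adjusted") g1 * sqrt(n * (n - 1)) / (n - 2) else g1
      if (n >= 4) {
        g2 <- mean((v - m)^4) / m2^2 - 3
        ku <- if (type == "adjusted")
          ((n + 1) * g2 + 6) * (n - 1) / ((n - 2) * (n - 3)) else g2
      }
    }
    data.frame(item = ds$schema$items[j], wave = ds$schema$waves[w],
               n = n, mean = m, sd = s, skewness = sk, kurtosis = ku,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Scale totals at one wave
#'
#' Sums the item scores per person at the given wave, for persons with all
#' items non-missing there.
#'
#' @param ds A [panel_dataset()].
#' @param wave Wave index (1-based) or wave label.
#' @return A list with `totals` (named per-person vector), `n`, `mean`, `sd`.
#' @export
scale_total <- function(ds, wave) {
  w <- resolve_wave(ds, wave)
  mat <- ds$scores[, w, , drop = TRUE]
  if (is.null(dim(mat))) mat <- matrix(mat, ncol = n_items(ds))
  ok <- stats::complete.cases(mat)
  totals <- rowSums(mat[ok, , drop = FALSE])
  names(totals) <- ds$person_ids[ok]
  list(totals = totals, n = sum(ok),
       mean = if (any(ok)) mean(totals) else NA_real_,
       sd = if (sum(ok) > 1) sd(totals) else NA_real_)
}

resolve_wave <- function(ds, wave) {
  if (is.character(wave)) {
    w <- match(wave, ds$schema$waves)
    if (is.na(w)) stop("unknown wave label: ", wave)
    return(w)
  }
  w <- as.integer(wave)
  if (w < 1 || w > n_waves(ds)) stop("wave index out of range")
  w
}

#' Cronbach's alpha with Feldt confidence interval
#'
#' Internal consistency \eqn{\alpha = k/(k-1) (1 - \sum s_i^2 / s_T^2)} on
#' complete cases at one wave. The interval uses Feldt's result that
#' \eqn{(1-\alpha)/(1-\hat\alpha)} follows an F distribution with
#' \eqn{(n-1)} and \eqn{(n-1)(k-1)} degrees of freedom.
#'
#' @param ds A [panel_dataset()].
#' @param wave Wave index or label.
#' @param ci_level Confidence level (default 0.95).
#' @return A list with `alpha`, `lower`, `upper`, `n`, `k`.
#' @export
cronbach_alpha <- function(ds, wave, ci_level = 0.95) {
  w <- resolve_wave(ds, wave)
  mat <- ds$scores[, w, , drop = TRUE]
  if (is.null(dim(mat))) mat <- matrix(mat, ncol = n_items(ds))
  mat <- mat[stats::complete.cases(mat), , drop = FALSE]
  n <- nrow(mat); k <- ncol(mat)
  if (k < 2) stop("alpha needs at least 2 items")
  if (n < 3) stop("alpha needs at least 3 complete cases")
  vt <- var(rowSums(mat))
  if (vt == 0) stop("zero total-score variance")
  alpha <- k / (k - 1) * (1 - sum(apply(mat, 2, var)) / vt)
  a2 <- (1 - ci_level) / 2
  df1 <- n - 1; df2 <- (n - 1) * (k - 1)
  lower <- 1 - (1 - alpha) * qf(1 - a2, df1, df2)
  upper <- 1 - (1 - alpha) * qf(a2, df1, df2)
  list(alpha = alpha, lower = lower, upper = upper, n = n, k = k)
}

#' Prevalence at or above a clinical cut-off
#'
#' Counts complete-case scale totals at or above (default) the cut-off score
#' and reports the percentage of complete cases (2 decimals). Strict
#' exceedance is available for sensitivity.
#'
#' @param ds A [panel_dataset()].
#' @param wave Wave index or label.
#' @param cutoff Integer cut-off on the total score.
#' @param strict If `TRUE`, count totals strictly above the cut-off.
#' @return A list with `count`, `n`, `percent`.
#' @export
cutoff_prevalence <- function(ds, wave, cutoff, strict = FALSE) {
  st <- scale_total(ds, wave)
  cnt <- if (strict) sum(st$totals > cutoff) else sum(st$totals >= cutoff)
  list(count = cnt, n = st$n, percent = round(100 * cnt / st$n, 2))
}

#' Compare baseline symptom totals of completers and dropouts
#'
#' Two-sample pooled-variance Student t test on scale totals at
#' `outcome_wave` (typically wave 1), comparing persons still participating
#' at `final_wave` against those who dropped out by then. Sign convention:
#' completers minus dropouts, so attrition of more-symptomatic persons gives
#' a negative t.
#'
#' @param ds A [panel_dataset()].
#' @param outcome_wave Wave whose totals are compared (default 1).
#' @param final_wave Wave defining completion (default: last).
#' @return A list with `t`, `df`, `p`, group sizes and means.
#' @export
attrition_comparison <- function(ds, outcome_wave = 1, final_wave = n_waves(ds)) {
  wo <- resolve_wave(ds, outcome_wave)
  wf <- resolve_wave(ds, final_wave)
  st <- scale_total(ds, wo)
  part <- participation_matrix(ds)[, wf]
  names(part) <- ds$person_ids
  completer <- part[names(st$totals)]
  x <- st$totals[completer]   # completers
  y <- st$totals[!completer]  # dropouts
  if (length(x) < 2 || length(y) < 2)
    stop("both completer and dropout groups need at least 2 persons with totals")
  n1 <- length(x); n2 <- length(y)
  sp2 <- ((n1 - 1) * var(x) + (n2 - 1) * var(y)) / (n1 + n2 - 2)
  tval <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  df <- n1 + n2 - 2
  list(t = tval, df = df, p = 2 * stats::pt(-abs(tval), df),
       n_completers = n1, n_dropouts = n2,
       mean_completers = mean(x), mean_dropouts = mean(y))
}
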