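#' Remove pooled linear time trends
#'
#' Fits, per item, an ordinary least-squares line of score on 0-based wave
#' index pooled over persons (non-missing cells only) and subtracts the
#' fitted values. This removes the fixed linear time effect so the residual
#' process can plausibly satisfy stationarity; with only three waves a
#' per-person line would absorb nearly all within-person variance, so the
#' trend is pooled.
#'
#' @param ds A [panel_dataset()] (scores may be ordinal or continuous).
#' @return A `panel_dataset` with detrended (continuous) scores; the
#'   missingness pattern is unchanged.
#' @export
detrend_panel <- function(ds) {
  sc <- ds$scores
  Tn <- n_waves(ds)
  wave_idx <- rep(seq_len(Tn) - 1, each = n_persons(ds))
  for (j in seq_len(n_items(ds))) {
    y <- as.vector(sc[, , j])
    ok <- !is.na(y)
    if (!any(ok)) stop("item ", ds$schema$items[j], " is entirely missing")
    if (length(unique(wave_idx[ok])) < 2)
      stop("item ", ds$schema$items[j], " has data at fewer than 2 waves")
    fit <- lm.fit(cbind(1, wave_idx[ok]), y[ok])
    co <- fit$coefficients
    sc[, , j] <- sc[, , j] - matrix(co[1] + co[2] * (seq_len(Tn) - 1),
                                    nrow = n_persons(ds), ncol = Tn, byrow = TRUE)
  }
  ds$scores <- sc
  ds
}

#' Standardize items across time points
#'
#' Each item is z-scored with its pooled mean and standard deviation computed
#' across all waves jointly (denominator n-1), not per wave, so that wave
#' differences in level and spread remain interpretable relative to one
#' common scale.
#'
#' @param ds A [panel_dataset()].
#' @return A `panel_dataset` with pooled mean 0 and pooled SD 1 per item.
#' @export
standardize_panel <- function(ds) {
  sc <- ds$scores
  for (j in seq_len(n_items(ds))) {
    y <- as.vector(sc[, , j])
    m <- mean(y, na.rm = TRUE)
    s <- sd(y, na.rm = TRUE)
    if (!is.finite(s) || s == 0)
      stop("item ", ds$schema$items[j],
           " has zero pooled variance; screen it out before standardizing")
    sc[, , j] <- (sc[, , j] - m) / s
  }
  ds$scores <- sc
  ds
}

#' Restrict to complete cases
#'
#' Retains only persons with no missing item at any wave, for sensitivity
#' reanalysis against the full-information fit.
#'
#' @param ds A [panel_dataset()].
#' @param quiet Suppress the retained/dropped message.
#' @return A `panel_dataset` containing only complete persons.
#' @export
complete_cases_panel <- function(ds, quiet = FALSE) {
  keep <- !apply(is.na(ds$scores), 1, any)
  if (!any(keep)) stop("no complete cases")
  if (!quiet)
    message("complete cases: retained ", sum(keep), ", dropped ", sum(!keep))
  panel_dataset(ds$scores[keep, , , drop = FALSE], ds$schema,
                person_ids = ds$person_ids[keep], group = ds$group)
}
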