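#' Case-drop subsampling stability of the pruned networks
#'
#' Repeatedly draws a person subsample without replacement, re-runs the
#' configured pipeline (preprocess, saturated fit, prune, optional search)
#' on it, and codes every possible edge 1 if present (free and non-zero in
#' the final pattern) or 0 otherwise. A non-converged replicate contributes
#' 0 to every edge. Standardization and detrending statistics are recomputed
#' on each subsample. Fully reproducible from `seed`: one independent
#' substream is derived per replicate index, so results do not depend on
#' execution order.
#'
#' @param ds A [panel_dataset()] with the analysis items (screen items
#'   before calling, so the edge grid is fixed across replicates).
#' @param config Pipeline settings: `detrend`, `standardize` (logicals,
#'   default TRUE), `complete_cases_only` (default FALSE), `prune_alpha`
#'   (default 0.01), `prune_auto` (default TRUE), `search` (default FALSE).
#' @param proportion Subsample fraction in (0, 1]; 0.75 replicates the
#'   common case-drop protocol.
#' @param reps Number of replicates.
#' @param seed Integer seed.
#'
#' @return An object of class `stability_result`: `presence_counts` (list of
#'   three integer matrices: `temporal` directed, `contemporaneous` and
#'   `between` symmetric), `n_replicates`, `subsample_proportion`,
#'   `n_nonconverged`, `seed`.
#' @export
casedrop_stability <- function(ds, config = list(), proportion = 0.75,
                               reps = 1000L, seed = 1L) {
  stopifnot(proportion > 0, proportion <= 1, reps >= 1)
  cfg <- modifyList(list(detrend = TRUE, standardize = TRUE,
                         complete_cases_only = FALSE,
                         prune_alpha = 0.01, prune_auto = TRUE,
                         search = FALSE), config)
  p <- n_items(ds)
  items <- ds$schema$items
  zero <- matrix(0L, p, p, dimnames = list(items, items))
  counts <- list(temporal = zero, contemporaneous = zero, between = zero)
  n <- n_persons(ds)
  m <- floor(proportion * n)
  set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max - 1L, reps)
  n_nonconv <- 0L
  for (r in seq_len(reps)) {
    set.seed(rep_seeds[r])
    take <- sample.int(n, m)
    sub <- tryCatch(
      panel_dataset(ds$scores[take, , , drop = FALSE], ds$schema,
                    person_ids = ds$person_ids[take], group = ds$group),
      error = function(e) NULL)
    fit <- if (is.null(sub)) NULL else
      tryCatch(pipeline_fit_networks(sub, cfg), error = function(e) NULL)
    if (is.null(fit)) {
      n_nonconv <- n_nonconv + 1L
      next
    }
    nets <- fit$networks
    counts$temporal <- counts$temporal + (abs(nets$temporal) > 0) * 1L
    counts$contemporaneous <- counts$contemporaneous +
      (abs(nets$contemporaneous) > 0) * 1L
    counts$between <- counts$between + (abs(nets$between) > 0) * 1L
  }
  structure(list(presence_counts = counts, n_replicates = as.integer(reps),
                 subsample_proportion = proportion,
                 n_nonconverged = n_nonconv, seed = as.integer(seed)),
            class = "stability_result")
}

# preprocess + fit + prune [+ search] on one dataset; returns NULL-free list
# or errors / non-convergence signalled by returning NULL from the caller
pipeline_fit_networks <- function(ds, cfg) {
  if (isTRUE(cfg$complete_cases_only)) ds <- complete_cases_panel(ds, quiet = TRUE)
  if (isTRUE(cfg$detrend)) ds <- detrend_panel(ds)
  if (isTRUE(cfg$standardize)) ds <- standardize_panel(ds)
  sat <- fit_gvar(ds)
  if (!sat$converged) return(NULL)
  pruned <- prune_gvar(sat, ds, alpha = cfg$prune_alpha,
                       prune_auto = cfg$prune_auto)
  if (!pruned$converged) return(NULL)
  final <- if (isTRUE(cfg$search))
    search_gvar(pruned, ds, alpha = cfg$prune_alpha,
                prune_auto = cfg$prune_auto)
  else pruned
  if (!final$converged) return(NULL)
  list(saturated = sat, final = final, networks = extract_networks(final),
       data = ds)
}

#' @export
print.stability_result <- function(x, ...) {
  cat("<stability_result> ", x$n_replicates, " replicates at proportion ",
      x$subsample_proportion, "; non-converged: ", x$n_nonconverged,
      "\n", sep = "")
  invisible(x)
}

#' Report edges with low replication presence
#'
#' Lists edges whose presence share across replicates falls below
#' `threshold` (shares reported to 3 decimals). By default all possible
#' edges are scanned; passing a reference [extract_networks()] set restricts
#' the report to edges actually displayed in a final network, which is the
#' usual reading of stability for a pruned network.
#'
#' @param res A [casedrop_stability()] result.
#' @param threshold Presence-share threshold in \[0, 1\].
#' @param reference Optional `network_set`; only its non-zero edges are
#'   considered.
#' @return A data frame with `network`, `source`, `target`, `count`, `share`.
#' @export
presence_report <- function(res, threshold = 0.10, reference = NULL) {
  items <- rownames(res$presence_counts$temporal)
  p <- length(items)
  rows <- list()
  add <- function(network, i, j) {
    cnt <- res$presence_counts[[network]][i, j]
    share <- cnt / res$n_replicates
    if (share < threshold)
      rows[[length(rows) + 1]] <<- data.frame(
        network = network, source = items[i], target = items[j],
        count = as.integer(cnt), share = round(share, 3),
        stringsAsFactors = FALSE)
  }
  keep <- function(network, i, j) {
    is.null(reference) || reference[[network]][i, j] != 0
  }
  for (i in seq_len(p)) for (j in seq_len(p))
    if (keep("temporal", i, j)) add("temporal", i, j)
  for (nm in c("contemporaneous", "between"))
    for (j in seq_len(p)) for (i in j:p) if (i != j && keep(nm, i, j))
      add(nm, i, j)
  if (!length(rows))
    return(data.frame(network = character(), source = character(),
                      target = character(), count = integer(),
                      share = numeric()))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
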