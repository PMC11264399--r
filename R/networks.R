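#' Partial correlations from a precision matrix
#'
#' The Gaussian graphical model identity
#' \eqn{\omega_{ij} = -\kappa_{ij} / \sqrt{\kappa_{ii}\kappa_{jj}}}, with the
#' diagonal set to zero.
#'
#' @param K Symmetric positive-definite precision matrix.
#' @return The symmetric partial-correlation matrix.
#' @export
precision_to_partial <- function(K) {
  check_symmetric_pd(K, "precision matrix")
  d <- sqrt(diag(K))
  W <- -K / outer(d, d)
  diag(W) <- 0
  (W + t(W)) / 2
}

#' Extract the three reported networks from a fitted model
#'
#' Temporal: directed matrix with entry `[i, j]` the lag-1 effect of item i
#' on item j (`temporal[i, j] = beta[j, i]`; predictor-to-receiver
#' orientation, raw coefficients on standardized variables). Contemporaneous
#' and between: partial-correlation networks of the innovation and
#' random-intercept precisions.
#'
#' @param model A converged [fit_gvar()] model (or a [gvar_parameters()]
#'   object).
#' @return An object of class `network_set` with elements `temporal`,
#'   `contemporaneous`, `between`, `items`.
#' @export
extract_networks <- function(model) {
  params <- if (inherits(model, "gvar_fit")) model$params else model
  nets <- list(
    temporal = t(params$beta),
    contemporaneous = precision_to_partial(params$kappa_zeta),
    between = precision_to_partial(params$kappa_between),
    items = params$items
  )
  dimnames(nets$temporal) <- dimnames(nets$contemporaneous) <-
    dimnames(nets$between) <- list(params$items, params$items)
  structure(nets, class = "network_set")
}

#' @export
print.network_set <- function(x, ...) {
  nz <- function(m) sum(m[row(m) != col(m)] != 0)
  cat("<network_set> ", length(x$items), " items; off-diagonal edges: ",
      "temporal ", nz(x$temporal), ", contemporaneous ",
      nz(x$contemporaneous) / 2, ", between ", nz(x$between) / 2, "\n", sep = "")
  invisible(x)
}

#' Strength centrality of the networks
#'
#' For the directed temporal network: out-strength is the sum of absolute
#' outgoing edge weights and in-strength the sum of absolute incoming edge
#' weights, excluding the autoregressive self-loops. For the undirected
#' contemporaneous and between networks: strength is the sum of absolute
#' edge weights connected to the node.
#'
#' @param nets A [extract_networks()] result.
#' @return A data frame with columns `item`, `in_strength`, `out_strength`,
#'   `strength`, `strength_between`.
#' @export
centrality <- function(nets) {
  tm <- nets$temporal
  off <- function(m) { diag(m) <- 0; m }
  a <- abs(off(tm))
  data.frame(
    item = nets$items,
    in_strength = colSums(a),
    out_strength = rowSums(a),
    strength = rowSums(abs(off(nets$contemporaneous))),
    strength_between = rowSums(abs(off(nets$between))),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Edge list of a network set
#'
#' One row per non-zero edge: undirected networks list each pair once
#' (lower triangle); full precision is retained (rounding is left to the
#' caller's export layer).
#'
#' @param x A `network_set`.
#' @param ... Unused.
#' @return A data frame with columns `source`, `target`, `weight`, `network`.
#' @export
as.data.frame.network_set <- function(x, ...) {
  rows <- list()
  p <- length(x$items)
  for (i in seq_len(p)) for (j in seq_len(p)) {
    w <- x$temporal[i, j]
    if (w != 0)
      rows[[length(rows) + 1]] <- data.frame(
        source = x$items[i], target = x$items[j], weight = w,
        network = "temporal", stringsAsFactors = FALSE)
  }
  for (nm in c("contemporaneous", "between"))
    for (j in seq_len(p)) for (i in j:p) if (i != j) {
      w <- x[[nm]][i, j]
      if (w != 0)
        rows[[length(rows) + 1]] <- data.frame(
          source = x$items[j], target = x$items[i], weight = w,
          network = nm, stringsAsFactors = FALSE)
    }
  if (!length(rows))
    return(data.frame(source = character(), target = character(),
                      weight = numeric(), network = character()))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
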