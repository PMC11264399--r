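#' Default study configuration
#'
#' Every analysis choice the method leaves open surfaces here as an explicit
#' key with its documented default, so a configuration file is a complete
#' record of a run.
#'
#' @return A nested list of configuration defaults.
#' @export
default_config <- function() {
  list(
    data = NULL,                      # CSV path; NULL = synthetic preset
    format = "long",
    group = "mothers",
    seed = 1L,
    synthetic = list(n = NULL, ordinal = TRUE, attrition = TRUE),
    screen = list(enabled = TRUE, max_modal_share = 0.95),
    preprocess = list(detrend = TRUE, standardize = TRUE,
                      complete_cases_only = FALSE),
    descriptives = list(cutoff = 11, alpha_ci = 0.95),
    model = list(prune_alpha = 0.01, prune_auto = TRUE, search = FALSE),
    stability = list(enabled = FALSE, reps = 50L, proportion = 0.75),
    out = NULL
  )
}

# deep-merge user settings over the defaults
merge_config <- function(config) {
  cfg <- default_config()
  if (is.character(config) && length(config) == 1) {
    config <- if (grepl("[.]json$", config)) jsonlite::read_json(config)
    else yaml::read_yaml(config)
  }
  modifyList(cfg, config)
}

# small stable polynomial hash so artifacts can be stamped with their config
# (two accumulators with distinct multipliers, exact in double arithmetic)
poly_hash <- function(raw) {
  b <- as.integer(raw)
  h1 <- 17; h2 <- 257
  for (x in b) {
    h1 <- (h1 * 31 + x) %% 2147483647
    h2 <- (h2 * 131 + x) %% 2147483629
  }
  sprintf("%04x%04x", as.integer(h1 %% 65536), as.integer(h2 %% 65536))
}
config_hash <- function(cfg) poly_hash(serialize(cfg, NULL, version = 2))

with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop(structure(class = c(paste0("panelgvar_stage_", stage),
                             "panelgvar_stage_error", "error", "condition"),
                   list(message = paste0("[stage ", stage, "] ",
                                         conditionMessage(e)),
                        call = NULL, stage = stage))))
}

#' Run the full study workflow
#'
#' Executes, per group: read (or simulate) data, variance screening,
#' optional complete-case filtering, detrending, standardization,
#' descriptives, saturated GVAR fit with fit indices, pruning (and optional
#' BIC search) with fit indices, BIC comparison, network extraction,
#' centrality, and (optionally) case-drop stability. When `config$out` is a
#' directory, writes a JSON results bundle, CSV tables (descriptives, edge
#' lists, centrality, stability counts), and a plain-text summary; every
#' artifact is stamped with the configuration hash and seed.
#'
#' @param config A configuration list (merged over [default_config()]) or a
#'   path to a YAML/JSON configuration file.
#' @return The results bundle, invisibly (a nested list mirroring the JSON).
#' @export
run_study <- function(config = list()) {
  cfg <- merge_config(config)
  hash <- config_hash(cfg[setdiff(names(cfg), "out")])  # where, not what
  msg <- function(...) message("[panelgvar] ", ...)

  truth <- NULL
  ds <- with_stage("read", {
    if (is.null(cfg$data)) {
      msg("simulating calibrated ", cfg$group, " preset (seed ", cfg$seed, ")")
      sim <- simulate_lin_like(cfg$group, n = cfg$synthetic$n, seed = cfg$seed,
                               ordinal = isTRUE(cfg$synthetic$ordinal),
                               attrition = isTRUE(cfg$synthetic$attrition))
      truth <- sim$truth
      sim$data
    } else {
      msg("reading ", cfg$data)
      read_panel(cfg$data, epds_schema(), format = cfg$format,
                 group = cfg$group)
    }
  })

  miss <- with_stage("missingness", missingness_profile(ds))
  scr <- with_stage("screen", {
    if (isTRUE(cfg$screen$enabled))
      screen_variance(ds, cfg$screen$max_modal_share)
    else list(dataset = ds, excluded = character(0))
  })
  ds <- scr$dataset
  if (length(scr$excluded)) msg("screened out: ", paste(scr$excluded, collapse = ", "))

  desc <- with_stage("descriptives", {
    waves <- ds$schema$waves
    list(
      moments = item_moments(ds),
      totals = lapply(setNames(waves, waves), function(w) {
        st <- scale_total(ds, w)
        st$totals <- NULL
        st
      }),
      alpha = lapply(setNames(waves, waves), function(w)
        cronbach_alpha(ds, w, cfg$descriptives$alpha_ci)),
      prevalence = lapply(setNames(waves, waves), function(w)
        cutoff_prevalence(ds, w, cfg$descriptives$cutoff)),
      attrition = tryCatch(attrition_comparison(ds), error = function(e) NULL)
    )
  })

  pp <- cfg$preprocess
  ds_model <- with_stage("preprocess", {
    d <- ds
    if (isTRUE(pp$complete_cases_only)) d <- complete_cases_panel(d, quiet = TRUE)
    if (isTRUE(pp$detrend)) d <- detrend_panel(d)
    if (isTRUE(pp$standardize)) d <- standardize_panel(d)
    d
  })

  msg("fitting saturated model (", n_persons(ds_model), " persons, ",
      n_items(ds_model), " items)")
  sat <- with_stage("fit_saturated", fit_gvar(ds_model))
  if (!sat$converged) stop("saturated model did not converge")
  sat_ref <- with_stage("fit_indices", fit_saturated(ds_model))
  fi_sat <- fit_indices(sat, ds_model, saturated = sat_ref)

  msg("pruning at alpha = ", cfg$model$prune_alpha)
  pruned <- with_stage("prune", prune_gvar(sat, ds_model,
                                           alpha = cfg$model$prune_alpha,
                                           prune_auto = cfg$model$prune_auto))
  final <- if (isTRUE(cfg$model$search)) {
    msg("BIC model search")
    with_stage("search", search_gvar(pruned, ds_model,
                                     alpha = cfg$model$prune_alpha,
                                     prune_auto = cfg$model$prune_auto))
  } else pruned
  fi_final <- fit_indices(final, ds_model, saturated = sat_ref)
  dbic <- compare_bic(sat, final)

  nets <- with_stage("networks", extract_networks(final))
  cent <- centrality(nets)
  edges <- as.data.frame(nets)

  stab <- NULL
  if (isTRUE(cfg$stability$enabled)) {
    msg("case-drop stability: ", cfg$stability$reps, " replicates")
    stab <- with_stage("stability", casedrop_stability(
      ds,
      config = list(detrend = pp$detrend, standardize = pp$standardize,
                    complete_cases_only = pp$complete_cases_only,
                    prune_alpha = cfg$model$prune_alpha,
                    prune_auto = cfg$model$prune_auto,
                    search = cfg$model$search),
      proportion = cfg$stability$proportion,
      reps = cfg$stability$reps, seed = cfg$seed))
  }

  bundle <- list(
    config_hash = hash, seed = cfg$seed, group = cfg$group,
    n_persons = n_persons(ds), items = ds$schema$items,
    screening = list(excluded = scr$excluded),
    missingness = miss,
    descriptives = desc,
    fit = list(
      n_persons_model = n_persons(ds_model),
      saturated = list(loglik = sat$loglik, n_params = sat$n_params,
                       indices = unclass(fi_sat)),
      final = list(loglik = final$loglik, n_params = final$n_params,
                   indices = unclass(fi_final)),
      delta_bic_saturated_minus_final = as.numeric(dbic),
      favored = if (as.numeric(dbic) > 0) "final" else "saturated"
    ),
    networks = list(edges = edges, centrality = cent),
    stability = if (!is.null(stab)) list(
      n_replicates = stab$n_replicates,
      proportion = stab$subsample_proportion,
      n_nonconverged = stab$n_nonconverged,
      presence_counts = lapply(stab$presence_counts, unname))
  )

  if (!is.null(cfg$out)) with_stage("write", {
    dir.create(cfg$out, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(bundle, file.path(cfg$out, "results.json"),
                         digits = NA, auto_unbox = TRUE, pretty = TRUE,
                         dataframe = "rows", na = "null")
    write.csv(desc$moments, file.path(cfg$out, "descriptives.csv"),
              row.names = FALSE)
    write.csv(edges, file.path(cfg$out, "edges.csv"), row.names = FALSE)
    write.csv(cent, file.path(cfg$out, "centrality.csv"), row.names = FALSE)
    if (!is.null(stab))
      for (nm in names(stab$presence_counts))
        write.csv(stab$presence_counts[[nm]],
                  file.path(cfg$out, paste0("stability_", nm, ".csv")))
    writeLines(summary_text(bundle), file.path(cfg$out, "summary.txt"))
  })
  invisible(bundle)
}

# plain-text run summary: fit, top edges, centralities
summary_text <- function(b) {
  fmt <- function(x, k = 3) formatC(x, digits = k, format = "f")
  lines <- c(
    paste0("panelgvar run ", b$config_hash, " (seed ", b$seed, ", group ",
           b$group, ", n = ", b$n_persons, ")"),
    paste0("screened out: ", if (length(b$screening$excluded))
      paste(b$screening$excluded, collapse = ", ") else "none"),
    paste0("saturated: logLik ", fmt(b$fit$saturated$loglik, 2),
           ", CFI ", fmt(b$fit$saturated$indices$cfi),
           ", TLI ", fmt(b$fit$saturated$indices$tli),
           ", RMSEA ", fmt(b$fit$saturated$indices$rmsea)),
    paste0("final:     logLik ", fmt(b$fit$final$loglik, 2),
           ", CFI ", fmt(b$fit$final$indices$cfi),
           ", TLI ", fmt(b$fit$final$indices$tli),
           ", RMSEA ", fmt(b$fit$final$indices$rmsea)),
    paste0("delta BIC (saturated - final) = ",
           fmt(b$fit$delta_bic_saturated_minus_final, 2),
           "; favored: ", b$fit$favored),
    "", "top |edges| per network:")
  ed <- b$networks$edges
  for (nm in unique(ed$network)) {
    sub <- ed[ed$network == nm, ]
    sub <- sub[order(-abs(sub$weight)), ][seq_len(min(5, nrow(sub))), ]
    lines <- c(lines, paste0("  [", nm, "] ",
      paste0(sub$source, "->", sub$target, " ", fmt(sub$weight, 2),
             collapse = ", ")))
  }
  cent <- b$networks$centrality
  lines <- c(lines, "", "centrality (in / out / contemporaneous strength):",
    paste0("  ", cent$item, ": ", fmt(cent$in_strength, 2), " / ",
           fmt(cent$out_strength, 2), " / ", fmt(cent$strength, 2)))
  lines
}
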