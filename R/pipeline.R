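# End-to-end orchestration: model + cohort in, per-sample scores, group
# assignment, contribution table with markers, optional sweeps, and a run
# manifest out.

#' Build and validate a pipeline configuration
#'
#' @param model a `metabolic_model` (objective set), or a path to an SBML
#'   file.
#' @param expr genes x samples expression matrix, or a path to an
#'   expression TSV.
#' @param med a `medium`, or a path to a medium JSON.
#' @param labels named character vector: `"control"` or a case label per
#'   sample column.
#' @param out_dir output directory.
#' @param t,l threshold and objective level.
#' @param N_null MC null-model size.
#' @param n_media random-media draws (0 disables the media sweep).
#' @param t_grid threshold-sweep grid (`NULL` disables).
#' @param currency_fraction per-compartment currency-metabolite cut.
#' @param weight_mode inconsistency weighting (`"deficit"`/`"uniform"`).
#' @param always_available always-available exchange ids for media draws.
#' @param marker_thresholds overrides for [marker_defaults()].
#' @param seed master seed.
#' @return validated list of class `run_config`.
#' @export
run_config <- function(model, expr, med, labels, out_dir,
                       t = 2, l = 0.8, N_null = 1000, n_media = 0,
                       t_grid = NULL, currency_fraction = 0.04,
                       weight_mode = "deficit",
                       always_available = character(),
                       marker_thresholds = list(), seed = 1L) {
  if (is.character(model)) model <- read_sbml_model(model)
  if (is.character(expr)) expr <- read_expression_tsv(expr)
  if (is.character(med)) med <- read_medium_json(med)
  stopifnot(inherits(model, "metabolic_model"), is.matrix(expr),
            inherits(med, "medium"))
  if (is.na(model$objective)) stop("config invalid: model has no objective")
  if (!(l > 0 && l <= 1)) stop("config invalid: l must be in (0, 1]")
  if (!is.finite(t)) stop("config invalid: t must be finite")
  if (is.null(names(labels)) || !all(colnames(expr) %in% names(labels))) {
    stop("config invalid: labels must be named by sample")
  }
  if (!any(labels == "control")) stop("config invalid: no control samples")
  structure(list(model = model, expr = expr, med = med,
                 labels = labels[colnames(expr)], out_dir = out_dir,
                 t = t, l = l, N_null = N_null, n_media = n_media,
                 t_grid = t_grid, currency_fraction = currency_fraction,
                 weight_mode = weight_mode,
                 always_available = always_available,
                 marker_thresholds = marker_thresholds, seed = seed),
            class = "run_config")
}

#' Run the full comparative analysis
#'
#' Stages: (1) currency removal and gene-network projection; (2) per-sample
#' expression mapping, inconsistency (I) and coherence (MC); (3) LIG/HIG
#' group assignment against the control mean; (4) contribution table with
#' specificity calls and topological markers; (5) optional threshold and
#' media sweeps. Artifacts are TSV/JSON files under `out_dir` plus a
#' `manifest.json` recording parameters, seeds and per-stage wall time.
#'
#' @param config a `run_config`.
#' @param quiet suppress stage messages.
#' @return (invisibly) list with all in-memory results (`samples`,
#'   `groups`, `contributions`, `markers`, `sweep_t`, `media`, `network`,
#'   `excluded_metabolites`, `manifest`).
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message("[metcoher] ", ...)
  stage_times <- list()
  clock <- function(stage, expr) {
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(expr, error = function(e) {
      stage_times[[stage]] <<- proc.time()[["elapsed"]] - t0
      .write_manifest(config, stage_times, complete = FALSE,
                      failed_stage = stage, error = conditionMessage(e))
      stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    stage_times[[stage]] <<- proc.time()[["elapsed"]] - t0
    out
  }
  model <- config$model
  expr <- config$expr
  samples <- colnames(expr)

  say("stage network: currency removal + gene-network projection")
  net <- clock("network", {
    excl <- remove_currency_metabolites(model, config$currency_fraction)
    list(excluded = excl, graph = project_gene_network(model, excl))
  })

  say("stage scores: per-sample inconsistency and coherence (",
      length(samples), " samples)")
  scores <- clock("scores", {
    m_app <- apply_medium(model, config$med)
    fba <- fba_max(m_app)
    res <- vector("list", length(samples))
    mcs <- vector("list", length(samples))
    for (i in seq_along(samples)) {
      rx <- reaction_expression(expr[, i], model, quiet = TRUE)
      pat <- threshold_pattern(rx, config$t, sample_id = samples[i])
      res[[i]] <- tryCatch(
        gimme(m_app, pat, l = config$l, fba = fba,
              weight_mode = config$weight_mode),
        error = function(e) NULL)
      mcs[[i]] <- metabolic_coherence(net$graph,
                                      active_genes(expr[, i], config$t),
                                      N = config$N_null,
                                      seed = config$seed + i)
    }
    list(gimme = stats::setNames(res, samples),
         mc = stats::setNames(mcs, samples))
  })
  samp_df <- data.frame(
    sample_id = samples,
    label = unname(config$labels),
    I = vapply(scores$gimme, function(r) if (is.null(r)) NA_real_ else r$inconsistency, 0),
    I_norm = vapply(scores$gimme, function(r) if (is.null(r)) NA_real_ else r$normalized, 0),
    v_obj = vapply(scores$gimme, function(r) if (is.null(r)) NA_real_ else r$v_obj, 0),
    MC = vapply(scores$mc, `[[`, 0, "mc"),
    ratio = vapply(scores$mc, `[[`, 0, "ratio"),
    stringsAsFactors = FALSE)

  say("stage groups: LIG/HIG split against control mean")
  groups <- clock("groups", {
    is_ctrl <- samp_df$label == "control"
    ok <- is.finite(samp_df$I)
    ga <- assign_groups(samp_df$I[is_ctrl & ok],
                        stats::setNames(samp_df$I[!is_ctrl & ok],
                                        samp_df$sample_id[!is_ctrl & ok]))
    grp <- stats::setNames(rep(NA_character_, nrow(samp_df)), samp_df$sample_id)
    grp[is_ctrl] <- "control"
    grp[names(ga$groups)] <- ga$groups
    list(assignment = grp, control_mean = ga$control_mean)
  })
  samp_df$group <- unname(groups$assignment[samp_df$sample_id])

  say("stage contributions: per-group strengths, specificity, markers")
  contrib <- clock("contributions", {
    by_grp <- split(seq_along(samples), samp_df$group)
    res_by_grp <- lapply(by_grp, function(ix) {
      Filter(Negate(is.null), scores$gimme[ix])
    })
    res_by_grp <- res_by_grp[vapply(res_by_grp, length, 0L) > 0]
    tab <- classify_specificity(contribution_table(res_by_grp))
    rx_expr <- vapply(seq_along(samples), function(i)
      reaction_expression(expr[, i], model, quiet = TRUE),
      numeric(nrow(model$reactions)))
    rownames(rx_expr) <- model$reactions$id
    pats <- lapply(seq_along(samples), function(i)
      threshold_pattern(rx_expr[, i], config$t, sample_id = samples[i]))
    m_app <- apply_medium(model, config$med)
    mks <- topological_markers(m_app, tab$reaction_id, pats,
                               reaction_expr = rx_expr, l = config$l,
                               excluded = net$excluded,
                               thresholds = config$marker_thresholds)
    tab$markers <- vapply(mks, paste, "", collapse = ";")[tab$reaction_id]
    list(table = tab, markers = mks)
  })

  sweep_t <- NULL
  if (!is.null(config$t_grid)) {
    say("stage sweep_t: threshold sweep over ", length(config$t_grid),
        " grid points")
    sweep_t <- clock("sweep_t", {
      threshold_sweep(model, net$graph, expr, config$med,
                      t_grid = config$t_grid, l = config$l,
                      N_null = config$N_null, seed = config$seed,
                      weight_mode = config$weight_mode)
    })
  }
  media <- NULL
  if (config$n_media > 0) {
    say("stage media: ", config$n_media, " random media")
    media <- clock("media", {
      media_sweep(model, net$graph, expr, t = config$t, l = config$l,
                  n_media = config$n_media, seed = config$seed,
                  N_null = config$N_null,
                  always_available = config$always_available,
                  weight_mode = config$weight_mode)
    })
  }

  say("stage write: artifacts -> ", config$out_dir)
  clock("write", {
    wt <- function(df, f) utils::write.table(
      df, file.path(config$out_dir, f), sep = "\t", quote = FALSE,
      row.names = FALSE)
    wt(samp_df, "samples.tsv")
    iv <- do.call(rbind, lapply(samples, function(s) {
      r <- scores$gimme[[s]]
      if (is.null(r) || !nrow(r$inconsistency_vector)) return(NULL)
      cbind(sample_id = s, r$inconsistency_vector)
    }))
    if (!is.null(iv)) wt(iv, "inconsistency_vectors.tsv")
    wt(as.data.frame(contrib$table), "contributions.tsv")
    if (!is.null(sweep_t)) wt(as.data.frame(sweep_t), "sweep_threshold.tsv")
    if (!is.null(media)) wt(media$draws, "media_sweep.tsv")
    el <- igraph::as_edgelist(net$graph)
    wt(data.frame(from = el[, 1], to = el[, 2]), "gene_network_edges.tsv")
  })
  manifest <- .write_manifest(config, stage_times, complete = TRUE)
  say("done")
  invisible(list(samples = samp_df, groups = groups,
                 contributions = contrib$table, markers = contrib$markers,
                 sweep_t = sweep_t, media = media, network = net$graph,
                 excluded_metabolites = net$excluded, manifest = manifest))
}

.write_manifest <- function(config, stage_times, complete, failed_stage = NULL,
                            error = NULL) {
  manifest <- list(
    package_version = as.character(utils::packageVersion("metcoher")),
    parameters = list(t = config$t, l = config$l, N_null = config$N_null,
                      n_media = config$n_media, t_grid = config$t_grid,
                      currency_fraction = config$currency_fraction,
                      weight_mode = config$weight_mode, seed = config$seed),
    n_samples = ncol(config$expr),
    stage_seconds = stage_times,
    complete = complete)
  if (!is.null(failed_stage)) {
    manifest$failed_stage <- failed_stage
    manifest$error <- error
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  manifest
}
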