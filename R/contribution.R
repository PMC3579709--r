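# Decomposing inconsistency into per-reaction contributions, splitting the
# cohort into low/high-inconsistency groups, and classifying contributing
# reactions by topological markers:
#   BN  bottleneck           knockout drops the FBA max below l * v_max
#   CD  chain disruptor      absent reaction flanked by present neighbours
#   IP  invisible path       GPR-less neighbourhood
#   CIL close to input layer near an uptake-enabled exchange
#   COL close to output layer near the objective reaction
#   JBT just below threshold absent everywhere, median expression within a
#                            small margin below t

#' Split a cohort into low/high inconsistency groups
#'
#' Case samples with inconsistency below the control-group mean form the
#' low-inconsistency group (LIG), the rest the high-inconsistency group
#' (HIG). Ties at the mean go to HIG (a measure-zero convention, fixed for
#' determinism).
#'
#' @param control_I inconsistencies of the control samples.
#' @param case_I inconsistencies of the case (e.g. adenoma) samples.
#' @return list with `groups` (character `"LIG"`/`"HIG"` per case sample,
#'   names preserved) and `control_mean`.
#' @export
assign_groups <- function(control_I, case_I) {
  stopifnot(length(control_I) > 0, length(case_I) > 0)
  m <- mean(control_I)
  groups <- ifelse(case_I < m, "LIG", "HIG")
  names(groups) <- names(case_I)
  list(groups = groups, control_mean = m)
}

#' Contribution strength of reactions over a set of inconsistency vectors
#'
#' Number of inconsistency vectors containing the reaction divided by the
#' number of vectors (the size of the data set).
#'
#' @param vectors list of inconsistency vectors: either `gimme_result`
#'   objects or plain character vectors of contributing reaction ids.
#' @param reaction_id one or more reaction ids.
#' @return named numeric vector of strengths in `[0, 1]`.
#' @export
contribution_strength <- function(vectors, reaction_id) {
  stopifnot(length(vectors) > 0)
  sets <- lapply(vectors, function(v) {
    if (inherits(v, "gimme_result")) v$inconsistency_vector$reaction_id else v
  })
  vapply(reaction_id, function(rid) {
    mean(vapply(sets, function(s) rid %in% s, logical(1)))
  }, numeric(1))
}

#' Per-group contribution table
#'
#' Tabulates contribution strength and usage frequency per reaction and
#' cohort group over the reactions that contribute at least once.
#'
#' @param results_by_group named list of lists of `gimme_result`, one
#'   entry per group (e.g. `control`, `LIG`, `HIG`).
#' @return data.frame of class `contribution_table`: `reaction_id`, one
#'   `strength_<group>` and one `usage_<group>` column per group.
#' @export
contribution_table <- function(results_by_group) {
  stopifnot(is.list(results_by_group), length(results_by_group) > 0,
            !is.null(names(results_by_group)))
  rids <- sort(unique(unlist(lapply(unlist(results_by_group, recursive = FALSE),
                                    function(r) r$inconsistency_vector$reaction_id))))
  out <- data.frame(reaction_id = rids, stringsAsFactors = FALSE)
  for (g in names(results_by_group)) {
    res <- results_by_group[[g]]
    out[[paste0("strength_", g)]] <- if (length(res)) {
      unname(contribution_strength(res, rids))
    } else NA_real_
    out[[paste0("usage_", g)]] <- if (length(res)) {
      unname(usage_frequency(res, rids))
    } else NA_real_
  }
  structure(out, class = c("contribution_table", "data.frame"))
}

#' Classify contribution specificity
#'
#' A reaction contributes *unspecifically* when its strength is high in
#' every group (min over groups `>= s_unspecific`) — the signature of
#' reconstruction gaps rather than biology. It is *specific* when the
#' largest pairwise difference between group strengths is at least
#' `delta_specific`. Reactions matching neither stay unlabelled.
#'
#' @param table a `contribution_table`.
#' @param s_unspecific minimum per-group strength for the unspecific call
#'   (default 0.9).
#' @param delta_specific minimum max pairwise group difference for the
#'   specific call (default 0.5).
#' @return the table with a `specificity` column
#'   (`"unspecific"`/`"specific"`/`NA`).
#' @export
classify_specificity <- function(table, s_unspecific = 0.9,
                                 delta_specific = 0.5) {
  scols <- grep("^strength_", names(table), value = TRUE)
  stopifnot(length(scols) >= 2)
  sm <- as.matrix(table[, scols, drop = FALSE])
  mins <- apply(sm, 1, min, na.rm = TRUE)
  maxs <- apply(sm, 1, max, na.rm = TRUE)
  spec <- rep(NA_character_, nrow(table))
  spec[maxs - mins >= delta_specific] <- "specific"
  spec[mins >= s_unspecific] <- "unspecific"
  table$specificity <- spec
  table
}

#' Directed reaction adjacency graph
#'
#' Nodes are reactions; an edge runs R1 -> R2 when R1 can produce a
#' non-excluded metabolite that R2 can consume (reversible reactions act
#' as producer and consumer on both sides). Used for the distance-based
#' and neighbourhood-based topological markers.
#'
#' @param model a `metabolic_model`.
#' @param excluded currency metabolite ids to ignore.
#' @return a directed `igraph` with reaction ids as node names.
#' @export
reaction_graph <- function(model, excluded = character()) {
  S <- model$S[!rownames(model$S) %in% excluded, , drop = FALSE]
  rids <- model$reactions$id
  rev <- model$reactions$reversible
  edges <- character(0)
  for (mi in seq_len(nrow(S))) {
    row <- S[mi, ]
    nz <- which(row != 0)
    if (length(nz) < 2) next
    producers <- nz[row[nz] > 0 | rev[nz]]
    consumers <- nz[row[nz] < 0 | rev[nz]]
    for (p in producers) {
      to <- setdiff(consumers, p)
      if (length(to)) edges <- c(edges, as.vector(rbind(rids[p], rids[to])))
    }
  }
  g <- igraph::make_empty_graph(n = 0, directed = TRUE) + igraph::vertices(rids)
  if (length(edges)) g <- igraph::add_edges(g, edges)
  igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
}

#' Default thresholds for the topological marker predicates
#'
#' The markers operationalise verbal criteria, so every cutoff is exposed:
#' `q_jbt` minimum absent fraction and `m_jbt` expression margin (log
#' units) for JBT; `q_cd` minimum fraction of samples with the
#' absent-but-flanked configuration for CD; `d_layer` maximum directed
#' distance (reaction steps) for CIL/COL; `r_ip` neighbourhood radius and
#' `q_ip` minimum GPR-less fraction for IP.
#'
#' @return named list of thresholds.
#' @export
marker_defaults <- function() {
  list(q_jbt = 0.95, m_jbt = 0.5, q_cd = 0.5, d_layer = 2, r_ip = 1,
       q_ip = 0.5)
}

#' Topological markers for contributing reactions
#'
#' Evaluates the six marker predicates for each requested reaction.
#' Markers are independent; a reaction can carry several (or none).
#'
#' @param model a `metabolic_model` with medium applied (uptake-enabled
#'   exchanges are read off the bounds).
#' @param reaction_ids reactions to classify.
#' @param patterns list of `presence_pattern` (the cohort).
#' @param reaction_expr reactions x samples matrix of reaction-level
#'   expression ([reaction_expression()] per sample); needed for JBT.
#' @param objective objective reaction id.
#' @param l level used for the bottleneck knockout test.
#' @param excluded currency metabolites for the reaction graph.
#' @param thresholds list from [marker_defaults()] (overridable).
#' @return named list mapping reaction id to a character vector drawn from
#'   `c("BN", "CD", "IP", "CIL", "COL", "JBT")`.
#' @export
topological_markers <- function(model, reaction_ids, patterns,
                                reaction_expr = NULL,
                                objective = model$objective, l = 0.8,
                                excluded = character(),
                                thresholds = marker_defaults()) {
  th <- utils::modifyList(marker_defaults(), thresholds)
  rids <- model$reactions$id
  unknown <- setdiff(reaction_ids, rids)
  if (length(unknown)) stop("unknown reaction(s): ", paste(unknown, collapse = ", "))
  g <- reaction_graph(model, excluded)
  t_used <- attr(patterns[[1]], "t")

  # absent/present calls per reaction x sample
  state_mat <- vapply(patterns, function(p) {
    stats::setNames(p$state == "absent", p$reaction_id)[rids]
  }, logical(length(rids)))
  rownames(state_mat) <- rids

  uptake_ex <- rids[model$reactions$is_exchange & model$reactions$lb < 0]
  d_from_in <- if (length(uptake_ex)) {
    suppressWarnings(igraph::distances(g, v = uptake_ex, mode = "out"))
  } else NULL
  d_to_obj <- if (!is.na(objective)) {
    suppressWarnings(igraph::distances(g, to = objective, mode = "out"))
  } else NULL

  fba_ref <- tryCatch(fba_max(model, objective), error = function(e) NULL)
  art <- stats::setNames(model$reactions$artificial, rids)

  out <- lapply(reaction_ids, function(rid) {
    mk <- character(0)
    absent_frac <- mean(state_mat[rid, ])
    # JBT: absent in nearly all samples with median expression a whisker
    # below the threshold
    if (!is.null(reaction_expr) && rid %in% rownames(reaction_expr)) {
      med_x <- stats::median(reaction_expr[rid, ], na.rm = TRUE)
      if (absent_frac >= th$q_jbt && is.finite(med_x) &&
          med_x < t_used && med_x >= t_used - th$m_jbt) {
        mk <- c(mk, "JBT")
      }
    }
    # CD: absent while flanked by present neighbours, in enough samples
    ups <- setdiff(igraph::neighbors(g, rid, mode = "in")$name, rid)
    dns <- setdiff(igraph::neighbors(g, rid, mode = "out")$name, rid)
    if (length(ups) && length(dns)) {
      per_sample <- vapply(seq_len(ncol(state_mat)), function(s) {
        state_mat[rid, s] &&
          any(!state_mat[ups, s]) && any(!state_mat[dns, s])
      }, logical(1))
      if (mean(per_sample) >= th$q_cd) mk <- c(mk, "CD")
    }
    # CIL / COL: directed distance to the boundary layers
    if (!is.null(d_from_in) && min(d_from_in[, rid]) <= th$d_layer) {
      mk <- c(mk, "CIL")
    }
    if (!is.null(d_to_obj) && d_to_obj[rid, 1] <= th$d_layer) {
      mk <- c(mk, "COL")
    }
    # IP: GPR-less neighbourhood (artificial and exchange reactions don't
    # count — boundary constructs, not annotation gaps)
    nb <- igraph::ego(g, order = th$r_ip, nodes = rid, mode = "all")[[1]]$name
    nb <- setdiff(nb, c(rid, rids[art[rids] | model$reactions$is_exchange]))
    if (length(nb)) {
      no_gpr <- vapply(model$gprs[nb], is.null, logical(1))
      if (mean(no_gpr) >= th$q_ip) mk <- c(mk, "IP")
    }
    # BN: knocking the reaction out breaks the objective level
    if (!is.null(fba_ref) && fba_ref$v_max > 1e-9) {
      ko <- set_bounds(model, rid, lb = 0, ub = 0)
      v_ko <- tryCatch(fba_max(ko, objective)$v_max, error = function(e) 0)
      if (v_ko < l * fba_ref$v_max - 1e-9) mk <- c(mk, "BN")
    }
    mk
  })
  names(out) <- reaction_ids
  out
}
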