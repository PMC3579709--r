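# Internal flux bound used to encode "unconstrained" (the usual COBRA
# convention); keeps every LP bounded.
INF_BOUND <- 1000

#' Construct a metabolic model
#'
#' The container used throughout the package: a stoichiometric matrix `S`
#' (metabolites x reactions, sparse), per-reaction flux bounds in
#' mmol/gDW/h, parsed GPR rules, and flags for exchange and artificial
#' reactions. Infinite bounds are clamped to +/-`1000`.
#'
#' @param metabolites data.frame with columns `id`, `compartment`.
#' @param reactions list of reaction descriptions, each a list with `id`,
#'   `stoich` (named numeric, metabolite id -> signed coefficient), `lb`,
#'   `ub`, optional `gpr` (rule string, `""`/`NULL` for none), optional
#'   `artificial` flag.
#' @param objective reaction id of the objective, or `NA`.
#' @param exchange_prefix reaction-id prefix also treated as marking an
#'   exchange reaction (BIGG dialect `"EX_"`); exchanges are additionally
#'   detected as reactions touching exactly one metabolite.
#' @return object of class `metabolic_model` with components `metabolites`,
#'   `reactions` (data.frame: id, lb, ub, reversible, is_exchange,
#'   artificial), `S` (sparse `dgCMatrix`), `gprs` (named list of `gpr`
#'   trees or `NULL`) and `objective`.
#' @export
metabolic_model <- function(metabolites, reactions, objective = NA_character_,
                            exchange_prefix = "EX_") {
  stopifnot(is.data.frame(metabolites), all(c("id", "compartment") %in% names(metabolites)))
  met_ids <- as.character(metabolites$id)
  if (anyDuplicated(met_ids)) stop("duplicate metabolite ids")
  rxn_ids <- vapply(reactions, function(r) as.character(r$id), character(1))
  if (anyDuplicated(rxn_ids)) stop("duplicate reaction ids: ",
                                   paste(rxn_ids[duplicated(rxn_ids)], collapse = ", "))
  n <- length(reactions)
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  lb <- ub <- numeric(n)
  art <- logical(n)
  gprs <- vector("list", n)
  names(gprs) <- rxn_ids
  for (j in seq_len(n)) {
    r <- reactions[[j]]
    st <- r$stoich
    if (is.null(st) || length(st) == 0L) {
      stop("reaction ", rxn_ids[j], " has empty stoichiometry")
    }
    idx <- match(names(st), met_ids)
    if (anyNA(idx)) {
      stop("reaction ", rxn_ids[j], " references unknown metabolite(s): ",
           paste(names(st)[is.na(idx)], collapse = ", "))
    }
    ii <- c(ii, idx); jj <- c(jj, rep.int(j, length(st))); xx <- c(xx, unname(st))
    lb[j] <- max(as.numeric(r$lb %||% 0), -INF_BOUND)
    ub[j] <- min(as.numeric(r$ub %||% INF_BOUND), INF_BOUND)
    if (lb[j] > ub[j]) stop("reaction ", rxn_ids[j], " has lb > ub")
    art[j] <- isTRUE(r$artificial)
    g <- r$gpr
    # gprs[j] <- list(...) keeps NULL entries (gprs[[j]] <- NULL would drop them)
    gprs[j] <- list(if (is.null(g) || inherits(g, "gpr")) g else parse_gpr(g))
  }
  S <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(length(met_ids), n),
                            dimnames = list(met_ids, rxn_ids))
  n_mets <- Matrix::colSums(S != 0)
  # artificial drains also touch one metabolite but are not boundary
  # reactions; media must never rebind them
  is_exchange <- (n_mets == 1L | startsWith(rxn_ids, exchange_prefix)) & !art
  if (any(is_exchange & n_mets != 1L)) {
    stop("exchange reaction(s) touching more than one metabolite: ",
         paste(rxn_ids[is_exchange & n_mets != 1L], collapse = ", "))
  }
  if (!is.na(objective) && !objective %in% rxn_ids) {
    stop("objective reaction ", objective, " not in model")
  }
  structure(list(
    metabolites = data.frame(id = met_ids,
                             compartment = as.character(metabolites$compartment),
                             stringsAsFactors = FALSE),
    reactions = data.frame(id = rxn_ids, lb = lb, ub = ub,
                           reversible = lb < 0, is_exchange = unname(is_exchange),
                           artificial = art, stringsAsFactors = FALSE),
    S = S,
    gprs = gprs,
    objective = objective
  ), class = "metabolic_model")
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat("<metabolic_model> ", nrow(x$metabolites), " metabolites (",
      length(unique(x$metabolites$compartment)), " compartments), ",
      nrow(x$reactions), " reactions (", sum(x$reactions$is_exchange),
      " exchange, ", sum(!vapply(x$gprs, is.null, logical(1))),
      " with GPR)\n", sep = "")
  if (!is.na(x$objective)) cat("  objective: ", x$objective, "\n", sep = "")
  invisible(x)
}

#' Exchange reaction ids of a model
#' @param model a `metabolic_model`.
#' @return character vector.
#' @export
exchange_reactions <- function(model) {
  model$reactions$id[model$reactions$is_exchange]
}

.rxn_index <- function(model, reaction_id) {
  j <- match(reaction_id, model$reactions$id)
  if (is.na(j)) stop("unknown reaction: ", reaction_id)
  j
}

#' Add an artificial drain for a metabolite
#'
#' Appends an irreversible reaction consuming one unit of the metabolite
#' (bounds `[0, 1000]`, no GPR, flagged artificial, id `ART_DRAIN_<met>`).
#' The classic use is unblocking a dead-end metabolite that otherwise
#' prevents steady-state flux through a downstream objective. Artificial
#' reactions have no GPR and are therefore treated as expressed; they are
#' excluded from inconsistency decompositions.
#'
#' @param model a `metabolic_model`.
#' @param metabolite_id metabolite to drain.
#' @param id reaction id for the drain (default `ART_DRAIN_<metabolite>`).
#' @return a new `metabolic_model`; the input is unmodified.
#' @export
add_drain <- function(model, metabolite_id, id = paste0("ART_DRAIN_", metabolite_id)) {
  if (!metabolite_id %in% model$metabolites$id) {
    stop("unknown metabolite: ", metabolite_id)
  }
  if (id %in% model$reactions$id) {
    stop("drain ", id, " already present in model")
  }
  rl <- .model_to_reaction_list(model)
  st <- stats::setNames(-1, metabolite_id)
  rl[[length(rl) + 1L]] <- list(id = id, stoich = st, lb = 0, ub = INF_BOUND,
                                gpr = NULL, artificial = TRUE)
  m2 <- metabolic_model(model$metabolites, rl, objective = model$objective)
  attr(m2, "truth") <- attr(model, "truth")
  m2
}

#' Add an artificial objective drain
#'
#' As [add_drain()], but the new reaction (id `ART_OBJ_<met>`) becomes the
#' model objective — the construction used to pose "maximal production of
#' metabolite X" (e.g. cytosolic ATP or a terminal biosynthetic product) as
#' an FBA objective.
#'
#' @inheritParams add_drain
#' @return a new `metabolic_model` with `objective` set to the drain id.
#' @export
add_objective_drain <- function(model, metabolite_id,
                                id = paste0("ART_OBJ_", metabolite_id)) {
  m2 <- add_drain(model, metabolite_id, id = id)
  m2$objective <- id
  m2
}

.model_to_reaction_list <- function(model) {
  S <- model$S
  lapply(seq_len(nrow(model$reactions)), function(j) {
    col <- S[, j]
    nz <- which(col != 0)
    list(id = model$reactions$id[j],
         stoich = stats::setNames(col[nz], rownames(S)[nz]),
         lb = model$reactions$lb[j], ub = model$reactions$ub[j],
         gpr = model$gprs[[j]],
         artificial = model$reactions$artificial[j])
  })
}

#' Split reversible reactions into irreversible pairs
#'
#' Every reaction with `lb < 0` is replaced by a forward copy (`<id>_fwd`,
#' bounds `[0, ub]`) and a backward copy with negated stoichiometry
#' (`<id>_bwd`, bounds `[0, -lb]`). The steady-state flux spaces are in
#' bijection via `v = v_fwd - v_bwd`, so FBA optima are preserved; the
#' split form is what lets the GIMME objective penalise `|v|` linearly.
#'
#' @param model a `metabolic_model`.
#' @return a `metabolic_model` whose reactions all have `lb >= 0`, with an
#'   attribute `"rev_mapping"`: data.frame `id`, `orig_id`, `dir` (+1/-1).
#' @export
split_reversible <- function(model) {
  rl <- .model_to_reaction_list(model)
  out <- list()
  map_id <- character(0); map_orig <- character(0); map_dir <- numeric(0)
  for (r in rl) {
    if (r$lb < 0) {
      fwd <- r; fwd$id <- paste0(r$id, "_fwd"); fwd$lb <- 0
      bwd <- r; bwd$id <- paste0(r$id, "_bwd")
      bwd$stoich <- -r$stoich; bwd$lb <- 0; bwd$ub <- -r$lb
      out <- c(out, list(fwd, bwd))
      map_id <- c(map_id, fwd$id, bwd$id)
      map_orig <- c(map_orig, r$id, r$id)
      map_dir <- c(map_dir, 1, -1)
    } else {
      out <- c(out, list(r))
      map_id <- c(map_id, r$id); map_orig <- c(map_orig, r$id); map_dir <- c(map_dir, 1)
    }
  }
  obj <- model$objective
  if (!is.na(obj) && !(obj %in% vapply(out, `[[`, character(1), "id"))) {
    obj <- paste0(obj, "_fwd")
  }
  m2 <- metabolic_model(model$metabolites, out, objective = obj)
  # splitting must not re-trigger exchange-prefix detection quirks
  attr(m2, "rev_mapping") <- data.frame(id = map_id, orig_id = map_orig,
                                        dir = map_dir, stringsAsFactors = FALSE)
  m2
}

#' Summarise a model as a plain list (JSON-ready)
#'
#' @param model a `metabolic_model`.
#' @return list with counts, compartments and the exchange reaction list.
#' @export
model_summary <- function(model) {
  list(
    n_metabolites = nrow(model$metabolites),
    n_reactions = nrow(model$reactions),
    n_exchange = sum(model$reactions$is_exchange),
    n_with_gpr = sum(!vapply(model$gprs, is.null, logical(1))),
    n_genes = length(model_genes(model)),
    compartments = sort(unique(model$metabolites$compartment)),
    objective = model$objective,
    exchange_reactions = exchange_reactions(model)
  )
}

#' All genes appearing in any GPR of a model
#' @param model a `metabolic_model`.
#' @return character vector of unique gene ids.
#' @export
model_genes <- function(model) {
  sort(unique(unlist(lapply(model$gprs, gpr_genes))))
}

#' Overwrite bounds of selected reactions
#'
#' @param model a `metabolic_model`.
#' @param reaction_ids reaction ids to modify.
#' @param lb,ub new bounds, recycled.
#' @return modified `metabolic_model`.
#' @export
set_bounds <- function(model, reaction_ids, lb = NULL, ub = NULL) {
  j <- match(reaction_ids, model$reactions$id)
  if (anyNA(j)) stop("unknown reaction(s): ",
                     paste(reaction_ids[is.na(j)], collapse = ", "))
  if (!is.null(lb)) model$reactions$lb[j] <- pmax(rep_len(lb, length(j)), -INF_BOUND)
  if (!is.null(ub)) model$reactions$ub[j] <- pmin(rep_len(ub, length(j)), INF_BOUND)
  if (any(model$reactions$lb[j] > model$reactions$ub[j])) stop("lb > ub after update")
  model$reactions$reversible <- model$reactions$lb < 0
  model
}
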