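# Flux balance analysis and the expression-constrained (GIMME-style) LP.
#
# FBA: maximise the objective reaction's flux subject to S v = 0 and the
# flux bounds. The expression-constrained step then minimises the
# (deficit-weighted) total flux through reactions called absent by the
# presence pattern, subject to the objective flux reaching a level l of
# the FBA maximum. The optimum is the inconsistency I; the absent
# reactions that still carry flux ("reinserted" reactions) form the
# inconsistency vector.

#' Flux balance analysis maximum
#'
#' @param model a `metabolic_model` (bounds already reflecting the medium).
#' @param objective objective reaction id; defaults to the model objective.
#' @return list with `v_max` (LP maximum), `flux` (named vector over the
#'   model's reaction ids, a witnessing distribution).
#' @export
fba_max <- function(model, objective = model$objective) {
  if (is.na(objective)) stop("no objective reaction set")
  sp <- split_reversible(model)
  map <- attr(sp, "rev_mapping")
  n <- nrow(sp$reactions)
  obj <- numeric(n)
  oi <- which(map$orig_id == objective)
  obj[oi] <- map$dir[oi]
  res <- solve_lp(obj, sp$S, rep(0, nrow(sp$S)),
                  lb = sp$reactions$lb, ub = sp$reactions$ub, maximize = TRUE)
  if (res$status != "optimal") {
    stop("FBA infeasible (solver status: ", res$status, ")")
  }
  flux <- .merge_split_flux(res$x, map)
  list(v_max = res$objval, flux = flux)
}

.merge_split_flux <- function(x, map) {
  v <- tapply(x * map$dir, map$orig_id, sum)
  out <- as.numeric(v)
  names(out) <- names(v)
  out[unique(map$orig_id)]
}

#' Expression-constrained flux minimisation (GIMME)
#'
#' Solves `min sum_i w_i |v_i|` over reactions `i` called absent by the
#' pattern, subject to `S v = 0`, the flux bounds, and
#' `v_obj >= l * v_max`. Weights are the reaction-level deficits
#' `w_i = max(0, t - x_i)` (`weight_mode = "deficit"`, the default) or 1
#' for every absent reaction (`"uniform"`, the plain sum-of-fluxes
#' reading); both readings of the inconsistency are reported in the
#' result. Artificial (`ART_`-prefixed) reactions are never penalised.
#'
#' @param model a `metabolic_model`.
#' @param pattern a `presence_pattern` from [threshold_pattern()].
#' @param objective objective reaction id.
#' @param l level in (0, 1]: required fraction of the FBA maximum.
#' @param weight_mode `"deficit"` or `"uniform"`.
#' @param eps_flux flux magnitude below which a reaction counts as unused
#'   (solver-noise floor).
#' @param fba optional precomputed [fba_max()] result (reused across
#'   samples sharing a model and medium).
#' @return object of class `gimme_result`: list with `inconsistency` (I),
#'   `inconsistency_uniform` (unweighted sum over the same reactions),
#'   `normalized` (I / v_obj), `v_obj`, `v_max`, `level`, `flux` (named
#'   vector), `inconsistency_vector` (data.frame `reaction_id`, `flux`,
#'   `weight`), `weight_mode`, `eps_flux`.
#' @export
gimme <- function(model, pattern, objective = model$objective, l = 0.8,
                  weight_mode = c("deficit", "uniform"), eps_flux = 1e-6,
                  fba = NULL) {
  weight_mode <- match.arg(weight_mode)
  stopifnot(l > 0, l <= 1)
  if (is.na(objective)) stop("no objective reaction set")
  if (is.null(fba)) fba <- fba_max(model, objective)
  if (fba$v_max <= 1e-9) {
    stop_named("gimme_degenerate",
               "objective maximum is zero; inconsistency undefined")
  }
  sp <- split_reversible(model)
  map <- attr(sp, "rev_mapping")
  n <- nrow(sp$reactions)

  pat_state <- stats::setNames(pattern$state, pattern$reaction_id)
  pat_def <- stats::setNames(pattern$deficit, pattern$reaction_id)
  rids <- model$reactions$id
  absent <- rids %in% names(pat_state) & pat_state[rids] %in% "absent" &
    !model$reactions$artificial
  w_orig <- stats::setNames(rep(0, length(rids)), rids)
  w_orig[absent] <- if (weight_mode == "deficit") {
    pat_def[rids[absent]]
  } else 1
  obj_coef <- w_orig[map$orig_id]

  oi <- which(map$orig_id == objective)
  arow <- numeric(n)
  arow[oi] <- map$dir[oi]
  res <- solve_lp(unname(obj_coef), sp$S, rep(0, nrow(sp$S)),
                  lb = sp$reactions$lb, ub = sp$reactions$ub, maximize = FALSE,
                  ineq = list(A = matrix(arow, 1), dir = ">=",
                              rhs = l * fba$v_max))
  if (res$status != "optimal") {
    stop("GIMME LP not solvable (status: ", res$status, ")")
  }
  flux <- .merge_split_flux(res$x, map)
  v_obj <- unname(flux[objective])
  absent_ids <- rids[absent]
  contrib <- absent_ids[abs(flux[absent_ids]) > eps_flux]
  I <- sum(w_orig[absent_ids] * abs(flux[absent_ids]))
  structure(list(
    inconsistency = I,
    inconsistency_uniform = sum(abs(flux[absent_ids]) *
                                  (abs(flux[absent_ids]) > eps_flux)),
    normalized = if (v_obj > 0) I / v_obj else NA_real_,
    v_obj = v_obj, v_max = fba$v_max, level = l,
    flux = flux,
    inconsistency_vector = data.frame(
      reaction_id = contrib,
      flux = abs(unname(flux[contrib])),
      weight = unname(w_orig[contrib]),
      stringsAsFactors = FALSE, row.names = NULL),
    weight_mode = weight_mode, eps_flux = eps_flux,
    sample_id = attr(pattern, "sample_id"),
    t = attr(pattern, "t")
  ), class = "gimme_result")
}

#' @export
print.gimme_result <- function(x, ...) {
  cat("<gimme_result> I = ", format(x$inconsistency, digits = 6),
      " (normalized ", format(x$normalized, digits = 4), "), v_obj = ",
      format(x$v_obj, digits = 6), " (level ", x$level, " of v_max ",
      format(x$v_max, digits = 6), "), ",
      nrow(x$inconsistency_vector), " contributing reaction(s)\n", sep = "")
  invisible(x)
}

#' Normalised inconsistency
#'
#' Inconsistency divided by the objective flux — the form used when
#' comparing runs across different (e.g. random) media.
#'
#' @param result a `gimme_result`.
#' @return numeric, or `NA` if the objective flux is zero.
#' @export
normalized_inconsistency <- function(result) {
  if (is.na(result$v_obj) || result$v_obj <= 0) return(NA_real_)
  result$inconsistency / result$v_obj
}

#' Usage frequency of reactions across a set of flux solutions
#'
#' Fraction of results in which the reaction carries flux above the noise
#' floor.
#'
#' @param results list of `gimme_result`.
#' @param reaction_id one or more reaction ids.
#' @param eps_flux noise floor (defaults to the one stored in the results).
#' @return named numeric vector of fractions in `[0, 1]`.
#' @export
usage_frequency <- function(results, reaction_id,
                            eps_flux = results[[1]]$eps_flux) {
  stopifnot(length(results) > 0)
  vapply(reaction_id, function(rid) {
    used <- vapply(results, function(r) {
      if (!rid %in% names(r$flux)) return(NA)
      abs(r$flux[[rid]]) > eps_flux
    }, logical(1))
    if (all(is.na(used))) {
      warning("usage_frequency: unknown reaction ", rid)
      return(0)
    }
    mean(used, na.rm = TRUE)
  }, numeric(1))
}
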