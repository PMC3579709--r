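# Correlating metabolic coherence and inconsistency across a cohort, with
# sweeps over the expression threshold t, the objective level l, and
# random growth media.

#' Pearson correlation with one-tailed p-value
#'
#' The p-value is the lower tail of `t = r * sqrt((n-2) / (1-r^2))` under
#' Student-t with `n - 2` df — the test of a *negative* association, the
#' direction of interest when coherence is expected to anticorrelate with
#' inconsistency.
#'
#' @param x,y numeric vectors of equal length (n >= 3).
#' @return list with `r`, `p` (one-tailed, negative alternative), `n`;
#'   `r`/`p` are `NA` when either input has zero variance.
#' @export
pearson_one_tailed <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("need at least 3 complete observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(list(r = NA_real_, p = NA_real_, n = n))
  }
  r <- stats::cor(x, y)
  p <- if (1 - r^2 < .Machine$double.eps) {
    if (r < 0) 0 else 1
  } else {
    stats::pt(r * sqrt((n - 2) / (1 - r^2)), df = n - 2)
  }
  list(r = r, p = p, n = n)
}

#' Spearman rank correlation
#'
#' Rank-transform (average ranks for ties) then Pearson.
#'
#' @param x,y numeric vectors of equal length.
#' @return rho, or `NA` when either rank vector has zero variance.
#' @export
spearman_rho <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (stats::sd(rank(x)) == 0 || stats::sd(rank(y)) == 0) return(NA_real_)
  stats::cor(x, y, method = "spearman")
}

# shared worker: per-sample (I, MC) at one (t, l) setting
.cohort_scores <- function(model, network, expr, med, objective, t, l,
                           N_null, seed, weight_mode, fba = NULL) {
  m_app <- apply_medium(model, med)
  if (is.null(fba)) {
    fba <- tryCatch(fba_max(m_app, objective), error = function(e) NULL)
  }
  samples <- colnames(expr)
  out <- data.frame(sample_id = samples, I = NA_real_, I_norm = NA_real_,
                    v_obj = NA_real_, MC = NA_real_, ratio = NA_real_,
                    stringsAsFactors = FALSE)
  if (is.null(fba) || fba$v_max <= 1e-9) {
    attr(out, "excluded") <- samples
    return(out)
  }
  for (i in seq_along(samples)) {
    prof <- expr[, i]
    rx <- reaction_expression(prof, model, quiet = TRUE)
    pat <- threshold_pattern(rx, t, sample_id = samples[i])
    gr <- tryCatch(gimme(m_app, pat, objective, l = l, fba = fba,
                         weight_mode = weight_mode),
                   error = function(e) NULL)
    mc <- metabolic_coherence(network, active_genes(prof, t), N = N_null,
                              seed = seed + i)
    if (!is.null(gr)) {
      out$I[i] <- gr$inconsistency
      out$I_norm[i] <- gr$normalized
      out$v_obj[i] <- gr$v_obj
    }
    out$MC[i] <- mc$mc
    out$ratio[i] <- mc$ratio
  }
  attr(out, "excluded") <- samples[is.na(out$I) | is.na(out$MC)]
  out
}

#' Threshold sweep of the MC-inconsistency correlation
#'
#' Recomputes per-sample (MC, I) for every threshold on the grid and
#' correlates them. Samples for which the LP is degenerate or the active
#' gene set is empty are excluded at that grid point (count reported).
#'
#' @param model a `metabolic_model` (objective set).
#' @param network gene network from [project_gene_network()].
#' @param expr genes x samples expression matrix.
#' @param med a `medium`.
#' @param t_grid numeric grid of thresholds.
#' @param l objective level.
#' @param N_null,seed null-model size and base seed for MC.
#' @param weight_mode passed to [gimme()].
#' @param objective objective reaction id.
#' @return data.frame of class `sweep_result`: `t`, `r`, `p`, `rho`, `n`,
#'   `n_excluded`.
#' @export
threshold_sweep <- function(model, network, expr, med, t_grid,
                            l = 0.8, N_null = 1000, seed = 1,
                            weight_mode = "deficit",
                            objective = model$objective) {
  stopifnot(length(t_grid) > 0)
  m_app <- apply_medium(model, med)
  fba <- tryCatch(fba_max(m_app, objective), error = function(e) NULL)
  rows <- lapply(seq_along(t_grid), function(gi) {
    t <- t_grid[gi]
    sc <- .cohort_scores(model, network, expr, med, objective, t, l,
                         N_null, seed + 1000L * gi, weight_mode, fba = fba)
    ok <- is.finite(sc$I) & is.finite(sc$MC)
    if (sum(ok) >= 3 && stats::sd(sc$I[ok]) > 0 && stats::sd(sc$MC[ok]) > 0) {
      pr <- pearson_one_tailed(sc$MC[ok], sc$I[ok])
      data.frame(t = t, r = pr$r, p = pr$p,
                 rho = spearman_rho(sc$MC[ok], sc$I[ok]),
                 n = pr$n, n_excluded = sum(!ok))
    } else {
      data.frame(t = t, r = NA_real_, p = NA_real_, rho = NA_real_,
                 n = sum(ok), n_excluded = sum(!ok))
    }
  })
  structure(do.call(rbind, rows), swept = "t",
            class = c("sweep_result", "data.frame"))
}

#' Objective-level sweep of the MC-inconsistency correlation
#'
#' As [threshold_sweep()] but over the level parameter `l` at fixed
#' threshold `t`. MC does not depend on `l`, so only the inconsistency
#' side is recomputed.
#'
#' @inheritParams threshold_sweep
#' @param l_grid grid of levels in (0, 1].
#' @param t expression threshold.
#' @return data.frame of class `sweep_result`: `l`, `r`, `p`, `rho`, `n`,
#'   `n_excluded`.
#' @export
level_sweep <- function(model, network, expr, med, l_grid, t = 2,
                        N_null = 1000, seed = 1, weight_mode = "deficit",
                        objective = model$objective) {
  stopifnot(length(l_grid) > 0, all(l_grid > 0), all(l_grid <= 1))
  rows <- lapply(seq_along(l_grid), function(gi) {
    sc <- .cohort_scores(model, network, expr, med, objective, t, l_grid[gi],
                         N_null, seed + 1000L * gi, weight_mode)
    ok <- is.finite(sc$I) & is.finite(sc$MC)
    if (sum(ok) >= 3 && stats::sd(sc$I[ok]) > 0 && stats::sd(sc$MC[ok]) > 0) {
      pr <- pearson_one_tailed(sc$MC[ok], sc$I[ok])
      data.frame(l = l_grid[gi], r = pr$r, p = pr$p,
                 rho = spearman_rho(sc$MC[ok], sc$I[ok]),
                 n = pr$n, n_excluded = sum(!ok))
    } else {
      data.frame(l = l_grid[gi], r = NA_real_, p = NA_real_, rho = NA_real_,
                 n = sum(ok), n_excluded = sum(!ok))
    }
  })
  structure(do.call(rbind, rows), swept = "l",
            class = c("sweep_result", "data.frame"))
}

#' Random-media sweep of the MC-inconsistency correlation
#'
#' Draws `n_media` random media; for each, recomputes the per-sample
#' *normalised* inconsistency (MC is medium-independent and computed
#' once) and the correlation pair. Media in which the objective is
#' unreachable are skipped and redrawn, up to a retry cap.
#'
#' @inheritParams threshold_sweep
#' @param n_media number of media draws (default 100).
#' @param t expression threshold.
#' @param always_available exchange ids uptake-enabled in every draw.
#' @param max_retry redraw cap for infeasible media.
#' @return list with `draws` (data.frame `medium`, `fraction`,
#'   `always_open` — whether every always-available exchange is
#'   uptake-enabled in that draw — `r`, `p`, `rho`, `n`), `mc` (per-sample
#'   MC used throughout) and `n_skipped`.
#' @export
media_sweep <- function(model, network, expr, t = 2, l = 0.8,
                        n_media = 100, seed = 1, N_null = 1000,
                        always_available = character(),
                        weight_mode = "deficit",
                        objective = model$objective, max_retry = 5 * n_media) {
  samples <- colnames(expr)
  rx_list <- lapply(seq_along(samples), function(i)
    reaction_expression(expr[, i], model, quiet = TRUE))
  pats <- lapply(seq_along(samples), function(i)
    threshold_pattern(rx_list[[i]], t, sample_id = samples[i]))
  mc <- vapply(seq_along(samples), function(i)
    metabolic_coherence(network, active_genes(expr[, i], t), N = N_null,
                        seed = seed + i)$mc, numeric(1))
  draws <- list()
  n_skipped <- 0L
  draw_i <- 0L
  attempt <- 0L
  while (length(draws) < n_media && attempt < max_retry) {
    attempt <- attempt + 1L
    md <- random_medium(model, seed = (seed %% 190000L) * 10000L + attempt,
                        always_available = always_available)
    m_app <- apply_medium(model, md)
    fba <- tryCatch(fba_max(m_app, objective), error = function(e) NULL)
    if (is.null(fba) || fba$v_max <= 1e-9) {
      n_skipped <- n_skipped + 1L
      next
    }
    alw_open <- !length(always_available) ||
      all(md$lb[match(always_available, md$exchange_id)] < 0)
    In <- vapply(seq_along(samples), function(i) {
      gr <- tryCatch(gimme(m_app, pats[[i]], objective, l = l, fba = fba,
                           weight_mode = weight_mode),
                     error = function(e) NULL)
      if (is.null(gr)) NA_real_ else gr$normalized
    }, numeric(1))
    ok <- is.finite(In) & is.finite(mc)
    draw_i <- draw_i + 1L
    if (sum(ok) >= 3 && stats::sd(In[ok]) > 0 && stats::sd(mc[ok]) > 0) {
      pr <- pearson_one_tailed(mc[ok], In[ok])
      draws[[draw_i]] <- data.frame(medium = draw_i,
                                    fraction = attr(md, "fraction"),
                                    always_open = alw_open,
                                    r = pr$r, p = pr$p,
                                    rho = spearman_rho(mc[ok], In[ok]),
                                    n = pr$n)
    } else {
      draws[[draw_i]] <- data.frame(medium = draw_i,
                                    fraction = attr(md, "fraction"),
                                    always_open = alw_open,
                                    r = NA_real_, p = NA_real_,
                                    rho = NA_real_, n = sum(ok))
    }
  }
  if (length(draws) < n_media) {
    warning("media_sweep: only ", length(draws), " of ", n_media,
            " media were feasible within the retry cap")
  }
  list(draws = do.call(rbind, draws), mc = stats::setNames(mc, samples),
       n_skipped = n_skipped)
}
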