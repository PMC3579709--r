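# Metabolic coherence: project the model onto an undirected gene network
# (after currency-metabolite removal), induce the subgraph of active genes,
# and compare its connected-node ratio against a random equal-size
# node-subset null, yielding the MC z-score.

#' Currency metabolites by per-compartment degree cut
#'
#' Marks, per compartment, the `ceiling(fraction * n)` metabolites of
#' highest reaction-degree (number of reactions touching them) for
#' exclusion before network projection — removing ubiquitous cofactor
#' hubs (ATP, water, protons, ...) that would otherwise connect everything
#' to everything. Degree ties at the cutoff are broken by metabolite id
#' sort order, so the exclusion set is deterministic.
#'
#' @param model a `metabolic_model`.
#' @param fraction fraction in `[0, 1)` of each compartment's metabolites
#'   to exclude (default 0.04).
#' @return character vector of excluded metabolite ids.
#' @export
remove_currency_metabolites <- function(model, fraction = 0.04) {
  stopifnot(fraction >= 0, fraction < 1)
  if (fraction == 0) return(character())
  deg <- Matrix::rowSums(model$S != 0)
  out <- character()
  for (cp in unique(model$metabolites$compartment)) {
    ids <- model$metabolites$id[model$metabolites$compartment == cp]
    k <- ceiling(fraction * length(ids))
    ord <- ids[order(-deg[ids], ids)]
    out <- c(out, ord[seq_len(k)])
  }
  sort(out)
}

#' Project a metabolic model onto a gene network
#'
#' Two reactions are adjacent when they share a non-excluded metabolite;
#' two genes are adjacent when they appear in the GPRs of the same
#' reaction or of adjacent reactions. Nodes are all genes appearing in any
#' GPR. The result is an undirected simple graph (no self-loops, no
#' parallel edges).
#'
#' @param model a `metabolic_model`.
#' @param excluded metabolite ids to ignore when linking reactions
#'   (typically from [remove_currency_metabolites()]).
#' @return an `igraph` undirected graph.
#' @export
project_gene_network <- function(model, excluded = character()) {
  has_gpr <- !vapply(model$gprs, is.null, logical(1))
  if (!any(has_gpr)) stop("model has no GPR associations; cannot project")
  keep <- !rownames(model$S) %in% excluded
  B <- model$S[keep, , drop = FALSE] != 0
  # reaction adjacency via shared metabolites; the diagonal is forced so
  # same-reaction gene pairs survive even when all of a reaction's
  # metabolites are excluded as currency
  adj <- Matrix::crossprod(B)
  Matrix::diag(adj) <- 1
  genes_by_rxn <- lapply(model$gprs, gpr_genes)
  all_genes <- sort(unique(unlist(genes_by_rxn)))
  edges <- character(0)
  adjT <- methods::as(methods::as(adj, "generalMatrix"), "TsparseMatrix")
  pairs <- cbind(adjT@i + 1L, adjT@j + 1L)
  pairs <- pairs[pairs[, 1] <= pairs[, 2], , drop = FALSE]
  el <- vector("list", nrow(pairs))
  for (k in seq_len(nrow(pairs))) {
    g1 <- genes_by_rxn[[pairs[k, 1]]]
    g2 <- genes_by_rxn[[pairs[k, 2]]]
    if (!length(g1) || !length(g2)) next
    el[[k]] <- as.vector(rbind(rep(g1, each = length(g2)),
                               rep(g2, times = length(g1))))
  }
  ev <- unlist(el)
  g <- igraph::make_empty_graph(n = 0, directed = FALSE) +
    igraph::vertices(all_genes)
  if (length(ev)) g <- igraph::add_edges(g, ev)
  igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
}

#' Connected-node ratio of an induced subgraph
#'
#' Fraction of the given nodes that have at least one neighbour among the
#' given nodes (the "coherence" C of an effective subnetwork).
#'
#' @param network an `igraph` graph.
#' @param node_subset character vector of node names (subset of the
#'   network's nodes).
#' @return ratio in `[0, 1]`, or `NA` for an empty subset.
#' @export
connected_ratio <- function(network, node_subset) {
  if (!length(node_subset)) return(NA_real_)
  stopifnot(all(node_subset %in% igraph::V(network)$name))
  sub <- igraph::induced_subgraph(network, node_subset)
  mean(igraph::degree(sub) > 0)
}

#' Metabolic coherence z-score
#'
#' Compares the connected-node ratio of the active-gene-induced subgraph
#' against `N` uniform random node subsets of the same size drawn from the
#' whole network: `MC = (ratio - mu) / sigma`, with `mu` and `sigma` the
#' mean and population (1/N) standard deviation of the null ratios.
#'
#' @param network an `igraph` gene network from [project_gene_network()].
#' @param active character vector of active gene ids (thresholded
#'   expression); genes outside the network are dropped.
#' @param N number of null subsets (default 1000).
#' @param seed RNG seed for a reproducible null (`NULL` = current RNG).
#' @return object of class `mc_result`: list with `ratio`, `mu`, `sigma`,
#'   `mc`, `N`, `seed`, `n_sub` (subset size) and `degenerate` (`TRUE` when
#'   `sigma = 0`, in which case `mc` is 0).
#' @export
metabolic_coherence <- function(network, active, N = 1000, seed = NULL) {
  nodes <- igraph::V(network)$name
  g_sub <- intersect(active, nodes)
  if (!length(g_sub)) {
    warning("metabolic_coherence: no active genes in the network")
    return(structure(list(ratio = NA_real_, mu = NA_real_, sigma = NA_real_,
                          mc = NA_real_, N = N, seed = seed, n_sub = 0L,
                          degenerate = TRUE), class = "mc_result"))
  }
  k <- length(g_sub)
  nv <- length(nodes)
  A <- igraph::as_adjacency_matrix(network, sparse = TRUE)
  A <- A[nodes, nodes]
  ratio <- .connected_ratio_adj(A, match(g_sub, nodes))
  null_ratios <- with_seed(seed, {
    vapply(seq_len(N), function(i) {
      .connected_ratio_adj(A, sample.int(nv, k))
    }, numeric(1))
  })
  mu <- mean(null_ratios)
  sigma <- sqrt(mean((null_ratios - mu)^2))  # population (1/N) form
  degenerate <- sigma == 0
  mc <- if (degenerate) 0 else (ratio - mu) / sigma
  structure(list(ratio = ratio, mu = mu, sigma = sigma, mc = mc, N = N,
                 seed = seed, n_sub = k, degenerate = degenerate),
            class = "mc_result")
}

.connected_ratio_adj <- function(A, idx) {
  sub <- A[idx, idx, drop = FALSE]
  mean(Matrix::rowSums(sub) > 0)
}

#' @export
print.mc_result <- function(x, ...) {
  cat("<mc_result> MC = ", format(x$mc, digits = 4), " (ratio ",
      format(x$ratio, digits = 4), ", null mu ", format(x$mu, digits = 4),
      ", sigma ", format(x$sigma, digits = 4), ", N = ", x$N,
      ", |g_sub| = ", x$n_sub, ")",
      if (x$degenerate) " [degenerate null]" else "", "\n", sep = "")
  invisible(x)
}
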