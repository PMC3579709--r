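# Shared fixtures and independent oracles.

# linear chain: EX_A (uptake -10) -> transport -> conversion -> objective
# drain; FBA maximum equals the uptake bound by flow conservation
chain_model <- function(uptake = 10) {
  mets <- data.frame(id = c("A_e", "A_c", "B_c"),
                     compartment = c("e", "c", "c"))
  rl <- list(
    list(id = "EX_A", stoich = c(A_e = -1), lb = -uptake, ub = 1000),
    list(id = "T1", stoich = c(A_e = -1, A_c = 1), lb = 0, ub = 1000,
         gpr = "g1"),
    list(id = "R2", stoich = c(A_c = -1, B_c = 1), lb = 0, ub = 1000,
         gpr = "g2"))
  m <- metabolic_model(mets, rl)
  add_objective_drain(m, "B_c")
}

# as chain_model but with two parallel conversions A_c -> B_c
parallel_model <- function(uptake = 10) {
  mets <- data.frame(id = c("A_e", "A_c", "B_c"),
                     compartment = c("e", "c", "c"))
  rl <- list(
    list(id = "EX_A", stoich = c(A_e = -1), lb = -uptake, ub = 1000),
    list(id = "T1", stoich = c(A_e = -1, A_c = 1), lb = 0, ub = 1000,
         gpr = "g1"),
    list(id = "R2a", stoich = c(A_c = -1, B_c = 1), lb = 0, ub = 1000,
         gpr = "g2a"),
    list(id = "R2b", stoich = c(A_c = -1, B_c = 1), lb = 0, ub = 1000,
         gpr = "g2b"))
  m <- metabolic_model(mets, rl)
  add_objective_drain(m, "B_c")
}

# conversion co-produces a dead-end metabolite: objective is blocked until
# a drain for D_c is added
deadend_model <- function(uptake = 10) {
  mets <- data.frame(id = c("A_e", "A_c", "B_c", "D_c"),
                     compartment = c("e", "c", "c", "c"))
  rl <- list(
    list(id = "EX_A", stoich = c(A_e = -1), lb = -uptake, ub = 1000),
    list(id = "T1", stoich = c(A_e = -1, A_c = 1), lb = 0, ub = 1000,
         gpr = "g1"),
    list(id = "R2", stoich = c(A_c = -1, B_c = 1, D_c = 1), lb = 0,
         ub = 1000, gpr = "g2"))
  m <- metabolic_model(mets, rl)
  add_objective_drain(m, "B_c")
}

# uniform pattern helper: everything present except `absent`, whose
# deficits are given
make_pattern <- function(model, absent = character(), deficit = 1, t = 2) {
  rx <- stats::setNames(rep(t + 1, nrow(model$reactions)),
                        model$reactions$id)
  rx[absent] <- t - rep_len(deficit, length(absent))
  threshold_pattern(rx, t)
}

# --- independent LP oracle: vertex enumeration -------------------------
# min cost'x s.t. Aeq x = beq, lb <= x <= ub. Enumerates candidate basic
# solutions by fixing (n - m) variables at a bound and solving the square
# system for the rest; exponential, for tiny instances only.
enum_lp <- function(cost, Aeq, beq, lb, ub, maximize = FALSE) {
  Aeq <- as.matrix(Aeq)
  n <- ncol(Aeq)
  m <- nrow(Aeq)
  stopifnot(n - m >= 0, n <= 14)
  lb <- rep_len(lb, n); ub <- rep_len(ub, n)
  sgn <- if (maximize) -1 else 1
  best <- Inf; best_x <- NULL
  fix_sets <- if (n == m) list(integer(0)) else
    utils::combn(n, n - m, simplify = FALSE)
  for (fx in fix_sets) {
    keep <- setdiff(seq_len(n), fx)
    Ak <- Aeq[, keep, drop = FALSE]
    nf <- length(fx)
    for (mask in seq_len(max(1, 2^nf)) - 1) {
      at_ub <- as.logical(bitwAnd(mask, 2^(seq_len(nf) - 1)))
      vals <- ifelse(at_ub, ub[fx], lb[fx])
      if (any(!is.finite(vals))) next
      rhs <- beq - if (nf) Aeq[, fx, drop = FALSE] %*% vals else 0
      xk <- tryCatch(solve(Ak, rhs), error = function(e) NULL)
      if (is.null(xk)) next
      if (max(abs(Ak %*% xk - rhs)) > 1e-8) next
      x <- numeric(n); x[fx] <- vals; x[keep] <- xk
      if (any(x < lb - 1e-8 | x > ub + 1e-8)) next
      val <- sgn * sum(cost * x)
      if (val < best - 1e-12) { best <- val; best_x <- x }
    }
  }
  if (is.null(best_x)) return(list(status = "infeasible"))
  list(status = "optimal", objval = sgn * best, x = best_x)
}

# --- independent MC null oracle: exhaustive subset enumeration ---------
# connected-node ratio computed from the raw edge list, not via the
# package's connected_ratio()
edge_ratio <- function(edges, subset) {
  if (!length(subset)) return(NA_real_)
  inset <- edges[, 1] %in% subset & edges[, 2] %in% subset
  touched <- unique(c(edges[inset, 1], edges[inset, 2]))
  length(intersect(touched, subset)) / length(subset)
}

exact_null <- function(network, k) {
  nodes <- igraph::V(network)$name
  edges <- igraph::as_edgelist(network)
  ratios <- vapply(utils::combn(nodes, k, simplify = FALSE),
                   function(s) edge_ratio(edges, s), numeric(1))
  mu <- mean(ratios)
  list(mu = mu, sigma = sqrt(mean((ratios - mu)^2)), ratios = ratios)
}

# small named graph from an edge vector, e.g. path4_graph()
graph_from_pairs <- function(pairs, isolated = character()) {
  g <- igraph::make_empty_graph(directed = FALSE) +
    igraph::vertices(unique(c(pairs, isolated)))
  igraph::add_edges(g, pairs)
}
path4_graph <- function() graph_from_pairs(c("a","b", "b","c", "c","d"))

# --- definition-level correlation oracles ------------------------------
brute_pearson <- function(x, y) {
  mx <- sum(x) / length(x); my <- sum(y) / length(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}
brute_rank <- function(x) {
  # average ranks for ties, from the definition
  vapply(seq_along(x), function(i) {
    sum(x < x[i]) + (sum(x == x[i]) + 1) / 2
  }, numeric(1))
}
brute_spearman <- function(x, y) brute_pearson(brute_rank(x), brute_rank(y))
brute_one_tailed_p <- function(r, n) {
  stats::pt(r * sqrt((n - 2) / (1 - r^2)), df = n - 2)
}
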