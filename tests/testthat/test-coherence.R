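test_that("currency removal takes the top-degree cut per compartment", {
  # 50 metabolites in one compartment, hub touches every reaction
  mets <- data.frame(id = sprintf("m%02d_c", 1:50), compartment = "c")
  rl <- lapply(1:49, function(i) list(
    id = sprintf("R%02d", i),
    stoich = stats::setNames(c(-1, 1), sprintf("m%02d_c", c(i, i + 1))),
    lb = 0, ub = 10))
  # make m01 and m02 hubs by adding them to many reactions
  for (i in 10:49) {
    rl[[i]]$stoich <- c(rl[[i]]$stoich,
                        stats::setNames(c(-1, 1), c("m01_c", "m02_c")))
  }
  m <- metabolic_model(mets, rl)
  excl <- remove_currency_metabolites(m, fraction = 0.04)
  expect_length(excl, 2)                       # ceiling(0.04 * 50)
  expect_setequal(excl, c("m01_c", "m02_c"))
  expect_length(remove_currency_metabolites(m, fraction = 0), 0)
})

test_that("degree ties at the cutoff break lexicographically", {
  mets <- data.frame(id = c("b_c", "a_c", "z_c"), compartment = "c")
  rl <- list(
    list(id = "R1", stoich = c(a_c = -1, b_c = 1), lb = 0, ub = 1),
    list(id = "R2", stoich = c(b_c = -1, a_c = 1, z_c = 1), lb = 0, ub = 1),
    list(id = "R3", stoich = c(a_c = -1, b_c = 1, z_c = -1), lb = 0, ub = 1))
  m <- metabolic_model(mets, rl)
  # degrees: a 3, b 3, z 2; one slot -> "a_c" wins the tie by id sort
  expect_identical(remove_currency_metabolites(m, 0.05), "a_c")
})

test_that("gene-network projection links genes through shared metabolites", {
  mets <- data.frame(id = c("A_c", "M_c", "B_c", "H_c"),
                     compartment = "c")
  rl <- list(
    list(id = "R1", stoich = c(A_c = -1, M_c = 1, H_c = 1), lb = 0, ub = 10,
         gpr = "g1"),
    list(id = "R2", stoich = c(M_c = -1, B_c = 1, H_c = -1), lb = 0, ub = 10,
         gpr = "g2"),
    list(id = "R3", stoich = c(H_c = -1), lb = 0, ub = 10,
         gpr = "g3 and g4"))
  m <- metabolic_model(mets, rl)
  g <- project_gene_network(m)
  expect_true(igraph::are_adjacent(g, "g1", "g2"))   # share M_c
  expect_true(igraph::are_adjacent(g, "g3", "g4"))   # same reaction (AND)
  expect_true(igraph::are_adjacent(g, "g1", "g3"))   # share hub H_c
  # excluding the hub removes hub-mediated edges only
  g2 <- project_gene_network(m, excluded = "H_c")
  expect_true(igraph::are_adjacent(g2, "g1", "g2"))
  expect_false(igraph::are_adjacent(g2, "g1", "g3"))
  expect_true(igraph::are_adjacent(g2, "g3", "g4"))
  # simple graph invariants
  expect_equal(sum(igraph::which_loop(g)), 0)
  expect_equal(sum(igraph::which_multiple(g)), 0)
  # no GPRs at all
  m0 <- metabolic_model(data.frame(id = "A_c", compartment = "c"),
                        list(list(id = "EX_A", stoich = c(A_c = -1),
                                  lb = -1, ub = 1)))
  expect_error(project_gene_network(m0), "no GPR")
})

test_that("connected ratio counts non-isolated nodes in the induced subgraph", {
  g <- path4_graph()
  expect_equal(connected_ratio(g, c("a", "b")), 1)
  expect_equal(connected_ratio(g, c("a", "c")), 0)
  expect_equal(connected_ratio(g, "a"), 0)
  expect_equal(connected_ratio(g, c("a", "b", "d")), 2 / 3)
  expect_true(is.na(connected_ratio(g, character())))
})

test_that("the 4-node path null matches exhaustive enumeration", {
  g <- path4_graph()
  ex <- exact_null(g, 2)                 # all 6 pairs: three ratio-1, three ratio-0
  expect_equal(ex$mu, 0.5)
  expect_equal(ex$sigma, 0.5)
  mc <- metabolic_coherence(g, c("a", "b"), N = 10000, seed = 1)
  expect_equal(mc$ratio, 1)
  se_mu <- ex$sigma / sqrt(mc$N)
  expect_lt(abs(mc$mu - ex$mu), 3 * se_mu)
  expect_lt(abs(mc$sigma - ex$sigma), 3 * ex$sigma / sqrt(2 * mc$N))
  # z-score against the exact null is exactly 1
  expect_equal((mc$ratio - ex$mu) / ex$sigma, 1)
})

test_that("sampled null statistics track enumeration on assorted graphs", {
  graphs <- list(
    path4 = path4_graph(),
    cycle6 = graph_from_pairs(c("a","b","b","c","c","d","d","e","e","f","f","a")),
    star = graph_from_pairs(c("h","x1","h","x2","h","x3","h","x4","h","x5")),
    split = graph_from_pairs(c("a","b","c","d","d","e"), isolated = c("u","v"))
  )
  set.seed(3)
  for (nm in names(graphs)) {
    g <- graphs[[nm]]
    nv <- igraph::vcount(g)
    for (k in unique(pmin(nv - 1, c(2, 3, nv %/% 2)))) {
      ex <- exact_null(g, k)
      sub <- sample(igraph::V(g)$name, k)
      mc <- metabolic_coherence(g, sub, N = 10000, seed = 7)
      expect_lt(abs(mc$mu - ex$mu), 3 * max(ex$sigma, 1e-12) / sqrt(mc$N) + 1e-12)
      expect_lt(abs(mc$sigma - ex$sigma), 3 * max(ex$sigma, 1e-12) / sqrt(2 * mc$N) + 1e-12)
      expect_equal(mc$ratio, edge_ratio(igraph::as_edgelist(g), sub))
    }
  }
})

test_that("metabolic coherence is deterministic and degenerate-safe", {
  g <- path4_graph()
  m1 <- metabolic_coherence(g, c("a", "b"), N = 500, seed = 99)
  m2 <- metabolic_coherence(g, c("a", "b"), N = 500, seed = 99)
  expect_identical(m1, m2)
  # whole node set: point-mass null
  m3 <- metabolic_coherence(g, c("a", "b", "c", "d"), N = 200, seed = 1)
  expect_true(m3$degenerate)
  expect_equal(m3$mc, 0)
  expect_equal(m3$mu, m3$ratio)
  # empty intersection
  expect_warning(m4 <- metabolic_coherence(g, "zz", N = 10, seed = 1),
                 "no active genes")
  expect_true(is.na(m4$mc))
})

test_that("MC is invariant under node relabelling", {
  g <- path4_graph()
  perm <- c(a = "w", b = "x", c = "y", d = "z")
  g2 <- graph_from_pairs(c("w","x", "x","y", "y","z"))
  m1 <- metabolic_coherence(g, c("a", "b"), N = 3000, seed = 5)
  m2 <- metabolic_coherence(g2, c("w", "x"), N = 3000, seed = 5)
  expect_equal(m1$mc, m2$mc)
})

test_that("connecting two isolated subset nodes never lowers the ratio", {
  set.seed(21)
  for (rep in 1:10) {
    g <- igraph::sample_gnp(10, 0.2)
    igraph::V(g)$name <- paste0("n", 1:10)
    sub <- sample(igraph::V(g)$name, 5)
    r0 <- connected_ratio(g, sub)
    iso <- sub[igraph::degree(igraph::induced_subgraph(g, sub)) == 0]
    if (length(iso) >= 2) {
      g2 <- igraph::add_edges(g, iso[1:2])
      expect_gt(connected_ratio(g2, sub), r0)
    }
  }
})
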