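test_that("group assignment splits cases at the control mean, ties to HIG", {
  ga <- assign_groups(c(5, 6, 7), c(a = 4, b = 8, c = 6))
  expect_equal(ga$control_mean, 6)
  expect_identical(unname(ga$groups), c("LIG", "HIG", "HIG"))
  expect_named(ga$groups, c("a", "b", "c"))
  # partition property on random draws
  set.seed(14)
  for (i in 1:10) {
    ctrl <- rnorm(8, 10); cases <- rnorm(15, 10, 3)
    g <- assign_groups(ctrl, cases)$groups
    expect_equal(sum(g == "LIG") + sum(g == "HIG"), 15)
  }
})

test_that("contribution strength is the containment fraction", {
  vectors <- c(rep(list(c("R1", "R2")), 3), rep(list("R2"), 7))
  expect_equal(unname(contribution_strength(vectors, "R1")), 0.3)
  expect_equal(unname(contribution_strength(vectors, "R2")), 1)
  expect_equal(unname(contribution_strength(vectors, "R9")), 0)
})

test_that("specificity labels follow the min/max-difference rules", {
  tab <- structure(data.frame(
    reaction_id = c("u", "s", "n"),
    strength_control = c(1, 0.9, 0.2),
    strength_LIG = c(1, 0.05, 0.25),
    strength_HIG = c(1, 0.9, 0.3)),
    class = c("contribution_table", "data.frame"))
  out <- classify_specificity(tab, s_unspecific = 0.9, delta_specific = 0.5)
  expect_identical(out$specificity, c("unspecific", "specific", NA))
})

test_that("contribution tables aggregate strengths and usage per group", {
  m <- parallel_model()
  res <- list(
    g1 = list(gimme(m, make_pattern(m, absent = "R2a")),
              gimme(m, make_pattern(m, absent = "R2a"))),
    g2 = list(gimme(m, make_pattern(m, absent = c("T1", "R2a")))))
  tab <- contribution_table(res)
  # T1 contributes only in group g2 (forced: only path to A_c)
  expect_equal(tab$strength_g1[tab$reaction_id == "T1"], 0)
  expect_equal(tab$strength_g2[tab$reaction_id == "T1"], 1)
  expect_true(all(tab$usage_g2[tab$reaction_id == "T1"] == 1))
  expect_true(all(unlist(tab[, -1][, grep("strength|usage", names(tab)[-1])]) >= 0))
})

test_that("bottleneck marker reflects knockout damage to the objective", {
  m <- chain_model()
  pats <- list(make_pattern(m))
  mk <- topological_markers(m, c("T1", "R2"), pats, l = 0.8)
  expect_true("BN" %in% mk$T1)
  expect_true("BN" %in% mk$R2)
  # a restored parallel path removes the bottleneck
  mp <- parallel_model()
  mkp <- topological_markers(mp, c("R2a", "T1"), list(make_pattern(mp)), l = 0.8)
  expect_false("BN" %in% mkp$R2a)
  expect_true("BN" %in% mkp$T1)
  expect_error(topological_markers(m, "nope", pats), "unknown reaction")
})

test_that("layer-proximity markers use directed distances", {
  m <- chain_model()   # EX_A -> T1 -> R2 -> ART_OBJ
  mk <- topological_markers(m, c("T1", "R2"), list(make_pattern(m)),
                            l = 0.8, thresholds = list(d_layer = 1))
  expect_true("CIL" %in% mk$T1)    # one step from the uptake exchange
  expect_false("CIL" %in% mk$R2)
  expect_true("COL" %in% mk$R2)    # one step from the objective drain
  expect_false("COL" %in% mk$T1)
})

test_that("chain-disruptor and just-below-threshold markers fire on a planted gap", {
  # T1 (present) -> R2 (absent, x just below t) -> R3 (present) -> objective
  mets <- data.frame(id = c("A_e", "A_c", "B_c", "C_c"),
                     compartment = c("e", "c", "c", "c"))
  rl <- list(
    list(id = "EX_A", stoich = c(A_e = -1), lb = -10, ub = 1000),
    list(id = "T1", stoich = c(A_e = -1, A_c = 1), lb = 0, ub = 1000, gpr = "g1"),
    list(id = "R2", stoich = c(A_c = -1, B_c = 1), lb = 0, ub = 1000, gpr = "g2"),
    list(id = "R3", stoich = c(B_c = -1, C_c = 1), lb = 0, ub = 1000, gpr = "g3"))
  m <- add_objective_drain(metabolic_model(mets, rl), "C_c")
  rx_expr <- matrix(rep(c(3, 3, 1.8, 3, NA), 4), ncol = 4,
                    dimnames = list(c("EX_A", "T1", "R2", "R3",
                                      "ART_OBJ_C_c"), NULL))
  pats <- lapply(1:4, function(i) threshold_pattern(rx_expr[, i], 2))
  mk <- topological_markers(m, "R2", pats, reaction_expr = rx_expr, l = 0.8)
  expect_true("CD" %in% mk$R2)
  expect_true("JBT" %in% mk$R2)
  # far below threshold: still CD, no longer JBT
  rx2 <- rx_expr; rx2["R2", ] <- 0.5
  pats2 <- lapply(1:4, function(i) threshold_pattern(rx2[, i], 2))
  mk2 <- topological_markers(m, "R2", pats2, reaction_expr = rx2, l = 0.8)
  expect_true("CD" %in% mk2$R2)
  expect_false("JBT" %in% mk2$R2)
})

test_that("invisible-path marker needs a GPR-poor neighbourhood", {
  mets <- data.frame(id = c("A_e", "A_c", "B_c", "C_c", "D_c"),
                     compartment = c("e", rep("c", 4)))
  rl <- list(
    list(id = "EX_A", stoich = c(A_e = -1), lb = -10, ub = 1000),
    list(id = "T1", stoich = c(A_e = -1, A_c = 1), lb = 0, ub = 1000, gpr = "g1"),
    list(id = "N1", stoich = c(A_c = -1, B_c = 1), lb = 0, ub = 1000),
    list(id = "N2", stoich = c(B_c = -1, C_c = 1), lb = 0, ub = 1000),
    list(id = "N3", stoich = c(C_c = -1, D_c = 1), lb = 0, ub = 1000))
  m <- add_objective_drain(metabolic_model(mets, rl), "D_c")
  mk <- topological_markers(m, "N2", list(make_pattern(m)), l = 0.8)
  expect_true("IP" %in% mk$N2)    # both neighbours lack GPRs
  # annotate the path: neighbourhood no longer GPR-poor
  rl2 <- rl
  rl2[[3]]$gpr <- "gN1"; rl2[[4]]$gpr <- "gN2"; rl2[[5]]$gpr <- "gN3"
  m2 <- add_objective_drain(metabolic_model(mets, rl2), "D_c")
  mk2 <- topological_markers(m2, "N2", list(make_pattern(m2)), l = 0.8)
  expect_false("IP" %in% mk2$N2)
})
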