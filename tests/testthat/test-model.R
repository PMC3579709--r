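test_that("model construction enforces the container invariants", {
  mets <- data.frame(id = c("A_c", "B_c"), compartment = "c")
  ok <- list(list(id = "R1", stoich = c(A_c = -1, B_c = 1), lb = 0, ub = 10))
  m <- metabolic_model(mets, ok)
  expect_s3_class(m, "metabolic_model")
  expect_false(m$reactions$reversible)

  expect_error(metabolic_model(mets, list(
    list(id = "R1", stoich = c(X_c = -1), lb = 0, ub = 1))),
    "unknown metabolite")
  expect_error(metabolic_model(mets, list(
    list(id = "R1", stoich = c(A_c = -1), lb = 5, ub = 1))), "lb > ub")
  expect_error(metabolic_model(mets, c(ok, ok)), "duplicate reaction")
  expect_error(metabolic_model(mets, list(
    list(id = "R1", stoich = numeric(0), lb = 0, ub = 1))),
    "empty stoichiometry")
  # EX_ prefix on a two-metabolite reaction is contradictory
  expect_error(metabolic_model(mets, list(
    list(id = "EX_R1", stoich = c(A_c = -1, B_c = 1), lb = 0, ub = 1))),
    "exchange")
})

test_that("exchange reactions are detected by stoichiometry and prefix", {
  m <- chain_model()
  # the artificial objective drain is single-metabolite but not an exchange
  expect_setequal(exchange_reactions(m), "EX_A")
  # single-metabolite but no prefix still counts
  mets <- data.frame(id = "A_c", compartment = "c")
  m2 <- metabolic_model(mets, list(
    list(id = "sink_A", stoich = c(A_c = -1), lb = 0, ub = 10)))
  expect_true(m2$reactions$is_exchange)
})

test_that("infinite bounds are clamped to the +/-1000 convention", {
  mets <- data.frame(id = "A_c", compartment = "c")
  m <- metabolic_model(mets, list(
    list(id = "EX_A", stoich = c(A_c = -1), lb = -Inf, ub = Inf)))
  expect_equal(m$reactions$lb, -1000)
  expect_equal(m$reactions$ub, 1000)
})

test_that("add_drain appends exactly one irreversible artificial reaction", {
  m <- chain_model()
  n0 <- nrow(m$reactions)
  m2 <- add_drain(m, "A_c")
  expect_equal(nrow(m2$reactions), n0 + 1L)
  j <- match("ART_DRAIN_A_c", m2$reactions$id)
  expect_equal(m2$reactions$lb[j], 0)
  expect_true(m2$reactions$artificial[j])
  expect_null(m2$gprs[["ART_DRAIN_A_c"]])
  # existing bounds untouched, original model unmodified
  expect_equal(m2$reactions[seq_len(n0), c("lb", "ub")],
               m$reactions[, c("lb", "ub")])
  expect_equal(nrow(m$reactions), n0)
  expect_error(add_drain(m2, "A_c"), "already present")
  expect_error(add_drain(m, "nope_c"), "unknown metabolite")
})

test_that("a drain unblocks an objective stalled by a dead-end metabolite", {
  m <- deadend_model()
  expect_equal(fba_max(m)$v_max, 0)
  m2 <- add_drain(m, "D_c")
  expect_equal(fba_max(m2)$v_max, 10)
})

test_that("add_objective_drain sets the objective; isolated targets stay at zero", {
  mets <- data.frame(id = c("A_c", "iso_c"), compartment = "c")
  m <- metabolic_model(mets, list(
    list(id = "EX_A", stoich = c(A_c = -1), lb = -10, ub = 1000)))
  m2 <- add_objective_drain(m, "iso_c")
  expect_identical(m2$objective, "ART_OBJ_iso_c")
  expect_equal(fba_max(m2)$v_max, 0)    # nothing produces iso_c
})

test_that("split_reversible produces an equivalent irreversible model", {
  mets <- data.frame(id = c("A_e", "A_c", "B_c"), compartment = c("e", "c", "c"))
  rl <- list(
    list(id = "EX_A", stoich = c(A_e = -1), lb = -10, ub = 1000),
    list(id = "T1", stoich = c(A_e = -1, A_c = 1), lb = -20, ub = 20,
         gpr = "g1"),
    list(id = "R2", stoich = c(A_c = -1, B_c = 1), lb = 0, ub = 1000))
  m <- add_objective_drain(metabolic_model(mets, rl), "B_c")
  sp <- split_reversible(m)
  expect_true(all(sp$reactions$lb >= 0))
  j <- match(c("T1_fwd", "T1_bwd"), sp$reactions$id)
  expect_false(any(is.na(j)))
  expect_equal(sp$reactions$ub[j], c(20, 20))
  # irreversible reactions pass through unchanged
  expect_true("R2" %in% sp$reactions$id)
  # FBA optimum preserved (flux spaces in bijection)
  expect_equal(fba_max(m)$v_max, 10)
  map <- attr(sp, "rev_mapping")
  expect_setequal(unique(map$orig_id), m$reactions$id)
})

test_that("model summary and bound edits behave", {
  m <- chain_model()
  s <- model_summary(m)
  expect_equal(s$n_reactions, nrow(m$reactions))
  expect_true("EX_A" %in% s$exchange_reactions)
  expect_setequal(model_genes(m), c("g1", "g2"))
  m2 <- set_bounds(m, "R2", ub = 3)
  expect_equal(fba_max(m2)$v_max, 3)
  expect_error(set_bounds(m, "nope", ub = 1), "unknown reaction")
})
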