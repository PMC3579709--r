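test_that("FBA on a linear chain saturates the uptake bound", {
  m <- chain_model(uptake = 10)
  f <- fba_max(m)
  expect_equal(f$v_max, 10)
  expect_equal(unname(f$flux["EX_A"]), -10)     # uptake is negative flux
  expect_equal(unname(f$flux["R2"]), 10)
})

test_that("FBA is zero for dead-end-blocked or closed models", {
  expect_equal(fba_max(deadend_model())$v_max, 0)
  m <- chain_model()
  blocked <- set_bounds(m, "EX_A", lb = 0)
  expect_equal(fba_max(blocked)$v_max, 0)
})

test_that("a single absent reaction on the only path gives I = w * l * v_max", {
  m <- chain_model(uptake = 10)
  for (w in c(1, 0.5, 0.9)) {
    for (l in c(0.5, 0.8, 0.95)) {
      pat <- make_pattern(m, absent = "R2", deficit = w)
      g <- gimme(m, pat, l = l)
      expect_equal(g$inconsistency, w * l * 10, tolerance = 1e-9)
      expect_identical(g$inconsistency_vector$reaction_id, "R2")
      expect_equal(g$v_obj, l * 10, tolerance = 1e-9)
      expect_equal(normalized_inconsistency(g), w, tolerance = 1e-9)
    }
  }
})

test_that("an all-present pattern has zero inconsistency and empty vector", {
  m <- chain_model()
  g <- gimme(m, make_pattern(m))
  expect_equal(g$inconsistency, 0)
  expect_equal(nrow(g$inconsistency_vector), 0)
  expect_equal(normalized_inconsistency(g), 0)
})

test_that("flux routes through the present one of two parallel paths", {
  m <- parallel_model()
  pat <- make_pattern(m, absent = "R2a", deficit = 1)
  g <- gimme(m, pat, l = 0.8)
  expect_equal(g$inconsistency, 0)
  expect_equal(abs(unname(g$flux["R2a"])), 0, tolerance = 1e-9)
  expect_equal(unname(g$flux["R2b"]), 8, tolerance = 1e-9)
})

test_that("a zero objective maximum raises the degenerate-objective error", {
  m <- deadend_model()
  expect_error(gimme(m, make_pattern(m)), class = "gimme_degenerate")
})

test_that("the GIMME optimum matches vertex enumeration on small networks", {
  set.seed(13)
  m <- parallel_model()
  # randomised deficits and levels; oracle solves the split-form LP by
  # brute force over basic solutions
  for (rep in 1:8) {
    ab <- sample(c("T1", "R2a", "R2b"), sample(1:2, 1))
    w <- round(runif(length(ab), 0.2, 1.5), 2)
    l <- sample(c(0.5, 0.8, 1), 1)
    pat <- make_pattern(m, absent = ab, deficit = w)
    g <- gimme(m, pat, l = l)
    sp <- split_reversible(m)
    map <- attr(sp, "rev_mapping")
    w_orig <- stats::setNames(rep(0, nrow(m$reactions)), m$reactions$id)
    w_orig[ab] <- w
    cost <- unname(w_orig[map$orig_id])
    oi <- which(map$orig_id == m$objective)
    # objective-level row as an equality via explicit slack
    n <- nrow(sp$reactions)
    Aeq <- rbind(as.matrix(sp$S), 0)
    Aeq <- cbind(Aeq, c(rep(0, nrow(sp$S)), -1))
    Aeq[nrow(Aeq), oi] <- map$dir[oi]
    oracle <- enum_lp(c(cost, 0), Aeq,
                      c(rep(0, nrow(sp$S)), l * 10),
                      lb = 0, ub = c(sp$reactions$ub, Inf))
    expect_equal(g$inconsistency, oracle$objval, tolerance = 1e-6)
  }
})

test_that("inconsistency never increases when the threshold is lowered", {
  spec <- synthetic_spec(n_decoy_chains = 1, n_wobbly_pairs = 1)
  m <- generate_toy_model(spec)
  m_app <- apply_medium(m, toy_reference_medium(m))
  fba <- fba_max(m_app)
  co <- generate_cohort(m, spec)
  for (i in c(1, 25, 45)) {
    rx <- reaction_expression(co$expr[, i], m, quiet = TRUE)
    Is <- vapply(c(3, 2.5, 2, 1.5, 1, 0.5), function(t) {
      gimme(m_app, threshold_pattern(rx, t), l = 0.8, fba = fba)$inconsistency
    }, numeric(1))
    expect_true(all(diff(Is) <= 1e-8))
  }
})

test_that("inconsistency vector reactions all carry nonzero flux", {
  spec <- synthetic_spec(n_decoy_chains = 1, n_wobbly_pairs = 1)
  m <- generate_toy_model(spec)
  m_app <- apply_medium(m, toy_reference_medium(m))
  co <- generate_cohort(m, spec)
  for (i in c(1, 30, 55)) {
    rx <- reaction_expression(co$expr[, i], m, quiet = TRUE)
    g <- gimme(m_app, threshold_pattern(rx, 2), l = 0.8)
    iv <- g$inconsistency_vector
    expect_true(all(abs(g$flux[iv$reaction_id]) > g$eps_flux))
    expect_true(all(iv$weight > 0))
    # no artificial reactions in the decomposition
    expect_false(any(startsWith(iv$reaction_id, "ART_")))
    # I decomposes over the vector
    expect_equal(g$inconsistency, sum(iv$flux * iv$weight), tolerance = 1e-7)
  }
})

test_that("usage frequency counts samples with flux above the noise floor", {
  m <- parallel_model()
  pats <- list(make_pattern(m, absent = "R2a"),
               make_pattern(m, absent = "R2b"),
               make_pattern(m))
  res <- lapply(pats, function(p) gimme(m, p, l = 0.8))
  uf <- usage_frequency(res, c("T1", "R2a"))
  expect_equal(unname(uf["T1"]), 1)            # objective path always used
  expect_lte(unname(uf["R2a"]), 2 / 3)         # avoided when penalised
  expect_warning(u0 <- usage_frequency(res, "nope"), "unknown reaction")
  expect_equal(unname(u0), 0)
})
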