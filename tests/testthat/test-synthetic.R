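test_that("spec validation rejects impossible study designs", {
  expect_error(synthetic_spec(main_chain_len = 2), "main_chain_len")
  expect_error(synthetic_spec(n_control = 0), "cohort sizes")
  expect_error(synthetic_spec(present_mean = 1.5), "present_mean > t")
  expect_error(synthetic_spec(sigma = 0), "sigma")
  expect_error(synthetic_spec(bypass_cap = 0), "bypass_cap")
})

test_that("the default toy model reaches its objective on the reference medium", {
  m <- generate_toy_model()
  expect_true(fba_max(apply_medium(m, toy_reference_medium(m)))$v_max > 0)
  # container sanity
  expect_gte(nrow(m$reactions), 50)
  expect_lte(nrow(m$reactions), 150)
  expect_equal(sort(unique(m$metabolites$compartment)), c("c", "e", "m"))
})

test_that("currency hubs touch many reactions and fall in the top-degree cut", {
  m <- generate_toy_model()
  tr <- attr(m, "truth")
  excl <- remove_currency_metabolites(m, 0.04)
  expect_true(all(tr$currency_hubs %in% excl))
  # hubs touch at least 30% of the non-exchange, non-decoy core
  core <- !m$reactions$is_exchange & !grepl("^(DEC|WOB)", m$reactions$id)
  hub_touch <- Matrix::colSums(m$S[tr$cofactor_mets, core, drop = FALSE] != 0) > 0
  expect_gte(mean(hub_touch), 0.3)
})

test_that("the generator is deterministic: identical SBML for a fixed seed", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  spec <- synthetic_spec(n_decoy_chains = 2, n_wobbly_pairs = 1, seed = 4,
                         n_control = 2, n_lig = 2, n_hig = 2)
  write_fixture_dir(d1, spec)
  write_fixture_dir(d2, spec)
  for (f in c("model.xml", "expression.tsv", "medium.json", "truth.json")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
  }
  # and the fixture round-trips
  m <- read_sbml_model(file.path(d1, "model.xml"))
  expect_s3_class(m, "metabolic_model")
  expect_equal(ncol(read_expression_tsv(file.path(d1, "expression.tsv"))), 6)
})

test_that("cohort expression is bimodal with well-separated modes", {
  spec <- synthetic_spec()
  m <- generate_toy_model(spec)
  co <- generate_cohort(m, spec)
  km <- stats::kmeans(as.vector(co$expr), centers = c(1, 3))
  sep <- abs(diff(sort(km$centers)))
  expect_gt(sep, 4 * spec$sigma)
})

test_that("the planted just-below-threshold gene is absent with median in margin", {
  spec <- synthetic_spec()
  m <- generate_toy_model(spec)
  co <- generate_cohort(m, spec)
  jbt <- co$truth$jbt_gene
  x <- co$expr[jbt, ]
  expect_equal(mean(x < spec$t), 1)                  # absent in all samples
  expect_gte(stats::median(x), spec$t - 0.5)
  expect_lt(stats::median(x), spec$t)
})

test_that("cohort labels, sizes and determinism are as specified", {
  spec <- synthetic_spec(n_control = 3, n_lig = 4, n_hig = 5,
                         n_decoy_chains = 1, n_wobbly_pairs = 1)
  m <- generate_toy_model(spec)
  co1 <- generate_cohort(m, spec)
  co2 <- generate_cohort(m, spec)
  expect_identical(co1$expr, co2$expr)
  expect_equal(as.integer(table(co1$labels)[c("control", "LIG", "HIG")]),
               c(3L, 4L, 5L))
  expect_identical(colnames(co1$expr), names(co1$labels))
  # different seed, different draws
  co3 <- generate_cohort(m, spec, seed = spec$seed + 1)
  expect_false(identical(co1$expr, co3$expr))
})

test_that("planted group structure is recovered from the generated cohort", {
  spec <- synthetic_spec(n_control = 6, n_lig = 6, n_hig = 6, seed = 3)
  m <- generate_toy_model(spec)
  m_app <- apply_medium(m, toy_reference_medium(m))
  fba <- fba_max(m_app)
  co <- generate_cohort(m, spec)
  Is <- vapply(seq_len(ncol(co$expr)), function(i) {
    rx <- reaction_expression(co$expr[, i], m, quiet = TRUE)
    gimme(m_app, threshold_pattern(rx, spec$t), l = 0.8, fba = fba)$inconsistency
  }, numeric(1))
  lab <- co$labels
  expect_gt(mean(Is[lab == "HIG"]), mean(Is[lab == "control"]))
  expect_gt(mean(Is[lab == "control"]), mean(Is[lab == "LIG"]))
})
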