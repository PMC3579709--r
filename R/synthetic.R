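# Synthetic metabolic model and expression cohort generator.
#
# The toy model is a two-membrane (extracellular / cytosol / mitochondrion)
# network with a terminal biosynthetic objective: carbon (glucose or
# glycerol) is taken up, processed through a cytosolic chain, shuttled into
# the mitochondrion, converted to a precursor and condensed with
# acetyl-CoA (from amino- or fatty-acid degradation) into the objective
# metabolite. The final synthase co-produces a dead-end by-product, which
# blocks the pathway at steady state until an artificial drain is added —
# the same mechanism by which a dead-end metabolite can silently block a
# genome-scale objective. Planted features give every downstream analysis
# a known ground truth:
#   * a "just-below-threshold" gene on the main chain (JBT + chain
#     disruptor marker, unspecific contributor in every sample),
#   * a penalised mitochondrial step with a parallel "energy pathway"
#     alternative that is expressed only in the low-inconsistency group,
#   * a capacity-limited GPR-less bypass route (invisible-path marker),
#   * currency cofactor hubs (ATP/ADP) touching most cytosolic reactions,
#   * decoy chains of never-expressed genes that give the gene network a
#     background of disconnected components.

#' Specification of the synthetic model and cohort
#'
#' Defaults define the study conditions used throughout the test-suite:
#' expression on a log-signal scale with present genes ~ Normal(3, 0.4),
#' absent genes ~ Normal(1, 0.4), threshold t = 2 between the modes, and a
#' cohort of 20 control + 20 low-inconsistency-like + 20
#' high-inconsistency-like samples.
#'
#' @param main_chain_len cytosolic main-chain length (>= 3; the
#'   just-below-threshold reaction sits at position 3).
#' @param n_decoy_chains,decoy_chain_len decoy gene-chain count and length.
#' @param n_extra_exchange decoy nutrient exchanges (never in the
#'   reference medium).
#' @param bypass_cap flux capacity of the GPR-less bypass route.
#' @param n_wobbly_pairs pendant two-gene "salvage" modules, borderline in
#'   control/HIG and solidly expressed in LIG; they carry no flux, so they
#'   shape coherence without touching the inconsistency.
#' @param n_control,n_lig,n_hig cohort sizes.
#' @param present_mean,absent_mean,sigma expression means and noise sd
#'   (log-signal units).
#' @param jbt_mean,jbt_sd planted just-below-threshold gene distribution.
#' @param pen_mean,pen_sd planted penalised-segment gene distribution.
#' @param wobbly_mean borderline expression mean of the partially-used
#'   glycerol/fatty-acid routes in control and HIG samples (LIG expresses
#'   them solidly).
#' @param hig_fraction range (or single value) of the per-sample fraction
#'   of pathway genes pushed below threshold in high-inconsistency
#'   samples.
#' @param t expression threshold the signal is planted around.
#' @param extra_gprless fraction of decoy reactions stripped of their GPR
#'   (on top of the structurally GPR-less bypass/exchange reactions).
#' @param seed generator seed.
#' @return list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(main_chain_len = 4, n_decoy_chains = 8,
                           decoy_chain_len = 3, n_extra_exchange = 6,
                           bypass_cap = 2, n_wobbly_pairs = 6,
                           n_control = 20, n_lig = 20, n_hig = 20,
                           present_mean = 3, absent_mean = 1, sigma = 0.4,
                           jbt_mean = 1.75, jbt_sd = 0.05,
                           pen_mean = 1.5, pen_sd = 0.1,
                           wobbly_mean = 2, hig_fraction = c(0.65, 0.9), t = 2,
                           extra_gprless = 0, seed = 1L) {
  if (main_chain_len < 3) stop("main_chain_len must be >= 3")
  if (n_decoy_chains < 1 || decoy_chain_len < 2) {
    stop("need at least one decoy chain of length >= 2")
  }
  if (n_control < 1 || n_lig < 1 || n_hig < 1) stop("cohort sizes must be >= 1")
  if (!(present_mean > t && t > absent_mean)) {
    stop("need present_mean > t > absent_mean")
  }
  if (sigma <= 0) stop("sigma must be > 0")
  if (bypass_cap <= 0) stop("bypass_cap must be > 0")
  structure(as.list(environment()), class = "synthetic_spec")
}

#' Generate the synthetic toy metabolic model
#'
#' See the package-level description of the planted topology. The model
#' passes all container invariants, is SBML-writable, and carries a
#' `"truth"` attribute with the planted ground truth: gene categories
#' (pathway / energy / just-below-threshold / penalised / decoy) and the
#' planted topological-marker reactions.
#'
#' @param spec a `synthetic_spec`.
#' @param include_drains add the artificial objective drain and the
#'   dead-end by-product drain (default). With `FALSE` the raw network is
#'   returned, in which the dead-end blocks all steady-state objective
#'   flux — the fixture for testing drain insertion.
#' @return a `metabolic_model` (with objective set when
#'   `include_drains = TRUE`).
#' @export
generate_toy_model <- function(spec = synthetic_spec(), include_drains = TRUE) {
  stopifnot(inherits(spec, "synthetic_spec"))
  L <- spec$main_chain_len
  mets <- list()
  add_met <- function(id, comp) mets[[length(mets) + 1L]] <<- c(id, comp)

  nutrient_ex <- c("EX_glc_e", "EX_gly_e", "EX_aa1_e", "EX_fa1_e")
  always_ex <- c("EX_o2_e", "EX_h_e", "EX_pi_e", "EX_h2o_e", "EX_so4_e")
  extra_ex <- if (spec$n_extra_exchange > 0) {
    sprintf("EX_u%02d_e", seq_len(spec$n_extra_exchange))
  } else character()
  ex_mets <- sub("^EX_", "", c(nutrient_ex, always_ex, extra_ex))
  for (mid in ex_mets) add_met(mid, "e")

  chain_mets <- c("glc_c", sprintf("mc%d_c", seq_len(L - 1)), "pyr_c")
  for (mid in chain_mets) add_met(mid, "c")
  for (mid in c("gly_c", "aa1_c", "fa1_c", "accoa_c", "prec_c", "ster_c",
                "byp_c", "nr1_c", "nr2_c", "atp_c", "adp_c")) add_met(mid, "c")
  for (mid in c("pyr_m", "mm1_m", "mm2_m", "em1_m", "em2_m", "prec_m",
                "atp_m", "adp_m")) {
    add_met(mid, "m")
  }
  for (p in seq_len(spec$n_wobbly_pairs)) {
    for (k in 1:3) add_met(sprintf("wob%d_%d_c", p, k), "c")
  }
  decoy_genes <- character()
  for (ch in seq_len(spec$n_decoy_chains)) {
    for (k in seq_len(spec$decoy_chain_len + 1L)) {
      add_met(sprintf("dec%d_%d_c", ch, k), "c")
    }
  }
  met_df <- data.frame(id = vapply(mets, `[`, "", 1),
                       compartment = vapply(mets, `[`, "", 2),
                       stringsAsFactors = FALSE)

  rl <- list()
  add_rxn <- function(id, stoich, gpr = NULL, lb = 0, ub = INF_BOUND) {
    rl[[length(rl) + 1L]] <<- list(id = id, stoich = stoich, gpr = gpr,
                                   lb = lb, ub = ub)
  }
  for (mid in ex_mets) {
    add_rxn(paste0("EX_", mid), stats::setNames(-1, mid), lb = -INF_BOUND)
  }
  add_rxn("GLCt", c(glc_e = -1, glc_c = 1), gpr = "gT1")
  add_rxn("GLYt", c(gly_e = -1, gly_c = 1), gpr = "gT4")
  add_rxn("AAt", c(aa1_e = -1, aa1_c = 1), gpr = "gT5")
  add_rxn("FAt", c(fa1_e = -1, fa1_c = 1), gpr = "gT6")
  # cytosolic main chain with alternating ATP/ADP involvement; the
  # just-below-threshold gene sits at step 3
  chain_nodes <- chain_mets
  jbt_pos <- 3L
  main_genes <- c("gT1", "gT4", "gT5", "gT6")
  for (k in seq_len(L)) {
    gene <- if (k == jbt_pos) "gJBT" else sprintf("gC%d", k)
    if (k != jbt_pos) main_genes <- c(main_genes, gene)
    cofact <- if (k %% 2 == 1) c(atp_c = -1, adp_c = 1) else c(adp_c = -1, atp_c = 1)
    add_rxn(sprintf("CYT%d", k),
            c(stats::setNames(c(-1, 1), chain_nodes[c(k, k + 1)]), cofact),
            gpr = gene)
  }
  add_rxn("GLYK", c(gly_c = -1, mc1_c = 1, atp_c = -1, adp_c = 1), gpr = "gGK")
  add_rxn("AADEG", c(aa1_c = -1, accoa_c = 5), gpr = "gA1")
  add_rxn("FAOX", c(fa1_c = -1, accoa_c = 5), gpr = "gF1")
  add_rxn("OXP", c(adp_c = -1, atp_c = 1), gpr = "gOX")
  main_genes <- c(main_genes, "gGK", "gA1", "gF1", "gOX")
  # GPR-less capacity-limited bypass (invisible path)
  add_rxn("NR1", c(mc1_c = -1, nr1_c = 1), ub = spec$bypass_cap)
  add_rxn("NR2", c(nr1_c = -1, nr2_c = 1))
  add_rxn("NR3", c(nr2_c = -1, prec_c = 1))
  # mitochondrial leg; step 2 is the penalised segment with the
  # energy-pathway alternative
  add_rxn("PYRt", c(pyr_c = -1, pyr_m = 1), gpr = "gT2a or gT2b")
  add_rxn("MITO1", c(pyr_m = -1, mm1_m = 1, atp_m = -1, adp_m = 1), gpr = "gM1")
  add_rxn("MITO2", c(mm1_m = -1, mm2_m = 1, atp_m = -1, adp_m = 1),
          gpr = "gPEN")
  # LIG-expressed "energy pathway": an unpenalised 3-step alternative
  add_rxn("MITO2B1", c(mm1_m = -1, em1_m = 1), gpr = "gE1")
  add_rxn("MITO2B2", c(em1_m = -1, em2_m = 1, adp_m = -1, atp_m = 1),
          gpr = "gE2")
  add_rxn("MITO2B3", c(em2_m = -1, mm2_m = 1), gpr = "gE3")
  add_rxn("MITO3", c(mm2_m = -1, prec_m = 1, adp_m = -1, atp_m = 1), gpr = "gM3")
  add_rxn("PRECt", c(prec_m = -1, prec_c = 1), gpr = "gT3")
  main_genes <- c(main_genes, "gT2a", "gT2b", "gM1", "gM3", "gT3")
  add_rxn("SYNTH", c(prec_c = -1, accoa_c = -1, atp_c = -1,
                     ster_c = 1, byp_c = 1, adp_c = 1),
          gpr = "gS1 and gS2")
  main_genes <- c(main_genes, "gS1", "gS2")
  # pendant "salvage" modules: two-reaction appendages with no connection
  # to the flux-carrying network
  wob_pair_genes <- character()
  for (p in seq_len(spec$n_wobbly_pairs)) {
    g1 <- sprintf("gW%d_1", p); g2 <- sprintf("gW%d_2", p)
    wob_pair_genes <- c(wob_pair_genes, g1, g2)
    add_rxn(sprintf("WOB%d_1", p),
            stats::setNames(c(-1, 1), sprintf("wob%d_%d_c", p, 1:2)), gpr = g1)
    add_rxn(sprintf("WOB%d_2", p),
            stats::setNames(c(-1, 1), sprintf("wob%d_%d_c", p, 2:3)), gpr = g2)
  }
  decoy_rxn <- character()
  for (ch in seq_len(spec$n_decoy_chains)) {
    for (k in seq_len(spec$decoy_chain_len)) {
      gene <- sprintf("gD%d_%d", ch, k)
      decoy_genes <- c(decoy_genes, gene)
      rid <- sprintf("DEC%d_%d", ch, k)
      decoy_rxn <- c(decoy_rxn, rid)
      add_rxn(rid, stats::setNames(c(-1, 1),
                                   sprintf("dec%d_%d_c", ch, c(k, k + 1))),
              gpr = gene)
    }
  }
  if (spec$extra_gprless > 0) {
    strip <- with_seed(spec$seed, {
      sample(decoy_rxn, round(spec$extra_gprless * length(decoy_rxn)))
    })
    for (i in seq_along(rl)) {
      if (rl[[i]]$id %in% strip) rl[[i]]$gpr <- NULL
    }
    decoy_genes <- setdiff(decoy_genes,
                           sprintf("gD%s", sub("^DEC", "", strip)))
  }
  model <- metabolic_model(met_df, rl, objective = NA_character_)
  if (include_drains) {
    model <- add_drain(model, "byp_c")
    model <- add_objective_drain(model, "ster_c")
  }
  wobbly_genes <- c("gT4", "gGK", "gT6", "gF1", wob_pair_genes)
  main_genes <- setdiff(main_genes, wobbly_genes)
  attr(model, "truth") <- list(
    pathway_genes = main_genes,
    wobbly_genes = wobbly_genes,
    energy_genes = c("gE1", "gE2", "gE3"),
    currency_hubs = c("atp_c", "adp_c"),
    cofactor_mets = c("atp_c", "adp_c", "atp_m", "adp_m"),
    jbt_gene = "gJBT",
    pen_gene = "gPEN",
    decoy_genes = decoy_genes,
    nutrient_exchanges = nutrient_ex,
    always_available = always_ex,
    carbon_sources = c("EX_glc_e", "EX_gly_e"),
    other_nutrients = c("EX_aa1_e", "EX_fa1_e"),
    markers = list(BN = c("PRECt", "SYNTH"), JBT = "CYT3", CD = "CYT3",
                   CIL = "GLCt", COL = "SYNTH", IP = "NR2"),
    spec = spec
  )
  model
}

#' Reference medium for the synthetic model
#'
#' Convenience wrapper wiring the toy model's nutrient ids into
#' [reference_medium()].
#'
#' @param model a model from [generate_toy_model()].
#' @return a `medium`.
#' @export
toy_reference_medium <- function(model) {
  tr <- attr(model, "truth")
  if (is.null(tr)) stop("model lacks generator ground truth")
  reference_medium(model,
                   carbon_sources = tr$carbon_sources,
                   nutrients = tr$other_nutrients,
                   always_available = tr$always_available)
}

#' Generate a seeded synthetic expression cohort
#'
#' Control samples express the pathway genes (mean `present_mean`) and
#' leave decoys, the energy gene, the penalised-segment gene and the
#' just-below-threshold gene low. Low-inconsistency (LIG-like) samples
#' additionally express the energy gene, opening an unpenalised
#' alternative to the penalised mitochondrial step. High-inconsistency
#' (HIG-like) samples push a random fraction `hig_fraction` of the pathway
#' genes below threshold. All draws are seeded.
#'
#' @param model model from [generate_toy_model()] (carries the truth
#'   attribute).
#' @param spec the `synthetic_spec` (defaults to the one stored in the
#'   model).
#' @param seed cohort seed (defaults to `spec$seed`).
#' @return list with `expr` (genes x samples matrix), `labels` (character:
#'   `control`/`LIG`/`HIG` per sample) and `truth` (the model's ground
#'   truth, with the per-sample HIG knockdown sets added).
#' @export
generate_cohort <- function(model, spec = NULL, seed = NULL) {
  tr <- attr(model, "truth")
  if (is.null(tr)) stop("model lacks generator ground truth")
  spec <- spec %||% tr$spec
  seed <- seed %||% spec$seed
  genes <- model_genes(model)
  n_tot <- spec$n_control + spec$n_lig + spec$n_hig
  labels <- rep(c("control", "LIG", "HIG"),
                c(spec$n_control, spec$n_lig, spec$n_hig))
  sample_ids <- sprintf("%s_%02d", labels,
                        sequence(c(spec$n_control, spec$n_lig, spec$n_hig)))
  hig_sets <- list()
  expr <- with_seed(seed, {
    m <- matrix(NA_real_, length(genes), n_tot,
                dimnames = list(genes, sample_ids))
    frange <- rep_len(spec$hig_fraction, 2)
    for (i in seq_len(n_tot)) {
      x <- stats::setNames(stats::rnorm(length(genes), spec$absent_mean,
                                        spec$sigma), genes)
      on_genes <- intersect(tr$pathway_genes, genes)
      wob <- intersect(tr$wobbly_genes, genes)
      if (labels[i] == "HIG") {
        pool <- c(on_genes, wob)
        f <- stats::runif(1, frange[1], frange[2])
        down <- sample(pool, round(f * length(pool)))
        hig_sets[[sample_ids[i]]] <- down
        on_genes <- setdiff(on_genes, down)
        wob <- setdiff(wob, down)
      }
      x[on_genes] <- stats::rnorm(length(on_genes), spec$present_mean,
                                  spec$sigma)
      if (labels[i] == "LIG") {
        lig_on <- intersect(c(tr$energy_genes, tr$wobbly_genes), genes)
        x[lig_on] <- stats::rnorm(length(lig_on), spec$present_mean,
                                  spec$sigma)
      } else {
        x[wob] <- stats::rnorm(length(wob), spec$wobbly_mean, spec$sigma)
      }
      if (tr$jbt_gene %in% genes) {
        x[tr$jbt_gene] <- stats::rnorm(1, spec$jbt_mean, spec$jbt_sd)
      }
      if (tr$pen_gene %in% genes) {
        x[tr$pen_gene] <- stats::rnorm(1, spec$pen_mean, spec$pen_sd)
      }
      m[, i] <- x
    }
    m
  })
  truth <- tr
  truth$hig_knockdowns <- hig_sets
  list(expr = expr, labels = stats::setNames(labels, sample_ids),
       truth = truth)
}

#' Write a complete synthetic fixture directory
#'
#' Emits the SBML model, the expression TSV, the reference medium JSON and
#' the ground-truth JSON.
#'
#' @param dir output directory (created if needed).
#' @param spec a `synthetic_spec`.
#' @return `dir`, invisibly.
#' @export
write_fixture_dir <- function(dir, spec = synthetic_spec()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  model <- generate_toy_model(spec)
  co <- generate_cohort(model, spec)
  write_sbml_model(model, file.path(dir, "model.xml"))
  df <- data.frame(gene_id = rownames(co$expr), co$expr,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, file.path(dir, "expression.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_medium_json(toy_reference_medium(model),
                    file.path(dir, "medium.json"))
  truth <- co$truth
  truth$spec <- unclass(truth$spec)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
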