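# SBML input/output.
#
# Writer emits SBML Level 3 Version 1 with the fbc (version 2) extension:
# bounds as fbc:lowerFluxBound/upperFluxBound parameters, GPR rules as
# fbc:geneProductAssociation trees, the objective as an fbc:listOfObjectives
# entry. Reader accepts that dialect plus the older Level 2 encoding in
# which bounds live in kineticLaw LOWER_BOUND/UPPER_BOUND parameters and
# GPRs in <notes> "GENE_ASSOCIATION:" lines (the encoding BIGG used for
# Recon-era models).

SBML_NS <- "http://www.sbml.org/sbml/level3/version1/core"
FBC_NS <- "http://www.sbml.org/sbml/level3/version1/fbc/version2"

#' Write a model to SBML (Level 3 + fbc)
#'
#' @param model a `metabolic_model`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_sbml_model <- function(model, path) {
  doc <- xml2::xml_new_root("sbml",
    "xmlns" = SBML_NS, "xmlns:fbc" = FBC_NS,
    level = "3", version = "1", "fbc:required" = "false")
  mdl <- xml2::xml_add_child(doc, "model", id = "model",
                             "fbc:strict" = "false")
  comps <- sort(unique(model$metabolites$compartment))
  lc <- xml2::xml_add_child(mdl, "listOfCompartments")
  for (cp in comps) {
    xml2::xml_add_child(lc, "compartment", id = cp, constant = "true")
  }
  ls <- xml2::xml_add_child(mdl, "listOfSpecies")
  for (i in seq_len(nrow(model$metabolites))) {
    xml2::xml_add_child(ls, "species",
      id = model$metabolites$id[i],
      compartment = model$metabolites$compartment[i],
      hasOnlySubstanceUnits = "false", boundaryCondition = "false",
      constant = "false")
  }
  # one shared parameter per distinct bound value; keys must be formatted
  # per element (vector format() pads with spaces)
  bnd_key <- function(x) sprintf("%.15g", x)
  bounds <- sort(unique(c(model$reactions$lb, model$reactions$ub)))
  bnd_id <- stats::setNames(sprintf("bnd_%d", seq_along(bounds)),
                            bnd_key(bounds))
  lp <- xml2::xml_add_child(mdl, "listOfParameters")
  for (i in seq_along(bounds)) {
    xml2::xml_add_child(lp, "parameter", id = unname(bnd_id[i]),
                        value = bnd_key(bounds[i]), constant = "true")
  }
  genes <- model_genes(model)
  if (length(genes)) {
    lg <- xml2::xml_add_child(mdl, "fbc:listOfGeneProducts")
    for (g in genes) {
      xml2::xml_add_child(lg, "fbc:geneProduct", "fbc:id" = .sbml_gid(g),
                          "fbc:label" = g)
    }
  }
  lr <- xml2::xml_add_child(mdl, "listOfReactions")
  for (j in seq_len(nrow(model$reactions))) {
    col <- model$S[, j]
    nz <- which(col != 0)
    rx <- xml2::xml_add_child(lr, "reaction",
      id = model$reactions$id[j],
      reversible = tolower(as.character(model$reactions$reversible[j])),
      fast = "false",
      "fbc:lowerFluxBound" = unname(bnd_id[bnd_key(model$reactions$lb[j])]),
      "fbc:upperFluxBound" = unname(bnd_id[bnd_key(model$reactions$ub[j])]))
    if (model$reactions$artificial[j]) {
      xml2::xml_set_attr(rx, "metaid", paste0("artificial_", model$reactions$id[j]))
    }
    re <- nz[col[nz] < 0]; pr <- nz[col[nz] > 0]
    if (length(re)) {
      lre <- xml2::xml_add_child(rx, "listOfReactants")
      for (i in re) {
        xml2::xml_add_child(lre, "speciesReference", species = rownames(model$S)[i],
                            stoichiometry = bnd_key(-col[i]),
                            constant = "true")
      }
    }
    if (length(pr)) {
      lpr <- xml2::xml_add_child(rx, "listOfProducts")
      for (i in pr) {
        xml2::xml_add_child(lpr, "speciesReference", species = rownames(model$S)[i],
                            stoichiometry = bnd_key(col[i]),
                            constant = "true")
      }
    }
    g <- model$gprs[[j]]
    if (!is.null(g)) {
      ga <- xml2::xml_add_child(rx, "fbc:geneProductAssociation")
      .sbml_write_gpr(ga, g)
    }
  }
  if (!is.na(model$objective)) {
    lo <- xml2::xml_add_child(mdl, "fbc:listOfObjectives",
                              "fbc:activeObjective" = "obj")
    ob <- xml2::xml_add_child(lo, "fbc:objective", "fbc:id" = "obj",
                              "fbc:type" = "maximize")
    lf <- xml2::xml_add_child(ob, "fbc:listOfFluxObjectives")
    xml2::xml_add_child(lf, "fbc:fluxObjective",
                        "fbc:reaction" = model$objective,
                        "fbc:coefficient" = "1")
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

.sbml_gid <- function(g) paste0("G_", gsub("[^A-Za-z0-9_]", "_", g))

.sbml_write_gpr <- function(parent, node) {
  if (node$op == "gene") {
    xml2::xml_add_child(parent, "fbc:geneProductRef",
                        "fbc:geneProduct" = .sbml_gid(node$gene))
  } else {
    el <- xml2::xml_add_child(parent, paste0("fbc:", node$op))
    for (a in node$args) .sbml_write_gpr(el, a)
  }
}

#' Read a metabolic model from SBML
#'
#' Accepts SBML Level 3 with the fbc extension (bounds as flux-bound
#' parameters, GPRs as geneProductAssociation trees) or SBML Level 2 with
#' kineticLaw bound parameters and notes-encoded `GENE_ASSOCIATION:`
#' strings. Reactions touching exactly one species, or whose id carries the
#' exchange prefix, are flagged as exchanges.
#'
#' @param path SBML file.
#' @param exchange_prefix id prefix marking exchange reactions (`"EX_"`).
#' @return a `metabolic_model`.
#' @export
read_sbml_model <- function(path, exchange_prefix = "EX_") {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop("unparsable SBML file ", path, ": ",
                                           conditionMessage(e)))
  root <- doc
  if (xml2::xml_name(root) != "sbml") stop("not an SBML document: ", path)
  xml2::xml_ns_strip(doc)
  mdl <- xml2::xml_find_first(doc, ".//model")
  if (inherits(mdl, "xml_missing")) stop("SBML file has no <model>: ", path)

  species <- xml2::xml_find_all(mdl, ".//listOfSpecies/species")
  mets <- data.frame(
    id = xml2::xml_attr(species, "id"),
    compartment = xml2::xml_attr(species, "compartment"),
    boundary = xml2::xml_attr(species, "boundaryCondition") %in% "true",
    stringsAsFactors = FALSE)
  boundary_ids <- mets$id[mets$boundary]
  mets <- mets[!mets$boundary, c("id", "compartment")]

  # fbc flux-bound parameters (L3) or global parameters
  pars <- xml2::xml_find_all(mdl, "./listOfParameters/parameter")
  par_val <- stats::setNames(as.numeric(xml2::xml_attr(pars, "value")),
                             xml2::xml_attr(pars, "id"))
  # fbc gene product labels
  gps <- xml2::xml_find_all(
    mdl, ".//*[local-name()='listOfGeneProducts']/*[local-name()='geneProduct']")
  gp_label <- stats::setNames(
    ifelse(is.na(xml2::xml_attr(gps, "label")), xml2::xml_attr(gps, "id"),
           xml2::xml_attr(gps, "label")),
    xml2::xml_attr(gps, "id"))

  rxn_nodes <- xml2::xml_find_all(mdl, ".//listOfReactions/reaction")
  reactions <- lapply(rxn_nodes, function(rx) {
    rid <- xml2::xml_attr(rx, "id")
    stoich <- numeric(0)
    add_sto <- function(sp, delta) {
      cur <- if (sp %in% names(stoich)) stoich[[sp]] else 0
      stoich[sp] <<- cur + delta
    }
    for (sr in xml2::xml_find_all(rx, "./listOfReactants/speciesReference")) {
      co <- as.numeric(xml2::xml_attr(sr, "stoichiometry"))
      add_sto(xml2::xml_attr(sr, "species"), -(if (is.na(co)) 1 else co))
    }
    for (sr in xml2::xml_find_all(rx, "./listOfProducts/speciesReference")) {
      co <- as.numeric(xml2::xml_attr(sr, "stoichiometry"))
      add_sto(xml2::xml_attr(sr, "species"), if (is.na(co)) 1 else co)
    }
    stoich <- stoich[!names(stoich) %in% boundary_ids]
    rev_attr <- !identical(xml2::xml_attr(rx, "reversible"), "false")
    lb_ref <- xml2::xml_attr(rx, "lowerFluxBound")
    ub_ref <- xml2::xml_attr(rx, "upperFluxBound")
    lb <- ub <- NA_real_
    if (!is.na(lb_ref)) lb <- unname(par_val[lb_ref])
    if (!is.na(ub_ref)) ub <- unname(par_val[ub_ref])
    # L2: kineticLaw parameters
    if (is.na(lb)) {
      kl <- xml2::xml_find_first(
        rx, "./kineticLaw//parameter[@id='LOWER_BOUND']")
      if (!inherits(kl, "xml_missing")) lb <- as.numeric(xml2::xml_attr(kl, "value"))
    }
    if (is.na(ub)) {
      kl <- xml2::xml_find_first(
        rx, "./kineticLaw//parameter[@id='UPPER_BOUND']")
      if (!inherits(kl, "xml_missing")) ub <- as.numeric(xml2::xml_attr(kl, "value"))
    }
    if (is.na(lb)) lb <- if (rev_attr) -INF_BOUND else 0
    if (is.na(ub)) ub <- INF_BOUND

    gpr <- .sbml_read_gpr(rx, rid, gp_label)
    meta <- xml2::xml_attr(rx, "metaid")
    list(id = rid, stoich = stoich, lb = lb, ub = ub, gpr = gpr,
         artificial = !is.na(meta) && startsWith(meta, "artificial_"))
  })
  empty <- vapply(reactions, function(r) length(r$stoich) == 0L, logical(1))
  reactions <- reactions[!empty]

  objective <- NA_character_
  fo <- xml2::xml_find_first(
    mdl, paste0(".//*[local-name()='listOfObjectives']",
                "/*[local-name()='objective']",
                "/*[local-name()='listOfFluxObjectives']",
                "/*[local-name()='fluxObjective']"))
  if (!inherits(fo, "xml_missing")) {
    objective <- xml2::xml_attr(fo, "reaction")
  }
  metabolic_model(mets, reactions, objective = objective,
                  exchange_prefix = exchange_prefix)
}

.sbml_read_gpr <- function(rx, rid, gp_label) {
  ga <- xml2::xml_find_first(rx, "./*[local-name()='geneProductAssociation']")
  if (!inherits(ga, "xml_missing")) {
    kids <- xml2::xml_children(ga)
    if (!length(kids)) return(NULL)
    return(.sbml_gpr_node(kids[[1]], rid, gp_label))
  }
  # L2 notes encoding
  notes <- xml2::xml_find_all(rx, "./notes//*")
  for (nd in notes) {
    tx <- xml2::xml_text(nd)
    if (grepl("GENE_ASSOCIATION\\s*:", tx)) {
      rule <- trimws(sub(".*GENE_ASSOCIATION\\s*:", "", tx))
      if (!nzchar(rule)) return(NULL)
      return(tryCatch(parse_gpr(rule),
                      error = function(e) stop("GPR parse error in reaction ",
                                               rid, ": ", conditionMessage(e))))
    }
  }
  NULL
}

.sbml_gpr_node <- function(node, rid, gp_label) {
  nm <- xml2::xml_name(node)
  if (nm == "geneProductRef") {
    gid <- xml2::xml_attr(node, "geneProduct")
    g <- if (gid %in% names(gp_label)) unname(gp_label[gid]) else gid
    return(structure(list(op = "gene", gene = g), class = "gpr"))
  }
  if (!nm %in% c("and", "or")) {
    stop("GPR parse error in reaction ", rid, ": unexpected element <", nm, ">")
  }
  args <- lapply(xml2::xml_children(node), .sbml_gpr_node, rid = rid,
                 gp_label = gp_label)
  if (!length(args)) stop("GPR parse error in reaction ", rid, ": empty <", nm, ">")
  structure(list(op = nm, args = args), class = "gpr")
}
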