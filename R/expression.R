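# Mapping per-gene log-signal intensities onto reactions and thresholding
# them into presence/absence patterns.

#' Read an expression table (TSV)
#'
#' First column `gene_id`, one column per sample, values are log-signal
#' intensities.
#'
#' @param path TSV file.
#' @return numeric matrix, genes x samples, rownames = gene ids.
#' @export
read_expression_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  m
}

#' Per-reaction expression from a gene expression profile
#'
#' Evaluates each reaction's GPR with `and -> min`, `or -> max` over the
#' profile. Genes present in the model but missing from the profile are
#' imputed with the profile-wide median (a neutral choice that avoids
#' manufacturing absence calls); reactions without a GPR map to `NA`, the
#' missing-marker meaning "assumed expressed" downstream.
#'
#' @param profile named numeric vector of log-signal intensities.
#' @param model a `metabolic_model`.
#' @param quiet suppress the message listing imputed genes.
#' @return named numeric vector over reaction ids (`NA` = no GPR).
#' @export
reaction_expression <- function(profile, model, quiet = FALSE) {
  stopifnot(is.numeric(profile), !is.null(names(profile)))
  med <- stats::median(profile, na.rm = TRUE)
  missing_genes <- setdiff(model_genes(model), names(profile))
  if (length(missing_genes) && !quiet) {
    message("reaction_expression: ", length(missing_genes),
            " model gene(s) not measured; imputed with profile median (",
            format(med, digits = 4), "): ",
            paste(utils::head(missing_genes, 5), collapse = ", "),
            if (length(missing_genes) > 5) ", ..." else "")
  }
  vapply(model$gprs, function(g) {
    if (is.null(g)) NA_real_ else eval_gpr(g, profile, missing = med)
  }, numeric(1))
}

#' Threshold reaction expression into a presence/absence pattern
#'
#' Values `>= t` are present (boundary ties resolve to present); values
#' below are absent with deficit weight `w = t - x`, the weight used by the
#' deficit-weighted inconsistency objective. `NA` (no GPR) is present with
#' deficit 0 — GPR-less reactions are assumed expressed.
#'
#' @param reaction_values named numeric vector from [reaction_expression()].
#' @param t expression threshold (log-signal units).
#' @param sample_id optional label carried along.
#' @return object of class `presence_pattern`: data.frame with
#'   `reaction_id`, `state` (`"present"`/`"absent"`), `deficit`; attributes
#'   `t` and `sample_id`.
#' @export
threshold_pattern <- function(reaction_values, t, sample_id = NA_character_) {
  stopifnot(is.finite(t))
  x <- reaction_values
  present <- is.na(x) | x >= t
  deficit <- ifelse(present, 0, t - x)
  out <- data.frame(reaction_id = names(x),
                    state = ifelse(present, "present", "absent"),
                    deficit = deficit,
                    stringsAsFactors = FALSE, row.names = NULL)
  structure(out, t = t, sample_id = sample_id,
            class = c("presence_pattern", "data.frame"))
}

#' Genes above threshold in a profile
#'
#' @param profile named numeric vector of log-signal intensities.
#' @param t threshold; genes with value `>= t` are active.
#' @return character vector of gene ids.
#' @export
active_genes <- function(profile, t) {
  names(profile)[!is.na(profile) & profile >= t]
}

#' Write per-sample presence patterns as TSV
#' @param pattern a `presence_pattern`.
#' @param path output path.
#' @return `path` invisibly.
#' @export
write_pattern_tsv <- function(pattern, path) {
  utils::write.table(as.data.frame(pattern), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
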