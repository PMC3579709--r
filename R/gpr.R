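#' Parse a gene-protein-reaction (GPR) association string
#'
#' GPR strings are boolean rules over gene identifiers using `and`/`or`
#' (case-insensitive) and parentheses, e.g. `"(g1 and g2) or g3"`. `and`
#' binds tighter than `or`, both left-associative, matching the usual COBRA
#' convention; fully parenthesised strings (the BIGG/Recon style) are
#' unaffected by precedence.
#'
#' @param text GPR string. The empty string (or `NA`) yields `NULL`, the
#'   marker for a reaction without gene association.
#' @return a `gpr` object: nested lists with `op` in `"and"`/`"or"` and
#'   `args`, leaves being `list(op = "gene", gene = <id>)`; or `NULL`.
#' @examples
#' parse_gpr("g1 or g2 and g3")   # OR(g1, AND(g2, g3))
#' parse_gpr("((g1))")            # collapses to the g1 leaf
#' @export
parse_gpr <- function(text) {
  if (is.null(text) || length(text) == 0L) return(NULL)
  if (is.na(text) || !nzchar(trimws(text))) return(NULL)
  toks <- .gpr_tokenize(text)
  st <- new.env(parent = emptyenv())
  st$toks <- toks
  st$pos <- 1L
  tree <- .gpr_parse_or(st, text)
  if (st$pos <= nrow(st$toks)) {
    stop(sprintf("GPR parse error at position %d in %s: unexpected '%s'",
                 st$toks$at[st$pos], sQuote(text), st$toks$tok[st$pos]))
  }
  tree
}

.gpr_tokenize <- function(text) {
  pat <- "\\(|\\)|[^()[:space:]]+"
  m <- gregexpr(pat, text)[[1]]
  if (m[1] == -1L) stop(sprintf("GPR parse error in %s: no tokens", sQuote(text)))
  toks <- regmatches(text, gregexpr(pat, text))[[1]]
  left <- gsub("\\(|\\)|[^()[:space:]]+|[[:space:]]+", "", text)
  if (nzchar(left)) {
    stop(sprintf("GPR parse error in %s: unparsable characters", sQuote(text)))
  }
  data.frame(tok = toks, at = as.integer(m), stringsAsFactors = FALSE)
}

.gpr_peek <- function(st) {
  if (st$pos > nrow(st$toks)) NULL else st$toks$tok[st$pos]
}

.gpr_parse_or <- function(st, text) {
  args <- list(.gpr_parse_and(st, text))
  while (!is.null(tk <- .gpr_peek(st)) && tolower(tk) == "or") {
    st$pos <- st$pos + 1L
    args[[length(args) + 1L]] <- .gpr_parse_and(st, text)
  }
  if (length(args) == 1L) args[[1L]] else
    structure(list(op = "or", args = args), class = "gpr")
}

.gpr_parse_and <- function(st, text) {
  args <- list(.gpr_parse_atom(st, text))
  while (!is.null(tk <- .gpr_peek(st)) && tolower(tk) == "and") {
    st$pos <- st$pos + 1L
    args[[length(args) + 1L]] <- .gpr_parse_atom(st, text)
  }
  if (length(args) == 1L) args[[1L]] else
    structure(list(op = "and", args = args), class = "gpr")
}

.gpr_parse_atom <- function(st, text) {
  tk <- .gpr_peek(st)
  if (is.null(tk)) {
    stop(sprintf("GPR parse error in %s: unexpected end of rule", sQuote(text)))
  }
  at <- st$toks$at[st$pos]
  if (tk == "(") {
    st$pos <- st$pos + 1L
    inner <- .gpr_parse_or(st, text)
    if (is.null(.gpr_peek(st)) || .gpr_peek(st) != ")") {
      stop(sprintf("GPR parse error at position %d in %s: unbalanced parentheses",
                   at, sQuote(text)))
    }
    st$pos <- st$pos + 1L
    return(inner)
  }
  if (tk == ")" || tolower(tk) %in% c("and", "or")) {
    stop(sprintf("GPR parse error at position %d in %s: unexpected '%s'",
                 at, sQuote(text), tk))
  }
  st$pos <- st$pos + 1L
  structure(list(op = "gene", gene = tk), class = "gpr")
}

#' Evaluate a GPR tree on per-gene expression values
#'
#' Replaces `and` with `min` and `or` with `max`, the standard mapping for
#' projecting transcript levels onto reactions.
#'
#' @param gpr a `gpr` object from [parse_gpr()] (or `NULL`).
#' @param values named numeric vector of per-gene expression.
#' @param missing value used for genes absent from `values` (default `NA`,
#'   which propagates through min/max).
#' @return numeric scalar, or `NA` for a `NULL` rule.
#' @export
eval_gpr <- function(gpr, values, missing = NA_real_) {
  if (is.null(gpr)) return(NA_real_)
  rec <- function(node) {
    if (node$op == "gene") {
      v <- unname(values[node$gene])
      if (is.null(v) || length(v) == 0L || is.na(v)) missing else v
    } else {
      vs <- vapply(node$args, rec, numeric(1))
      if (node$op == "and") min(vs) else max(vs)
    }
  }
  rec(gpr)
}

#' Genes referenced by a GPR tree
#' @param gpr a `gpr` object or `NULL`.
#' @return character vector of unique gene ids (empty for `NULL`).
#' @export
gpr_genes <- function(gpr) {
  if (is.null(gpr)) return(character())
  rec <- function(node) {
    if (node$op == "gene") node$gene else unlist(lapply(node$args, rec))
  }
  unique(rec(gpr))
}

#' Render a GPR tree back to a rule string
#' @param gpr a `gpr` object or `NULL`.
#' @return character scalar (`""` for `NULL`).
#' @export
gpr_to_string <- function(gpr) {
  if (is.null(gpr)) return("")
  rec <- function(node) {
    if (node$op == "gene") return(node$gene)
    inner <- vapply(node$args, rec, character(1))
    paste0("(", paste(inner, collapse = paste0(" ", node$op, " ")), ")")
  }
  rec(gpr)
}

#' @export
print.gpr <- function(x, ...) {
  cat("<gpr> ", gpr_to_string(x), "\n", sep = "")
  invisible(x)
}
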