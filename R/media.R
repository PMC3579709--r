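# Growth media: reference medium, random media, application to a model.
# A medium is a table of exchange-reaction bounds; uptake is a negative
# lower bound by the usual sign convention (exchange written as export of
# the external metabolite).

#' Construct a medium object
#'
#' @param exchange_id character vector of exchange reaction ids.
#' @param lb,ub bounds per exchange.
#' @param label medium label.
#' @return object of class `medium` (data.frame `exchange_id`, `lb`, `ub`).
#' @export
medium <- function(exchange_id, lb, ub, label = "medium") {
  stopifnot(length(exchange_id) == length(lb), length(lb) == length(ub),
            all(lb <= ub))
  structure(data.frame(exchange_id = exchange_id, lb = lb, ub = ub,
                       stringsAsFactors = FALSE),
            label = label, class = c("medium", "data.frame"))
}

#' Reference (minimal) growth medium
#'
#' Enables uptake exactly for a configured nutrient list — by default a
#' glucose/glycerol carbon supply plus amino- and fatty-acid exchanges —
#' leaves oxygen (and the other always-available exchanges) unconstrained,
#' blocks uptake on every other exchange, and keeps secretion open
#' everywhere. Uptake magnitudes are conventions, not measurements, and are
#' config-exposed: carbon sources default to -10, other nutrients to -1.
#'
#' @param model a `metabolic_model`.
#' @param carbon_sources exchange ids of carbon sources (uptake `carbon_lb`).
#' @param nutrients exchange ids of other nutrients (uptake `nutrient_lb`).
#' @param always_available exchange ids left fully open (lb `-1000`):
#'   oxygen, protons, sulfate, phosphate, water in the default id scheme.
#' @param carbon_lb,nutrient_lb uptake lower bounds.
#' @return a `medium` covering every exchange of the model.
#' @export
reference_medium <- function(model,
                             carbon_sources = character(),
                             nutrients = character(),
                             always_available = character(),
                             carbon_lb = -10, nutrient_lb = -1) {
  ex <- exchange_reactions(model)
  if (!length(ex)) stop("model has no exchange reactions")
  check <- function(ids, what) {
    miss <- setdiff(ids, ex)
    if (length(miss)) {
      warning("reference_medium: no matching exchange for ", what, ": ",
              paste(miss, collapse = ", "), " (skipped)")
    }
    intersect(ids, ex)
  }
  carbon_sources <- check(carbon_sources, "carbon source(s)")
  nutrients <- check(nutrients, "nutrient(s)")
  always_available <- check(always_available, "always-available id(s)")
  lb <- stats::setNames(rep(0, length(ex)), ex)
  lb[carbon_sources] <- carbon_lb
  lb[nutrients] <- nutrient_lb
  lb[always_available] <- -INF_BOUND
  medium(ex, unname(lb), rep(INF_BOUND, length(ex)), label = "reference")
}

#' Draw a random growth medium
#'
#' A fraction `f ~ Uniform(frac_range)` of the model's exchanges is
#' selected (without replacement); each selected exchange receives
#' `lb ~ Uniform(-bound_mag, 0)` and `ub ~ Uniform(0, bound_mag)`. The
#' always-available exchanges are uptake-enabled (lb `-1000`) in every
#' draw; unselected exchanges are uptake-blocked with secretion open.
#'
#' @param model a `metabolic_model`.
#' @param seed RNG seed for a reproducible draw (`NULL` = current RNG).
#' @param frac_range range of the selected-exchange fraction, default
#'   `c(0.04, 1)` — the lower end matching the share of exchanges enabled
#'   in the reference medium.
#' @param bound_mag magnitude of the random bound intervals (default 20).
#' @param always_available exchange ids open in every draw.
#' @return a `medium`; attribute `"selected"` holds the sampled exchange
#'   ids and `"fraction"` the drawn fraction.
#' @export
random_medium <- function(model, seed = NULL, frac_range = c(0.04, 1),
                          bound_mag = 20, always_available = character()) {
  ex <- exchange_reactions(model)
  if (!length(ex)) stop("model has no exchange reactions")
  always_available <- intersect(always_available, ex)
  with_seed(seed, {
    f <- stats::runif(1, frac_range[1], frac_range[2])
    k <- max(1L, round(f * length(ex)))
    sel <- sample(ex, k)
    lb <- stats::setNames(rep(0, length(ex)), ex)
    ub <- stats::setNames(rep(INF_BOUND, length(ex)), ex)
    lb[sel] <- stats::runif(k, -bound_mag, 0)
    ub[sel] <- stats::runif(k, 0, bound_mag)
    lb[always_available] <- -INF_BOUND
    ub[always_available] <- INF_BOUND
    md <- medium(ex, unname(lb), unname(ub), label = "random")
    attr(md, "selected") <- sel
    attr(md, "fraction") <- f
    md
  })
}

#' Apply a medium to a model
#'
#' Overwrites the bounds of every exchange reaction named in the medium;
#' non-exchange bounds are untouched. Applying medium A then medium B over
#' the full exchange set equals applying B alone.
#'
#' @param model a `metabolic_model`.
#' @param medium a `medium`.
#' @return modified `metabolic_model`.
#' @export
apply_medium <- function(model, medium) {
  ex <- exchange_reactions(model)
  bad <- setdiff(medium$exchange_id, ex)
  if (length(bad)) {
    stop("medium references non-exchange reaction(s): ",
         paste(bad, collapse = ", "))
  }
  set_bounds(model, medium$exchange_id, lb = medium$lb, ub = medium$ub)
}

#' Read / write a medium as JSON
#' @param medium a `medium`.
#' @param path file path.
#' @return `path` invisibly, or the `medium` read.
#' @export
write_medium_json <- function(medium, path) {
  jsonlite::write_json(list(label = attr(medium, "label"),
                            exchanges = as.data.frame(medium)),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_medium_json
#' @export
read_medium_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  medium(x$exchanges$exchange_id, x$exchanges$lb, x$exchanges$ub,
         label = x$label %||% "medium")
}
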