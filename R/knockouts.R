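# The in silico knockout machinery: the 10 gut knockout variants, the 15
# combination sets, and indicator-gated application to a model.

#' Catalogue of the 10 gut knockout variants
#'
#' Four passive-diffusion knockouts (one per gut segment, affecting
#' ester, butanediol and BHB absorption into portal) and an
#' apical/basolateral active-transport pair for each of the three
#' transporter-expressing segments (affecting BHB only).
#'
#' @return Data frame with columns `variant`, `process`, `region`,
#'   `substrates` (comma-separated).
#' @export
ko_catalogue <- function() {
  passive_subs <- "ester, butanediol, BHB"
  data.frame(
    variant = 1:10,
    process = c("passive", "passive", "active_apical", "active_basolateral",
                "passive", "active_apical", "active_basolateral",
                "passive", "active_apical", "active_basolateral"),
    region = c("upper_proximal", "lower_proximal", "lower_proximal",
               "lower_proximal", "upper_distal", "upper_distal",
               "upper_distal", "lower_distal", "lower_distal",
               "lower_distal"),
    substrates = c(passive_subs, passive_subs, "BHB", "BHB", passive_subs,
                   "BHB", "BHB", passive_subs, "BHB", "BHB"),
    stringsAsFactors = FALSE
  )
}

#' The 15 explored knockout combination sets
#'
#' @return Data frame with columns `set`, `variants` (list column of
#'   integer vectors), `process`, `region`.
#' @export
ko_sets <- function() {
  variants <- list(
    1L, 2L, 5L, 8L, c(3L, 4L), c(6L, 7L), c(9L, 10L), 1L,
    c(2L, 3L, 4L), c(5L, 6L, 7L), c(8L, 9L, 10L),
    c(1L, 2L, 5L, 8L), c(3L, 4L, 6L, 7L, 9L, 10L),
    c(1L, 2L, 3L, 4L), c(5L, 6L, 7L, 8L, 9L, 10L)
  )
  data.frame(
    set = 1:15,
    variants = I(variants),
    process = c("passive", "passive", "passive", "passive",
                "active", "active", "active", "passive",
                "passive+active", "passive+active", "passive+active",
                "passive", "active", "passive+active", "passive+active"),
    region = c("upper_proximal", "lower_proximal", "upper_distal",
               "lower_distal", "lower_proximal", "upper_distal",
               "lower_distal", "upper_proximal", "lower_proximal",
               "upper_distal", "lower_distal", "whole_gut", "whole_gut",
               "proximal_gut", "distal_gut"),
    stringsAsFactors = FALSE
  )
}

#' Apply a knockout set (or explicit variant list) to a model
#'
#' Sets `indicator = 0` on every process tagged with any of the member
#' variants; all processes were tagged at build time, so the Table of
#' variants maps one-to-one onto process groups. The original model is
#' untouched; applying an empty set returns a trajectory-identical
#' clone. Application is idempotent and order-independent.
#'
#' @param model a `keto_model` built with knockout tags.
#' @param set a set id (1..15) from [ko_sets()].
#' @param variants explicit integer vector of variant ids (1..10);
#'   overrides `set`.
#' @return A knocked-out `keto_model` clone.
#' @export
ko_apply <- function(model, set = NULL, variants = NULL) {
  if (is.null(variants)) {
    if (is.null(set)) variants <- integer(0)
    else {
      sets <- ko_sets()
      if (!set %in% sets$set) stop("unknown knockout set: ", set)
      variants <- sets$variants[[match(set, sets$set)]]
    }
  }
  variants <- as.integer(variants)
  if (length(variants) && !all(variants %in% 1:10))
    stop("unknown variant id(s): ",
         paste(setdiff(variants, 1:10), collapse = ", "))
  if (!length(variants)) return(model)
  model_clone(model, tags = as.character(variants), tag_value = 0L)
}
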