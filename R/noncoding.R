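#' The non-coding variants-reduction funnel
#'
#' Restricts shared rare variants to non-coding classes, then to positions
#' inside evolutionarily constrained elements (GERP++ rejected-substitution
#' elements with score > 2), then to positions inside 'active promoter'
#' (chromHMM state 1) or 'strong enhancer' (states 4 and 5) chromatin-state
#' intervals from a 15-state segmentation.
#'
#' @name noncoding-funnel
NULL

DEFAULT_STATE_CLASSES <- c("1" = "active promoter",
                           "4" = "strong enhancer",
                           "5" = "strong enhancer")

point_in_intervals <- function(variants, iv) {
  # index of the first interval containing each variant position (NA if none)
  if (nrow(variants) == 0L || nrow(iv) == 0L)
    return(rep(NA_integer_, nrow(variants)))
  q <- as_granges(variants$chrom, variants$pos, variants$pos)
  s <- as_granges(iv$chrom, iv$start, iv$end)
  hits <- GenomicRanges::findOverlaps(q, s, select = "first")
  as.integer(hits)
}

#' Keep variants inside conserved elements
#'
#' @param variants data.frame with `chrom`, `pos`.
#' @param elements data.frame of conserved elements with `chrom`, `start`,
#'   `end`, `score` (element-level GERP++ score), e.g. from [read_bed()].
#' @param score_min retain only elements with score strictly above this.
#' @return filtered data.frame with an `element_score` column.
#' @export
filter_conserved <- function(variants, elements, score_min = 2.0) {
  stopifnot(all(c("chrom", "start", "end", "score") %in% names(elements)))
  el <- elements[is.finite(elements$score) & elements$score > score_min, , drop = FALSE]
  idx <- point_in_intervals(variants, el)
  out <- variants[!is.na(idx), , drop = FALSE]
  out$element_score <- el$score[idx[!is.na(idx)]]
  out
}

#' Keep variants in selected chromatin states
#'
#' @param variants data.frame with `chrom`, `pos`.
#' @param states data.frame with `chrom`, `start`, `end` and `state` (integer
#'   1..15) or a `name` column holding the state number.
#' @param keep named character vector mapping kept state numbers to class
#'   labels (default: state 1 = active promoter, states 4 and 5 = strong
#'   enhancer).
#' @return filtered data.frame with `state` and `state_class` columns.
#' @export
filter_chromatin_state <- function(variants, states, keep = DEFAULT_STATE_CLASSES) {
  if (is.null(states$state)) {
    if (is.null(states$name)) stop("state map needs a 'state' or 'name' column")
    states$state <- as.integer(sub("^E", "", states$name))
  }
  if (any(is.na(states$state)) || any(states$state < 1 | states$state > 15))
    stop("chromatin states must be integers in 1..15")
  sel <- states[as.character(states$state) %in% names(keep), , drop = FALSE]
  idx <- point_in_intervals(variants, sel)
  out <- variants[!is.na(idx), , drop = FALSE]
  st <- sel$state[idx[!is.na(idx)]]
  out$state <- st
  out$state_class <- unname(keep[as.character(st)])
  out
}

#' Run the non-coding funnel
#'
#' Per proband: restrict to non-coding classes and apply the three-database
#' rarity filter; intersect the probands' surviving variants; then apply the
#' conserved-element and chromatin-state filters to the shared list.
#'
#' @param p1,p2 classified per-proband variant data.frames with `maf_*`
#'   columns.
#' @param elements conserved-element table (see [filter_conserved()]).
#' @param states chromatin-state table (see [filter_chromatin_state()]).
#' @param config a [funnel_config()].
#' @param keep_states state-to-class map.
#' @return list with `prioritized` (surviving variants with element score and
#'   state class) and `report`.
#' @export
run_noncoding_funnel <- function(p1, p2, elements, states,
                                 config = funnel_config(),
                                 keep_states = DEFAULT_STATE_CLASSES) {
  report <- new_funnel_report()
  rare <- list()
  for (nm in c("proband1", "proband2")) {
    v <- if (nm == "proband1") p1 else p2
    st <- run_stage(v, report, "noncoding", nm, filter_noncoding)
    v <- st$state; report <- st$report
    st <- run_stage(v, report, "rarity", nm, function(x)
      filter_by_frequency(x, config$maf_databases, config$maf_threshold))
    v <- st$state; report <- st$report
    rare[[nm]] <- v
  }
  shared_keys <- intersect(rare$proband1$key, rare$proband2$key)
  v <- rare$proband1[rare$proband1$key %in% shared_keys, , drop = FALSE]
  report <- add_stage(report, "shared", "both", nrow(rare$proband1), nrow(v))
  st <- run_stage(v, report, "conserved_element", "both", function(x)
    filter_conserved(x, elements, config$gerp_min))
  v <- st$state; report <- st$report
  st <- run_stage(v, report, "chromatin_state", "both", function(x)
    filter_chromatin_state(x, states, keep_states))
  v <- st$state; report <- st$report
  list(prioritized = v, report = report)
}
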