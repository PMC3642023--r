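#' The coding variants-reduction funnel
#'
#' Reduces a proband's whole-genome variant calls to candidate recessive
#' genes: call-quality filter, restriction to splicing/protein-altering
#' classes, rarity against reference allele-frequency databases, a recessive
#' gene model (two deleterious hits per gene), intersection between the two
#' probands, and an alternative shared-variant deleteriousness strategy
#' (SIFT/PolyPhen/GERP++ thresholds) that makes no inheritance-model
#' assumption.
#'
#' @name coding-funnel
NULL

#' Default funnel configuration
#'
#' Thresholds of the prioritization pipeline: quality minimums by zygosity,
#' the MAF cutoff applied per database, and the deleteriousness score
#' thresholds.
#'
#' @param quality_hom_min,quality_het_min minimum call quality (on the
#'   10*log10 odds scale) for homozygous resp. heterozygous calls.
#' @param maf_threshold variants with MAF strictly above this in any database
#'   are removed.
#' @param maf_databases names of the `maf_` columns consulted.
#' @param sift_max,polyphen_min,gerp_min deleteriousness thresholds (SIFT
#'   strictly below, PolyPhen and GERP++ strictly above).
#' @param missing_passes whether a missing score passes its own criterion
#'   (frameshift and splicing variants typically carry no SIFT/PolyPhen).
#' @param splice_window canonical splice-site window in bp.
#' @return named list of settings.
#' @export
funnel_config <- function(quality_hom_min = 20, quality_het_min = 40,
                          maf_threshold = 0.01,
                          maf_databases = c("g1000", "esp5400", "cg46"),
                          sift_max = 0.05, polyphen_min = 0.85, gerp_min = 2.0,
                          missing_passes = TRUE, splice_window = 2L) {
  stopifnot(maf_threshold > 0, maf_threshold <= 0.5)
  list(quality_hom_min = quality_hom_min, quality_het_min = quality_het_min,
       maf_threshold = maf_threshold, maf_databases = maf_databases,
       sift_max = sift_max, polyphen_min = polyphen_min, gerp_min = gerp_min,
       missing_passes = missing_passes, splice_window = splice_window)
}

#' Call-quality filter
#'
#' Removes homozygous calls with quality below `hom_min` and heterozygous
#' calls with quality below `het_min`; calls with no quality score are
#' removed (an upstream caller omission) and counted in the attached
#' `n_missing_quality` attribute.
#'
#' @param variants data.frame with `zygosity` and `quality`.
#' @param hom_min,het_min thresholds (calls at the threshold are retained).
#' @return filtered data.frame (order preserved).
#' @export
filter_by_quality <- function(variants, hom_min = 20, het_min = 40) {
  stopifnot(all(variants$zygosity %in% c("het", "hom")))
  miss <- is.na(variants$quality)
  keep <- !miss & ifelse(variants$zygosity == "hom",
                         variants$quality >= hom_min,
                         variants$quality >= het_min)
  out <- variants[keep, , drop = FALSE]
  attr(out, "n_missing_quality") <- sum(miss)
  out
}

#' Keep splicing / protein-altering classes
#'
#' Retains `nonsynonymous`, `stopgain`, `stoploss`, `frameshift`,
#' `nonframeshift` and `splicing`; synonymous and all non-coding classes are
#' removed.
#'
#' @param variants classified variants (with `function_class`).
#' @return filtered data.frame.
#' @export
filter_coding_changes <- function(variants) {
  stopifnot(all(variants$function_class %in% FUNCTION_CLASSES))
  variants[variants$function_class %in% CODING_CLASSES, , drop = FALSE]
}

#' Keep the complement: non-coding classes only
#' @rdname filter_coding_changes
#' @export
filter_noncoding <- function(variants) {
  stopifnot(all(variants$function_class %in% FUNCTION_CLASSES))
  variants[!variants$function_class %in% CODING_CLASSES, , drop = FALSE]
}

#' Population-frequency (rarity) filter
#'
#' A variant is removed iff its MAF is strictly above `threshold` in ANY of
#' the listed databases; a variant absent from every database (NA) is
#' retained. Database `x` is read from column `maf_x`.
#'
#' @param variants data.frame carrying `maf_*` columns.
#' @param databases database names to consult.
#' @param threshold MAF cutoff (default 0.01, i.e. 1%).
#' @return filtered data.frame.
#' @export
filter_by_frequency <- function(variants, databases = c("g1000", "esp5400", "cg46"),
                                threshold = 0.01) {
  stopifnot(threshold > 0, threshold <= 0.5)
  cols <- paste0("maf_", databases)
  missing <- setdiff(cols, names(variants))
  if (length(missing))
    stop("unknown frequency database column(s): ", paste(missing, collapse = ", "))
  if (nrow(variants) == 0L) return(variants)
  m <- as.matrix(variants[cols])
  if (any(m > 0.5 | m < 0, na.rm = TRUE)) stop("MAF values must lie in [0, 0.5]")
  common <- apply(m, 1L, function(x) any(!is.na(x) & x > threshold))
  variants[!common, , drop = FALSE]
}

#' Deleteriousness score filter
#'
#' Retains variants with SIFT < `sift_max`, PolyPhen > `polyphen_min` and
#' GERP++ > `gerp_min`. With `missing_passes = TRUE` each missing score
#' passes its own criterion, so unscored frameshift/splicing variants
#' survive; with `FALSE` no unscored variant survives.
#'
#' @param variants data.frame with `sift`, `polyphen`, `gerp` columns.
#' @param sift_max,polyphen_min,gerp_min thresholds.
#' @param missing_passes see above.
#' @return filtered data.frame.
#' @export
deleteriousness_filter <- function(variants, sift_max = 0.05, polyphen_min = 0.85,
                                   gerp_min = 2.0, missing_passes = TRUE) {
  ok1 <- variants$sift < sift_max
  ok2 <- variants$polyphen > polyphen_min
  ok3 <- variants$gerp > gerp_min
  fill <- function(ok) ifelse(is.na(ok), missing_passes, ok)
  variants[fill(ok1) & fill(ok2) & fill(ok3), , drop = FALSE]
}

#' Recessive gene model: genes with two deleterious hits
#'
#' A gene qualifies iff it carries at least one homozygous qualifying variant
#' or at least two distinct heterozygous qualifying variants (compound
#' heterozygote); a single homozygous hit supplies both alleles. Variants
#' without a gene assignment are ignored. Phase between compound-het pairs
#' is not checked at this stage (no parental genotypes are consumed here).
#'
#' @param variants one proband's coding- and rarity-filtered variants.
#' @return named list: gene -> data.frame of its supporting variants.
#' @export
recessive_gene_candidates <- function(variants) {
  v <- variants[!is.na(variants$gene), , drop = FALSE]
  if (nrow(v) == 0L) return(stats::setNames(list(), character()))
  v <- v[!duplicated(v$key), , drop = FALSE]
  by_gene <- split(v, v$gene)
  hits <- Filter(function(g) any(g$zygosity == "hom") || sum(g$zygosity == "het") >= 2,
                 by_gene)
  hits[order(names(hits))]
}

#' Genes supported in both probands
#' @param a,b per-proband candidate maps from [recessive_gene_candidates()].
#' @return sorted character vector of shared gene symbols.
#' @export
shared_candidates <- function(a, b) {
  sort(intersect(as.character(names(a)), as.character(names(b))))
}

new_funnel_report <- function() {
  data.frame(stage = character(), scope = character(),
             n_in = integer(), n_out = integer(), stringsAsFactors = FALSE)
}

add_stage <- function(report, stage, scope, n_in, n_out) {
  if (n_out > n_in) stop("funnel stage increased variant count: ", stage)
  rbind(report, data.frame(stage = stage, scope = scope,
                           n_in = n_in, n_out = n_out, stringsAsFactors = FALSE))
}

run_stage <- function(state, report, stage, scope, f) {
  out <- tryCatch(f(state), error = function(e)
    stop(sprintf("funnel stage '%s' (%s) failed: %s", stage, scope, conditionMessage(e)),
         call. = FALSE))
  list(state = out, report = add_stage(report, stage, scope, nrow(state), nrow(out)))
}

#' Run the full coding funnel on two probands
#'
#' Chains quality filter, functional classification, restriction to coding
#' changes, the three-database rarity filter and the recessive gene model on
#' each proband, then intersects candidate genes between the probands. Also
#' runs the alternative model-free strategy: the rare coding variants shared
#' by both probands, passed through the deleteriousness score filter.
#'
#' @param p1,p2 per-proband variant data.frames (as from
#'   [read_vcf_variants()], joined with `maf_*` and score columns; if
#'   `function_class` is absent, `genes` must be supplied for
#'   classification).
#' @param genes list of [gene_model()]s (optional when variants are already
#'   classified).
#' @param config a [funnel_config()].
#' @return list with `candidates` (per-proband gene maps), `shared_genes`,
#'   `shared_deleterious` (the model-free shared-variant list) and `report`
#'   (stage/scope/n_in/n_out data.frame).
#' @export
run_coding_funnel <- function(p1, p2, genes = NULL, config = funnel_config()) {
  report <- new_funnel_report()
  per_proband <- list()
  rare <- list()
  for (nm in c("proband1", "proband2")) {
    v <- if (nm == "proband1") p1 else p2
    st <- run_stage(v, report, "quality", nm, function(x)
      filter_by_quality(x, config$quality_hom_min, config$quality_het_min))
    v <- st$state; report <- st$report
    if (is.null(v$function_class)) {
      if (is.null(genes)) stop("variants are unclassified and no gene models supplied")
      v <- classify_variants(v, genes, config$splice_window)
    }
    st <- run_stage(v, report, "coding_change", nm, filter_coding_changes)
    v <- st$state; report <- st$report
    st <- run_stage(v, report, "rarity", nm, function(x)
      filter_by_frequency(x, config$maf_databases, config$maf_threshold))
    v <- st$state; report <- st$report
    rare[[nm]] <- v
    cand <- recessive_gene_candidates(v)
    report <- add_stage(report, "recessive_genes", nm, nrow(v), length(cand))
    per_proband[[nm]] <- cand
  }
  shared_genes <- shared_candidates(per_proband$proband1, per_proband$proband2)
  report <- add_stage(report, "shared_genes", "both",
                      max(length(per_proband$proband1), length(per_proband$proband2)),
                      length(shared_genes))
  shared_keys <- intersect(rare$proband1$key, rare$proband2$key)
  shared_v <- rare$proband1[rare$proband1$key %in% shared_keys, , drop = FALSE]
  report <- add_stage(report, "shared_variants", "both", nrow(rare$proband1), nrow(shared_v))
  deleterious <- deleteriousness_filter(shared_v, config$sift_max,
                                        config$polyphen_min, config$gerp_min,
                                        config$missing_passes)
  report <- add_stage(report, "deleterious_shared", "both", nrow(shared_v), nrow(deleterious))
  list(candidates = per_proband, shared_genes = shared_genes,
       shared_deleterious = deleterious, report = report)
}
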