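#' Join variants with annotation resources
#'
#' Classifies variants against gene models (when not already classified) and
#' joins the per-database MAF and deleteriousness score tables by the
#' canonical `chrom:pos:ref:alt` key. Variants absent from a table get NA
#' (absent from all databases = never observed, which the rarity filter
#' retains).
#'
#' @param variants data.frame from [read_vcf_variants()].
#' @param freqs data.frame with `key` and `maf_*` columns.
#' @param scores data.frame with `key`, `sift`, `polyphen`, `gerp`.
#' @param genes list of [gene_model()]s (optional if `function_class`
#'   already present).
#' @param splice_window canonical splice-site window in bp.
#' @return annotated variant data.frame.
#' @export
annotate_variants <- function(variants, freqs = NULL, scores = NULL,
                              genes = NULL, splice_window = 2L) {
  v <- variants
  if (is.null(v$key)) v$key <- variant_key(v)
  if (is.null(v$function_class)) {
    if (is.null(genes)) stop("no gene models supplied for classification")
    v <- classify_variants(v, genes, splice_window)
  }
  if (!is.null(freqs)) {
    stopifnot("key" %in% names(freqs))
    v <- merge(v, freqs, by = "key", all.x = TRUE, sort = FALSE)
  }
  if (!is.null(scores)) {
    stopifnot("key" %in% names(scores))
    v <- merge(v, scores, by = "key", all.x = TRUE, sort = FALSE)
  }
  v[order(v$chrom, v$pos), , drop = FALSE]
}
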