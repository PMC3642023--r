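#' CNV call post-filtering, family grouping and signal validation
#'
#' Post-filters published CNV call tables (marker support, marker sparsity,
#' blacklist overlap; separate confident-call thresholds for read-depth
#' calls), groups per-sample calls into family-level regions, assigns
#' inheritance per child carrier, checks segregation with affected status,
#' and computes the two read-level validation signals — normalized sequence
#' count and B-allele frequency — with a rule-based hemizygous-deletion
#' evidence call.
#'
#' @name cnv-analysis
NULL

#' Marker-support filter: keep calls spanning at least `min_snps` markers
#' @param calls CNV call data.frame (see [read_cnv_calls()]).
#' @param min_snps minimum marker count (calls at the threshold kept).
#' @return filtered calls.
#' @export
filter_min_snps <- function(calls, min_snps = 10) {
  stopifnot(!is.null(calls$n_snps))
  calls[calls$n_snps >= min_snps, , drop = FALSE]
}

#' Sparsity filter: drop calls with mean inter-marker distance above a cap
#'
#' The mean gap of a call spanning `n_snps` markers is
#' `span / (n_snps - 1)` (n markers have n-1 gaps). Calls with a single
#' marker have no defined gap and are removed with a warning.
#'
#' @param calls CNV call data.frame.
#' @param max_mean_gap maximum mean inter-marker distance in bp (strictly
#'   above is removed); default 50 kb.
#' @return filtered calls.
#' @export
filter_sparse <- function(calls, max_mean_gap = 50000) {
  single <- calls$n_snps == 1
  if (any(single)) {
    warning(sum(single), " single-marker call(s) removed (inter-marker gap undefined)")
    calls <- calls[!single, , drop = FALSE]
  }
  span <- interval_length(calls$chrom, calls$start, calls$end)
  gap <- span / (calls$n_snps - 1)
  calls[gap <= max_mean_gap, , drop = FALSE]
}

#' Blacklist filter: drop calls mostly inside masked regions
#'
#' Removes calls whose span overlaps any one mask (e.g. immunoglobulin
#' regions, centromeres) by strictly more than `max_frac` of the *call's*
#' length.
#'
#' @param calls CNV call data.frame.
#' @param masks named list of region sets (or coercible data.frames).
#' @param max_frac overlap fraction cutoff (default 0.5).
#' @return filtered calls.
#' @export
filter_blacklist <- function(calls, masks, max_frac = 0.5) {
  if (length(masks) == 0L || nrow(calls) == 0L) return(calls)
  masks <- lapply(masks, as_region_set)
  drop <- vapply(seq_len(nrow(calls)), function(i) {
    any(vapply(masks, function(m)
      overlap_fraction(calls$chrom[i], calls$start[i], calls$end[i], m) > max_frac,
      logical(1)))
  }, logical(1))
  calls[!drop, , drop = FALSE]
}

#' Confident-call thresholds for read-depth (sequence-based) CNV calls
#'
#' Deletions and duplications are modelled differently by read-depth
#' callers, so the confident set uses separate size floors: deletions longer
#' than `del_min_bp`, duplications longer than `dup_min_bp`, each with
#' confidence strictly above `conf_min`. Calls without a confidence score
#' are removed with a warning.
#'
#' @param calls CNV call data.frame with `confidence`.
#' @param del_min_bp,dup_min_bp minimum lengths (strict) in bp.
#' @param conf_min minimum confidence score (strict).
#' @return filtered calls.
#' @export
erds_confident_filter <- function(calls, del_min_bp = 10000, dup_min_bp = 200000,
                                  conf_min = 300) {
  miss <- is.na(calls$confidence)
  if (any(miss)) {
    warning(sum(miss), " call(s) without confidence score removed")
    calls <- calls[!miss, , drop = FALSE]
  }
  len <- interval_length(calls$chrom, calls$start, calls$end)
  min_len <- ifelse(calls$type == "del", del_min_bp, dup_min_bp)
  calls[len > min_len & calls$confidence > conf_min, , drop = FALSE]
}

#' Group per-sample CNV calls into family-level regions
#'
#' Calls of the same kind whose spans overlap reciprocally by at least
#' `reciprocal_min` are merged (transitively) into one family-level region:
#' the union span, with the contributing samples as the carrier set.
#'
#' @param calls CNV call data.frame across family members.
#' @param reciprocal_min minimum reciprocal overlap (default 0.5).
#' @return data.frame with one row per family region: `chrom`, `start`,
#'   `end`, `type`, `carriers` (comma-joined sample ids), `n_calls`.
#' @export
group_family_calls <- function(calls, reciprocal_min = 0.5) {
  n <- nrow(calls)
  if (n == 0L)
    return(data.frame(chrom = character(), start = numeric(), end = numeric(),
                      type = character(), carriers = character(), n_calls = integer()))
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  len <- interval_length(calls$chrom, calls$start, calls$end)
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
    if (calls$type[i] != calls$type[j] || calls$chrom[i] != calls$chrom[j]) next
    ov <- min(calls$end[i], calls$end[j]) - max(calls$start[i], calls$start[j]) + 1
    if (ov <= 0) next
    if (ov / len[i] >= reciprocal_min && ov / len[j] >= reciprocal_min)
      parent[find(i)] <- find(j)
  }
  comp <- vapply(seq_len(n), find, integer(1))
  groups <- split(seq_len(n), comp)
  out <- do.call(rbind, lapply(groups, function(idx) {
    data.frame(chrom = calls$chrom[idx[1]],
               start = min(calls$start[idx]), end = max(calls$end[idx]),
               type = calls$type[idx[1]],
               carriers = paste(sort(unique(calls$sample[idx])), collapse = ","),
               n_calls = length(idx), stringsAsFactors = FALSE)
  }))
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

carrier_ids <- function(region) strsplit(region$carriers, ",", fixed = TRUE)[[1]]

#' Inheritance of family-level CNV regions
#'
#' For every child in a region's carrier set: inherited-from-father if the
#' father carries the same family-level region, inherited-from-mother if the
#' mother does (both, if both do), otherwise a de-novo candidate.
#'
#' @param regions output of [group_family_calls()].
#' @param ped a [pedigree()].
#' @return data.frame with one row per (region, child carrier):
#'   `region_id`, `chrom`, `start`, `end`, `type`, `child`, `inheritance`
#'   (one of `"father"`, `"mother"`, `"both"`, `"de_novo_candidate"`).
#' @export
assess_inheritance <- function(regions, ped) {
  fa <- ped_father(ped); mo <- ped_mother(ped)
  rows <- lapply(seq_len(nrow(regions)), function(i) {
    carriers <- carrier_ids(regions[i, ])
    kids <- intersect(carriers, ped_children(ped))
    if (!length(kids)) return(NULL)
    from_f <- fa %in% carriers; from_m <- mo %in% carriers
    lab <- if (from_f && from_m) "both" else if (from_f) "father" else
      if (from_m) "mother" else "de_novo_candidate"
    data.frame(region_id = i, chrom = regions$chrom[i], start = regions$start[i],
               end = regions$end[i], type = regions$type[i], child = kids,
               inheritance = lab, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(region_id = integer(), chrom = character(), start = numeric(),
                      end = numeric(), type = character(), child = character(),
                      inheritance = character())
  out
}

#' Does a CNV region segregate with affected status?
#'
#' TRUE iff the region's child carriers are exactly the affected children.
#' Parents are exempt: an unaffected transmitting parent is expected under
#' incomplete penetrance.
#'
#' @param region one row of [group_family_calls()] output.
#' @param ped a [pedigree()].
#' @return logical.
#' @export
segregation_check <- function(region, ped) {
  kids <- intersect(carrier_ids(region), ped_children(ped))
  setequal(kids, ped_probands(ped))
}

#' B-allele frequency from a site pileup
#'
#' Fraction of reads supporting the non-reference allele; NA where the site
#' has no reads.
#'
#' @param ref_count,alt_count non-negative read counts (vectorised).
#' @return numeric vector in \[0,1\] with NA at zero-coverage sites.
#' @export
compute_baf <- function(ref_count, alt_count) {
  tot <- ref_count + alt_count
  ifelse(tot > 0, alt_count / tot, NA_real_)
}

#' Normalized sequence count (read depth) track
#'
#' Divides raw per-position depth by the sample's diploid baseline (its
#' genome-wide median depth), so two copies sit near 1.0 and a hemizygous
#' deletion near 0.5. Positions are tagged with `is_snv` so BAF is only
#' interpreted at SNV sites.
#'
#' @param pileup data.frame with `chrom`, `pos`, `ref_count`, `alt_count`
#'   and optionally `is_snv` (default: sites with any alternate read).
#' @param baseline sample diploid baseline depth; default the median total
#'   depth of the pileup.
#' @return data.frame with `chrom`, `pos`, `sequence_count`, `baf`,
#'   `is_snv`.
#' @export
compute_sequence_count <- function(pileup, baseline = NULL) {
  tot <- pileup$ref_count + pileup$alt_count
  if (is.null(baseline)) baseline <- stats::median(tot)
  if (is.na(baseline) || baseline <= 0) stop("baseline depth must be > 0")
  is_snv <- if (!is.null(pileup$is_snv)) as.logical(pileup$is_snv) else pileup$alt_count > 0
  data.frame(chrom = pileup$chrom, pos = pileup$pos,
             sequence_count = tot / baseline,
             baf = ifelse(is_snv, compute_baf(pileup$ref_count, pileup$alt_count), NA_real_),
             is_snv = is_snv, stringsAsFactors = FALSE)
}

#' Rule-based evidence for a hemizygous (1-copy) deletion
#'
#' A region supports a 1-copy deletion when its mean normalized sequence
#' count is below `depth_max` AND the fraction of its SNV sites with BAF
#' inside the heterozygous band is below `het_frac_max` (hemizygous former
#' het sites collapse to BAF 0 or 1, so the 0.5 cluster disappears). A
#' region without SNV sites is decided on depth alone and flagged.
#'
#' @param region list/row with `chrom`, `start`, `end`.
#' @param track signal track from [compute_sequence_count()].
#' @param depth_max mean sequence-count threshold (default 0.75).
#' @param het_band BAF interval treated as heterozygous (default
#'   \[0.25, 0.75\]).
#' @param het_frac_max maximum fraction of SNV sites in the het band
#'   (default 0.1).
#' @return list with `deletion` (logical), `mean_sequence_count`,
#'   `het_fraction` (NA when no SNV sites), `n_sites`, `n_snv_sites`,
#'   `no_het_sites` flag.
#' @export
deletion_evidence <- function(region, track, depth_max = 0.75,
                              het_band = c(0.25, 0.75), het_frac_max = 0.1) {
  sel <- track$chrom == region$chrom & track$pos >= region$start & track$pos <= region$end
  if (!any(sel)) stop("region has no overlap with the signal track")
  t <- track[sel, , drop = FALSE]
  mean_sc <- mean(t$sequence_count)
  snv <- t[t$is_snv & !is.na(t$baf), , drop = FALSE]
  if (nrow(snv) == 0L) {
    return(list(deletion = mean_sc < depth_max, mean_sequence_count = mean_sc,
                het_fraction = NA_real_, n_sites = nrow(t), n_snv_sites = 0L,
                no_het_sites = TRUE))
  }
  het_frac <- mean(snv$baf >= het_band[1] & snv$baf <= het_band[2])
  list(deletion = mean_sc < depth_max && het_frac < het_frac_max,
       mean_sequence_count = mean_sc, het_fraction = het_frac,
       n_sites = nrow(t), n_snv_sites = nrow(snv), no_het_sites = FALSE)
}
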