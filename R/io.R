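#' Readers and writers for the standard formats of the pipeline
#'
#' BED files are 0-based half-open on disk and converted to the package's
#' 1-based inclusive convention on read (and back on write). TSV tables carry
#' a header line; parsers reject duplicate identifiers and report the
#' offending line number.
#'
#' @name famprior-io
NULL

#' Read/write BED
#'
#' `read_bed()` returns a data.frame with 1-based inclusive `chrom`, `start`,
#' `end` plus `name` and `score` columns when present in the file.
#' `write_bed()` accepts any data.frame with those columns.
#'
#' @param path file path.
#' @param strip_chr_prefix if `TRUE`, a leading `"chr"` is removed from
#'   chromosome names on read (to reconcile "chr1" vs "1" dialects).
#' @return data.frame (see above).
#' @export
read_bed <- function(path, strip_chr_prefix = FALSE) {
  gr <- rtracklayer::import(path, format = "BED")
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = as.numeric(GenomicRanges::start(gr)),
                   end = as.numeric(GenomicRanges::end(gr)),
                   stringsAsFactors = FALSE)
  md <- S4Vectors::mcols(gr)
  if (!is.null(md$name)) df$name <- as.character(md$name)
  if (!is.null(md$score)) df$score <- as.numeric(md$score)
  if (strip_chr_prefix) df$chrom <- sub("^chr", "", df$chrom)
  df
}

#' @rdname read_bed
#' @param df data.frame with `chrom`, `start`, `end` (1-based inclusive) and
#'   optionally `name`, `score`.
#' @export
write_bed <- function(df, path) {
  validate_intervals(as.character(df$chrom), df$start, df$end)
  gr <- as_granges(df$chrom, df$start, df$end)
  if (!is.null(df$name)) S4Vectors::mcols(gr)$name <- df$name
  if (!is.null(df$score)) S4Vectors::mcols(gr)$score <- df$score
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Read variant calls from a VCF file
#'
#' Returns one row per bi-allelic alternate allele (multi-allelic records are
#' decomposed). Zygosity is derived from the first sample's GT field and the
#' quality score from QUAL, on the caller's 10*log10[P(true)/P(false)] scale.
#'
#' @param path VCF (v4.x) file, plain or gzipped.
#' @return data.frame with columns `chrom`, `pos`, `end`, `ref`, `alt`,
#'   `quality`, `zygosity` (`"het"`/`"hom"`) and `key`
#'   (`chrom:pos:ref:alt`).
#' @export
read_vcf_variants <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  gt <- vcfR::extract.gt(v, element = "GT")
  rows <- lapply(seq_len(nrow(fix)), function(i) {
    alts <- strsplit(fix[i, "ALT"], ",", fixed = TRUE)[[1]]
    g <- gt[i, 1]
    alleles <- if (is.na(g)) integer() else
      suppressWarnings(as.integer(strsplit(g, "[/|]")[[1]]))
    out <- lapply(seq_along(alts), function(k) {
      carried <- sum(alleles == k, na.rm = TRUE)
      if (carried == 0L) return(NULL)
      data.frame(chrom = fix[i, "CHROM"],
                 pos = as.numeric(fix[i, "POS"]),
                 ref = fix[i, "REF"], alt = alts[k],
                 quality = suppressWarnings(as.numeric(fix[i, "QUAL"])),
                 zygosity = if (carried >= 2L) "hom" else "het",
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, out)
  })
  df <- do.call(rbind, rows)
  if (is.null(df)) {
    df <- data.frame(chrom = character(), pos = numeric(), ref = character(),
                     alt = character(), quality = numeric(), zygosity = character())
  }
  df$end <- df$pos + pmax(nchar(df$ref), 1L) - 1L
  df$key <- variant_key(df)
  df[c("chrom", "pos", "end", "ref", "alt", "quality", "zygosity", "key")]
}

#' Canonical variant identifier `chrom:pos:ref:alt`
#' @param df data.frame with `chrom`, `pos`, `ref`, `alt`.
#' @return character vector.
#' @export
variant_key <- function(df) {
  paste(df$chrom, format(df$pos, scientific = FALSE, trim = TRUE),
        df$ref, df$alt, sep = ":")
}

#' Write variants to a minimal VCF v4.2 file
#'
#' One single-sample record per variant with GT (0/1 for het, 1/1 for hom)
#' and the call quality in QUAL. Written as plain text so emitted fixtures
#' stay inspectable.
#'
#' @param df data.frame with `chrom`, `pos`, `ref`, `alt`, `quality`,
#'   `zygosity`.
#' @param path output path.
#' @param sample sample name for the genotype column.
#' @export
write_vcf <- function(df, path, sample = "SAMPLE") {
  hdr <- c("##fileformat=VCFv4.2",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t", sample))
  df <- df[order(df$chrom, df$pos), , drop = FALSE]
  qual <- ifelse(is.na(df$quality), ".", format(df$quality, scientific = FALSE, trim = TRUE))
  gt <- ifelse(df$zygosity == "hom", "1/1", "0/1")
  rec <- paste(df$chrom, format(df$pos, scientific = FALSE, trim = TRUE), ".",
               df$ref, df$alt, qual, "PASS", ".", "GT", gt, sep = "\t")
  writeLines(c(hdr, rec), path)
  invisible(path)
}

#' Read a TSV table with a header, rejecting duplicate identifiers
#'
#' @param path file path.
#' @param id_cols columns whose combination must be unique; a violation stops
#'   with the 1-based data line number of the first duplicate.
#' @return data.frame.
#' @export
read_tsv_table <- function(path, id_cols = NULL) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (!is.null(id_cols)) {
    missing <- setdiff(id_cols, names(df))
    if (length(missing)) stop("missing column(s) ", paste(missing, collapse = ", "),
                              " in ", path)
    key <- do.call(paste, c(df[id_cols], sep = "\r"))
    dup <- which(duplicated(key))
    if (length(dup))
      stop(sprintf("duplicate id '%s' at line %d of %s",
                   gsub("\r", ":", key[dup[1]]), dup[1] + 1L, path))
  }
  df
}

#' Write a TSV table
#' @param df data.frame.
#' @param path output path.
#' @export
write_tsv_table <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a CNV call table
#'
#' Expected columns: `chrom`, `start`, `end`, `type` (`del`/`dup`), `sample`,
#' `n_snps`; optional `confidence` and any extra columns are kept.
#'
#' @param path TSV file.
#' @return data.frame of calls.
#' @export
read_cnv_calls <- function(path) {
  df <- read_tsv_table(path)
  need <- c("chrom", "start", "end", "type", "sample", "n_snps")
  missing <- setdiff(need, names(df))
  if (length(missing)) stop("CNV table missing column(s): ", paste(missing, collapse = ", "))
  if (!all(df$type %in% c("del", "dup")))
    stop("CNV type must be 'del' or 'dup'")
  df$sample <- as.character(df$sample)
  validate_intervals(df$chrom, df$start, df$end)
  df
}

#' Read a site pileup table (`chrom`, `pos`, `ref_count`, `alt_count`)
#' @param path TSV file.
#' @return data.frame.
#' @export
read_pileup <- function(path) {
  df <- read_tsv_table(path, id_cols = c("chrom", "pos"))
  stopifnot(all(c("ref_count", "alt_count") %in% names(df)))
  if (any(df$ref_count < 0 | df$alt_count < 0)) stop("negative read counts")
  df
}
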