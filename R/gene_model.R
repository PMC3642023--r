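#' Gene models and functional classification of variants
#'
#' A gene model is a transcript: ordered non-overlapping exons, an optional
#' CDS span, and (for coding genes) the coding-strand CDS sequence used for
#' codon lookup. Classification assigns each variant exactly one function
#' class with precedence exonic/splicing > UTR > intronic >
#' upstream/downstream > intergenic; across overlapping transcripts a variant
#' takes its most deleterious classification.
#'
#' @name gene-models
NULL

FUNCTION_CLASSES <- c("stopgain", "stoploss", "frameshift", "splicing",
                      "nonsynonymous", "nonframeshift", "synonymous", "UTR",
                      "noncoding_gene", "intronic", "upstream", "downstream",
                      "intergenic")

CODING_CLASSES <- c("nonsynonymous", "stopgain", "stoploss", "frameshift",
                    "nonframeshift", "splicing")

#' Construct a gene model
#'
#' @param gene gene symbol.
#' @param chrom chromosome.
#' @param strand `"+"` or `"-"`.
#' @param exon_start,exon_end sorted vectors of 1-based inclusive exon
#'   coordinates.
#' @param cds_start,cds_end CDS span (NA for non-coding genes).
#' @param cds_seq coding-strand CDS sequence (A/C/G/T), length equal to the
#'   summed CDS exon widths; required for codon-level SNV classification.
#' @return list of class `gene_model`.
#' @export
gene_model <- function(gene, chrom, strand, exon_start, exon_end,
                       cds_start = NA, cds_end = NA, cds_seq = NA) {
  stopifnot(strand %in% c("+", "-"), length(exon_start) == length(exon_end))
  o <- order(exon_start)
  exon_start <- exon_start[o]; exon_end <- exon_end[o]
  validate_intervals(rep(chrom, length(exon_start)), exon_start, exon_end)
  if (any(utils::head(exon_end, -1) >= utils::tail(exon_start, -1) - 0))
    stop("exons must be non-overlapping and sorted: ", gene)
  g <- list(gene = gene, chrom = chrom, strand = strand,
            exon_start = exon_start, exon_end = exon_end,
            cds_start = as.numeric(cds_start), cds_end = as.numeric(cds_end),
            cds_seq = if (is.na(cds_seq)) NA_character_ else toupper(cds_seq),
            coding = !is.na(cds_start))
  if (g$coding) {
    s <- pmax(g$exon_start, g$cds_start)
    e <- pmin(g$exon_end, g$cds_end)
    keep <- s <= e
    g$cds <- data.frame(start = s[keep], end = e[keep])  # cached: hot path
    if (!is.na(g$cds_seq) && nchar(g$cds_seq) != sum(g$cds$end - g$cds$start + 1))
      stop("cds_seq length does not match CDS width: ", gene)
  }
  class(g) <- "gene_model"
  g
}

cds_intervals <- function(g) {
  if (!is.null(g$cds)) return(g$cds)
  s <- pmax(g$exon_start, g$cds_start)
  e <- pmin(g$exon_end, g$cds_end)
  keep <- s <= e
  data.frame(start = s[keep], end = e[keep])
}

#' Read/write gene model tables
#'
#' TSV with one row per transcript: `gene`, `chrom`, `strand`,
#' `exon_starts`/`exon_ends` (comma-separated), `cds_start`, `cds_end`,
#' `cds_seq` (empty for non-coding genes).
#'
#' @param path TSV file.
#' @return list of [gene_model()]s.
#' @export
read_gene_models <- function(path) {
  df <- read_tsv_table(path, id_cols = "gene")
  lapply(seq_len(nrow(df)), function(i) {
    cseq <- df$cds_seq[i]
    gene_model(gene = df$gene[i], chrom = df$chrom[i], strand = df$strand[i],
               exon_start = as.numeric(strsplit(df$exon_starts[i], ",")[[1]]),
               exon_end = as.numeric(strsplit(df$exon_ends[i], ",")[[1]]),
               cds_start = suppressWarnings(as.numeric(df$cds_start[i])),
               cds_end = suppressWarnings(as.numeric(df$cds_end[i])),
               cds_seq = if (is.null(cseq) || is.na(cseq) || !nzchar(cseq))
                 NA_character_ else cseq)
  })
}

#' @rdname read_gene_models
#' @param genes list of gene models.
#' @export
write_gene_models <- function(genes, path) {
  df <- do.call(rbind, lapply(genes, function(g) {
    data.frame(gene = g$gene, chrom = g$chrom, strand = g$strand,
               exon_starts = paste(format(g$exon_start, scientific = FALSE, trim = TRUE), collapse = ","),
               exon_ends = paste(format(g$exon_end, scientific = FALSE, trim = TRUE), collapse = ","),
               cds_start = g$cds_start, cds_end = g$cds_end,
               cds_seq = ifelse(is.na(g$cds_seq), "", g$cds_seq),
               stringsAsFactors = FALSE)
  }))
  write_tsv_table(df, path)
}

complement_base <- function(x) chartr("ACGT", "TGCA", x)

translate_codon <- function(codon) {
  aa <- Biostrings::GENETIC_CODE[[codon]]
  if (is.null(aa)) NA_character_ else aa
}

# Position of a genomic base within the coding sequence (1-based, 5'->3' of
# the mRNA), or NA when outside the CDS.
cds_position <- function(g, pos) {
  cds <- cds_intervals(g)
  if (!nrow(cds)) return(NA_real_)
  hit <- which(pos >= cds$start & pos <= cds$end)
  if (!length(hit)) return(NA_real_)
  before <- if (hit > 1) sum(cds$end[seq_len(hit - 1)] - cds$start[seq_len(hit - 1)] + 1) else 0
  asc <- before + (pos - cds$start[hit] + 1)
  if (g$strand == "+") asc else sum(cds$end - cds$start + 1) - asc + 1
}

classify_against_gene <- function(chrom, pos, end, ref, alt, g, splice_window) {
  if (chrom != g$chrom) return(NA_character_)
  tx_start <- min(g$exon_start); tx_end <- max(g$exon_end)
  flank <- 1000L
  if (end < tx_start - flank || pos > tx_end + flank) return(NA_character_)
  in_exon <- any(pos <= g$exon_end & end >= g$exon_start)
  is_snv <- nchar(ref) == 1L && nchar(alt) == 1L
  if (in_exon) {
    if (g$coding) {
      cds <- cds_intervals(g)
      in_cds <- nrow(cds) > 0 && any(pos <= cds$end & end >= cds$start)
      if (in_cds) {
        if (is_snv) return(snv_coding_class(g, pos, ref, alt))
        shift <- abs(nchar(ref) - nchar(alt))
        return(if (shift %% 3 == 0) "nonframeshift" else "frameshift")
      }
      return("UTR")
    }
    return("noncoding_gene")
  }
  if (pos >= tx_start && end <= tx_end) {
    # intronic; canonical splice site when within splice_window bp of an
    # exon-intron boundary (measured inside the intron)
    d_acceptor <- g$exon_start - 1 - end      # bases between variant and next exon start
    d_donor <- pos - (g$exon_end + 1)         # bases past the previous exon end
    near <- any(d_acceptor >= 0 & d_acceptor < splice_window) ||
      any(d_donor >= 0 & d_donor < splice_window)
    if (near && g$coding) return("splicing")
    return("intronic")
  }
  upstream_side <- end < tx_start  # variant left of the transcript
  if (g$strand == "+") {
    if (upstream_side) "upstream" else "downstream"
  } else {
    if (upstream_side) "downstream" else "upstream"
  }
}

snv_coding_class <- function(g, pos, ref, alt) {
  if (is.na(g$cds_seq)) return("nonsynonymous")
  cp <- cds_position(g, pos)
  if (is.na(cp)) return("UTR")
  n <- nchar(g$cds_seq)
  ref_c <- if (g$strand == "+") ref else complement_base(ref)
  alt_c <- if (g$strand == "+") alt else complement_base(alt)
  if (substr(g$cds_seq, cp, cp) != ref_c)
    stop(sprintf("reference allele mismatch for %s at %s:%s (cds has %s, variant ref %s)",
                 g$gene, g$chrom, format(pos, scientific = FALSE), substr(g$cds_seq, cp, cp), ref))
  ci <- (cp - 1) %/% 3
  c1 <- ci * 3 + 1
  if (c1 + 2 > n) return("nonsynonymous")  # trailing partial codon in toy models
  ref_codon <- substr(g$cds_seq, c1, c1 + 2)
  within <- cp - c1 + 1
  alt_codon <- ref_codon
  substr(alt_codon, within, within) <- alt_c
  ref_aa <- translate_codon(ref_codon); alt_aa <- translate_codon(alt_codon)
  if (is.na(ref_aa) || is.na(alt_aa)) return("nonsynonymous")
  if (ref_aa == alt_aa) return("synonymous")
  if (alt_aa == "*") return("stopgain")
  if (ref_aa == "*") return("stoploss")
  "nonsynonymous"
}

#' Classify variants against a set of gene models
#'
#' Adds `function_class` and `gene` columns. SNVs inside a CDS are
#' subclassified by codon translation; indels by length modulo 3; positions
#' within `splice_window` bp of an exon-intron boundary (inside the intron)
#' are `splicing`. A variant overlapping several transcripts takes the most
#' deleterious classification.
#'
#' @param variants data.frame with `chrom`, `pos`, `end`, `ref`, `alt`.
#' @param genes list of [gene_model()]s.
#' @param splice_window intronic bases adjacent to an exon counted as
#'   canonical splice sites (default 2).
#' @return input data.frame with `function_class` and `gene` columns.
#' @export
classify_variants <- function(variants, genes, splice_window = 2L) {
  bad <- which(nchar(variants$ref) != variants$end - variants$pos + 1)
  if (length(bad))
    stop("variant ref allele inconsistent with declared span at ",
         variant_key(variants[bad[1], , drop = FALSE]))
  if (any(variants$ref == variants$alt)) stop("ref and alt alleles must differ")
  by_chrom <- split(seq_along(genes), vapply(genes, `[[`, "", "chrom"))
  n <- nrow(variants)
  cls <- rep("intergenic", n); gn <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    idx <- by_chrom[[variants$chrom[i]]]
    if (is.null(idx)) next
    best <- Inf
    for (j in idx) {
      cj <- classify_against_gene(variants$chrom[i], variants$pos[i], variants$end[i],
                                  variants$ref[i], variants$alt[i], genes[[j]],
                                  splice_window)
      if (is.na(cj)) next
      r <- match(cj, FUNCTION_CLASSES)
      if (r < best) { best <- r; cls[i] <- cj; gn[i] <- genes[[j]]$gene }
    }
  }
  variants$function_class <- cls
  variants$gene <- gn
  variants
}
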