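# Shared fixtures and independent oracles for the test suite.
# The region-algebra oracles work per base over a toy genome, deliberately
# independent of the GenomicRanges-backed implementation they check.

extdata <- function(f) system.file("extdata", f, package = "famprior")

# per-base membership vector of a region set over a toy genome
# (named list chrom -> length)
oracle_bases <- function(rs, genome) {
  out <- lapply(genome, function(L) logical(L))
  for (i in seq_len(nrow(rs))) {
    ch <- rs$chrom[i]
    out[[ch]][rs$start[i]:rs$end[i]] <- TRUE
  }
  out
}

# rebuild maximal intervals from a membership vector
oracle_regions <- function(bases) {
  rows <- list()
  for (ch in names(bases)) {
    v <- bases[[ch]]
    r <- rle(v)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    keep <- which(r$values)
    if (length(keep))
      rows[[ch]] <- data.frame(chrom = ch, start = starts[keep], end = ends[keep])
  }
  if (!length(rows))
    return(data.frame(chrom = character(), start = numeric(), end = numeric()))
  do.call(rbind, rows)
}

random_raw_intervals <- function(n, genome) {
  ch <- sample(names(genome), n, replace = TRUE)
  L <- unlist(genome)[ch]
  start <- floor(runif(n, 1, L - 50))
  data.frame(chrom = ch, start = start,
             end = pmin(L, start + floor(runif(n, 0, 400))))
}

# plus-strand toy gene: 2 exons; CDS covers all of both exons.
# CDS sequence: ATG CGA TTT GGG | CCC AAA TAG  (exon1 12 bp, exon2 9 bp)
toy_gene_plus <- function() {
  gene_model("TOYP", "chrT", "+",
             exon_start = c(101, 213), exon_end = c(112, 221),
             cds_start = 101, cds_end = 221,
             cds_seq = "ATGCGATTTGGGCCCAAATAG")
}

# minus-strand toy gene: one 12 bp exon; mRNA reads ATG AAA CCC TAA,
# so the genomic plus strand is the reverse complement TTAGGGTTTCAT
toy_gene_minus <- function() {
  gene_model("TOYM", "chrT", "-",
             exon_start = 501, exon_end = 512,
             cds_start = 501, cds_end = 512,
             cds_seq = "ATGAAACCCTAA")
}

snv <- function(chrom, pos, ref, alt, zygosity = "het", quality = 100) {
  data.frame(chrom = chrom, pos = pos, end = pos + nchar(ref) - 1,
             ref = ref, alt = alt, zygosity = zygosity, quality = quality,
             stringsAsFactors = FALSE)
}

# annotated-variant row builder for funnel tests
avar <- function(key, gene = NA, class = "nonsynonymous", zyg = "het",
                 qual = 100, g1000 = NA, esp = NA, cg46 = NA,
                 sift = NA, polyphen = NA, gerp = NA) {
  data.frame(key = key, chrom = "chr1", pos = abs(sum(utf8ToInt(key))), end = 1,
             ref = "A", alt = "C", zygosity = zyg, quality = qual,
             function_class = class, gene = gene,
             maf_g1000 = g1000, maf_esp5400 = esp, maf_cg46 = cg46,
             sift = sift, polyphen = polyphen, gerp = gerp,
             stringsAsFactors = FALSE)
}

# lighter background for speed; marker density stays at the default so
# planted CNVs retain enough marker support for the post-filters
small_sim_config <- function(...) {
  simulation_config(n_background = 800, n_genes = 16, ...)
}

# deterministic transmission_track builder for hand-constructed IBD cases
manual_track <- function(markers, children, father_origin, mother_origin) {
  structure(list(markers = markers, children = children,
                 origin = list(father = father_origin, mother = mother_origin)),
            class = "transmission_track")
}
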