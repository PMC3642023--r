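#' Synthetic multiplex-family study generator
#'
#' Generates a complete, seedable synthetic study mirroring a two-generation
#' multiplex pedigree design: two parents and eight children, two affected.
#' Founder haplotypes are simulated at dense bi-allelic SNP markers,
#' transmitted through Poisson-crossover meioses; the two affected children
#' are made compound-heterozygous at one planted causal gene (one rare
#' deleterious variant per parental haplotype) and every unaffected child
#' lacks at least one of the two variants. Rare-variant background, reference
#' allele-frequency databases, deleteriousness scores, conserved elements,
#' chromatin states, inherited CNVs with per-site pileup signals and all
#' standard-format files are emitted alongside a ground-truth record, so
#' every pipeline stage can be tested against planted truth. The genome is
#' scaled down (default 4 chromosomes of 20 Mb) so the full pipeline runs in
#' seconds; all rates are configuration-driven.
#'
#' @name synthetic-family
NULL

#' Simulation configuration
#'
#' @param n_children number of children (default 8, two affected).
#' @param affected ids of the affected (sequenced) children.
#' @param ungenotyped ids of children without DNA (in the pedigree but
#'   absent from the genotype table).
#' @param genome data.frame `chrom`, `length_bp`, `morgans` (default: 4
#'   chromosomes x 20 Mb at 1 cM/Mb).
#' @param n_markers total SNP-array markers across the genome.
#' @param n_genes number of toy gene models.
#' @param n_background founder background variant sites (roughly half are
#'   carried per child).
#' @param coding_fraction fraction of background sites placed inside coding
#'   exons (kept small so chance recessive candidates are rare).
#' @param common_fraction fraction of background sites given database MAF
#'   above 1% (exercises the rarity filter).
#' @param deleterious_fraction fraction of background coding sites given
#'   deleterious-looking scores.
#' @param low_quality_fraction fraction of proband calls drawn below the
#'   quality thresholds (exercises the quality filter).
#' @param hom_capable_fraction fraction of sites present on one haplotype of
#'   each parent (children can be homozygous there).
#' @param coverage sequencing depth for pileup simulation.
#' @param plant_causal plant the compound-het causal gene?
#' @param plant_noncoding plant a conserved promoter variant shared by the
#'   probands?
#' @param plant_cnvs plant inherited CNVs (with junk calls that the
#'   post-filters must remove)?
#' @return named list of settings.
#' @export
simulation_config <- function(n_children = 8,
                              affected = c("8", "10"),
                              ungenotyped = "9",
                              genome = data.frame(
                                chrom = paste0("chr", 1:4),
                                length_bp = rep(20e6, 4),
                                morgans = rep(0.2, 4)),
                              n_markers = 2000,
                              n_genes = 30,
                              n_background = 2000,
                              coding_fraction = 0.02,
                              common_fraction = 0.3,
                              deleterious_fraction = 0.3,
                              low_quality_fraction = 0.08,
                              hom_capable_fraction = 0.05,
                              coverage = 50,
                              plant_causal = TRUE,
                              plant_noncoding = TRUE,
                              plant_cnvs = TRUE) {
  stopifnot(n_children >= 2, n_markers >= n_children, all(genome$length_bp > 0),
            all(genome$morgans >= 0))
  child_ids <- as.character(seq(3, 2 + n_children))
  if (!all(affected %in% child_ids)) stop("affected ids must be children")
  list(n_children = n_children, child_ids = child_ids, affected = affected,
       ungenotyped = intersect(ungenotyped, child_ids), genome = genome,
       n_markers = n_markers, n_genes = n_genes, n_background = n_background,
       coding_fraction = coding_fraction, common_fraction = common_fraction,
       deleterious_fraction = deleterious_fraction,
       low_quality_fraction = low_quality_fraction,
       hom_capable_fraction = hom_capable_fraction, coverage = coverage,
       plant_causal = plant_causal, plant_noncoding = plant_noncoding,
       plant_cnvs = plant_cnvs)
}

#' Simulate one meiosis
#'
#' Crossover count is Poisson over the chromosome's genetic length,
#' positions uniform, no interference; the gamete alternates between the two
#' parental haplotypes at each crossover. Uses the current RNG state (seed
#' at the caller).
#'
#' @param morgans genetic length of the chromosome in Morgans.
#' @param length_bp physical length in bp.
#' @return list with `start_hap` (1 or 2) and `breaks` (sorted crossover
#'   positions in bp).
#' @export
simulate_meiosis <- function(morgans, length_bp) {
  list(start_hap = sample(2L, 1L), breaks = meiosis_breaks(morgans, length_bp))
}

# haplotype of origin (1/2) of a gamete at position(s) pos
gamete_origin_at <- function(gamete, pos) {
  ((gamete$start_hap - 1 + findInterval(pos, gamete$breaks)) %% 2) + 1
}

# constant origin `target` across [lo, hi]?
gamete_constant_origin <- function(gamete, lo, hi, target) {
  o <- gamete_origin_at(gamete, c(lo, hi))
  all(o == target) && findInterval(lo, gamete$breaks) == findInterval(hi, gamete$breaks)
}

#' Simulate per-site read pileups under a copy-number state
#'
#' Total reads per site are Poisson(depth * copy / 2); alternate reads are
#' Binomial(total, dose / copy) where `dose` is the number of copies
#' carrying the alternate allele. At a formerly heterozygous site a
#' hemizygous deletion keeps ref or alt with equal probability, so BAF
#' collapses to 0 or 1; a 3-copy duplication doses the alternate allele at 1
#' or 2 of 3 copies.
#'
#' @param chrom chromosome label for the output.
#' @param positions site positions (bp).
#' @param copy copy number in {1, 2, 3}.
#' @param het logical per site: heterozygous in the diploid state (these are
#'   the SNV sites where BAF is interpretable).
#' @param depth haploid-pair (diploid) sequencing depth.
#' @return data.frame `chrom`, `pos`, `ref_count`, `alt_count`, `is_snv`.
#' @export
simulate_pileup <- function(chrom, positions, copy, het, depth) {
  stopifnot(copy %in% 1:3, depth > 0, length(het) == length(positions))
  n <- length(positions)
  total <- stats::rpois(n, depth * copy / 2)
  dose <- integer(n)
  if (copy == 2L) dose[het] <- 1L
  if (copy == 1L) dose[het] <- sample(0:1, sum(het), replace = TRUE)
  if (copy == 3L) dose[het] <- sample(1:2, sum(het), replace = TRUE)
  alt <- stats::rbinom(n, total, dose / copy)
  data.frame(chrom = chrom, pos = positions, ref_count = total - alt,
             alt_count = alt, is_snv = het, stringsAsFactors = FALSE)
}

random_bases <- function(n) sample(c("A", "C", "G", "T"), n, replace = TRUE)

# toy transcript structures tiled along each chromosome
sim_gene_models <- function(config) {
  genes <- list()
  gi <- 0
  per_chrom <- ceiling(config$n_genes / nrow(config$genome))
  for (ci in seq_len(nrow(config$genome))) {
    L <- config$genome$length_bp[ci]
    # keep genes away from chromosome ends and from each other
    anchors <- seq(2e6, L - 2e6, length.out = per_chrom + 1)[seq_len(per_chrom)]
    for (a in anchors) {
      if (gi >= config$n_genes) break
      gi <- gi + 1
      n_ex <- sample(3:6, 1)
      widths <- sample(120:300, n_ex, replace = TRUE)
      gaps <- sample(500:3000, n_ex - 1, replace = TRUE)
      starts <- a + cumsum(c(0, widths[-n_ex] + gaps))
      ends <- starts + widths - 1
      cds_start <- starts[1] + sample(20:60, 1)
      cds_end <- ends[n_ex] - sample(20:60, 1)
      cds_w <- sum(pmin(ends, cds_end) - pmax(starts, cds_start) + 1)
      genes[[gi]] <- gene_model(
        gene = sprintf("GENE%03d", gi), chrom = config$genome$chrom[ci],
        strand = sample(c("+", "-"), 1), exon_start = starts, exon_end = ends,
        cds_start = cds_start, cds_end = cds_end,
        cds_seq = paste(random_bases(cds_w), collapse = ""))
    }
  }
  genes
}

# genomic reference base implied by a gene's CDS sequence at position pos
cds_ref_base <- function(g, pos) {
  cp <- cds_position(g, pos)
  b <- substr(g$cds_seq, cp, cp)
  if (g$strand == "+") b else complement_base(b)
}

# pick a position+alt giving a protein-altering SNV near `anchor` (some CDS
# positions are 4-fold degenerate, so scan outward until one works)
deleterious_alt <- function(g, anchor) {
  cds <- cds_intervals(g)
  in_cds <- unlist(lapply(seq_len(nrow(cds)), function(i) cds$start[i]:cds$end[i]))
  for (pos in in_cds[order(abs(in_cds - anchor))][1:min(30, length(in_cds))]) {
    ref <- cds_ref_base(g, pos)
    for (alt in setdiff(c("A", "C", "G", "T"), ref)) {
      v <- data.frame(chrom = g$chrom, pos = pos, end = pos, ref = ref,
                      alt = alt, stringsAsFactors = FALSE)
      cl <- classify_variants(v, list(g))$function_class
      if (cl %in% c("nonsynonymous", "stopgain"))
        return(list(pos = pos, ref = ref, alt = alt, class = cl))
    }
  }
  NULL
}

#' Simulate a complete synthetic family study
#'
#' See the module description under [synthetic-family]. With `out_dir` set,
#' all standard-format files (PED, genotype TSV, per-proband VCFs, gene
#' model / frequency / score TSVs, conserved-element and chromatin-state
#' BEDs, CNV call TSV, mask BED, pileup TSVs, `truth.json`) are written;
#' identical seeds yield identical outputs.
#'
#' @param config a [simulation_config()].
#' @param seed RNG seed.
#' @param out_dir optional output directory (created if missing).
#' @return list with `ped`, `genes`, `geno` (genotype table), `probands`
#'   (named list of annotated variant data.frames, proband1 = older-id
#'   affected child), `freqs`, `scores`, `elements`, `states`, `cnv_calls`,
#'   `masks`, `pileups`, `truth`, and `files` (paths, when written).
#' @export
simulate_family <- function(config = simulation_config(), seed = 1, out_dir = NULL) {
  set.seed(seed)
  genome <- config$genome
  if (config$n_markers < 10 * nrow(genome))
    stop("infeasible configuration: too few markers (", config$n_markers, ")")
  fa <- "2"; mo <- "1"
  kids <- config$child_ids
  ped <- pedigree(id = c(mo, fa, kids),
                  father = c(NA, NA, rep(fa, length(kids))),
                  mother = c(NA, NA, rep(mo, length(kids))),
                  sex = c(2, 1, rep_len(c(1, 2), length(kids))),
                  affected = c(FALSE, FALSE, kids %in% config$affected))

  ## markers and founder haplotypes -------------------------------------
  per_chrom <- round(config$n_markers * genome$length_bp / sum(genome$length_bp))
  marker_df <- do.call(rbind, lapply(seq_len(nrow(genome)), function(ci) {
    pos <- sort(sample(seq(1e4, genome$length_bp[ci] - 1e4), per_chrom[ci]))
    data.frame(chrom = genome$chrom[ci], pos = pos, stringsAsFactors = FALSE)
  }))
  marker_df$marker <- sprintf("m%05d", seq_len(nrow(marker_df)))
  nm <- nrow(marker_df)
  p_freq <- stats::runif(nm, 0.25, 0.75)
  founder_hap <- list()  # founder_hap[[member]][[hap 1/2]] = allele vector
  for (m in c(fa, mo)) founder_hap[[m]] <- lapply(1:2, function(h)
    ifelse(stats::runif(nm) < p_freq, "A", "B"))

  ## gene models ---------------------------------------------------------
  genes <- sim_gene_models(config)
  causal <- if (config$plant_causal) genes[[1]] else NULL

  ## background variant sites --------------------------------------------
  nb <- config$n_background
  n_cod <- round(nb * config$coding_fraction)
  coding_genes <- genes[vapply(genes, `[[`, TRUE, "coding")]
  site_rows <- list()
  for (i in seq_len(n_cod)) {
    g <- coding_genes[[sample(length(coding_genes), 1)]]
    cds <- cds_intervals(g)
    e <- sample(nrow(cds), 1)
    pos <- sample(cds$start[e]:cds$end[e], 1)
    ref <- cds_ref_base(g, pos)
    site_rows[[i]] <- data.frame(chrom = g$chrom, pos = pos, ref = ref,
                                 stringsAsFactors = FALSE)
  }
  n_rest <- nb - n_cod
  ci <- sample(nrow(genome), n_rest, replace = TRUE,
               prob = genome$length_bp / sum(genome$length_bp))
  rest <- data.frame(chrom = genome$chrom[ci],
                     pos = vapply(ci, function(k)
                       sample(genome$length_bp[k] - 1, 1) + 0, numeric(1)),
                     ref = random_bases(n_rest), stringsAsFactors = FALSE)
  sites <- rbind(do.call(rbind, site_rows), rest)
  # a position falling inside a CDS must carry the gene sequence's ref base
  for (i in seq_len(nrow(sites))) {
    for (g in coding_genes) {
      if (sites$chrom[i] != g$chrom || is.na(g$cds_seq)) next
      cds <- cds_intervals(g)
      if (any(sites$pos[i] >= cds$start & sites$pos[i] <= cds$end)) {
        sites$ref[i] <- cds_ref_base(g, sites$pos[i])
        break
      }
    }
  }
  sites$alt <- vapply(sites$ref, function(r) sample(setdiff(c("A", "C", "G", "T"), r), 1), "")
  sites <- sites[!duplicated(paste(sites$chrom, sites$pos)), , drop = FALSE]
  nbv <- nrow(sites)
  # haplotype ownership: one founder haplotype, or one hap of each parent
  owner_parent <- sample(c(fa, mo), nbv, replace = TRUE)
  owner_hap <- sample(1:2, nbv, replace = TRUE)
  biparental <- stats::runif(nbv) < config$hom_capable_fraction
  second_hap <- sample(1:2, nbv, replace = TRUE)
  # database MAFs
  is_common <- stats::runif(nbv) < config$common_fraction
  maf_draw <- function(common) {
    if (common) stats::runif(1, 0.02, 0.4) else stats::runif(1, 1e-4, 0.009)
  }
  maf <- t(vapply(seq_len(nbv), function(i) {
    base <- maf_draw(is_common[i])
    present <- stats::runif(3) < ifelse(is_common[i], 0.95, 0.6)
    if (is_common[i]) present[sample(3, 1)] <- TRUE
    out <- ifelse(present, pmin(0.5, abs(base + stats::rnorm(3, 0, base / 5))), NA_real_)
    if (!is_common[i]) out <- pmin(out, 0.0099)
    out
  }, numeric(3)))
  colnames(maf) <- c("maf_g1000", "maf_esp5400", "maf_cg46")
  # deleteriousness scores
  deleterious <- stats::runif(nbv) < config$deleterious_fraction
  sift <- ifelse(deleterious, stats::runif(nbv, 0, 0.04), stats::runif(nbv, 0.06, 1))
  polyphen <- ifelse(deleterious, stats::runif(nbv, 0.86, 1), stats::runif(nbv, 0, 0.8))
  gerp <- ifelse(deleterious, stats::runif(nbv, 2.1, 6), stats::runif(nbv, -3, 1.9))
  unscored <- stats::runif(nbv) < 0.05
  sift[unscored] <- NA; polyphen[unscored] <- NA; gerp[unscored] <- NA

  sites$key <- variant_key(sites)

  ## planted causal and non-coding variants ------------------------------
  truth <- list(seed = seed, causal_gene = NA, causal_keys = character(),
                noncoding_key = NA)
  planted <- NULL
  if (config$plant_causal) {
    cds <- cds_intervals(causal)
    v1 <- deleterious_alt(causal, cds$start[1] + 5)
    v2 <- deleterious_alt(causal, cds$end[nrow(cds)] - 5)
    if (is.null(v1) || is.null(v2) || v1$pos == v2$pos)
      stop("could not plant causal variants")
    planted <- data.frame(
      chrom = causal$chrom,
      pos = c(v1$pos, v2$pos),
      ref = c(v1$ref, v2$ref), alt = c(v1$alt, v2$alt),
      parent = c(fa, mo), hap = 1L, stringsAsFactors = FALSE)
    planted$key <- variant_key(planted)
    truth$causal_gene <- causal$gene
    truth$causal_keys <- planted$key
  }
  nc_pos <- NA
  if (config$plant_noncoding && config$plant_causal) {
    nc_pos <- min(causal$exon_start) - 300  # promoter-proximal, upstream
    nc_ref <- random_bases(1)
    nc <- data.frame(chrom = causal$chrom, pos = nc_pos, ref = nc_ref,
                     alt = sample(setdiff(c("A", "C", "G", "T"), nc_ref), 1),
                     parent = fa, hap = 1L, stringsAsFactors = FALSE)
    nc$key <- variant_key(nc)
    truth$noncoding_key <- nc$key
    planted <- rbind(planted, nc)
  }

  ## planted CNV regions (fixed before the meioses so transmission can be
  ## conditioned to give both a carrier and a non-carrier child) ----------
  typed_kids <- setdiff(kids, config$ungenotyped)
  masks <- list(); cnv_specs <- NULL
  if (config$plant_cnvs) {
    masks$centromere <- region_set(genome$chrom,
                                   genome$length_bp / 2 - 250e3,
                                   genome$length_bp / 2 + 250e3)
    # anchor each planted CNV to a window of 14 consecutive markers whose
    # span stays under 600 kb, clear of the synthetic centromere, so the
    # marker-support (>=10) and sparsity (<=50 kb mean gap) filters are
    # guaranteed to keep it
    pick_window <- function(chrom, anchor) {
      pos <- marker_df$pos[marker_df$chrom == chrom]
      cen_lo <- genome$length_bp[match(chrom, genome$chrom)] / 2 - 4e5
      w <- 14L
      for (i in seq_len(length(pos) - w + 1)) {
        lo <- pos[i]; hi <- pos[i + w - 1]
        if (lo >= anchor && hi - lo <= 6e5 && hi < cen_lo)
          return(c(lo - 1000, hi + 1000))
      }
      stop("no usable marker window for a planted CNV on ", chrom)
    }
    cnv_specs <- data.frame(
      chrom = c("chr2", "chr3", "chr4"),
      type = c("del", "dup", "del"),
      parent = c(fa, mo, mo), hap = c(1L, 2L, 1L), stringsAsFactors = FALSE)
    win <- t(vapply(seq_len(nrow(cnv_specs)), function(i)
      pick_window(cnv_specs$chrom[i], 2e6), numeric(2)))
    cnv_specs$start <- win[, 1]; cnv_specs$end <- win[, 2]
  }

  ## meioses with conditioning at the causal locus -----------------------
  lock_lo <- if (config$plant_causal) min(nc_pos, min(causal$exon_start), na.rm = TRUE) else NA
  lock_hi <- if (config$plant_causal) max(causal$exon_end) else NA
  causal_chrom <- if (config$plant_causal) causal$chrom else NA
  gametes <- list()
  for (k in kids) {
    gametes[[k]] <- list()
    for (par in c(fa, mo)) {
      gametes[[k]][[par]] <- list()
      for (ci2 in seq_len(nrow(genome))) {
        ch <- genome$chrom[ci2]
        gametes[[k]][[par]][[ch]] <-
          simulate_meiosis(genome$morgans[ci2], genome$length_bp[ci2])
      }
    }
    if (config$plant_causal) {
      want_both <- k %in% config$affected
      for (try in seq_len(10000)) {
        gf <- gametes[[k]][[fa]][[causal_chrom]]
        gm <- gametes[[k]][[mo]][[causal_chrom]]
        has_f <- gamete_constant_origin(gf, lock_lo, lock_hi, 1L)
        has_m <- gamete_constant_origin(gm, lock_lo, lock_hi, 1L)
        ok <- if (want_both) has_f && has_m else !(has_f && has_m)
        if (ok) break
        ci2 <- match(causal_chrom, genome$chrom)
        gametes[[k]][[fa]][[causal_chrom]] <-
          simulate_meiosis(genome$morgans[ci2], genome$length_bp[ci2])
        gametes[[k]][[mo]][[causal_chrom]] <-
          simulate_meiosis(genome$morgans[ci2], genome$length_bp[ci2])
        if (try == 10000) stop("conditioning on the causal locus failed")
      }
    }
  }
  # ensure the first planted CNV (the pileup example) has at least one
  # carrier and one non-carrier among the genotyped children, resampling a
  # single child's gamete on that chromosome if transmission was one-sided
  if (config$plant_cnvs) {
    sp <- cnv_specs[1, ]
    ci2 <- match(sp$chrom, genome$chrom)
    carrier_of <- function(k)
      gamete_origin_at(gametes[[k]][[sp$parent]][[sp$chrom]],
                       (sp$start + sp$end) / 2) == sp$hap
    for (try in seq_len(1000)) {
      st <- vapply(typed_kids, carrier_of, logical(1))
      if (any(st) && !all(st)) break
      flip_kid <- if (all(st)) typed_kids[length(typed_kids)] else typed_kids[1]
      gametes[[flip_kid]][[sp$parent]][[sp$chrom]] <-
        simulate_meiosis(genome$morgans[ci2], genome$length_bp[ci2])
      if (try == 1000) stop("conditioning on the planted CNV failed")
    }
  }
  truth$gametes <- gametes

  ## marker genotypes ----------------------------------------------------
  child_hap <- function(k, par) {
    out <- character(nm)
    for (ch in unique(marker_df$chrom)) {
      rows <- which(marker_df$chrom == ch)
      org <- gamete_origin_at(gametes[[k]][[par]][[ch]], marker_df$pos[rows])
      h1 <- founder_hap[[par]][[1]][rows]; h2 <- founder_hap[[par]][[2]][rows]
      out[rows] <- ifelse(org == 1L, h1, h2)
    }
    out
  }
  geno <- marker_df[c("marker", "chrom", "pos")]
  geno[[mo]] <- paste(founder_hap[[mo]][[1]], founder_hap[[mo]][[2]], sep = "/")
  geno[[fa]] <- paste(founder_hap[[fa]][[1]], founder_hap[[fa]][[2]], sep = "/")
  pat <- list(); mat <- list()
  for (k in kids) { pat[[k]] <- child_hap(k, fa); mat[[k]] <- child_hap(k, mo) }
  for (k in typed_kids) geno[[k]] <- paste(pat[[k]], mat[[k]], sep = "/")

  ## variant carriage per child ------------------------------------------
  carries_site <- function(k, chrom_v, pos_v, par, hap) {
    org <- gamete_origin_at(gametes[[k]][[par]][[chrom_v]], pos_v)
    org == hap
  }
  proband_variants <- function(k) {
    n_copies <- integer(nbv)
    for (i in seq_len(nbv)) {
      n_copies[i] <- carries_site(k, sites$chrom[i], sites$pos[i],
                                  owner_parent[i], owner_hap[i])
      if (biparental[i]) {
        other <- if (owner_parent[i] == fa) mo else fa
        n_copies[i] <- n_copies[i] +
          carries_site(k, sites$chrom[i], sites$pos[i], other, second_hap[i])
      }
    }
    idx <- which(n_copies > 0)
    v <- sites[idx, c("chrom", "pos", "ref", "alt", "key")]
    v$end <- v$pos
    v$zygosity <- ifelse(n_copies[idx] == 2L, "hom", "het")
    lowq <- stats::runif(length(idx)) < config$low_quality_fraction
    v$quality <- ifelse(v$zygosity == "hom",
                        ifelse(lowq, stats::runif(length(idx), 1, 19.5),
                               stats::runif(length(idx), 25, 250)),
                        ifelse(lowq, stats::runif(length(idx), 1, 39.5),
                               stats::runif(length(idx), 45, 250)))
    v$quality <- round(v$quality, 1)
    # planted variants carried by this child
    if (!is.null(planted)) {
      carried <- vapply(seq_len(nrow(planted)), function(i)
        carries_site(k, planted$chrom[i], planted$pos[i],
                     planted$parent[i], planted$hap[i]), logical(1))
      if (any(carried)) {
        pv <- planted[carried, c("chrom", "pos", "ref", "alt", "key")]
        pv$end <- pv$pos; pv$zygosity <- "het"
        pv$quality <- round(stats::runif(nrow(pv), 90, 200), 1)
        v <- rbind(v, pv[names(v)])
      }
    }
    v[order(v$chrom, v$pos), , drop = FALSE]
  }
  probands <- config$affected[order(as.numeric(config$affected), decreasing = TRUE)]
  prob_vars <- stats::setNames(lapply(probands, proband_variants), c("proband1", "proband2"))

  ## annotation tables ----------------------------------------------------
  freqs <- data.frame(key = sites$key, maf, stringsAsFactors = FALSE)
  scores <- data.frame(key = sites$key, sift = round(sift, 3),
                       polyphen = round(polyphen, 3), gerp = round(gerp, 2),
                       stringsAsFactors = FALSE)
  if (!is.null(planted)) {
    pk <- planted$key
    freqs <- rbind(freqs, data.frame(key = pk, maf_g1000 = 0.002,
                                     maf_esp5400 = NA_real_, maf_cg46 = NA_real_))
    scores <- rbind(scores, data.frame(key = pk, sift = 0.01, polyphen = 0.95,
                                       gerp = 4.5))
  }

  ## conserved elements and chromatin states ------------------------------
  n_el <- 60
  eci <- sample(nrow(genome), n_el, replace = TRUE)
  el_start <- vapply(eci, function(k) sample(genome$length_bp[k] - 3000, 1) + 0, numeric(1))
  elements <- data.frame(chrom = genome$chrom[eci], start = el_start,
                         end = el_start + sample(200:2000, n_el, replace = TRUE),
                         score = round(stats::runif(n_el, -1, 6), 2),
                         stringsAsFactors = FALSE)
  n_st <- 80
  sci <- sample(nrow(genome), n_st, replace = TRUE)
  st_start <- vapply(sci, function(k) sample(genome$length_bp[k] - 6000, 1) + 0, numeric(1))
  states <- data.frame(chrom = genome$chrom[sci], start = st_start,
                       end = st_start + sample(400:4000, n_st, replace = TRUE),
                       state = sample(1:15, n_st, replace = TRUE),
                       stringsAsFactors = FALSE)
  if (config$plant_noncoding && config$plant_causal) {
    elements <- rbind(elements, data.frame(chrom = causal$chrom, start = nc_pos - 150,
                                           end = nc_pos + 150, score = 3.5))
    states <- rbind(states, data.frame(chrom = causal$chrom, start = nc_pos - 400,
                                       end = nc_pos + 400, state = 1L))
  }

  ## CNVs: planted inherited events, junk calls, pileups ------------------
  cnv_calls <- NULL; pileups <- list(); cnv_truth <- list()
  if (config$plant_cnvs) {
    specs <- cnv_specs
    call_rows <- list()
    for (i in seq_len(nrow(specs))) {
      mid <- (specs$start[i] + specs$end[i]) / 2
      kid_carriers <- typed_kids[vapply(typed_kids, function(k)
        carries_site(k, specs$chrom[i], mid, specs$parent[i], specs$hap[i]), logical(1))]
      carriers <- c(specs$parent[i], kid_carriers)
      call_rows[[i]] <- data.frame(
        chrom = specs$chrom[i], start = specs$start[i], end = specs$end[i],
        type = specs$type[i], sample = carriers, n_snps = 14L,
        confidence = round(stats::runif(length(carriers), 350, 900)),
        stringsAsFactors = FALSE)
      cnv_truth[[i]] <- list(chrom = specs$chrom[i], start = specs$start[i],
                             end = specs$end[i], type = specs$type[i],
                             parent = specs$parent[i], carriers = carriers)
    }
    cen <- as.data.frame(masks$centromere)
    junk <- data.frame(
      chrom = c("chr1", "chr1", "chr2"),
      start = c(3e6, 6e6, cen$start[2] + 1e4),
      end = c(3e6 + 2e5, 6e6 + 1.2e6, cen$start[2] + 4.2e5),
      type = c("del", "del", "dup"),
      sample = c("3", "4", "5"),
      n_snps = c(4L, 10L, 12L),   # too few markers; too sparse; in the mask
      confidence = c(400, 420, 410), stringsAsFactors = FALSE)
    cnv_calls <- rbind(do.call(rbind, call_rows), junk)
    truth$cnv_regions <- cnv_truth
    truth$junk_calls <- nrow(junk)
    # pileup signal for the first planted deletion: one carrier child, one
    # non-carrier child
    del <- specs[1, ]
    kidsc <- cnv_truth[[1]]$carriers
    carrier <- intersect(typed_kids, kidsc)[1]
    control <- setdiff(typed_kids, kidsc)[1]
    if (!is.na(carrier) && !is.na(control)) {
      flank <- 0.5 * (del$end - del$start + 1)
      pu_pos <- sort(sample(seq(max(1, del$start - flank), del$end + flank), 400))
      in_region <- pu_pos >= del$start & pu_pos <= del$end
      het <- stats::runif(length(pu_pos)) < 0.5
      mk <- function(target_copy) {
        df <- rbind(simulate_pileup(del$chrom, pu_pos[!in_region], 2L,
                                    het[!in_region], config$coverage),
                    simulate_pileup(del$chrom, pu_pos[in_region], target_copy,
                                    het[in_region], config$coverage))
        df[order(df$pos), , drop = FALSE]
      }
      pileups[[carrier]] <- mk(1L)
      pileups[[control]] <- mk(2L)
      truth$pileup_carrier <- carrier
      truth$pileup_control <- control
      truth$pileup_region <- list(chrom = del$chrom, start = del$start, end = del$end)
    }
  }

  ## annotate proband variants -------------------------------------------
  for (nm2 in names(prob_vars)) {
    v <- classify_variants(prob_vars[[nm2]], genes)
    v <- merge(v, freqs, by = "key", all.x = TRUE, sort = FALSE)
    v <- merge(v, scores, by = "key", all.x = TRUE, sort = FALSE)
    prob_vars[[nm2]] <- v[order(v$chrom, v$pos), , drop = FALSE]
  }
  truth$probands <- stats::setNames(probands, c("proband1", "proband2"))

  result <- list(ped = ped, genome = genome, genes = genes, geno = geno,
                 probands = prob_vars, freqs = freqs, scores = scores,
                 elements = elements, states = states, cnv_calls = cnv_calls,
                 masks = masks, pileups = pileups, truth = truth)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    fp <- function(x) file.path(out_dir, x)
    files <- c(ped = fp("family.ped"), genotypes = fp("genotypes.tsv"),
               genes = fp("genes.tsv"), freqs = fp("freqs.tsv"),
               scores = fp("scores.tsv"), elements = fp("conserved_elements.bed"),
               states = fp("chromatin_states.bed"), truth = fp("truth.json"))
    write_ped(ped, files["ped"])
    write_tsv_table(geno, files["genotypes"])
    write_gene_models(genes, files["genes"])
    write_tsv_table(freqs, files["freqs"])
    write_tsv_table(scores, files["scores"])
    el <- elements; el$name <- "elem"; write_bed(el, files["elements"])
    st <- states; st$name <- as.character(st$state); write_bed(st, files["states"])
    for (nm2 in names(prob_vars)) {
      f <- fp(paste0(nm2, ".vcf"))
      keep <- prob_vars[[nm2]][c("chrom", "pos", "ref", "alt", "quality", "zygosity")]
      write_vcf(keep, f, sample = truth$probands[[nm2]])
      files[nm2] <- f
    }
    if (!is.null(cnv_calls)) {
      files["cnv_calls"] <- fp("cnv_calls.tsv")
      write_tsv_table(cnv_calls, files["cnv_calls"])
      cen <- as.data.frame(masks$centromere); cen$name <- "centromere"
      files["masks"] <- fp("masks.bed")
      write_bed(cen, files["masks"])
      for (s in names(pileups)) {
        f <- fp(paste0("pileup_", s, ".tsv"))
        write_tsv_table(pileups[[s]], f)
        files[paste0("pileup_", s)] <- f
      }
    }
    tr <- truth; tr$gametes <- NULL  # breakpoints are real-valued; keep JSON compact
    jsonlite::write_json(tr, files["truth"], auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    result$files <- files
  }
  result
}

#' True IBD segments for a sibling pair from simulation truth
#'
#' Computes, from the planted gametes, the exact segments over which a pair
#' of children shares 0, 1 or 2 parental haplotypes.
#'
#' @param sim result of [simulate_family()].
#' @param pair two child ids.
#' @return data.frame `chrom`, `start`, `end`, `state`.
#' @export
true_ibd_segments <- function(sim, pair) {
  fa <- ped_father(sim$ped); mo <- ped_mother(sim$ped)
  out <- list()
  for (ci in seq_len(nrow(sim$genome))) {
    ch <- sim$genome$chrom[ci]; L <- sim$genome$length_bp[ci]
    g <- lapply(pair, function(k) sim$truth$gametes[[k]])
    bf <- c(g[[1]][[fa]][[ch]]$breaks, g[[2]][[fa]][[ch]]$breaks)
    bm <- c(g[[1]][[mo]][[ch]]$breaks, g[[2]][[mo]][[ch]]$breaks)
    cuts <- sort(unique(c(1, bf, bm, L)))
    starts <- cuts[-length(cuts)]
    eqF <- gamete_origin_at(g[[1]][[fa]][[ch]], starts) ==
      gamete_origin_at(g[[2]][[fa]][[ch]], starts)
    eqM <- gamete_origin_at(g[[1]][[mo]][[ch]], starts) ==
      gamete_origin_at(g[[2]][[mo]][[ch]], starts)
    st <- eqF + eqM
    run_end <- c(which(st[-1] != st[-length(st)]), length(st))
    run_start <- c(1, utils::head(run_end, -1) + 1)
    out[[ch]] <- data.frame(chrom = ch, start = ceiling(cuts[run_start]),
                            end = floor(c(cuts[run_end + 1])),
                            state = st[run_start], stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
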