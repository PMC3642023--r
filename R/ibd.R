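#' Transmission phasing and sibling IBD segment inference
#'
#' For a two-founder nuclear family genotyped at dense bi-allelic SNPs, each
#' child's genotype at markers where a parent is heterozygous often pins
#' down which parental allele was transmitted. Chaining those deductions
#' under a minimal-recombination assumption yields, per child and parent, a
#' grandparental-origin track (hapA/hapB of that parent, named consistently
#' along each chromosome). Comparing two siblings' origin tracks gives their
#' IBD state (0, 1 or 2 shared parental haplotypes) in maximal segments.
#'
#' @name ibd-haplotype
NULL

#' Read a genotype table
#'
#' TSV with columns `marker`, `chrom`, `pos`, then one column per pedigree
#' member holding unordered allele pairs `"A/B"` (`"./."` = missing).
#'
#' @param path TSV file.
#' @return data.frame sorted by chromosome and position.
#' @export
read_genotypes <- function(path) {
  df <- read_tsv_table(path, id_cols = "marker")
  stopifnot(all(c("marker", "chrom", "pos") %in% names(df)))
  df[order(df$chrom, df$pos), , drop = FALSE]
}

split_gt <- function(g) {
  if (is.na(g) || g == "./." || g == ".") return(NULL)
  strsplit(g, "/", fixed = TRUE)[[1]]
}

# transmitted allele from parent P given the other parent's alleles;
# NULL = not deducible, NA = Mendelian-impossible
deduce_transmitted <- function(child, p_alleles, o_alleles) {
  if (is.null(child)) return(NULL)
  cand <- character()
  for (perm in list(child, rev(child))) {
    x <- perm[1]; y <- perm[2]
    if (x %in% p_alleles && (is.null(o_alleles) || y %in% o_alleles))
      cand <- c(cand, x)
  }
  cand <- unique(cand)
  if (length(cand) == 0L) return(NA_character_)
  if (length(cand) == 1L) return(cand)
  NULL
}

#' Phase a nuclear family by minimal-recombination transmission inference
#'
#' At each marker where a parent is heterozygous, the transmitted allele is
#' deduced for every child where the trio genotypes force it. The parent's
#' two haplotypes are then anchored along each chromosome by choosing, per
#' adjacent pair of informative markers, the relative phase that minimises
#' apparent crossovers across the children (majority vote; ties keep the
#' running phase). Origin labels between a child's informative markers are
#' imputed when both flanks agree; unknowable stretches, including
#' chromosome ends beyond the outermost informative marker, stay `NA`.
#'
#' @param geno genotype data.frame from [read_genotypes()].
#' @param ped a [pedigree()]; both founders must be genotype columns.
#' @return object of class `transmission_track`: list with `markers`
#'   (marker/chrom/pos data.frame), `children`, and `origin` — per parent a
#'   markers-by-children matrix with entries `"A"`, `"B"` or `NA`.
#' @export
phase_nuclear_family <- function(geno, ped) {
  fa <- ped_father(ped); mo <- ped_mother(ped)
  kids <- intersect(ped_children(ped), names(geno))
  if (!all(c(fa, mo) %in% names(geno))) stop("both parents must be genotyped")
  if (length(kids) == 0L) stop("no genotyped children found in genotype table")
  geno <- geno[order(geno$chrom, geno$pos), , drop = FALSE]
  n <- nrow(geno)
  gts <- lapply(c(stats::setNames(c(fa, mo), c(fa, mo)), stats::setNames(kids, kids)),
                function(m) lapply(geno[[m]], split_gt))
  # Mendelian consistency check (joint over both parents)
  for (i in seq_len(n)) {
    fg <- gts[[fa]][[i]]; mg <- gts[[mo]][[i]]
    if (is.null(fg) || is.null(mg)) next
    for (k in kids) {
      cg <- gts[[k]][[i]]
      if (is.null(cg)) next
      ok <- any(vapply(list(cg, rev(cg)), function(p)
        p[1] %in% fg && p[2] %in% mg, logical(1)))
      if (!ok)
        stop(sprintf("Mendelian inconsistency at marker %s for child %s",
                     geno$marker[i], k))
    }
  }
  origin <- list()
  for (parent in c(fa, mo)) {
    other <- if (parent == fa) mo else fa
    lab <- matrix(NA_character_, nrow = n, ncol = length(kids),
                  dimnames = list(NULL, kids))
    for (ch in unique(geno$chrom)) {
      rows <- which(geno$chrom == ch)
      bits <- matrix(NA, nrow = length(rows), ncol = length(kids))
      informative <- logical(length(rows))
      for (ri in seq_along(rows)) {
        i <- rows[ri]
        pg <- gts[[parent]][[i]]
        if (is.null(pg) || pg[1] == pg[2]) next  # missing or homozygous: uninformative
        informative[ri] <- TRUE
        og <- gts[[other]][[i]]
        for (kj in seq_along(kids)) {
          tr <- deduce_transmitted(gts[[kids[kj]]][[i]], pg, og)
          if (!is.null(tr) && !is.na(tr)) bits[ri, kj] <- (tr == pg[1])
        }
      }
      inf_idx <- which(informative & rowSums(!is.na(bits)) > 0)
      if (!length(inf_idx)) next
      flip <- logical(length(inf_idx))
      for (q in seq_along(inf_idx)[-1]) {
        a <- bits[inf_idx[q - 1], ]; b <- bits[inf_idx[q], ]
        both <- !is.na(a) & !is.na(b)
        # crossovers implied by keeping the running phase vs flipping it
        d_keep <- sum(xor(a[both], b[both]))
        d_flip <- sum(both) - d_keep
        flip[q] <- if (d_flip < d_keep) !flip[q - 1] else flip[q - 1]
      }
      for (q in seq_along(inf_idx)) {
        b <- bits[inf_idx[q], ]
        v <- xor(b, flip[q])            # phased bit: TRUE = hapA
        lab[rows[inf_idx[q]], ] <- ifelse(is.na(v), NA, ifelse(v, "A", "B"))
      }
      # impute constant origin between informative markers with equal flanks
      for (kj in seq_along(kids)) {
        col <- lab[rows, kj]
        known <- which(!is.na(col))
        if (length(known) >= 2) {
          for (q in seq_len(length(known) - 1)) {
            a <- known[q]; b <- known[q + 1]
            if (b > a + 1 && col[a] == col[b]) col[(a + 1):(b - 1)] <- col[a]
          }
        }
        lab[rows, kj] <- col
      }
    }
    origin[[if (parent == fa) "father" else "mother"]] <- lab
  }
  structure(list(markers = geno[c("marker", "chrom", "pos")],
                 children = kids, origin = origin),
            class = "transmission_track")
}

#' IBD segments for a sibling pair
#'
#' At each marker where both siblings have a known origin label from both
#' parents, the IBD state is the number of parents from whom the two
#' inherited the same haplotype. Runs of equal state merge into segments;
#' the boundary between two states is placed at the midpoint between the
#' flanking informative markers, and segments are clipped to the outermost
#' informative markers of each chromosome.
#'
#' @param track a `transmission_track` from [phase_nuclear_family()].
#' @param pair character vector of two child ids.
#' @return data.frame with `chrom`, `start`, `end`, `state` (0/1/2),
#'   `id1`, `id2`.
#' @export
ibd_states <- function(track, pair) {
  stopifnot(length(pair) == 2L)
  if (!all(pair %in% track$children))
    stop("IBD states are defined for genotyped siblings; unknown id: ",
         paste(setdiff(pair, track$children), collapse = ", "))
  eqF <- track$origin$father[, pair[1]] == track$origin$father[, pair[2]]
  eqM <- track$origin$mother[, pair[1]] == track$origin$mother[, pair[2]]
  state <- ifelse(is.na(eqF) | is.na(eqM), NA, eqF + eqM)
  out <- list()
  for (ch in unique(track$markers$chrom)) {
    rows <- which(track$markers$chrom == ch)
    inf <- rows[!is.na(state[rows])]
    if (length(inf) == 0L) next
    pos <- track$markers$pos[inf]
    s <- state[inf]
    brk <- which(s[-1] != s[-length(s)])
    seg_start <- c(pos[1], floor((pos[brk] + pos[brk + 1]) / 2) + 1)
    seg_end <- c(floor((pos[brk] + pos[brk + 1]) / 2), pos[length(pos)])
    out[[ch]] <- data.frame(chrom = ch, start = seg_start, end = seg_end,
                            state = s[c(1, brk + 1)],
                            id1 = pair[1], id2 = pair[2], stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(chrom = character(), start = numeric(), end = numeric(),
                      state = numeric(), id1 = character(), id2 = character()))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Candidate regions: proband IBD2 minus sib-shared IBD2
#'
#' Regions where the two probands share both parental haplotypes
#' (IBD = 2), excluding any region where either proband also shares both
#' haplotypes with an unaffected genotyped sibling (so the remaining
#' regions have IBD 0 or 1 between each proband and every unaffected sib).
#'
#' @param track a `transmission_track`.
#' @param ped a [pedigree()] with exactly two affected children.
#' @return a `region_set`.
#' @export
select_candidate_regions <- function(track, ped) {
  probands <- intersect(ped_probands(ped), track$children)
  if (length(probands) != 2L)
    stop("exactly two genotyped probands required, found ", length(probands))
  seg <- ibd_states(track, probands)
  ibd2 <- seg[seg$state == 2, c("chrom", "start", "end"), drop = FALSE]
  if (nrow(ibd2) == 0L) return(region_set())
  keep <- region_set(ibd2)
  unaffected <- setdiff(track$children, ped_probands(ped))
  for (p in probands) for (u in unaffected) {
    s <- ibd_states(track, c(p, u))
    s2 <- s[s$state == 2, c("chrom", "start", "end"), drop = FALSE]
    if (nrow(s2)) keep <- subtract_region_sets(keep, region_set(s2))
  }
  keep
}

#' Default genetic map: 22 human-like autosomes at 1 cM/Mb
#'
#' Physical lengths approximate the human autosomes (~2.88 Gb, hence ~28.8
#' Morgans at the uniform 1 cM/Mb rate).
#'
#' @return data.frame with `chrom`, `length_bp`, `morgans`.
#' @export
default_genetic_map <- function() {
  mb <- c(249, 243, 198, 191, 181, 171, 159, 146, 141, 136, 135, 134,
          115, 107, 102, 90, 81, 78, 59, 63, 48, 51)
  data.frame(chrom = paste0("chr", seq_along(mb)),
             length_bp = mb * 1e6, morgans = mb / 100)
}

# crossover breakpoints of one meiosis: Poisson count over the chromosome's
# genetic length, positions uniform, no interference
meiosis_breaks <- function(morgans, length_bp) {
  k <- stats::rpois(1, morgans)
  if (k == 0) return(numeric())
  sort(stats::runif(k, min = 0, max = length_bp))
}

# equality parity of two gametes along [0, L]: segments where the two sibs
# received the same parental haplotype
sib_share_parity <- function(bp_all, breaks1, breaks2, same_start) {
  # at position x equality = same_start XOR parity of breaks before x
  nb <- findInterval(bp_all, sort(c(breaks1, breaks2)))
  xor(rep(same_start, length(bp_all)), nb %% 2 == 1)
}

#' Expected genome fraction in each sibling IBD state, by simulation
#'
#' Simulates full-sibling pairs under the crossover model (Poisson crossover
#' counts over each chromosome's genetic length, uniform positions, random
#' founder haplotype starts) and measures the fraction of the genome where
#' the pair shares 0, 1 or 2 parental haplotypes. For any map the IBD = 2
#' fraction converges to 1/4 (states 0/1/2 to 1/4, 1/2, 1/4).
#'
#' @param n_pairs number of simulated sib pairs.
#' @param map genetic map data.frame (`chrom`, `length_bp`, `morgans`);
#'   default [default_genetic_map()].
#' @param seed RNG seed.
#' @return mean IBD = 2 genome fraction, with attribute `state_fractions`
#'   (named mean fractions for states 0, 1, 2) and `per_pair` (vector of
#'   per-pair IBD2 fractions).
#' @export
expected_ibd2_fraction <- function(n_pairs = 2000, map = default_genetic_map(),
                                   seed = 1) {
  stopifnot(n_pairs >= 1, nrow(map) >= 1, all(map$length_bp > 0))
  set.seed(seed)
  total <- sum(map$length_bp)
  frac2 <- numeric(n_pairs)
  acc <- c(`0` = 0, `1` = 0, `2` = 0)
  for (p in seq_len(n_pairs)) {
    len_state <- c(`0` = 0, `1` = 0, `2` = 0)
    for (ci in seq_len(nrow(map))) {
      L <- map$length_bp[ci]; gl <- map$morgans[ci]
      bf1 <- meiosis_breaks(gl, L); bf2 <- meiosis_breaks(gl, L)
      bm1 <- meiosis_breaks(gl, L); bm2 <- meiosis_breaks(gl, L)
      sameF0 <- stats::runif(1) < 0.5  # both sibs start on the same paternal haplotype
      sameM0 <- stats::runif(1) < 0.5
      cuts <- sort(unique(c(0, bf1, bf2, bm1, bm2, L)))
      starts <- cuts[-length(cuts)]
      widths <- diff(cuts)
      eqF <- sib_share_parity(starts, bf1, bf2, sameF0)
      eqM <- sib_share_parity(starts, bm1, bm2, sameM0)
      st <- eqF + eqM
      for (s in 0:2) len_state[s + 1] <- len_state[s + 1] + sum(widths[st == s])
    }
    frac2[p] <- len_state["2"] / total
    acc <- acc + len_state / total
  }
  structure(mean(frac2),
            state_fractions = acc / n_pairs,
            per_pair = frac2)
}
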