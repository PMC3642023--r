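# fully informative toy design: father het A/B at every marker (haplotype 1
# carries A, haplotype 2 carries B), mother homozygous A/A, so the paternal
# transmitted allele is always deducible and the maternal track is unknown.
toy_geno <- function(origins, pos = seq(10, 10 * ncol(origins), by = 10)) {
  n <- ncol(origins)
  g <- data.frame(marker = sprintf("m%02d", seq_len(n)), chrom = "chr1",
                  pos = pos, stringsAsFactors = FALSE)
  g[["1"]] <- "A/A"   # mother
  g[["2"]] <- "A/B"   # father
  for (k in rownames(origins))
    g[[k]] <- paste(ifelse(origins[k, ] == 1, "A", "B"), "A", sep = "/")
  g
}

toy_ped <- function(kids, affected = kids[1:2]) {
  pedigree(id = c("1", "2", kids), father = c(NA, NA, rep("2", length(kids))),
           mother = c(NA, NA, rep("1", length(kids))),
           sex = c(2, 1, rep(1, length(kids))),
           affected = c(FALSE, FALSE, kids %in% affected))
}

test_that("a forced trio deduction assigns the transmitted haplotype", {
  origins <- matrix(2, nrow = 1, ncol = 1, dimnames = list("3", NULL))
  tr <- phase_nuclear_family(toy_geno(origins), toy_ped("3", affected = "3"))
  # child carries B from the het father; the label is anchored to father's
  # second allele and the mother is uninformative throughout
  expect_equal(unname(tr$origin$father[1, "3"]), "B")
  expect_true(is.na(tr$origin$mother[1, "3"]))
})

test_that("phasing recovers a planted crossover from fully informative markers", {
  origins <- rbind(`3` = rep(1, 10), `4` = rep(2, 10), `5` = c(rep(1, 5), rep(2, 5)),
                   `6` = rep(1, 10))
  tr <- phase_nuclear_family(toy_geno(origins), toy_ped(c("3", "4", "5", "6")))
  of <- tr$origin$father
  expect_false(any(is.na(of)))
  # recovered tracks equal the planted ones up to a global haplotype swap:
  # relative agreement patterns are invariant
  expect_true(all(of[, "3"] == of[, "6"]))
  expect_true(all(of[, "3"] != of[, "4"]))
  expect_equal(of[, "3"] == of[, "5"], rep(c(TRUE, FALSE), each = 5),
               ignore_attr = TRUE)
  # exactly one crossover recovered in child 5, none elsewhere
  switches <- function(x) sum(x[-1] != x[-length(x)])
  expect_equal(unname(apply(of, 2, switches)), c(0, 0, 1, 0))
})

test_that("greedy phase anchoring attains the brute-force minimal crossover count", {
  set.seed(33)
  for (rep in 1:6) {
    n_mark <- 8; kids <- c("3", "4", "5")
    origins <- do.call(rbind, lapply(kids, function(k) {
      o <- numeric(n_mark); h <- sample(2, 1)
      for (m in seq_len(n_mark)) { if (runif(1) < 0.2) h <- 3 - h; o[m] <- h }
      o
    }))
    rownames(origins) <- kids
    tr <- phase_nuclear_family(toy_geno(origins), toy_ped(kids))
    got_cost <- sum(apply(tr$origin$father, 2, function(x)
      sum(x[-1] != x[-length(x)])))
    # oracle: enumerate all 2^8 per-marker phase assignments
    bits <- origins == 1
    best <- Inf
    for (code in 0:(2^n_mark - 1)) {
      fv <- as.logical(bitwAnd(code, 2^(seq_len(n_mark) - 1)))
      ph <- t(xor(t(bits), fv))
      cost <- sum(ph[, -1] != ph[, -n_mark])
      best <- min(best, cost)
    }
    expect_equal(got_cost, best)
  }
})

test_that("Mendelian inconsistencies abort with the marker and child named", {
  origins <- matrix(1, nrow = 1, ncol = 3, dimnames = list("3", NULL))
  g <- toy_geno(origins)
  g[2, "3"] <- "C/C"
  expect_error(phase_nuclear_family(g, toy_ped("3", affected = "3")),
               "marker m02 for child 3")
})

test_that("IBD segments merge runs with midpoint boundaries and are symmetric", {
  mk <- data.frame(marker = sprintf("m%02d", 1:10), chrom = "chr1",
                   pos = seq(10, 100, by = 10))
  oA <- matrix("A", 10, 2, dimnames = list(NULL, c("3", "4")))
  of <- oA; of[6:10, "4"] <- "B"
  tr <- manual_track(mk, c("3", "4"), of, oA)
  seg <- ibd_states(tr, c("3", "4"))
  expect_equal(seg$state, c(2, 1))
  expect_equal(seg$start, c(10, 56))  # boundary at floor((50+60)/2) = 55
  expect_equal(seg$end, c(55, 100))
  seg2 <- ibd_states(tr, c("4", "3"))
  expect_equal(seg2[c("chrom", "start", "end", "state")],
               seg[c("chrom", "start", "end", "state")])
  expect_error(ibd_states(tr, c("3", "9")), "unknown id")
})

test_that("candidate regions exclude spans where a sib matches a proband IBD2", {
  mk <- data.frame(marker = sprintf("m%02d", 1:10), chrom = "chr1",
                   pos = seq(10, 100, by = 10))
  oA <- matrix("A", 10, 3, dimnames = list(NULL, c("3", "4", "5")))
  of <- oA; of[1:5, "5"] <- "A"; of[6:10, "5"] <- "B"
  tr <- manual_track(mk, c("3", "4", "5"), of, oA)
  ped <- toy_ped(c("3", "4", "5"), affected = c("3", "4"))
  cand <- select_candidate_regions(tr, ped)
  # sib 5 is IBD2 with both probands over pos 10-55: that span is excluded
  expect_equal(as.data.frame(cand),
               data.frame(chrom = "chr1", start = 56, end = 100),
               ignore_attr = TRUE)
  # without unaffected sibs the proband IBD2 set is returned unchanged
  tr2 <- manual_track(mk, c("3", "4"), of[, 1:2], oA[, 1:2])
  cand2 <- select_candidate_regions(tr2, toy_ped(c("3", "4")))
  expect_equal(as.data.frame(cand2),
               data.frame(chrom = "chr1", start = 10, end = 100),
               ignore_attr = TRUE)
  expect_error(select_candidate_regions(tr2, toy_ped(c("3", "4"), affected = "3")),
               "two genotyped probands")
})

test_that("inferred IBD states replay the simulator's true transmission", {
  sim <- simulate_family(simulation_config(), seed = 3)
  tr <- phase_nuclear_family(sim$geno, sim$ped)
  for (pair in list(c("10", "8"), c("3", "7"))) {
    seg <- ibd_states(tr, pair)
    truth <- true_ibd_segments(sim, pair)
    # segments tile each chromosome without overlap
    for (ch in unique(seg$chrom)) {
      s <- seg[seg$chrom == ch, ]
      if (nrow(s) > 1) expect_equal(s$start[-1], s$end[-nrow(s)] + 1)
    }
    ok <- 0; tot <- 0
    for (i in seq_len(nrow(seg))) {
      m <- sim$geno[sim$geno$chrom == seg$chrom[i] &
                      sim$geno$pos >= seg$start[i] & sim$geno$pos <= seg$end[i], ]
      for (j in seq_len(nrow(m))) {
        ts <- truth$state[truth$chrom == m$chrom[j] &
                            truth$start <= m$pos[j] & truth$end >= m$pos[j]]
        tot <- tot + 1
        if (length(ts) == 1 && ts == seg$state[i]) ok <- ok + 1
      }
    }
    # disagreement only possible at midpoint-placed boundaries
    expect_gt(ok / tot, 0.98)
  }
  cand <- select_candidate_regions(tr, sim$ped)
  ibd2 <- ibd_states(tr, sort(ped_probands(sim$ped)))
  ibd2 <- region_set(ibd2[ibd2$state == 2, c("chrom", "start", "end")])
  # candidate set is a subset of the proband IBD2 set
  expect_equal(summarize_region_set(intersect_region_sets(cand, ibd2))$total_bp,
               summarize_region_set(cand)$total_bp)
})

test_that("sib-pair IBD state fractions behave under the crossover model", {
  f0 <- expected_ibd2_fraction(n_pairs = 800,
                               map = data.frame(chrom = "chr1", length_bp = 1e6,
                                                morgans = 0),
                               seed = 5)
  # no recombination: each pair is all-or-nothing, P(IBD2) = 1/4
  expect_true(all(attr(f0, "per_pair") %in% c(0, 1)))
  expect_lt(abs(as.numeric(f0) - 0.25), 3 * sqrt(0.25 * 0.75 / 800))
  f <- expected_ibd2_fraction(n_pairs = 400,
                              map = data.frame(chrom = paste0("chr", 1:4),
                                               length_bp = rep(20e6, 4),
                                               morgans = rep(0.2, 4)),
                              seed = 6)
  sf <- attr(f, "state_fractions")
  expect_equal(sum(sf), 1)
  expect_lt(abs(sf[["2"]] - 0.25), 0.05)
  expect_lt(abs(sf[["1"]] - 0.50), 0.05)
})
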