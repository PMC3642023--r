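cnv_row <- function(chrom = "chr1", start = 1e6, end = 1.1e6, type = "del",
                    sample = "3", n_snps = 12, confidence = 500) {
  data.frame(chrom = chrom, start = start, end = end, type = type,
             sample = sample, n_snps = n_snps, confidence = confidence,
             stringsAsFactors = FALSE)
}

test_that("marker-support and sparsity post-filters apply the published rules", {
  calls <- rbind(cnv_row(n_snps = 9), cnv_row(n_snps = 10), cnv_row(n_snps = 44))
  expect_equal(filter_min_snps(calls)$n_snps, c(10, 44))
  # 11 markers over 16,914 bp: mean gap ~1,691 bp, kept
  dense <- cnv_row("chr2", 41082092, 41099005, n_snps = 11)
  expect_equal(nrow(filter_sparse(dense)), 1L)
  # 10 markers over 600 kb: mean gap ~66.7 kb, removed
  sparse <- cnv_row("chr5", 1e6, 1e6 + 6e5 - 1, n_snps = 10)
  expect_equal(nrow(filter_sparse(sparse)), 0L)
  # 2 markers exactly 50 kb apart: gap not strictly above the cap, kept
  edge <- cnv_row("chr5", 1e6, 1e6 + 50000 - 1, n_snps = 2)
  expect_equal(nrow(filter_sparse(edge)), 1L)
  expect_warning(out <- filter_sparse(cnv_row(n_snps = 1)), "single-marker")
  expect_equal(nrow(out), 0L)
})

test_that("blacklist filter removes calls mostly inside masked regions", {
  masks <- list(cen = region_set("chr1", 1e6, 1059999),
                ig = region_set("chr9", 1, 1e6))
  sixty <- cnv_row("chr1", 1e6, 1099999)              # 60,000/100,000 masked
  fifty <- cnv_row("chr1", 1010000, 1109999)          # exactly 50%: kept
  away <- cnv_row("chr2")
  expect_equal(nrow(filter_blacklist(sixty, masks)), 0L)
  expect_equal(nrow(filter_blacklist(fifty, masks)), 1L)
  expect_equal(nrow(filter_blacklist(away, masks)), 1L)
})

test_that("confident read-depth calls need type-specific size and confidence", {
  calls <- rbind(
    cnv_row("chr1", 193574801, 193871200, "del", confidence = 500),  # 296,400 bp
    cnv_row("chr13", 26049001, 26110000, "dup", confidence = 400),   # 61,000 bp
    cnv_row("chr2", 1e6, 1e6 + 9998, "del", confidence = 999),       # 9,999 bp
    cnv_row("chr3", 1e6, 1e6 + 3e5, "dup", confidence = 250))
  out <- erds_confident_filter(calls)
  expect_equal(out$chrom, "chr1")
  calls$confidence[2] <- NA
  expect_warning(out2 <- erds_confident_filter(calls), "without confidence")
  expect_equal(nrow(out2), 1L)
})

test_that("the three post-filters commute", {
  set.seed(9)
  masks <- list(cen = region_set("chr1", 5e6, 5.5e6))
  calls <- do.call(rbind, lapply(1:40, function(i) {
    s <- runif(1, 1e5, 9e6)
    cnv_row("chr1", s, s + runif(1, 1e4, 1.2e6),
            sample = as.character(sample(3:10, 1)),
            n_snps = sample(c(1, 5, 10, 20, 40), 1))
  }))
  perms <- list(c(1, 2, 3), c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  fs <- list(function(x) filter_min_snps(x),
             function(x) suppressWarnings(filter_sparse(x)),
             function(x) filter_blacklist(x, masks))
  results <- lapply(perms, function(p) {
    out <- calls
    for (k in p) out <- fs[[k]](out)
    sort(paste(out$chrom, out$start, out$sample))
  })
  for (r in results[-1]) expect_equal(r, results[[1]])
})

test_that("family grouping needs reciprocal overlap and partitions the calls", {
  a <- cnv_row("chr1", 1e6, 2e6, sample = "3")
  b <- cnv_row("chr1", 1.7e6, 2.7e6, sample = "4")   # 30% reciprocal: separate
  expect_equal(nrow(group_family_calls(rbind(a, b))), 2L)
  # random fragmentation of one true CNV across 6 samples merges to one region
  set.seed(4)
  frags <- do.call(rbind, lapply(3:8, function(s)
    cnv_row("chr2", 5e6 - round(runif(1, 0, 5e4)), 6e6 + round(runif(1, 0, 5e4)),
            sample = as.character(s))))
  g <- group_family_calls(frags)
  expect_equal(nrow(g), 1L)
  expect_equal(g$carriers, paste(3:8, collapse = ","))
  expect_equal(g$start, min(frags$start))
  expect_equal(g$end, max(frags$end))
  # same span, different kind: never merged
  two <- rbind(cnv_row("chr3", 1e6, 2e6, "del"), cnv_row("chr3", 1e6, 2e6, "dup"))
  expect_equal(nrow(group_family_calls(two)), 2L)
  mixed <- rbind(a, b, frags, two)
  gg <- group_family_calls(mixed)
  expect_equal(sum(gg$n_calls), nrow(mixed))  # carrier sets partition the input
})

test_that("inheritance labels child carriers and flags de-novo candidates", {
  ped <- read_ped(extdata("family.ped"))
  g <- rbind(
    data.frame(chrom = "chr1", start = 1, end = 2, type = "del",
               carriers = "1,5,7", n_calls = 3),
    data.frame(chrom = "chr2", start = 1, end = 2, type = "dup",
               carriers = "10,8", n_calls = 2),
    data.frame(chrom = "chr3", start = 1, end = 2, type = "del",
               carriers = "1,2,3", n_calls = 3))
  inh <- assess_inheritance(g, ped)
  expect_equal(inh$inheritance[inh$region_id == 1], rep("mother", 2))
  expect_equal(inh$inheritance[inh$region_id == 2], rep("de_novo_candidate", 2))
  expect_equal(inh$inheritance[inh$region_id == 3], "both")
  expect_true(segregation_check(g[2, ], ped))     # carriers exactly the probands
  expect_false(segregation_check(g[1, ], ped))
  expect_false(segregation_check(
    data.frame(carriers = "10", stringsAsFactors = FALSE), ped))  # misses one affected
})

test_that("BAF and sequence count follow their read-count definitions", {
  expect_equal(compute_baf(10, 10), 0.5)
  expect_equal(compute_baf(12, 0), 0)
  expect_equal(compute_baf(3, 9), 0.75)
  expect_true(is.na(compute_baf(0, 0)))
  p <- data.frame(chrom = "chr1", pos = 1:3, ref_count = c(30, 10, 0),
                  alt_count = c(0, 10, 25), is_snv = c(FALSE, TRUE, TRUE))
  tk <- compute_sequence_count(p, baseline = 30)
  expect_equal(tk$sequence_count, c(1, 2 / 3, 25 / 30))
  expect_equal(tk$baf, c(NA, 0.5, 1))
  expect_error(compute_sequence_count(p, baseline = 0), "baseline")
})

test_that("simulated deletions and diploid regions separate in depth and BAF", {
  set.seed(21)
  pos <- seq(1e6, 1e6 + 2e5, by = 500)
  het <- runif(length(pos)) < 0.5
  del <- simulate_pileup("chr1", pos, copy = 1L, het = het, depth = 50)
  dip <- simulate_pileup("chr1", pos, copy = 2L, het = het, depth = 50)
  dup <- simulate_pileup("chr1", pos, copy = 3L, het = het, depth = 50)
  region <- list(chrom = "chr1", start = 1e6, end = 1e6 + 2e5)
  ev_del <- deletion_evidence(region, compute_sequence_count(del, baseline = 50))
  ev_dip <- deletion_evidence(region, compute_sequence_count(dip, baseline = 50))
  expect_true(ev_del$deletion)
  expect_false(ev_dip$deletion)
  expect_lt(abs(ev_del$mean_sequence_count - 0.5), 0.05)
  expect_lt(abs(mean(compute_sequence_count(dup, baseline = 50)$sequence_count) - 1.5),
            0.05)
  # all-homozygous region at normal depth: decided on depth alone, flagged
  hom <- simulate_pileup("chr1", pos, copy = 2L, het = rep(FALSE, length(pos)),
                         depth = 50)
  ev_hom <- deletion_evidence(region, compute_sequence_count(hom, baseline = 50))
  expect_false(ev_hom$deletion)
  expect_true(ev_hom$no_het_sites)
})
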