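test_that("meiosis follows the Poisson crossover model and is seed-deterministic", {
  set.seed(1)
  counts <- replicate(10000, length(meiosis_breaks(1, 1e8)))
  expect_lt(abs(mean(counts) - 1), 0.03)
  expect_equal(length(meiosis_breaks(0, 1e8)), 0L)
  set.seed(2); g1 <- simulate_meiosis(0.5, 1e7)
  set.seed(2); g2 <- simulate_meiosis(0.5, 1e7)
  expect_identical(g1, g2)
  expect_true(all(g1$breaks >= 0 & g1$breaks <= 1e7))
})

test_that("pileup simulation reflects copy number in depth and BAF", {
  set.seed(8)
  het <- rep(TRUE, 2000)
  p2 <- simulate_pileup("c", 1:2000, copy = 2L, het = het, depth = 50)
  expect_lt(abs(mean(compute_baf(p2$ref_count, p2$alt_count), na.rm = TRUE) - 0.5),
            0.01)
  expect_lt(abs(mean(p2$ref_count + p2$alt_count) - 50), 1)
  p1 <- simulate_pileup("c", 1:2000, copy = 1L, het = het, depth = 50)
  baf1 <- compute_baf(p1$ref_count, p1$alt_count)
  # hemizygous former-het sites collapse to BAF 0 or 1
  expect_gt(mean(baf1 %in% c(0, 1), na.rm = TRUE), 0.99)
  expect_lt(abs(mean(p1$ref_count + p1$alt_count) - 25), 1)
})

test_that("identical seeds reproduce byte-identical output trees", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  cfg <- small_sim_config()
  s1 <- simulate_family(cfg, seed = 5, out_dir = d1)
  s2 <- simulate_family(cfg, seed = 5, out_dir = d2)
  f1 <- sort(list.files(d1)); f2 <- sort(list.files(d2))
  expect_equal(f1, f2)
  for (f in f1)
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  s3 <- simulate_family(cfg, seed = 6, out_dir = withr::local_tempdir())
  expect_false(identical(s1$geno, s3$geno))
})

test_that("emitted files round-trip through the package readers", {
  d <- withr::local_tempdir()
  sim <- simulate_family(small_sim_config(), seed = 7, out_dir = d)
  expect_equal(read_ped(sim$files["ped"]), sim$ped)
  geno <- read_genotypes(sim$files["genotypes"])
  expect_equal(geno$marker, sim$geno$marker)
  expect_equal(geno[["10"]], sim$geno[["10"]])
  genes <- read_gene_models(sim$files["genes"])
  expect_equal(genes, sim$genes)
  v <- read_vcf_variants(sim$files["proband1"])
  expect_equal(v$key, sim$probands$proband1$key)
  expect_equal(v$zygosity, sim$probands$proband1$zygosity)
  el <- read_bed(sim$files["elements"])
  expect_equal(nrow(el), nrow(sim$elements))
  expect_setequal(paste(el$chrom, el$start, el$end),
                  paste(sim$elements$chrom, sim$elements$start, sim$elements$end))
  calls <- read_cnv_calls(sim$files["cnv_calls"])
  expect_equal(nrow(calls), nrow(sim$cnv_calls))
  pu <- read_pileup(sim$files[paste0("pileup_", sim$truth$pileup_carrier)])
  expect_equal(pu$ref_count, sim$pileups[[sim$truth$pileup_carrier]]$ref_count)
  expect_true(file.exists(sim$files["truth"]))
})

test_that("affected children are compound heterozygous at the planted gene", {
  for (seed in c(1, 23)) {
    sim <- simulate_family(small_sim_config(), seed = seed)
    keys <- sim$truth$causal_keys
    expect_length(keys, 2L)
    for (p in c("proband1", "proband2"))
      expect_true(all(keys %in% sim$probands[[p]]$key))
    # every unaffected child lacks at least one of the two causal variants
    causal <- sim$genes[[match(sim$truth$causal_gene,
                               vapply(sim$genes, `[[`, "", "gene"))]]
    lo <- min(causal$exon_start); hi <- max(causal$exon_end)
    unaffected <- setdiff(ped_children(sim$ped), ped_probands(sim$ped))
    for (k in unaffected) {
      gf <- sim$truth$gametes[[k]][["2"]][[causal$chrom]]
      gm <- sim$truth$gametes[[k]][["1"]][[causal$chrom]]
      has_f <- all(famprior:::gamete_origin_at(gf, c(lo, hi)) == 1) &&
        findInterval(lo, gf$breaks) == findInterval(hi, gf$breaks)
      has_m <- all(famprior:::gamete_origin_at(gm, c(lo, hi)) == 1) &&
        findInterval(lo, gm$breaks) == findInterval(hi, gm$breaks)
      expect_false(has_f && has_m)
    }
  }
})

test_that("planted CNVs group, inherit and fail segregation as constructed", {
  sim <- simulate_family(simulation_config(), seed = 9)
  ped <- sim$ped
  surv <- filter_blacklist(suppressWarnings(filter_sparse(
    filter_min_snps(sim$cnv_calls))), sim$masks)
  g <- group_family_calls(surv)
  # the junk calls are gone; one family region per planted CNV remains
  expect_equal(nrow(g), length(sim$truth$cnv_regions))
  inh <- assess_inheritance(g, ped)
  expect_false(any(inh$inheritance == "de_novo_candidate"))
  for (i in seq_len(nrow(g))) {
    tr <- sim$truth$cnv_regions[[which(vapply(sim$truth$cnv_regions, function(x)
      x$chrom == g$chrom[i] && x$start == g$start[i], logical(1)))]]
    expect_setequal(strsplit(g$carriers[i], ",")[[1]], tr$carriers)
    lab <- unique(inh$inheritance[inh$region_id == i])
    expect_equal(lab, ifelse(tr$parent == "2", "father", "mother"))
  }
})

test_that("an undisturbed background yields few chance shared candidates", {
  hits <- 0; runs <- 6
  for (seed in seq_len(runs)) {
    sim <- simulate_family(small_sim_config(plant_causal = FALSE,
                                            plant_noncoding = FALSE,
                                            plant_cnvs = FALSE), seed = 100 + seed)
    res <- run_coding_funnel(sim$probands$proband1, sim$probands$proband2)
    hits <- hits + length(res$shared_genes)
  }
  expect_lt(hits / runs, 2)
})
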