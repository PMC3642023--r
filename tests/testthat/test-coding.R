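test_that("call-quality filter applies zygosity-specific thresholds", {
  v <- rbind(snv("chr1", 1, "A", "G", "hom", 10), snv("chr1", 2, "A", "G", "hom", 25),
             snv("chr1", 3, "A", "G", "het", 39), snv("chr1", 4, "A", "G", "het", 40),
             snv("chr1", 5, "A", "G", "het", 90))
  out <- filter_by_quality(v)
  expect_equal(out$pos, c(2, 4, 5))  # 3 survivors
  expect_equal(filter_by_quality(snv("chr1", 9, "A", "G", "hom", 20))$pos, 9)  # boundary kept
  expect_equal(nrow(filter_by_quality(snv("chr1", 9, "A", "G", "het", 39.9))), 0L)
  noq <- snv("chr1", 7, "A", "G", "het", NA)
  out2 <- filter_by_quality(noq)
  expect_equal(nrow(out2), 0L)
  expect_equal(attr(out2, "n_missing_quality"), 1L)
})

test_that("coding and non-coding class filters partition classified variants", {
  classes <- c("nonsynonymous", "synonymous", "stopgain", "frameshift",
               "splicing", "UTR", "intronic", "intergenic")
  v <- do.call(rbind, lapply(seq_along(classes), function(i) {
    x <- snv("chr1", i, "A", "G"); x$function_class <- classes[i]; x
  }))
  cod <- filter_coding_changes(v)
  non <- filter_noncoding(v)
  expect_equal(sort(cod$function_class),
               sort(c("nonsynonymous", "stopgain", "frameshift", "splicing")))
  expect_equal(nrow(cod) + nrow(non), nrow(v))
  expect_length(intersect(cod$pos, non$pos), 0L)
  expect_false("synonymous" %in% cod$function_class)
})

test_that("rarity filter removes a variant only when some database MAF exceeds 1%", {
  v <- rbind(avar("k1", g1000 = 0.0027, esp = 0.0047),          # rare everywhere
             avar("k2", g1000 = 0.01),                          # boundary: not > 1%
             avar("k3", cg46 = 0.05),                           # common in one db
             avar("k4"))                                        # never observed
  out <- filter_by_frequency(v)
  expect_equal(out$key, c("k1", "k2", "k4"))
  expect_error(filter_by_frequency(v, databases = c("g1000", "nope")), "unknown")
  bad <- avar("k5", g1000 = 0.7)
  expect_error(filter_by_frequency(bad), "0.5")
})

test_that("deleteriousness filter reproduces the benign shared-variant worked example", {
  # a shared NOTCH2-like missense with SIFT 0.4 and PolyPhen 0.07 must fail
  d1327g <- avar("d1327g", sift = 0.4, polyphen = 0.07, gerp = 3)
  expect_equal(nrow(deleteriousness_filter(d1327g)), 0L)
  # ...while its MAF of 0.27% / 0.47% passes the rarity step
  expect_equal(nrow(filter_by_frequency(avar("d1327g", g1000 = 0.0027, esp = 0.0047))), 1L)
  hit <- avar("hit", sift = 0.01, polyphen = 0.95, gerp = 3.1)
  expect_equal(nrow(deleteriousness_filter(hit)), 1L)
  fs <- avar("fs", class = "frameshift")
  expect_equal(nrow(deleteriousness_filter(fs, missing_passes = TRUE)), 1L)
  expect_equal(nrow(deleteriousness_filter(fs, missing_passes = FALSE)), 0L)
})

test_that("tight PolyPhen threshold is at least as strict as the loose one", {
  set.seed(7)
  v <- do.call(rbind, lapply(1:200, function(i)
    avar(paste0("v", i),
         sift = ifelse(runif(1) < 0.1, NA, runif(1)),
         polyphen = ifelse(runif(1) < 0.1, NA, runif(1)),
         gerp = runif(1, -3, 6))))
  tight <- deleteriousness_filter(v, polyphen_min = 0.85)
  loose <- deleteriousness_filter(v, polyphen_min = 0.80)
  expect_true(all(tight$key %in% loose$key))
  none <- deleteriousness_filter(v, missing_passes = FALSE)
  expect_false(any(is.na(none$sift) | is.na(none$polyphen) | is.na(none$gerp)))
})

test_that("recessive model requires a homozygote or two distinct heterozygotes", {
  v <- rbind(avar("a1", gene = "A", zyg = "hom"),
             avar("b1", gene = "B", zyg = "het"),
             avar("c1", gene = "C", zyg = "het"), avar("c2", gene = "C", zyg = "het"),
             avar("d1", gene = "D", zyg = "het"), avar("d2", gene = "D", zyg = "het"),
             avar("d3", gene = "D", zyg = "het"),
             avar("e1", gene = NA, zyg = "hom"),
             avar("f1", gene = "F", zyg = "het"))
  cand <- recessive_gene_candidates(v)
  # independent oracle: exhaustive rule application per gene
  oracle <- Filter(function(g) {
    w <- v[!is.na(v$gene) & v$gene == g, ]
    any(w$zygosity == "hom") || sum(w$zygosity == "het") >= 2
  }, unique(v$gene[!is.na(v$gene)]))
  expect_equal(names(cand), sort(unlist(oracle)))
  expect_equal(nrow(cand$D), 3L)
  # invariant to input order
  set.seed(1)
  cand2 <- recessive_gene_candidates(v[sample(nrow(v)), ])
  expect_equal(names(cand2), names(cand))
  expect_equal(shared_candidates(cand, cand["C"]), "C")
  expect_equal(shared_candidates(cand, list()), character())
})

test_that("the full coding funnel is monotone and recovers a planted gene", {
  sim <- simulate_family(simulation_config(), seed = 11)
  res <- run_coding_funnel(sim$probands$proband1, sim$probands$proband2)
  expect_true(all(res$report$n_out <= res$report$n_in))
  expect_true(sim$truth$causal_gene %in% res$shared_genes)
  expect_true(all(sim$truth$causal_keys %in% res$candidates$proband1[[sim$truth$causal_gene]]$key))
  # both planted variants also survive the model-free shared-deleterious route
  expect_true(all(sim$truth$causal_keys %in% res$shared_deleterious$key))
})

test_that("funnel report counts replay against independent sequential filtering", {
  sim <- simulate_family(small_sim_config(), seed = 12)
  cfg <- funnel_config()
  res <- run_coding_funnel(sim$probands$proband1, sim$probands$proband2, config = cfg)
  v <- sim$probands$proband1
  r <- res$report[res$report$scope == "proband1", ]
  expect_equal(r$n_in[r$stage == "quality"], nrow(v))
  v <- v[!is.na(v$quality) &
           ifelse(v$zygosity == "hom", v$quality >= 20, v$quality >= 40), ]
  expect_equal(r$n_out[r$stage == "quality"], nrow(v))
  v <- v[v$function_class %in% c("nonsynonymous", "stopgain", "stoploss",
                                 "frameshift", "nonframeshift", "splicing"), ]
  expect_equal(r$n_out[r$stage == "coding_change"], nrow(v))
  keep <- !apply(as.matrix(v[c("maf_g1000", "maf_esp5400", "maf_cg46")]), 1,
                 function(x) any(!is.na(x) & x > 0.01))
  v <- v[keep, ]
  expect_equal(r$n_out[r$stage == "rarity"], nrow(v))
})

test_that("empty variant input yields empty outputs and a zero report", {
  empty <- avar("x")[0, ]
  res <- run_coding_funnel(empty, empty)
  expect_equal(res$shared_genes, character())
  expect_equal(nrow(res$shared_deleterious), 0L)
  expect_true(all(res$report$n_in == 0) && all(res$report$n_out == 0))
})
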