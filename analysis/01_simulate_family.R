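#!/usr/bin/env Rscript
# Step 1: generate the synthetic multiplex-family study.
#
# Emits a complete stand-in for the study's (undeposited) raw data: a PED
# pedigree of two parents and eight children (two affected, one child
# without DNA), dense SNP genotypes, per-proband whole-genome variant calls
# with quality scores, annotation resources (gene models, three reference
# MAF databases, SIFT/PolyPhen/GERP++ scores, conserved elements, chromatin
# states), an inherited-CNV call table with junk calls for the post-filters
# to remove, and read pileups over a planted hemizygous deletion. The two
# affected children are compound heterozygous at the planted causal gene.

suppressMessages(library(famprior))

seed <- 101
out <- "results/synthetic_family"
sim <- simulate_family(simulation_config(), seed = seed, out_dir = out)

cat("Synthetic study written to", out, "(seed", seed, ")\n\n")
cat("Pedigree: father 2 x mother 1;",
    length(ped_children(sim$ped)), "children; probands:",
    paste(ped_probands(sim$ped), collapse = ", "), "\n")
cat("Markers:", nrow(sim$geno), " gene models:", length(sim$genes), "\n")
cat("Variant calls: proband1 (id 10):", nrow(sim$probands$proband1),
    "; proband2 (id 8):", nrow(sim$probands$proband2), "\n")
cat("Planted causal gene:", sim$truth$causal_gene, "with variants",
    paste(sim$truth$causal_keys, collapse = " and "), "\n")
cat("Planted shared non-coding promoter variant:", sim$truth$noncoding_key, "\n")
cat("Planted CNV regions:", length(sim$truth$cnv_regions),
    "(+", sim$truth$junk_calls, "junk calls that the filters must remove)\n")
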