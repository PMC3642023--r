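#!/usr/bin/env Rscript
# Step 5: the non-coding variants-reduction funnel.
#
# Restricts each proband's calls to non-coding classes, applies the same
# three-database rarity rule, intersects the probands' surviving variants,
# and keeps only positions inside GERP++-conserved elements (score > 2) that
# also fall in 'active promoter' (chromHMM state 1) or 'strong enhancer'
# (states 4/5) intervals.

suppressMessages(library(famprior))

ind <- "results/synthetic_family"
if (!dir.exists(ind)) stop("run analysis/01_simulate_family.R first")
out <- "results/noncoding"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

genes <- read_gene_models(file.path(ind, "genes.tsv"))
freqs <- read_tsv_table(file.path(ind, "freqs.tsv"), id_cols = "key")
scores <- read_tsv_table(file.path(ind, "scores.tsv"), id_cols = "key")
p1 <- annotate_variants(read_vcf_variants(file.path(ind, "proband1.vcf")),
                        freqs, scores, genes)
p2 <- annotate_variants(read_vcf_variants(file.path(ind, "proband2.vcf")),
                        freqs, scores, genes)
elements <- read_bed(file.path(ind, "conserved_elements.bed"))
states <- read_bed(file.path(ind, "chromatin_states.bed"))
states$state <- as.integer(states$name)

res <- run_noncoding_funnel(p1, p2, elements, states)
write_tsv_table(res$report, file.path(out, "funnel_report.tsv"))
write_tsv_table(res$prioritized[c("key", "function_class", "element_score",
                                  "state", "state_class")],
                file.path(out, "prioritized_noncoding.tsv"))

cat("Funnel stages (variants in -> out):\n")
print(res$report, row.names = FALSE)
cat("\nPrioritized non-coding variants:", nrow(res$prioritized), "\n")
if (nrow(res$prioritized))
  print(res$prioritized[c("key", "state_class", "element_score")],
        row.names = FALSE)
truth <- jsonlite::read_json(file.path(ind, "truth.json"))
cat("Planted promoter variant recovered:",
    truth$noncoding_key %in% res$prioritized$key, "\n")
cat("Tables written to", out, "\n")
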