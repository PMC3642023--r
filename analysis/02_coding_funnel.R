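#!/usr/bin/env Rscript
# Step 2: the coding variants-reduction funnel on the two probands.
#
# Quality filter (hom >= Q20, het >= Q40) -> splicing/protein-altering
# classes -> MAF <= 1% in all of three reference databases -> recessive gene
# model (a homozygote or >= 2 heterozygotes per gene) -> genes shared by the
# probands; plus the model-free alternative: shared rare coding variants
# passing SIFT < 0.05, PolyPhen > 0.85, GERP++ > 2 (missing scores pass).

suppressMessages(library(famprior))

ind <- "results/synthetic_family"
if (!dir.exists(ind)) stop("run analysis/01_simulate_family.R first")
out <- "results/coding"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

genes <- read_gene_models(file.path(ind, "genes.tsv"))
freqs <- read_tsv_table(file.path(ind, "freqs.tsv"), id_cols = "key")
scores <- read_tsv_table(file.path(ind, "scores.tsv"), id_cols = "key")
p1 <- annotate_variants(read_vcf_variants(file.path(ind, "proband1.vcf")),
                        freqs, scores, genes)
p2 <- annotate_variants(read_vcf_variants(file.path(ind, "proband2.vcf")),
                        freqs, scores, genes)

res <- run_coding_funnel(p1, p2)

write_tsv_table(res$report, file.path(out, "funnel_report.tsv"))
for (nm in names(res$candidates)) {
  tab <- do.call(rbind, lapply(names(res$candidates[[nm]]), function(g) {
    v <- res$candidates[[nm]][[g]]
    data.frame(gene = g, key = v$key, zygosity = v$zygosity,
               function_class = v$function_class)
  }))
  if (is.null(tab)) tab <- data.frame(gene = character())
  write_tsv_table(tab, file.path(out, paste0(nm, "_candidates.tsv")))
}
write_tsv_table(data.frame(gene = res$shared_genes),
                file.path(out, "shared_genes.tsv"))
write_tsv_table(res$shared_deleterious[c("key", "gene", "function_class",
                                         "sift", "polyphen", "gerp")],
                file.path(out, "shared_deleterious_variants.tsv"))

cat("Funnel stages (variants in -> out):\n")
print(res$report, row.names = FALSE)
cat("\nCandidate recessive genes: proband1:", length(res$candidates$proband1),
    "; proband2:", length(res$candidates$proband2),
    "; shared:", length(res$shared_genes),
    paste0("(", paste(res$shared_genes, collapse = ", "), ")"), "\n")
cat("Model-free shared deleterious variants:", nrow(res$shared_deleterious), "\n")
cat("Tables written to", out, "\n")
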