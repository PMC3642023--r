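#!/usr/bin/env Rscript
# Step 4: CNV post-filtering, family segregation and read-level validation.
#
# Applies the array-call post-filters (>= 10 markers, mean inter-marker gap
# <= 50 kb, <= 50% blacklist overlap) to both the synthetic call table and
# the package's published family CNV table, groups calls into family-level
# regions, assigns inheritance, checks segregation with affected status, and
# validates the planted hemizygous deletion from sequence-count/BAF pileup
# signals in a carrier versus a non-carrier child.

suppressMessages(library(famprior))

ind <- "results/synthetic_family"
if (!dir.exists(ind)) stop("run analysis/01_simulate_family.R first")
out <- "results/cnv"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

analyse <- function(calls, masks, ped, label) {
  kept <- filter_blacklist(suppressWarnings(filter_sparse(filter_min_snps(calls))),
                           masks)
  g <- group_family_calls(kept)
  inh <- assess_inheritance(g, ped)
  g$segregates <- vapply(seq_len(nrow(g)), function(i)
    segregation_check(g[i, ], ped), logical(1))
  g$inherited_from <- vapply(seq_len(nrow(g)), function(i) {
    l <- unique(inh$inheritance[inh$region_id == i])
    if (length(l)) l else "none"
  }, "")
  cat(sprintf("%s: %d calls -> %d after post-filters -> %d family regions; ",
              label, nrow(calls), nrow(kept), nrow(g)))
  cat(sprintf("%d de-novo candidates, %d segregating with disease\n",
              sum(inh$inheritance == "de_novo_candidate"), sum(g$segregates)))
  g
}

ped_syn <- read_ped(file.path(ind, "family.ped"))
calls_syn <- read_cnv_calls(file.path(ind, "cnv_calls.tsv"))
masks_syn <- list(centromere = read_bed(file.path(ind, "masks.bed")))
g_syn <- analyse(calls_syn, masks_syn, ped_syn, "synthetic family")
write_tsv_table(g_syn, file.path(out, "synthetic_family_regions.tsv"))

# the published family call table shipped with the package (hg18)
calls_fam <- read_cnv_calls(system.file("extdata", "family_cnv_calls.tsv",
                                        package = "famprior"))
calls_fam$confidence <- NA_real_
masks_fam <- list(immunoglobulin = read_bed(system.file(
  "extdata", "immunoglobulin_hg18.bed", package = "famprior")))
ped_fam <- read_ped(system.file("extdata", "family.ped", package = "famprior"))
g_fam <- analyse(calls_fam, masks_fam, ped_fam, "study family (arrays)")
write_tsv_table(g_fam, file.path(out, "study_family_regions.tsv"))

# read-level deletion evidence on the planted 1-copy deletion
truth <- jsonlite::read_json(file.path(ind, "truth.json"))
reg <- truth$pileup_region
rows <- list()
for (who in c(truth$pileup_carrier, truth$pileup_control)) {
  pu <- read_pileup(file.path(ind, paste0("pileup_", who, ".tsv")))
  ev <- deletion_evidence(reg, compute_sequence_count(pu, baseline = 50))
  cat(sprintf("sample %s: mean sequence count %.2f, het BAF fraction %s -> deletion: %s\n",
              who, ev$mean_sequence_count,
              ifelse(is.na(ev$het_fraction), "NA", sprintf("%.2f", ev$het_fraction)),
              ev$deletion))
  rows[[who]] <- data.frame(sample = who, deletion = ev$deletion,
                            mean_sequence_count = ev$mean_sequence_count,
                            het_fraction = ev$het_fraction,
                            n_snv_sites = ev$n_snv_sites)
}
write_tsv_table(do.call(rbind, rows), file.path(out, "deletion_evidence.tsv"))
cat("Tables written to", out, "\n")
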