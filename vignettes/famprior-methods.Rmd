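---
title: "Prioritizing inherited variants in a multiplex pedigree: methods and design"
author: "famprior"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Prioritizing inherited variants in a multiplex pedigree: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(famprior)
```

## The analysis problem

famprior implements a family-based strategy for finding inherited disease
candidate variants from whole-genome sequencing of a two-generation
multiplex pedigree: two unaffected parents, eight children, two of them
affected (the probands, both sequenced; all members except one child
genotyped on a dense SNP array). Because both parents are unaffected and
2/8 children are affected, a recessive model is a natural first hypothesis,
and sibling haplotype sharing gives an orthogonal, annotation-free way to
shrink the candidate territory. The package provides four coordinated
analyses over standard file formats (VCF, PED, TSV, BED), plus a synthetic
study generator that plants known causal signals so that the whole pipeline
is testable end to end without access to protected human data.

Coordinates are 1-based inclusive everywhere (`length = end - start + 1`);
BED files are converted to/from their native 0-based half-open convention
only at read/write time, and the conversion is round-trip tested.

## The coding variants-reduction funnel

Per proband, variant calls pass through an ordered cascade:

1. **Call quality.** Calls carry a quality score on the
   $10\log_{10}[P(\mathrm{true})/P(\mathrm{false})]$ scale; homozygous
   calls below 20 and heterozygous calls below 40 are removed (calls at the
   threshold are kept; calls with no score at all are removed and counted
   separately, since they signal an upstream caller omission).
2. **Functional class.** Variants are classified against transcript models
   with precedence exonic/splicing > UTR > intronic > upstream/downstream >
   intergenic. CDS SNVs are subclassified by codon translation
   (synonymous/nonsynonymous/stopgain/stoploss), CDS indels by length
   modulo 3 (frameshift/non-frameshift), and intronic positions within 2 bp
   of an exon boundary (configurable) are splice-site variants. A variant
   hitting several transcripts takes its most deleterious class — the
   inclusive choice appropriate for the funnel's first step. Only
   splicing/protein-altering classes continue.
3. **Rarity.** A variant is removed iff its minor allele frequency exceeds
   1% in *any* of three reference databases (a 1000-Genomes-like, an
   exome-server-like, and a platform-control-like panel, supplied as TSV).
   A variant absent from every database is kept: never-observed is the
   strongest rarity evidence. dbSNP membership is deliberately *not* a
   filter — most dbSNP entries carry no frequency information and known
   pathogenic variants can be present there.
4. **Recessive gene model.** A gene qualifies if it carries at least one
   homozygous qualifying variant or at least two distinct heterozygous ones
   (compound heterozygote); the homozygous reading is forced by treating a
   homozygote as two mutated alleles. Compound-het pairs are *not*
   phase-checked at this stage — the funnel deliberately uses no parental
   genotypes, matching its role as a per-proband reduction; phase
   information enters later through the IBD analysis.
5. **Sharing.** Candidate genes present in both probands.

An alternative, model-free route skips step 4: the rare coding variants
shared by both probands are scored directly with SIFT < 0.05,
PolyPhen > 0.85 and GERP++ > 2.0. Two documented ambiguities are exposed as
options. The PolyPhen threshold appears in the source analysis as both
0.85 and 0.8; the default follows the stricter 0.85 and the looser value is
one keyword away (the strict output is provably a subset of the loose one,
which the tests assert). And "deleterious **or without predictions**" is
implemented per score — each missing score passes its own criterion
(`missing_passes = TRUE`) — because frameshift and splicing variants
legitimately have no SIFT/PolyPhen predictions; setting
`missing_passes = FALSE` gives the conservative bracket in which no
unscored variant survives.

Multi-allelic VCF records are decomposed into bi-allelic rows on read; the
source analysis does not state how they were handled, and decomposition is
the convention the rest of the pipeline assumes.

## Transmission phasing and sibling IBD

At a marker where a parent is heterozygous, a child's transmitted parental
allele is often forced by the trio of genotypes. Those deductions give, per
child, a sequence of haplotype-of-origin observations; what is not
observable from genotypes alone is the parent's own phase, i.e. how the
labels at neighbouring markers line up. famprior anchors the labels with a
minimal-recombination rule suitable for dense SNP data in a nuclear family:
for each adjacent pair of informative markers, the relative phase is chosen
by majority vote across children (the choice that implies fewer apparent
crossovers; ties keep the running phase). When every child is typed at both
flanking markers this greedy choice is exactly the global minimal-crossover
assignment, because each transition can be optimised independently; a
brute-force enumeration over all phase assignments on small families backs
this in the test suite. A dedicated external phasing engine is therefore
not wrapped: for this family shape the minimal-recombination inference is
the whole computation.

Between a child's informative markers the origin is imputed as constant
when both flanks agree, and left unknown otherwise; nothing is extrapolated
beyond the outermost informative marker of a chromosome. Mendelian
inconsistencies abort with the marker and child named — genotyping error is
not silently repaired. Chromosome X is excluded by the analysis defaults
(hemizygous males break the two-haplotype model).

Two siblings' IBD state at a marker is the number of parents (0, 1, 2) from
whom both inherited the same haplotype label. Runs of equal state merge
into segments, with the boundary placed at the midpoint between the
flanking informative markers — the unbiased choice when the true crossover
position is unobserved — and the marker-delimited convention means segment
sets are clipped to the genotyped territory. The candidate-region selection
is pure region algebra: the proband pair's IBD=2 set, minus the union over
(proband, unaffected sib) pairs of *their* IBD=2 sets, so every surviving
base has IBD 0 or 1 between each proband and every unaffected sibling.
Abutting segments merge, so region sets are always maximal runs.

The theoretical expectation that 25% of the genome is IBD=2 between two
sibs is checked by Monte-Carlo simulation: crossovers per meiosis are
Poisson over a chromosome's genetic length with uniform positions and no
interference, on a default map of 22 human-scale autosomes at a uniform
1 cM/Mb (~28.8 Morgans). With 2,000 simulated pairs the estimate lands
within a percentage point of 25%. On the scaled-down synthetic genome (see
below) any *single* family deviates widely from 25% — with only ~0.8
Morgans, segments are few and long — which is expected behaviour, not an
error; the 25% value is an expectation over meioses.

## CNV post-filtering, segregation and read-level validation

The package does not call CNVs: array-HMM and read-depth callers are
established external tools, and the computation the analysis itself defines
is what happens *after* calling. Array calls are kept when they span at
least 10 markers, have mean inter-marker distance at most 50 kb — computed
as span/(n−1), since n markers bound n−1 gaps — and overlap any blacklist
region (immunoglobulin loci, where somatic rearrangement mimics CNVs, and
centromeres) by no more than 50% *of the call's own span*, the standard
post-filter convention. Read-depth calls use separate confident-call
floors: deletions > 10 kb, duplications > 200 kb, confidence > 300.

Per-sample calls of the same kind merge into family-level regions at ≥ 50%
reciprocal overlap (transitively; the union span is reported). A child
carrier's region is inherited-from-father/mother if that parent carries the
same family region, else a de-novo candidate. A region *segregates* when
its child carriers are exactly the affected children; carrier parents are
exempt, as obligate unaffected transmitters under incomplete penetrance.

Read-level validation uses two signals counted from pileups: the
*sequence count* (depth normalised by the sample's diploid baseline, so two
copies sit near 1.0) and the *B-allele frequency* (fraction of reads
supporting the non-reference allele; diploid het sites cluster near 0.5).
A region supports a 1-copy deletion when its mean sequence count is below
0.75 **and** fewer than 10% of its SNV sites have BAF inside [0.25, 0.75] —
hemizygous former-het sites collapse to BAF 0 or 1. The 0.75/10% defaults
are this package's own operating point, chosen for clear class separation
at 50× coverage in simulation (sensitivity and specificity both ≥ 0.95 over
200 simulated regions); both are configurable, and a region with no SNV
sites is decided on depth alone and flagged.

## The non-coding funnel

Non-coding classes (UTR, intronic, upstream/downstream, intergenic,
non-coding transcripts) are the exact complement of the coding funnel's
classes — the two filters provably partition any classified input. The same
three-database 1% rarity rule applies per proband *before* the probands'
lists are intersected (the source analysis is ambiguous on the order;
per-proband-then-intersect is assumed and documented). Survivors are kept
only inside evolutionarily constrained elements — GERP++ elements with
element score > 2; an optional per-site score column is honoured when
present — and then only inside 'active promoter' (state 1) or 'strong
enhancer' (states 4–5) intervals of a 15-state chromHMM-style segmentation.
The state-to-class dictionary is an argument, so other segmentations can be
swapped in.

## What the synthetic study emulates — and what it does not

`simulate_family()` generates founder haplotypes at ~2,000 bi-allelic
markers over a scaled-down genome (4 chromosomes × 20 Mb at 1 cM/Mb — small
enough that the full pipeline runs in seconds, config-driven throughout),
transmits them through Poisson-crossover meioses, and emits every file the
pipeline consumes. Planted truth: one causal gene in which the two affected
children are compound heterozygous (one rare, deleterious variant per
parental haplotype; transmission at the locus is conditioned by rejection
sampling so every unaffected child lacks at least one variant — the
conditional crossover model is untouched), a rare shared promoter variant
inside a conserved element and a state-1 interval, three inherited CNVs
anchored to 14-marker windows (so the marker-support and sparsity filters
are guaranteed to keep them) plus junk calls those filters must remove, and
pileups over the planted deletion for a carrier and a non-carrier child
(transmission of that deletion is likewise conditioned so both a carrier
and a non-carrier child always exist).
Affected status is fully penetrant *in the generator* — the pipeline itself
never assumes penetrance.

Background sites (~2,000 per family, roughly half carried per child) get
database MAFs from a rare/common mixture (30% above the 1% cutoff, to
exercise the rarity filter), deleteriousness scores from a
benign/deleterious mixture, and ~8% deliberately low-quality calls. Only
~2% of background sites are coding, keeping chance recessive candidates
below about one gene per run so planted-gene recovery is measurable (the
acceptance suite requires recovery in ≥ 95% of 50 seeds).

Deliberate non-realism, hence what passing tests do **not** show about real
data: no linkage disequilibrium among founder haplotypes, no genotyping or
sequencing error beyond Poisson/binomial sampling, no crossover
interference, uniform recombination, no population structure in the MAF
draws, full penetrance, and a genome three orders of magnitude smaller than
human. The pipeline's *decision logic* is what the simulation validates;
calibration claims about real genomes are outside its reach.

## Numerical and interface choices

* All thresholds are strict or non-strict exactly as published: quality
  *< 20 / < 40* removed (so scores at the threshold survive), MAF *> 1%*
  removed, marker support *≥ 10* kept, mean gap *> 50 kb* removed, mask
  overlap *> 50%* removed, deletions *> 10 kb* / duplications *> 200 kb*
  with confidence *> 300* kept, SIFT *< 0.05* / PolyPhen *> 0.85* /
  GERP++ *> 2* kept. Boundary cases are pinned by tests.
* Funnel stages are monotone by construction and the runner refuses a
  stage that grows; stage errors abort with the stage name.
* Chromosome-name dialects ("chr1" vs "1") are reconciled by an optional
  prefix strip at read time; names are otherwise compared verbatim.
* TSV parsers reject duplicate identifiers and report the line number.
* Single-marker CNV calls have no defined inter-marker gap and are removed
  with a warning; calls lacking a confidence score are likewise removed
  with a warning by the confident-call filter.
* Test-suite problem sizes: the IBD Monte-Carlo uses 2,000 pairs (standard
  error ≈ 0.4 percentage points), deletion-evidence calibration 200
  regions × 40 sites at 50×, and pipeline recovery 50 seeded simulations at
  the generator defaults — sizes chosen so the whole suite completes in a
  few minutes while keeping the statistical checks well-powered.

## Known limitations

Only a single two-founder nuclear family is supported — no multi-generation
pedigrees, half-sibs, or population-based (unrelated-pair) IBD. The
phasing heuristic degrades when markers are sparse relative to crossover
density (about ten informative markers per crossover interval are needed
for exact recovery, per the simulation properties). SIFT/PolyPhen/GERP++
scores, conserved elements and chromatin states are consumed as inputs,
never computed; reference-genome handling (FASTA, liftover) is out of
scope, and the shipped study tables use hg18 coordinates as printed.
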