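---
title: "Methods: multi-omic analysis of an extreme-polyposis case"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-omic analysis of an extreme-polyposis case}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polypomics)
```

# Scope

`polypomics` re-implements, as tested and reusable functions, the
computations behind a multi-omic case study of extreme intestinal polyposis
in a dog: paired tumor (polyp) and normal tissue profiled by both WGS and
RNA-seq, alongside a 28-sample expression panel, shotgun microbiome data
and read-depth copy-number analysis. The package does not run aligners or
variant callers; it consumes candidate calls, alignment-hit records and
count matrices, and it ships synthetic-data generators that emulate each
input with planted ground truth so that every stage is verifiable offline.

# The prioritization cascade

Candidate germline missense variants carry read support in four contexts
(WGS/RNA x normal/polyp). The cascade applies, in order:

1. **Concordance** — keep variants found in all four contexts. The
   original analysis intersected caller outputs per context; since caller
   call sets are not part of the package's inputs, "found" is approximated
   by read support: at least 2 alt reads *and* VAF >= 0.05, both
   configurable (`presence_min_alt`, `presence_min_vaf`).
2. **Uniqueness** — drop variants seen in a comparison panel of other
   intestinal-tumor cases or in known-SNP sets, matched by exact
   (chrom, pos, ref, alt). No fuzzy indel matching: exact identity is the
   simplest defensible rule and the generators only plant exact matches.
3. **Annotation** — drop variants in genes flagged `retrogene` or
   `pseudogene` (closed vocabulary; unknown flags are an error rather than
   silently passing).
4. **Read support** — WGS depth >= 10 in *both* tissues, RNA depth >= 30
   in *either* tissue, polyp VAF >= 0.5 in *either* assay. All thresholds
   are inclusive (`>=`) and configurable.
5. **Polyp selection** — heterozygous variants whose polyp VAF strictly
   exceeds the normal VAF in *every* assay observed in both tissues are
   ranked first. This step ranks rather than filters because the original
   procedure prioritized rather than excluded; `selection_as_filter = TRUE`
   switches behaviour. Zygosity is inferred from the WGS normal VAF
   (het in [0.2, 0.8], hom above 0.8) because the selection rule is scoped
   to heterozygous variants and no genotype field is assumed.
6. **Conservation** (missense mode only) — drop a variant when its
   alternate allele occurs at the homologous position in >= 1 ortholog: a
   change that already happened during evolution is most likely a tolerated
   natural variant. Variants lacking a profile are retained with a warning.
7. **Structure annotation** (missense mode only) — copy an externally
   computed destabilization prediction into a priority flag; never a
   filter. Computing the stability change itself is out of scope.

Truncation mode runs the same cascade minus conservation and structure.

**Survivor tier.** The report's `top_keys` are the survivors that are both
polyp-selected and structure-prioritized (missense mode). Recovery metrics
compare this tier against planted truth: the selection and structure steps
never remove rows, so the tier — not the raw survivor list — is the
cascade's answer.

# Consequence classification and the substitution spectrum

Coding consequences are determined by codon substitution against a CDS
exon model (any indel whose length change is not a multiple of 3 is a
frameshift), with protein notation `<refAA><codon><altAA>`, `X` for stop
gains and `fs` for frameshifts. Indel calls inside or immediately adjacent
to a single-base run of length >= 6 can be flagged as homopolymer-prone.
Single-base substitutions collapse, via reverse-complement symmetry, onto
six classes; the spectrum reports per-class counts, the number of skipped
indels and the dominant class (`NA` on ties, rather than an arbitrary
winner).

# Expression analyses

**FPKM** is `count / (exonic kb x library millions)`; the log transform is
`log2(FPKM + 1)` — the study plots `log2(FPKM)` without stating zero
handling, and a pseudocount of 1 pins zero FPKM at 0. **Outlier calls** for
the case sample require the value to fall outside the across-sample
mean +/- 1 SD *and* to be the strict extremum over all samples (ties yield
no call); mean and SD include the case sample, and the statistic is
computed in log space (the study does not state log vs linear; log is the
default and the matrix handed in decides). **ssGSEA** follows the
rank-weighted running-sum formulation with exponent `alpha = 0.75` and the
unnormalized integral reported; the weight is the expression *rank* (N for
the top gene), which makes scores invariant under monotone transforms.
**Category fractions** report `round(100 * annotated / members)` with a
two-sided exact hypergeometric (Fisher) p-value against the background,
Benjamini–Hochberg-adjusted across categories; the original annotation
tool is unnamed, so the exact test is the package's choice. **Sample
clustering** is average-linkage agglomerative clustering on Euclidean
distances between score profiles, with a Newick rendering of the tree.

# Microbiome profiling

Profiling consumes read-pair hit records against a strain-resolved
database. Host depletion keeps pairs with *neither* read host-mapped.
Selection has two branches: a pair with >= 1 uniquely mapped read is
selected iff a uniquely mapped read has MAPQ > 0 (strict); a pair with
both reads multi-mapped is selected iff some hit combination is on the
same target, convergent (forward/reverse), and spans 50–1000 bp — the
"reasonable genomic distance" is unquantified in the source, so the bounds
are configuration. Rank-exclusive assignment then counts a pair once for a
rank iff all hits of both reads fall under one taxon at that rank, no
matter how many placements within it; pairs touching >= 2 taxa at the rank
are discarded, independently per rank. A pair multi-mapped across two
strains of one species is therefore discarded at strain rank but counted
at species rank — the source does not state its strain-rank behaviour, and
the discard rule is the literal reading. Accounting is total:
`assigned + discarded + unselected` equals the host-depleted input for
every rank. Cross-sample enrichment is compared on counts per million
host-depleted pairs. Bacterial gene tallies count a uniquely placed pair
for a gene iff all its aligned bases fall inside the gene's interval;
pairs overlapping two genes are ambiguous and uncounted, ties in the
ranking break by gene id.

# Copy-number analysis

Mapped-pair densities are tabulated per 1-kb tiling window by fragment
midpoint (`floor(midpoint/1000)`, final partial window included). Case
windows are normalized against the control genome:
`log2(case_cpm / control_cpm)` after scaling both to pairs per million,
with windows below 10 raw control pairs masked. The default library-size
estimate is the median over chromosomes of per-chromosome median window
counts (times the window count): a plain sum would absorb genuine
whole-chromosome gains into the library size and shrink their own ratio by
~0.2 units at 3 gained chromosomes in 10. Callers that know true library
sizes can pass them explicitly. A chromosome is called gained when the
median unmasked ratio is >= 0.32 and lost at <= -0.42; a pure single-copy
gain in a diploid genome sits at `log2(1.5) = 0.585`, and the defaults are
deliberately below that to tolerate impure or subclonal tissue. The
original study's exact calling statistic lives in unavailable
supplementary material, so medians against configurable thresholds are
this package's declared procedure.

# Synthetic data: what it emulates, and what it does not

All generators are pure functions of `(seed, config)`; reruns are
byte-identical.

* **Variant table** — one survivor is planted with the exemplar support
  pattern (VAF 0.67 to 0.82 in WGS, 0.50 to 0.70 in RNA; around 21X WGS
  and 100X RNA depth, the study's approximate fragment coverages), plus
  ten decoy families of 55 (default), one per cascade step, each built to
  pass every step before its own and to violate its own deterministically.
  Bulk alt counts are binomial draws around target VAFs, *clamped* into
  the VAF interval the family requires: unconstrained draws would let
  sampling noise move a decoy across the threshold it is meant to probe,
  making planted truth unrecoverable by construction. The survivor's own
  counts are deterministic (`round(VAF x depth)`) because it must pass all
  steps by construction, not with high probability.
* **Expression matrix** — 28 samples (case first) x 2,000 genes; planted
  outliers are shifted +/- 5 SD in the case sample. Two truncations make
  recovery exact rather than probable: non-case draws are clipped to
  |z| <= 3 and the case sample's baseline for unplanted genes to
  |z| <= 0.5. With a fully i.i.d. baseline the case sample would be the
  strict extremum of roughly 1/28 of unplanted genes — some 70 spurious
  calls at this scale — because the outlier definition flags any strict
  extremum beyond 1 SD. Real data behave like the i.i.d. baseline, so
  passing recovery tests demonstrates the statistic's correctness, not a
  false-discovery guarantee on real matrices.
* **Metagenome** — per-pair source taxa are multinomial in the configured
  mixture (default 70/20/10 across three gut phyla, mirroring the
  dominance structure the study reports); 5% of pairs come from a
  conserved cassette copied into strains of two phyla (discarded at phylum
  rank by construction), 5% multi-map within a species, 2% are MAPQ-0 or
  discordant noise, 10% are host-flagged. Hit records are emitted
  directly rather than via FASTQ and a real aligner: this keeps the
  pipeline download-free and the truth exact, at the cost of not
  exercising aligner quirks.
* **CNV** — 10 chromosomes x 1,000 windows, control Poisson(100) per
  window, three chromosomes at ratio 1.5 (a clonal single-copy gain).

# Problem sizes and numerics

Default scales (551 candidate variants; 2,000 x 28 expression; 50,000
read pairs; 10,000 CNV windows) were chosen as the smallest sizes at which
the statistical checks — 3-SE binomial recovery of mixtures, exact
planted-truth recovery, medians within 0.05 of `log2(1.5)` — are
meaningfully sharp; each runs in seconds on one core. Ties: the dominant
spectrum class and outlier extremum tests are strict, reporting no call on
ties. VAF at zero depth is an error, never silently 0 or NA. Empty inputs
return empty, fully-formed reports (all-zero step counts, empty abundance
tables) rather than errors.

# Known limitations

The package consumes alignment records in its documented TSV dialect and
does not parse SAM/BAM itself; no sequencing-error or GC-bias model; no
focal CNV segmentation (the study reported none); conservation and
structure annotations are inputs, not computed; the cascade matches
variants across assays by exact key, so representation-shifted indels
would not be merged.
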