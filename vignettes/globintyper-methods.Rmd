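---
title: "Methods: genotyping and haplotype analysis of targeted long-read globin amplicons"
author: "globintyper authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: genotyping and haplotype analysis of targeted long-read globin amplicons}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(globintyper)
```

# The assay this package models

Targeted long-read sequencing (T-LRS) of the globin gene clusters works by
multiplex long-range PCR: each target — the *HBA1/HBA2* and *HBG1/HBG2*
homologous regions, *HBB/HBD*, and a set of HbF modifier genes — is amplified
as one fragment of roughly 3–20 kb, and the pooled amplicons are sequenced in
circular-consensus (CCS/HiFi) mode, giving full-length reads of each fragment
at a per-base error rate well below 1%. Because every read spans its entire
amplicon, three analyses that are hard with short reads become direct:

1. **Structural variants from primer identity and read length.** A read's
   terminal primers identify its amplicon; its length, compared with the
   expected product length, exposes internal deletions and duplications.
   Deletions that remove a whole fragment (the SEA-type α-thalassemia
   deletions) are caught gap-PCR style, through a deletion-spanning primer
   pair whose wild-type product is too long to amplify.
2. **Within-amplicon phasing as 2-clustering.** Full-length reads cover every
   heterozygous site of the fragment, so phasing is not a fragment-assembly
   problem: reads simply cluster into the two parental haplotypes.
3. **Paralog resolution.** The ~4-kb duplicated units of the α- and γ-globin
   clusters differ at fixed paralog-diagnostic positions. Long reads anchor
   on unique flanks, so a variant can be placed into one unit, the other, or
   both, and gene-conversion tracts appear as runs of diagnostic sites
   carrying the other paralog's allele.

The package implements this whole bioinformatic chain — read assignment, SV
calling with split-read breakpoint refinement, diploid SNV/indel calling,
minimum-error-correction (MEC) phasing, paralog and conversion analysis,
population haplotype clustering, LD, motif scanning, and genotype–phenotype
association — together with a simulator that generates diploid cohorts with
machine-readable truth, so every stage is validated end to end.

# The synthetic mini-reference and what it does (not) emulate

Real patient data for this assay are not redistributable, so validation runs
on a deterministic mini-reference (`build_mini_reference()`):

* `alphaC` — an α-like cluster: two paralogous 4-kb units separated by an
  800-bp spacer inside a 9.4-kb amplicon, embedded in a 20-kb span whose
  flanking primers (`sea_span`) only yield product when a catalogued 19-kb
  deletion shortens it;
* `gammaC` — a γ-like cluster with the same two-unit geometry;
* `modC` — a single-copy, 3-kb modifier-like fragment.

Each paralog pair differs at `n_diagnostic = 40` positions (matching the
scale of divergence between real globin paralogs over 4 kb). The shipped
allele catalog (`default_catalog()`) has 23 entries — 14 SNVs, 4 small
indels, 4 large deletions, 1 tandem duplication — the size and composition
of a routine PCR panel for thalassemia, including a 4.9-kb deletion spanning
from one γ-like unit across the spacer into the other (real γ-cluster
deletions remove one gene; a purely intergenic 4.9-kb event cannot fit
between 4-kb units inside a desk-scale fragment).

The default amplicon lengths (9.4 kb for the two-unit fragments) are a
desk-scale design; a configured panel TSV can express any geometry,
including the real 7,122/8,135-bp fragment lengths used for *HBG1/HBG2* and
*HBA1/HBA2*.

The simulator emulates: diploid genotypes drawn per catalogued allele,
founder-structured background haplotypes (for haplogroup analyses),
in-silico PCR with mismatch-tolerant primer sites and a product size limit,
full-length CCS reads with independent substitution and 1-bp indel errors,
both read orientations, and phenotypes with additive genetic effects plus
Gaussian noise and exponential, genotype-scaled transfusion hazards. It does
**not** emulate homopolymer-biased indels, chimeric PCR products, barcode
hopping, coverage dropout gradients, or population stratification — passing
tests therefore demonstrate algorithmic correctness under clean CCS-like
conditions, not robustness to every artifact of real instruments. One
deliberate simulation constraint: a small allele is never planted opposite a
deletion that removes its entire amplicon, because such loci are truly
hemizygous and their zygosity is not observable from within-amplicon read
fractions (the real assay reads them as homozygous too).

# Methods and numerical choices

## Read assignment

Each read end (window 50 bp) is compared against every primer and its
reverse complement, allowing up to `max_mismatch = 2` substitutions and no
indels inside the primer match. A read is assigned when a unique amplicon's
two primers match opposite ends consistently; any second matching amplicon
leaves the read unassigned with an ambiguity flag. Reads whose primer
sequence contains an indel error are deliberately lost (~2 × 24 × indel
rate per read); depth margins absorb this.

## SV calling and breakpoints

Per amplicon, read-length deviations are split into a REF-like cluster
(|deviation| ≤ `length_tolerance`, default 100 bp) and shifted clusters via
1-D gap clustering (gap > tolerance). Shifted clusters match the SV catalog
by length shift; deletions are negative, duplications positive. Genotypes
come from the shifted-read fraction: heterozygous in [0.25, 0.75],
homozygous at ≥ 0.9 — read sampling is binomial around 0.5 and 1.0, so these
windows are many standard deviations wide at depth ≥ 20. Catalog entries may
declare a `linked_amplicon`: a deletion seen through a spanning product is
homozygous only when the linked amplicon has no reads at all, and a fully
shifted amplicon opposite such a linked deletion is re-typed heterozygous
(the compound-deletion case).

Deletion breakpoints are refined from split reads: each supporting read is
aligned, its long gap extracted and left-normalised, and per-read
(left, size) votes are aggregated by majority. The reported breakpoint is
the leftmost equivalent placement; the length of the flanking repeat that
makes placements equivalent is reported as the microhomology.

## Alignment

Full-length reads are aligned globally to their amplicon reference by a
greedy anchored edit walk (linear time; extends exact matches and resolves
each divergence by a short lookahead over substitution and ≤ 8-bp indel
candidates, with unique-anchor jumps for SV-scale gaps), falling back to a
banded affine-gap dynamic program (compiled) whenever the walk cannot
explain the read at ≥ 90% match identity. Because greedy and optimal
alignments can represent clustered differences differently, any cluster of
edits within 16 bp is re-aligned with the exact DP, and all indels are
left-normalised against the reference — so every read carrying the same
local haplotype yields byte-identical variant records. Alignment identity is
gap-compressed (a long SV gap counts once); reads under 70% identity are
excluded from pileups.

## Small-variant calling

Amplicon reads cover every column, so depth is uniform per sample × fragment.
Alternate alleles need fraction ≥ 0.2 and ≥ 5 supporting reads; genotypes
follow the same fraction windows as SVs. Columns with depth < 20 are
reported but never PASS — the assay's hard depth filter. Columns supporting
more than two plausible alleles are flagged ambiguous. Indel records longer
than 50 bp belong to the SV caller and are excluded here. Because a
sequencing error adjacent to a real indel can produce an equivalent-score
alignment whose records differ from the canonical form, indel candidates are
re-genotyped by local haplotype: a read also supports the indel when the
local sequence implied by its records is closer, in edit distance, to the
alternate window than to the reference window — the lightweight analogue of
the local realignment haplotype callers perform.

## Phasing

Reads are reduced to 0/1 vectors over the heterozygous PASS sites. The MEC
objective — two consensus vectors minimising total Hamming distance — is
solved exactly when the distinct read vectors number ≤ 12 (enumeration of
bipartitions; the optimal consensus given a partition is the column-wise
weighted majority, so this search is exhaustive), and by k-modes refinement
seeded from every pair of distinct vectors otherwise. Ties break
lexicographically (cluster 1 holds the smaller consensus), making output
invariant to read order. Samples with no heterozygous site phase trivially
into two identical haplotypes, flagged `no_het_sites`; where cluster
consensi agree at a het site, the side with weaker allele support is
flipped so haplotypes always remain genotype-consistent. Phasing across
different amplicons is not attempted — single-fragment reads carry no
linkage between fragments.

## Conversion and paralog logic

A conversion call needs ≥ `min_run = 3` consecutive diagnostic positions
carrying the donor paralog's allele; fewer remain point variants (the run
threshold is the package's choice of where "a conversion" begins — no
standard exists). Tract bounds are the first and last switched diagnostic
positions, so resolution is limited by diagnostic spacing.

## Population analytics

The per-fragment haplotype matrix has two rows per phased sample and 0/1
cells over the union of variant loci. Duplicate rows collapse with
multiplicity; distinct haplotypes cluster by complete linkage on
1 − Pearson correlation (the distance the field's heatmap tooling applies
to 0/1 allele rows; Hamming is available as an option). The group count is
chosen at the largest relative gap between consecutive merge heights
(capped at 8), overridable with an explicit `k`; groups are labelled
`Hap_s1`, `Hap_s2`, … by descending size. Pairs with undefined Pearson
correlation (a constant row) get the maximum distance, with a message.

LD uses the phased-haplotype formulas directly — `D = p(AB) − p(A)p(B)`,
`r² = D²/(p(A)p(a)p(B)p(b))` — after a MAF ≥ 0.01 filter; blocks are maximal
runs of consecutive loci with all pairwise r² ≥ 0.8. Motif scanning uses
IUPAC consensi of the five key erythroid regulators (KLF1 CACCC box, BCL11A
TGACCA half-site, GATA1 WGATAR, NF-Y CCAAT, TAL1 E-box CANNTG) on both
strands of the reference and alternate windows; these are consensus
approximations shipped as configuration, not position-weight matrices.

## Association

Per-variant association is a linear model `phenotype ~ dosage + covariates`
(default covariates age and sex; the identity link fits the continuous
HbF/ferritin scales), with Wald tests and Benjamini–Hochberg FDR over all
tested variants, significance at q < 0.05. Monomorphic, rare
(MAF < 0.01), undersized (n < 10) and singular designs are skipped with
recorded reasons. Group comparisons offer the unpaired t-test, the
one-sample t-test (the design of record when only a couple of carriers
exist), and one-way ANOVA with Dunnett contrasts via the multivariate-t
adjustment. Transfusion-free survival is Kaplan–Meier with right censoring
at follow-up and a log-rank chi-square on g − 1 degrees of freedom; the
burden score counts beneficial allele copies and is tested by a linear
trend.

# Validation scales

The shipped validation functions run at these problem sizes, chosen so a
laptop-class single core completes each in minutes: mutation detection on
200 simulated diploid samples at depth 30 and 0.5% total error (the CCS
regime); routine-catalog concordance on 100 samples at depth 40; split-read
sizing of the 4.9-kb deletion from 40 error-free reads; and matrix
dimensionality by phasing 1,020 samples at depth 30 for the γ-like fragment.
Property suites check the MEC solver against exhaustive bipartition up to 8
reads × 6 sites, BH-FDR against a hand-written step-up, r² against direct
haplotype counting, GLM type-I error at nominal 0.05, and planted-haplogroup
recovery at adjusted Rand index 1.

# Known limitations

* Primer matching tolerates substitutions only; indel-in-primer reads are
  dropped rather than rescued.
* Hemizygous loci (opposite a whole-amplicon deletion) are reported with
  their apparent (homozygous) genotype; resolving them would need
  cross-amplicon depth normalisation, which single-fragment fractions do not
  support.
* Mosaic fractions, SVs smaller than the length tolerance (handled as small
  indels instead), and cross-amplicon phasing are out of scope.
* The motif scan is consensus-based; a PWM scorer would rank partial matches
  but is left as an extension.
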