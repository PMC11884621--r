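# globintyper

Genotyping, phasing and haplotype association for targeted long-read (T-LRS)
globin amplicon panels.

## The problem

Thalassemia diagnostics must resolve a hard mix of variation in the globin
gene clusters: point mutations and small indels in *HBB*, large deletions
(−α3.7, −α4.2, --SEA and relatives), duplications and rearrangements in the
α-cluster, and variants inside the highly homologous ~4-kb paralogous units
of *HBA1/HBA2* and *HBG1/HBG2*, where short reads cannot be placed. A T-LRS
assay solves this with multiplex long-range PCR: each target region becomes
one 3–20-kb amplicon, sequenced as full-length CCS/HiFi reads. This package
is the bioinformatics core for such an assay, plus a simulator that
validates every stage against known truth:

* **read → amplicon assignment** by terminal primer matching, either strand;
* **structural variants** from primer-pair identity plus read length, with
  gap-PCR-style logic for whole-fragment deletions and **split-read
  breakpoint refinement** (left-normalised, with microhomology);
* **diploid SNV/indel calling** from full-length-read pileups, with the
  assay's hard depth ≥ 20 filter;
* **phasing** each amplicon by exact minimum-error-correction (MEC)
  2-clustering of reads over heterozygous sites;
* **paralog resolution** (unit 1 / unit 2 / both) and **gene-conversion
  tract detection** from paralog-diagnostic positions;
* **population analytics**: 0/1 haplotype matrix, de-duplication,
  complete-linkage haplogroups on Pearson distance (`Hap_s1`, `Hap_s2`, …),
  LD (r², D′, blocks), and erythroid TF motif alteration scanning
  (KLF1, BCL11A, GATA1, NFY, TAL1);
* **association**: per-variant linear models with Benjamini–Hochberg FDR,
  unpaired/one-sample t-tests and ANOVA + Dunnett, beneficial-allele burden
  scores, and Kaplan–Meier transfusion-free survival with log-rank tests.

The statistics at its core: SV genotypes come from the shifted-read fraction
(het in [0.25, 0.75], hom ≥ 0.9); phasing minimises the MEC objective
min over consensus pairs (h₁,h₂) of Σᵣ min(d(r,h₁), d(r,h₂)); LD is computed
from phased haplotype frequencies, D = p(AB) − p(A)p(B),
r² = D² / (p(A)p(a)p(B)p(b)); association fits phenotype ~ dosage + age +
sex with step-up FDR control at q < 0.05.

## Worked example

Simulate a small cohort over the bundled synthetic mini-reference (two
globin-like clusters with 4-kb paralogous units, a modifier-like gene, and a
23-allele thalassemia catalog), genotype it, and compare with truth:

```r
library(globintyper)
mini <- build_mini_reference(seed = 7)
pnl  <- mini_panel(mini)
ctl  <- default_catalog(mini)

co <- simulate_cohort(mini, pnl, ctl, n_samples = 5,
                      allele_freqs = c(gamma_del4.9k = 0.2, gamma_m158 = 0.3,
                                       mod_snv1 = 0.3, sea_del19k = 0.15),
                      depth = 40, sub_rate = 0.003, ins_rate = 0.001,
                      del_rate = 0.001, seed = 42)
geno <- run_genotyping(co, pnl, mini = mini, catalog = ctl)

geno[["S0001"]]$annotation$diplotype
#> [1] "gamma_del4.9k(het)/gamma_m158(het)"

geno[["S0001"]]$sv_calls[, c("amplicon_id", "class", "length_shift",
                             "genotype", "matched_catalog_allele",
                             "bp_left", "bp_right")]
#>   amplicon_id    class length_shift genotype matched_catalog_allele bp_left bp_right
#> 1  gamma_frag deletion        -4899      het          gamma_del4.9k    2097     6997

ev <- evaluate_genotypes(geno, co)
c(sensitivity = ev$sensitivity, specificity = ev$specificity,
  concordance = ev$concordance)
#> sensitivity specificity concordance
#>         100         100         100
```

Sample S0001 carries a heterozygous 4.9-kb deletion in the γ-like fragment
and a heterozygous promoter-region SNV. The read-length cluster estimates
the shift at −4,899 bp (median over error-bearing reads); the split-read
refinement recovers the exact left-normalised breakpoints 2097–6997 on
`gammaC` — a 4,900-bp deletion. Across the cohort, every catalogued allele
is detected with the correct zygosity.

Population-scale analyses take the genotyping results plus a phenotype
table: `run_population()` builds the haplotype matrix, clusters haplogroups,
computes LD and motif hits, and runs the association and survival battery.
A command-line wrapper with `simulate`, `genotype`, `population` and `demo`
subcommands is installed at `inst/scripts/globintyper-cli.R`.

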