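#' Validate mutation detection on a simulated catalog cohort
#'
#' Simulates a diploid cohort carrying the full shipped allele catalog
#' (SNVs, indels, large deletions and a duplication) at CCS-like error
#' rates, runs the genotyping pipeline, and scores allele detection against
#' the simulator truth. Samples carrying no catalogued allele act as
#' negatives.
#'
#' @param n_samples number of diploid samples (default 200).
#' @param depth per-amplicon read depth (default 30).
#' @param allele_freq per-haplotype frequency of each catalogued allele.
#' @param sub_rate,ins_rate,del_rate per-base error rates (default totals
#'   0.5%, the CCS regime).
#' @param seed integer seed.
#' @return list with `sensitivity`, `specificity`, `concordance` (percent),
#'   `n_samples`, `n_positive_alleles`.
#' @export
validate_mutation_detection <- function(n_samples = 200L, depth = 30L,
                                        allele_freq = 0.05,
                                        sub_rate = 0.003, ins_rate = 0.001,
                                        del_rate = 0.001, seed = 1L) {
  mini <- build_mini_reference(seed = derive_seed(seed, 101L))
  pnl <- mini_panel(mini)
  ctl <- default_catalog(mini)
  freqs <- stats::setNames(rep(allele_freq, nrow(ctl)), ctl$name)
  co <- simulate_cohort(mini, pnl, ctl, n_samples = n_samples,
                        allele_freqs = freqs, depth = depth,
                        sub_rate = sub_rate, ins_rate = ins_rate,
                        del_rate = del_rate, seed = derive_seed(seed, 102L))
  geno <- run_genotyping(co, pnl, mini = mini, catalog = ctl)
  ev <- evaluate_genotypes(geno, co)
  list(sensitivity = ev$sensitivity, specificity = ev$specificity,
       concordance = ev$concordance, n_samples = n_samples,
       n_positive_alleles = ev$n_true_positive + ev$n_false_negative)
}

#' Validate genotype concordance on a routine-style 23-allele catalog
#'
#' Restricts simulation to the 23-entry catalog (the size of a routine
#' PCR panel for thalassemia), genotypes every sample, and reports the
#' fraction of samples whose full catalog diplotype matches truth exactly.
#'
#' @param n_samples number of samples (default 100).
#' @param depth read depth (default 40).
#' @param allele_freq per-haplotype allele frequency.
#' @param seed integer seed.
#' @return list with `concordance` (percent), `n_samples`, `n_alleles`.
#' @export
validate_routine_concordance <- function(n_samples = 100L, depth = 40L,
                                         allele_freq = 0.08, seed = 1L) {
  mini <- build_mini_reference(seed = derive_seed(seed, 201L))
  pnl <- mini_panel(mini)
  ctl <- default_catalog(mini)
  freqs <- stats::setNames(rep(allele_freq, nrow(ctl)), ctl$name)
  co <- simulate_cohort(mini, pnl, ctl, n_samples = n_samples,
                        allele_freqs = freqs, depth = depth,
                        sub_rate = 0.003, ins_rate = 0.001, del_rate = 0.001,
                        seed = derive_seed(seed, 202L))
  geno <- run_genotyping(co, pnl, mini = mini, catalog = ctl)
  ev <- evaluate_genotypes(geno, co)
  list(concordance = ev$concordance, n_samples = n_samples,
       n_alleles = nrow(ctl))
}

#' Validate split-read sizing of the 4.9-kb gamma-cluster deletion
#'
#' Plants the catalogued 4.9-kb deletion spanning the gamma-like paralog
#' units on one haplotype, simulates error-free reads, runs SV calling with
#' split-read breakpoint refinement, and reports the recovered deletion
#' size.
#'
#' @param n_reads total reads over the fragment (default 40).
#' @param seed integer seed.
#' @return list with `size_kb`, `size_bp`, `left`, `right`,
#'   `matched_allele`, `genotype`.
#' @export
validate_deletion_sizing <- function(n_reads = 40L, seed = 1L) {
  mini <- build_mini_reference(seed = derive_seed(seed, 301L))
  pnl <- mini_panel(mini)
  ctl <- default_catalog(mini)
  del <- catalog_event(ctl[ctl$name == "gamma_del4.9k", ])
  prods <- list()
  for (h in 1:2) {
    hseq <- mini$contigs
    if (h == 1L)
      hseq[["gammaC"]] <- apply_events(mini$contigs[["gammaC"]],
                                       list(del))$seq
    pr <- in_silico_pcr(hseq, pnl)
    pr <- pr[pr$amplicon_id == "gamma_frag", ]
    prods[[h]] <- pr
  }
  reads <- simulate_ccs_reads(do.call(rbind, prods),
                              depth = as.integer(ceiling(n_reads / 2)),
                              sub_rate = 0, ins_rate = 0, del_rate = 0,
                              seed = derive_seed(seed, 302L))
  g <- genotype_sample(reads[, c("read_id", "seq")], pnl, ctl, mini = mini)
  sv <- g$sv_calls
  sv <- sv[!is.na(sv$length_shift) & sv$amplicon_id == "gamma_frag", ]
  stopifnot(nrow(sv) == 1L, !is.na(sv$bp_left))
  size <- sv$bp_right - sv$bp_left
  list(size_kb = size / 1000, size_bp = size, left = sv$bp_left,
       right = sv$bp_right, matched_allele = sv$matched_catalog_allele,
       genotype = sv$genotype)
}

#' Validate haplotype-matrix dimensionality on a population scale
#'
#' Simulates diploid samples for the gamma-like fragment (founder-structured
#' background SNVs guarantee heterozygous sites), phases every sample, and
#' builds the population 0/1 haplotype matrix.
#'
#' @param n_samples number of diploid samples (default 1020).
#' @param depth read depth (default 30).
#' @param seed integer seed.
#' @return list with `n_rows`, `n_samples_phased`, `n_loci`, `n_excluded`.
#' @export
validate_matrix_dimensions <- function(n_samples = 1020L, depth = 30L,
                                       seed = 1L) {
  mini <- build_mini_reference(seed = derive_seed(seed, 401L))
  full <- mini_panel(mini)
  pnl <- panel(full$amplicons["gamma_frag"], mini$contigs,
               max_product_len = full$max_product_len)
  ctl <- default_catalog(mini)
  fo <- make_founders(mini, n_loci = 12L, k = 3L,
                      founder_freqs = c(0.45, 0.35, 0.2),
                      seed = derive_seed(seed, 402L))
  co <- simulate_cohort(mini, pnl, ctl, n_samples = n_samples,
                        allele_freqs = c(gamma_m158 = 0.1),
                        founders = fo, depth = depth,
                        sub_rate = 0, ins_rate = 0, del_rate = 0,
                        seed = derive_seed(seed, 403L))
  geno <- run_genotyping(co, pnl, mini = mini, catalog = ctl)
  ph <- lapply(geno, function(g) {
    p <- g$phase[["gamma_frag"]]
    if (is.null(p)) list(phased = FALSE, flag = "no_reads") else p
  })
  bm <- build_matrix(ph)
  list(n_rows = nrow(bm$matrix), n_samples_phased = nrow(bm$matrix) / 2,
       n_loci = nrow(bm$loci), n_excluded = bm$n_excluded)
}
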