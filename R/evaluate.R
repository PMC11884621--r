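#' Compare pipeline genotypes with simulator truth
#'
#' Tabulates, per sample and catalogued allele, the called dosage (0 absent,
#' 1 het, 2 hom) against the simulator's truth dosage. Detection sensitivity
#' is the fraction of truth-present (sample, allele) pairs called present;
#' specificity the fraction of truth-absent pairs called absent; genotype
#' concordance the fraction of samples whose full catalog diplotype
#' (dosage vector over all alleles) matches truth exactly.
#'
#' @param geno [run_genotyping()] results.
#' @param cohort the [simulate_cohort()] object the reads came from.
#' @return list with `sensitivity`, `specificity`, `concordance` (all in
#'   percent), `n_true_positive`, `n_false_negative`, `n_false_positive`,
#'   `per_sample` (data.frame), `called_dosages` (matrix).
#' @export
evaluate_genotypes <- function(geno, cohort) {
  truth <- cohort$dosages
  ids <- cohort$phenotypes$sample_id
  alleles <- colnames(truth)
  called <- matrix(0L, nrow(truth), ncol(truth), dimnames = dimnames(truth))
  for (i in seq_along(ids)) {
    ann <- geno[[ids[i]]]$annotation$annotations
    if (is.null(ann) || nrow(ann) == 0L) next
    for (k in seq_len(nrow(ann))) {
      a <- ann$allele[k]
      if (!a %in% alleles) next
      called[i, a] <- if (!is.na(ann$zygosity[k]) && ann$zygosity[k] == "hom")
        2L else 1L
    }
  }
  present_t <- truth > 0L; present_c <- called > 0L
  tp <- sum(present_t & present_c)
  fn <- sum(present_t & !present_c)
  fp <- sum(!present_t & present_c)
  tn <- sum(!present_t & !present_c)
  conc <- mean(vapply(seq_along(ids), function(i)
    all(called[i, ] == truth[i, ]), TRUE))
  per_sample <- data.frame(
    sample_id = ids,
    concordant = vapply(seq_along(ids), function(i)
      all(called[i, ] == truth[i, ]), TRUE))
  list(sensitivity = 100 * tp / max(1L, tp + fn),
       specificity = 100 * tn / max(1L, tn + fp),
       concordance = 100 * conc,
       n_true_positive = tp, n_false_negative = fn, n_false_positive = fp,
       per_sample = per_sample, called_dosages = called)
}
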