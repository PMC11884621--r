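test_that("apply_events edits haplotypes and maps coordinates", {
  mini <- get_mini()
  ref <- mini$contigs[["gammaC"]]
  # empty event list: identity
  out <- apply_events(ref, list())
  expect_identical(out$seq, ref)
  expect_equal(map_coord(out$map, c(0L, 100L, nchar(ref) - 1L)),
               c(0L, 100L, nchar(ref) - 1L))
  # one SNV differs at exactly one position
  ref_base <- substr(ref, 1001, 1001)
  alt <- setdiff(c("A", "C", "G", "T"), ref_base)[1]
  snv <- allele_event("SNV", "gammaC", 1000L, 1001L, alt)
  mut <- apply_events(ref, list(snv))$seq
  expect_equal(nchar(mut), nchar(ref))
  expect_identical(str_hamming(mut, ref), 1L)
  # a 4900-bp deletion shortens by exactly 4900 and unmaps the interval
  del <- allele_event("large_deletion", "gammaC", 2000L, 6900L, name = "d49")
  outd <- apply_events(ref, list(del))
  expect_equal(nchar(outd$seq), nchar(ref) - 4900L)
  expect_true(is.na(map_coord(outd$map, 3000L)))
  expect_equal(map_coord(outd$map, 7000L), 7000L - 4900L)
  # overlap detection
  expect_error(apply_events(ref, list(del,
    allele_event("large_deletion", "gammaC", 6000L, 7000L, name = "x"))),
    "overlapping")
})

test_that("in-silico PCR emits expected products and models primer loss", {
  mini <- get_mini(); pnl <- get_panel()
  pr <- in_silico_pcr(mini$contigs, pnl)
  # sea_span's wild-type product exceeds the PCR size limit
  expect_setequal(pr$amplicon_id, c("alpha_frag", "gamma_frag", "mod_frag"))
  for (k in seq_len(nrow(pr)))
    expect_equal(pr$length[k],
                 pnl$amplicons[[pr$amplicon_id[k]]]$expected_length)
  # internal deletion shortens the product by exactly its size
  hap <- mini$contigs
  hap[["gammaC"]] <- apply_events(mini$contigs[["gammaC"]],
    list(allele_event("large_deletion", "gammaC", 2100L, 7000L, name = "d")))$seq
  pr2 <- in_silico_pcr(hap, pnl)
  expect_equal(pr2$length[pr2$amplicon_id == "gamma_frag"],
               pnl$amplicons$gamma_frag$expected_length - 4900L)
  # deleting the reverse primer site drops the amplicon
  gend <- pnl$amplicons$gamma_frag$end
  hap[["gammaC"]] <- apply_events(mini$contigs[["gammaC"]],
    list(allele_event("large_deletion", "gammaC", gend - 30L, gend + 10L,
                      name = "x")))$seq
  pr3 <- in_silico_pcr(hap, pnl)
  expect_false("gamma_frag" %in% pr3$amplicon_id)
})

test_that("CCS read simulation respects error rates, depth and seed", {
  mini <- get_mini(); pnl <- get_panel()
  pr <- in_silico_pcr(mini$contigs, pnl)
  # error-free reads equal their product up to strand
  r0 <- simulate_ccs_reads(pr, depth = 5, sub_rate = 0, ins_rate = 0,
                           del_rate = 0, seed = 2)
  expect_equal(nrow(r0), 5L * nrow(pr))
  for (k in seq_len(nrow(r0))) {
    tmpl <- pr$seq[pr$amplicon_id == r0$amplicon_id[k]]
    expect_true(r0$seq[k] == tmpl || r0$seq[k] == revcomp(tmpl))
  }
  # substitutions: mean per read ~ n * rate, within 3 sigma of binomial
  prod8k <- data.frame(amplicon_id = "x", seq = rand_dna(8000), length = 8000)
  rs <- simulate_ccs_reads(prod8k, depth = 200, sub_rate = 0.005,
                           ins_rate = 0, del_rate = 0, seed = 3)
  nmm <- vapply(rs$seq, function(s)
    min(str_hamming(s, prod8k$seq), str_hamming(revcomp(s), prod8k$seq)), 0L)
  n <- 8000; p <- 0.005
  expect_lt(abs(mean(nmm) - n * p), 3 * sqrt(n * p * (1 - p) / 200))
  # determinism
  ra <- simulate_ccs_reads(pr, depth = 3, sub_rate = 0.01, ins_rate = 0.002,
                           del_rate = 0.002, seed = 9)
  rb <- simulate_ccs_reads(pr, depth = 3, sub_rate = 0.01, ins_rate = 0.002,
                           del_rate = 0.002, seed = 9)
  expect_identical(ra, rb)
  expect_warning(simulate_ccs_reads(pr[0, ], depth = 3, seed = 1), "empty")
})

test_that("cohort genotypes, truth and phenotypes follow the additive model", {
  mini <- get_mini(); pnl <- get_panel(); ctl <- get_catalog()
  # frequency-1 allele lands on every haplotype
  co1 <- simulate_cohort(mini, pnl, ctl, n_samples = 20,
                         allele_freqs = c(mod_snv1 = 1), seed = 5)
  expect_true(all(co1$dosages[, "mod_snv1"] == 2L))
  # null effects: dosage does not predict HbF
  co0 <- simulate_cohort(mini, pnl, ctl, n_samples = 300,
                         allele_freqs = c(mod_snv2 = 0.3),
                         phenotype_model = list(effects = c(mod_snv2 = 0)),
                         seed = 6)
  f0 <- summary(lm(co0$phenotypes$hbf ~ co0$dosages[, "mod_snv2"]))$coefficients
  expect_lt(abs(f0[2, 1]), 3 * f0[2, 2])  # slope CI covers zero
  # planted beta = 2 g/L per allele recovered within 3 SE by OLS on truth
  co2 <- simulate_cohort(mini, pnl, ctl, n_samples = 500,
                         allele_freqs = c(mod_snv2 = 0.3),
                         phenotype_model = list(effects = c(mod_snv2 = 2),
                                                sd = 3),
                         seed = 7)
  f2 <- summary(lm(co2$phenotypes$hbf ~ co2$dosages[, "mod_snv2"]))$coefficients
  expect_lt(abs(f2[2, 1] - 2), 3 * f2[2, 2])
})

test_that("emitted products are consistent with the recorded truth", {
  mini <- get_mini(); pnl <- get_panel(); ctl <- get_catalog()
  co <- simulate_cohort(mini, pnl, ctl, n_samples = 4,
                        allele_freqs = stats::setNames(rep(0.3, nrow(ctl)),
                                                       ctl$name),
                        depth = 2, sub_rate = 0, ins_rate = 0, del_rate = 0,
                        seed = 8)
  for (i in 1:4) {
    sr <- cohort_sample_reads(co, i, mini, pnl)
    for (h in 1:2) {
      hseq <- mini$contigs
      evs <- co$genotypes[[i]][[h]]
      for (ct in unique(vapply(evs, `[[`, "", "contig")))
        hseq[[ct]] <- apply_events(mini$contigs[[ct]],
          evs[vapply(evs, `[[`, "", "contig") == ct])$seq
      expected <- in_silico_pcr(hseq, pnl)
      got <- sr$products[sr$products$hap == h, ]
      expect_equal(got$seq, expected$seq)
    }
  }
  # byte-identical FASTQ for the same seed
  d1 <- tempfile(); d2 <- tempfile()
  co_small <- simulate_cohort(mini, pnl, ctl, n_samples = 2,
                              allele_freqs = c(mod_snv1 = 0.5), depth = 4,
                              seed = 9)
  write_cohort(co_small, mini, pnl, d1)
  write_cohort(co_small, mini, pnl, d2)
  expect_identical(readLines(file.path(d1, "S0001.fastq")),
                   readLines(file.path(d2, "S0001.fastq")))
  expect_true(file.exists(file.path(d1, "truth.vcf")))
  expect_true(file.exists(file.path(d1, "phenotypes.tsv")))
})
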