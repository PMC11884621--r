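test_that("reads are assigned by terminal primers in either orientation", {
  mini <- get_mini(); pnl <- get_panel()
  pr <- in_silico_pcr(mini$contigs, pnl)
  gseq <- pr$seq[pr$amplicon_id == "gamma_frag"]
  a <- assign_read(gseq, pnl)
  expect_equal(a$amplicon_id, "gamma_frag")
  expect_equal(a$orientation, "+")
  expect_equal(a$fwd_mismatches + a$rev_mismatches, 0L)
  am <- assign_read(revcomp(gseq), pnl)
  expect_equal(am$amplicon_id, "gamma_frag")
  expect_equal(am$orientation, "-")
  expect_identical(am$oriented_seq, gseq)
  # two substitutions inside the forward primer still assign at max_mismatch 2
  mut <- gseq
  substr(mut, 3, 3) <- setdiff(c("A", "C", "G", "T"), substr(mut, 3, 3))[1]
  substr(mut, 9, 9) <- setdiff(c("A", "C", "G", "T"), substr(mut, 9, 9))[1]
  a2 <- assign_read(mut, pnl)
  expect_equal(a2$amplicon_id, "gamma_frag")
  expect_equal(a2$fwd_mismatches, 2L)
  # a third mismatch exceeds the tolerance (exhaustive Hamming over primers)
  substr(mut, 15, 15) <- setdiff(c("A", "C", "G", "T"), substr(mut, 15, 15))[1]
  expect_equal(assign_read(mut, pnl)$amplicon_id, "UNASSIGNED")
  # random sequence has no primer hit
  withr::local_seed(1)
  expect_equal(assign_read(rand_dna(5000), pnl)$amplicon_id, "UNASSIGNED")
})

test_that("length-shift SV calling recovers genotypes over a size grid", {
  mini <- get_mini(); pnl <- get_panel()
  gu1 <- mini$paralog_pairs$gammaC$unit_a[1]
  for (size in c(500L, 1000L, 4900L, 19000L)) {
    for (gt in c("het", "hom")) {
      if (size == 19000L) {
        ev <- allele_event("large_deletion", "alphaC", 1000L, 1000L + size,
                           name = "sea")
      } else {
        ev <- allele_event("large_deletion", "gammaC", gu1 + 200L,
                           gu1 + 200L + size, name = paste0("d", size))
      }
      haps <- if (gt == "het") list(list(ev), list()) else
        list(list(ev), list(ev))
      reads <- sim_reads_for(haps, mini, pnl, depth = 20, seed = size + 7L)
      asn <- assign_reads(reads[, c("read_id", "seq")], pnl)
      sv <- call_svs(asn, pnl)
      sv <- sv[!is.na(sv$length_shift), ]
      expect_equal(nrow(sv), 1L, info = sprintf("size=%d %s", size, gt))
      expect_equal(sv$length_shift, -size)
      # 4900 and 19000 match catalogued deletions by length shift
      expect_equal(sv$class,
                   if (size %in% c(4900L, 19000L)) "deletion" else "novel")
      expect_equal(sv$genotype, gt, info = sprintf("size=%d %s", size, gt))
    }
  }
})

test_that("tolerant read lengths produce no SV call and low depth no-calls", {
  mini <- get_mini(); pnl <- get_panel()
  reads <- sim_reads_for(list(list(), list()), mini, pnl, depth = 10, seed = 2)
  asn <- assign_reads(reads[, c("read_id", "seq")], pnl)
  sv <- call_svs(asn, pnl, length_tolerance = 200L)
  expect_equal(nrow(sv), 0L)
  sv_low <- call_svs(asn[seq_len(8), ], pnl, min_depth = 10L)
  expect_true(all(sv_low$filter[sv_low$class == "no_call"] == "LOW_DEPTH"))
})

test_that("duplications shift positive and deletions negative vs truth", {
  mini <- get_mini(); pnl <- get_panel(); ctl <- get_catalog()
  dup <- catalog_event(ctl[ctl$name == "alpha_dup3.7k", ])
  del <- catalog_event(ctl[ctl$name == "alpha_del3.7k", ])
  reads <- sim_reads_for(list(list(dup), list(del)), mini, pnl, depth = 16,
                         seed = 3)
  asn <- assign_reads(reads[, c("read_id", "seq")], pnl)
  sv <- call_svs(asn, pnl)
  expect_setequal(sv$matched_catalog_allele,
                  c("alpha_dup3.7k", "alpha_del3.7k"))
  expect_equal(sv$length_shift[sv$matched_catalog_allele == "alpha_dup3.7k"],
               3700L)
  expect_equal(sv$length_shift[sv$matched_catalog_allele == "alpha_del3.7k"],
               -3700L)
  expect_true(all(sv$genotype == "het"))
})

test_that("SEA-like hom deletion is read from the spanning product plus dropout", {
  mini <- get_mini(); pnl <- get_panel(); ctl <- get_catalog()
  sea <- catalog_event(ctl[ctl$name == "sea_del19k", ])
  reads <- sim_reads_for(list(list(sea), list(sea)), mini, pnl, depth = 16,
                         seed = 4)
  asn <- assign_reads(reads[, c("read_id", "seq")], pnl)
  sv <- call_svs(asn, pnl)
  hit <- sv[!is.na(sv$matched_catalog_allele) &
              sv$matched_catalog_allele == "sea_del19k", ]
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$genotype, "hom")
  expect_false("dropout" %in% sv$class)   # absorbed by the linked call
  # het: the alpha fragment retains coverage from the intact haplotype
  reads2 <- sim_reads_for(list(list(sea), list()), mini, pnl, depth = 16,
                          seed = 5)
  sv2 <- call_svs(assign_reads(reads2[, c("read_id", "seq")], pnl), pnl)
  hit2 <- sv2[!is.na(sv2$matched_catalog_allele) &
                sv2$matched_catalog_allele == "sea_del19k", ]
  expect_equal(hit2$genotype, "het")
})

test_that("split reads recover exact left-normalised breakpoints", {
  mini <- get_mini(); pnl <- get_panel()
  amp <- pnl$amplicons$gamma_frag
  ref <- substr(mini$contigs[["gammaC"]], amp$start + 1, amp$end)
  L <- 1800L; D <- 4900L
  read <- paste0(substr(ref, 1, L), substr(ref, L + D + 1, nchar(ref)))
  bp <- refine_breakpoint(rep(read, 5), ref)
  oracle <- del_placements(read, ref)
  expect_equal(bp$left, min(oracle))
  expect_equal(bp$size, D)
  expect_equal(bp$microhomology_len, max(oracle) - min(oracle))
  # engineered 5-bp microhomology flanking the deleted interval
  ref2 <- ref
  substr(ref2, L - 4, L) <- "ACGTA"
  substr(ref2, L + D - 4, L + D) <- "ACGTA"
  read2 <- paste0(substr(ref2, 1, L), substr(ref2, L + D + 1, nchar(ref2)))
  bp2 <- refine_breakpoint(rep(read2, 5), ref2)
  oracle2 <- del_placements(read2, ref2)
  expect_equal(bp2$left, min(oracle2))
  expect_gte(bp2$microhomology_len, 5L)
  expect_equal(bp2$microhomology_len, max(oracle2) - min(oracle2))
  # with CCS-like errors the estimate stays within the homology span
  withr::local_seed(6)
  noisy <- vapply(1:6, function(z)
    globintyper:::mutate_read(read, 0.004, 0.0005, 0.0005), "")
  bp3 <- refine_breakpoint(noisy, ref)
  expect_lte(abs(bp3$left - min(oracle)), bp$microhomology_len)
  expect_equal(bp3$size, D)
  expect_error(refine_breakpoint(character(0), ref), "insufficient")
})
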