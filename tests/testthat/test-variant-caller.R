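test_that("alignment reproduces isolated edits exactly", {
  withr::local_seed(21)
  ref <- rand_dna(3000)
  a0 <- align_read(ref, ref)
  expect_equal(a0$nmismatch, 0L)
  expect_equal(a0$cigar, data.frame(op = "M", len = 3000L))
  # one substitution -> exactly one mismatch column
  rd <- ref
  substr(rd, 1500, 1500) <- setdiff(c("A", "C", "G", "T"),
                                    substr(rd, 1500, 1500))[1]
  a1 <- align_read(rd, ref)
  expect_equal(a1$nmismatch, 1L)
  rv <- read_variants(rd, ref, a1)
  expect_equal(rv$pos, 1499L)
  expect_equal(rv$type, "SNV")
})

test_that("indels in repeats are left-normalised to the placement oracle", {
  withr::local_seed(22)
  base <- rand_dna(400)
  # embed a homopolymer/repeat, delete 2 bp from its right end
  ref <- paste0(substr(base, 1, 200), "ACACACAC", substr(base, 201, 400))
  read <- paste0(substr(base, 1, 200), "ACACAC", substr(base, 201, 400))
  aln <- align_read(read, ref)
  rv <- read_variants(read, ref, aln)
  rv <- rv[rv$type == "del", ]
  expect_equal(nrow(rv), 1L)
  placements <- del_placements(read, ref)
  expect_equal(rv$pos + 1L, min(placements))  # leftmost equivalent gap
  # representation is stable when the evidence arrives in reverse order
  pile_f <- pileup_reads(rep(read, 10), ref)
  pile_r <- pileup_reads(rev(rep(read, 10)), ref)
  expect_equal(as.data.frame(pile_f$counts), as.data.frame(pile_r$counts))
})

test_that("diploid small-variant genotyping follows fraction windows and depth", {
  withr::local_seed(23)
  ref <- rand_dna(2000)
  alt_read <- ref
  substr(alt_read, 1000, 1000) <- setdiff(c("A", "C", "G", "T"),
                                          substr(ref, 1000, 1000))[1]
  # 15 alt / 30 reads: heterozygous at fraction 0.5
  pile <- pileup_reads(c(rep(ref, 15), rep(alt_read, 15)), ref)
  calls <- call_small_variants(pile)
  expect_equal(calls$genotype, "0/1")
  expect_equal(calls$allele_fraction, 0.5)
  expect_equal(calls$filter, "PASS")
  # binomial genotype likelihood agrees: P(15/30 | het) >> P(15/30 | hom)
  expect_gt(dbinom(15, 30, 0.5), dbinom(15, 30, 0.95))
  # depth 19 at an alt-bearing column is never PASS
  pile19 <- pileup_reads(c(rep(ref, 9), rep(alt_read, 10)), ref)
  calls19 <- call_small_variants(pile19)
  expect_equal(calls19$filter, "LOW_DEPTH")
  # error-free reference reads yield no PASS calls
  expect_equal(nrow(call_small_variants(pileup_reads(rep(ref, 25), ref))), 0L)
  # hom alt
  pileh <- pileup_reads(rep(alt_read, 30), ref)
  expect_equal(call_small_variants(pileh)$genotype, "1/1")
})

test_that("no PASS call is emitted below the depth filter", {
  withr::local_seed(24)
  ref <- rand_dna(1500)
  for (depth in c(6L, 12L, 19L, 20L, 35L)) {
    alt_read <- ref
    substr(alt_read, 700, 700) <- "A"
    if (substr(ref, 700, 700) == "A") substr(alt_read, 700, 700) <- "C"
    nalt <- ceiling(depth / 2)
    pile <- pileup_reads(c(rep(ref, depth - nalt), rep(alt_read, nalt)), ref)
    calls <- call_small_variants(pile)
    if (nrow(calls))
      expect_true(all(calls$depth[calls$filter == "PASS"] >= 20L),
                  info = paste("depth", depth))
    if (depth < 20L) expect_false(any(calls$filter == "PASS"))
  }
})

test_that("more than two plausible alleles flags the column AMBIGUOUS", {
  withr::local_seed(25)
  ref <- rand_dna(1200)
  b <- substr(ref, 600, 600)
  alts <- setdiff(c("A", "C", "G", "T"), b)
  mk <- function(a) { x <- ref; substr(x, 600, 600) <- a; x }
  pile <- pileup_reads(c(rep(mk(alts[1]), 12), rep(mk(alts[2]), 12),
                         rep(mk(alts[3]), 12)), ref)
  calls <- call_small_variants(pile)
  expect_true(all(calls$filter == "AMBIGUOUS"))
})

test_that("catalog annotation builds diplotypes and flags conflicts", {
  ctl <- get_catalog()
  empty <- annotate_alleles(
    data.frame(contig = character(), pos = integer(), ref = character(),
               alt = character(), genotype = character(),
               filter = character()),
    data.frame(amplicon_id = character(), class = character(),
               length_shift = integer(), genotype = character(),
               supporting_reads = integer(), total_reads = integer(),
               matched_catalog_allele = character(), filter = character()),
    ctl)
  expect_equal(nrow(empty$annotations), 0L)
  expect_equal(empty$diplotype, "")
  # compound het of two catalogued SNVs
  two <- ctl[ctl$name %in% c("mod_snv1", "mod_snv2"), ]
  calls <- data.frame(contig = two$contig, pos = two$pos, ref = two$ref,
                      alt = two$alt, genotype = "0/1", filter = "PASS")
  ann <- annotate_alleles(calls, empty_sv_calls(), ctl)
  expect_setequal(ann$annotations$allele, c("mod_snv1", "mod_snv2"))
  expect_true(all(ann$annotations$zygosity == "het"))
  expect_match(ann$diplotype, "mod_snv1\\(het\\)")
})

test_that("planted genotypes are recovered exactly at CCS-like error rates", {
  mini <- get_mini(); pnl <- get_panel(); ctl <- get_catalog()
  freqs <- stats::setNames(rep(0.1, nrow(ctl)), ctl$name)
  co <- simulate_cohort(mini, pnl, ctl, n_samples = 12, allele_freqs = freqs,
                        depth = 30, sub_rate = 0.006, ins_rate = 0.002,
                        del_rate = 0.002, seed = 31)
  geno <- run_genotyping(co, pnl, mini = mini, catalog = ctl)
  ev <- evaluate_genotypes(geno, co)
  expect_equal(ev$sensitivity, 100)
  expect_equal(ev$specificity, 100)
  expect_equal(ev$concordance, 100)
})
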