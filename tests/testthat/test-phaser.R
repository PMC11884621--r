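test_that("MEC clustering equals the exhaustive bipartition optimum", {
  withr::local_seed(41)
  for (rep in 1:40) {
    n <- sample(3:8, 1); s <- sample(2:6, 1)
    M <- matrix(rbinom(n * s, 1, 0.5), n, s)
    cl <- cluster_reads_by_hets(M, min_reads_per_cluster = 1L)
    expect_equal(cl$mec_cost, mec_brute(M), info = paste("rep", rep))
  }
})

test_that("error-free reads from two haplotypes partition perfectly", {
  withr::local_seed(42)
  h1 <- c(0L, 1L, 0L); h2 <- c(1L, 0L, 1L)
  M <- rbind(matrix(rep(h1, 20), 20, byrow = TRUE),
             matrix(rep(h2, 20), 20, byrow = TRUE))
  cl <- cluster_reads_by_hets(M)
  expect_equal(cl$mec_cost, 0)
  expect_length(unique(cl$assignment[1:20]), 1L)
  expect_length(unique(cl$assignment[21:40]), 1L)
  expect_true(cl$assignment[1] != cl$assignment[21])
  # cluster 1 carries the lexicographically smaller consensus
  expect_true(paste(cl$consensus[1, ], collapse = "") <=
                paste(cl$consensus[2, ], collapse = ""))
})

test_that("phasing is error-tolerant: zero switch errors at 1% flip rate", {
  withr::local_seed(43)
  fails <- 0L
  for (rep in 1:100) {
    h1 <- rbinom(5, 1, 0.5); h2 <- 1L - h1   # 5 het sites
    M <- rbind(matrix(rep(h1, 25), 25, byrow = TRUE),
               matrix(rep(h2, 25), 25, byrow = TRUE))
    flip <- matrix(runif(length(M)) < 0.01, nrow(M))
    M <- ifelse(flip, 1L - M, M)
    cl <- cluster_reads_by_hets(M)
    cons <- apply(cl$consensus, 1, paste, collapse = "")
    truth <- sort(c(paste(h1, collapse = ""), paste(h2, collapse = "")))
    if (!identical(sort(cons), truth)) fails <- fails + 1L
  }
  expect_equal(fails, 0L)
})

test_that("clustering is invariant to read input order", {
  withr::local_seed(44)
  M <- matrix(rbinom(60, 1, 0.5), 12, 5)
  cl1 <- cluster_reads_by_hets(M)
  perm <- sample(nrow(M))
  cl2 <- cluster_reads_by_hets(M[perm, ])
  expect_identical(cl1$consensus, cl2$consensus)
  expect_identical(cl1$mec_cost, cl2$mec_cost)
  expect_identical(cl1$assignment[perm], cl2$assignment)
})

test_that("phased haplotypes stay genotype-consistent end to end", {
  mini <- get_mini(); pnl <- get_panel(); ctl <- get_catalog()
  co <- simulate_cohort(mini, pnl, ctl, n_samples = 4,
                        allele_freqs = c(mod_snv1 = 0.5, mod_snv2 = 0.5,
                                         mod_snv3 = 0.5, mod_del4 = 0.4),
                        depth = 30, sub_rate = 0.005, ins_rate = 0.001,
                        del_rate = 0.001, seed = 45)
  geno <- run_genotyping(co, pnl, mini = mini, catalog = ctl)
  for (g in geno) {
    ph <- g$phase$mod_frag
    if (is.null(ph) || !ph$phased || nrow(ph$loci) == 0L) next
    calls <- g$small_calls[g$small_calls$amplicon_id == "mod_frag" &
                             g$small_calls$filter == "PASS", ]
    het <- calls$genotype == "0/1"
    ix <- match(paste(calls$pos, calls$ref, calls$alt),
                paste(ph$loci$pos, ph$loci$ref, ph$loci$alt))
    expect_true(all(ph$haplotypes[1, ix[het]] != ph$haplotypes[2, ix[het]]))
    hom <- calls$genotype == "1/1"
    expect_true(all(ph$haplotypes[1, ix[hom]] == 1L &
                      ph$haplotypes[2, ix[hom]] == 1L))
  }
})

test_that("samples without het sites are trivially phased and flagged", {
  withr::local_seed(46)
  ref <- rand_dna(2000)
  alt <- ref; substr(alt, 900, 900) <- setdiff(c("A","C","G","T"),
                                               substr(ref, 900, 900))[1]
  pile <- pileup_reads(rep(alt, 30), ref)   # hom alt everywhere
  calls <- call_small_variants(pile)
  ph <- phase_amplicon(pile, calls)
  expect_true(ph$phased)
  expect_equal(ph$flag, "no_het_sites")
  expect_identical(ph$haplotypes[1, ], ph$haplotypes[2, ])
})

test_that("variants are assigned to paralogous units, both copies, or spacer", {
  mini <- get_mini(); pnl <- get_panel()
  amp <- pnl$amplicons$gamma_frag
  pp <- mini$paralog_pairs$gammaC
  expect_equal(assign_paralog(pp$unit_a[1] + 100L, amp), "gammaC_u1")
  expect_equal(assign_paralog(pp$unit_b[1] + 100L, amp), "gammaC_u2")
  expect_equal(assign_paralog(pp$unit_a[2] + 10L, amp), "intergenic")
  # same substitution at homologous offsets of both units reports "both"
  off <- 777L
  while (off %in% pp$diagnostic$offset) off <- off + 1L
  refb <- substr(mini$contigs[["gammaC"]], pp$unit_a[1] + off + 1L,
                 pp$unit_a[1] + off + 1L)
  altb <- setdiff(c("A", "C", "G", "T"), refb)[1]
  calls <- data.frame(pos = c(pp$unit_a[1] + off, pp$unit_b[1] + off),
                      ref = refb, alt = altb)
  pd <- paralog_duplicates(calls, pp)
  expect_true(all(pd$unit == "both"))
  solo <- paralog_duplicates(data.frame(pos = pp$unit_a[1] + off, ref = refb,
                                        alt = altb), pp)
  expect_equal(solo$unit, "unit_a")
})

test_that("conversion tracts require a run of switched diagnostic sites", {
  mini <- get_mini(); pnl <- get_panel()
  pp <- mini$paralog_pairs$gammaC
  amp <- pnl$amplicons$gamma_frag
  dpos <- pp$unit_a[1] + pp$diagnostic$offset
  # haplotype matching its own paralog: no call
  loci <- data.frame(pos = dpos, ref = pp$diagnostic$allele_a,
                     alt = pp$diagnostic$allele_b,
                     type = "SNV")
  none <- detect_conversion(rep(0L, nrow(loci)), loci, pp, "unit_a")
  expect_equal(nrow(none), 0L)
  # six consecutive switched sites form one tract with correct bounds
  hap <- rep(0L, nrow(loci)); hap[11:16] <- 1L
  tr <- detect_conversion(hap, loci, pp, "unit_a")
  expect_equal(nrow(tr), 1L)
  expect_equal(tr$n_diagnostic_switched, 6L)
  expect_equal(tr$tract_start, dpos[11])
  expect_equal(tr$tract_end, dpos[16] + 1L)
  expect_equal(tr$donor_paralog, "unit_b")
  # two isolated switched sites stay point variants
  hap2 <- rep(0L, nrow(loci)); hap2[c(5, 20)] <- 1L
  expect_equal(nrow(detect_conversion(hap2, loci, pp, "unit_a")), 0L)
})

test_that("a simulated conversion tract is detected end to end", {
  mini <- get_mini(); pnl <- get_panel(); ctl <- get_catalog()
  pp <- mini$paralog_pairs$gammaC
  # convert a tract of unit 1 to the unit-2 allele over >= 6 diagnostic sites
  off <- pp$diagnostic$offset
  t0 <- off[8] - 5L; t1 <- off[14] + 5L
  conv <- allele_event("conversion", "gammaC", pp$unit_a[1] + t0,
                       pp$unit_a[1] + t1,
                       donor_start = pp$unit_b[1] + t0, name = "conv")
  reads <- sim_reads_for(list(list(conv), list()), mini, pnl, depth = 20,
                         seed = 47)
  g <- genotype_sample(reads[, c("read_id", "seq")], pnl, ctl, mini = mini)
  cv <- g$conversions
  expect_false(is.null(cv))
  cv <- cv[cv$donor_paralog == "unit_b", ]
  expect_gte(nrow(cv), 1L)
  expect_equal(max(cv$n_diagnostic_switched), 7L)
  expect_lte(abs(cv$tract_start[1] - (pp$unit_a[1] + off[8])),
             off[8] - off[7])   # within one inter-diagnostic interval
})
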