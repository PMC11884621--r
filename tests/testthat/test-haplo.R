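fake_phase <- function(h1, h2, pos = seq_along(h1) * 10L) {
  loci <- data.frame(pos = pos, ref = "A", alt = "T", type = "SNV")
  list(haplotypes = rbind(h1, h2), loci = loci, phased = TRUE,
       flag = NA_character_, mec_cost = 0, supporting_reads = c(10L, 10L))
}

test_that("the haplotype matrix has two rows per phased sample", {
  ph <- list(S1 = fake_phase(c(0L, 1L), c(1L, 0L)),
             S2 = fake_phase(c(0L, 0L), c(0L, 0L)),
             S3 = fake_phase(c(1L, 1L), c(1L, 1L)),
             S4 = list(phased = FALSE, flag = "low support"))
  bm <- build_matrix(ph)
  expect_equal(nrow(bm$matrix), 6L)       # 2n rows for 3 phased samples
  expect_equal(bm$n_excluded, 1L)
  expect_identical(bm$matrix["S3_h1", ], bm$matrix["S3_h2", ])
  # columns are the union of loci
  ph2 <- list(S1 = fake_phase(c(1L), pos = 10L, h2 = c(0L)),
              S2 = fake_phase(c(1L), pos = 20L, h2 = c(1L)))
  bm2 <- build_matrix(ph2)
  expect_equal(ncol(bm2$matrix), 2L)
  expect_equal(unname(bm2$matrix["S1_h1", ]), c(1L, 0L))
})

test_that("dedup collapses duplicates and preserves total multiplicity", {
  withr::local_seed(51)
  M <- matrix(rbinom(300, 1, 0.4), 30, 10)
  M <- M[sample(30, 60, replace = TRUE), ]
  cl <- dedup_and_cluster(M)
  expect_equal(sum(cl$multiplicity), nrow(M))
  expect_equal(nrow(cl$unique_haplotypes),
               nrow(unique(as.data.frame(M))))
  ident <- matrix(1L, 8, 5)
  cli <- dedup_and_cluster(ident)
  expect_equal(nrow(cli$unique_haplotypes), 1L)
  expect_equal(cli$k, 1L)
  expect_true(all(cli$groups == "Hap_s1"))
})

test_that("planted clades are recovered with ARI 1 and stable under shuffling", {
  withr::local_seed(52)
  founders <- rbind(c(1,1,1,1,0,0,0,0,0,0,0,0),
                    c(0,0,0,0,1,1,1,1,0,0,0,0),
                    c(0,0,0,0,0,0,0,0,1,1,1,1))
  lab <- sample(1:3, 300, replace = TRUE, prob = c(0.5, 0.3, 0.2))
  M <- founders[lab, ]
  flip <- matrix(runif(length(M)) < 0.01, nrow(M))
  M <- ifelse(flip, 1 - M, M)
  cl <- dedup_and_cluster(M, k = 3)
  expect_equal(adjusted_rand(lab, cl$groups), 1)
  expect_equal(levels(cl$groups)[1], "Hap_s1")
  expect_equal(as.character(cl$groups[lab == 1][1]), "Hap_s1")  # largest clade
  # automatic k lands on 3 and shuffling rows changes nothing
  cl_auto <- dedup_and_cluster(M)
  expect_equal(cl_auto$k, 3L)
  perm <- sample(nrow(M))
  cl_perm <- dedup_and_cluster(M[perm, ], k = 3)
  expect_equal(adjusted_rand(cl$groups[perm], cl_perm$groups), 1)
})

test_that("a small dendrogram matches brute-force complete linkage", {
  M <- rbind(c(1, 1, 0), c(1, 0, 1), c(0, 0, 1), c(0, 1, 1))
  cl <- dedup_and_cluster(M, k = 2)
  # brute-force: complete-linkage agglomeration over 1 - Pearson distances,
  # on the deduplicated rows the clustering actually operates on
  d <- 1 - suppressWarnings(cor(t(cl$unique_haplotypes)))
  # first merge joins the closest pair
  hc <- cl$hclust
  pair <- sort(-hc$merge[1, ])
  dm <- d; diag(dm) <- Inf
  expect_equal(unname(dm[pair[1], pair[2]]), min(dm))
  expect_equal(hc$height[1], min(dm))
  # heights are the complete-linkage (maximum) inter-cluster distances
  expect_equal(hc$height[length(hc$height)], max(hc$height))
})

test_that("r-squared and D follow the haplotype-frequency formulas", {
  # AB=40, ab=40, Ab=10, aB=10 -> D = 0.15, r2 = 0.36
  M <- rbind(matrix(rep(c(1L, 1L), 40), ncol = 2, byrow = TRUE),
             matrix(rep(c(0L, 0L), 40), ncol = 2, byrow = TRUE),
             matrix(rep(c(1L, 0L), 10), ncol = 2, byrow = TRUE),
             matrix(rep(c(0L, 1L), 10), ncol = 2, byrow = TRUE))
  colnames(M) <- c("l1", "l2")
  ld <- compute_ld(M)
  expect_equal(ld$r2[1, 2], 0.36, tolerance = 1e-12)
  # duplicated column: perfect LD
  M2 <- cbind(M, l3 = M[, 1])
  expect_equal(compute_ld(M2)$r2[1, 3], 1)
  expect_equal(unname(diag(ld$r2)), c(1, 1))
})

test_that("r-squared equals the brute-force counting oracle", {
  withr::local_seed(53)
  M <- matrix(rbinom(100 * 20, 1, 0.4), 100, 20)
  colnames(M) <- sprintf("l%d", 1:20)
  ld <- compute_ld(M, maf_min = 0.01)
  kept <- ld$kept
  for (i in seq_along(kept)) for (j in seq_along(kept)) {
    if (i >= j) next
    expect_equal(ld$r2[i, j], r2_brute(M[, kept[i]], M[, kept[j]]),
                 tolerance = 1e-12)
  }
  expect_true(isSymmetric(ld$r2))
  expect_true(all(ld$r2 >= 0 & ld$r2 <= 1 + 1e-12, na.rm = TRUE))
})

test_that("independent loci show background-level LD and blocks need linkage", {
  withr::local_seed(54)
  M <- matrix(rbinom(2000 * 8, 1, 0.5), 2000, 8)
  colnames(M) <- sprintf("l%d", 1:8)
  ld <- compute_ld(M)
  off <- ld$r2[upper.tri(ld$r2)]
  expect_true(all(off < 0.05))
  expect_equal(nrow(ld$blocks), 0L)
  # three copies of one column form a full-linkage block
  B <- cbind(M[, 1], M[, 1], M[, 1])
  colnames(B) <- c("a", "b", "c")
  expect_equal(compute_ld(B)$blocks, data.frame(start = 1L, end = 3L))
})

test_that("motif scanning reports created and destroyed sites per strand", {
  # GATA1 WGATAR: ref window TGATAA destroyed by the final A->C
  region <- paste0("CCCCCC", "TGATAA", "CCCCCC")
  hits <- scan_tfbs(region, data.frame(pos = 11L, ref = "A", alt = "C"))
  g <- hits[hits$factor == "GATA1", ]
  expect_gte(nrow(g), 1L)
  expect_true(all(g$effect == "destroyed"))
  expect_true(all(g$win_start <= 11L & 11L < g$win_end))
  # a variant far from any motif yields nothing
  none <- scan_tfbs("ACACACACACACAC", data.frame(pos = 7L, ref = "A", alt = "T"))
  expect_equal(nrow(none), 0L)
  # reverse-complement planted motif is found on the minus strand
  region2 <- paste0("GGGGGG", revcomp("TGATAA"), "GGGGGG")
  hits2 <- scan_tfbs(region2, data.frame(pos = 8L, ref = substr(region2, 9, 9),
                                         alt = "G"))
  g2 <- hits2[hits2$factor == "GATA1", ]
  expect_gte(nrow(g2), 1L)
  expect_true(all(g2$strand == "-"))
})
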