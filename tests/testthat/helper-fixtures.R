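# Shared fixtures: one mini-reference/panel/catalog per session, plus
# independent oracles used across test files.

fixture_env <- new.env(parent = emptyenv())

get_mini <- function(seed = 11L) {
  key <- paste0("mini", seed)
  if (is.null(fixture_env[[key]]))
    fixture_env[[key]] <- build_mini_reference(seed = seed)
  fixture_env[[key]]
}

get_panel <- function(seed = 11L) {
  key <- paste0("panel", seed)
  if (is.null(fixture_env[[key]]))
    fixture_env[[key]] <- mini_panel(get_mini(seed))
  fixture_env[[key]]
}

get_catalog <- function(seed = 11L) {
  key <- paste0("catalog", seed)
  if (is.null(fixture_env[[key]]))
    fixture_env[[key]] <- default_catalog(get_mini(seed))
  fixture_env[[key]]
}

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                              collapse = "")

str_hamming <- function(a, b) sum(charToRaw(a) != charToRaw(b))

# reads for a list of per-haplotype event lists, at given depth/error
sim_reads_for <- function(events_by_hap, mini, pnl, depth = 20L,
                          sub = 0, ins = 0, del = 0, seed = 1L) {
  prods <- list()
  for (h in seq_along(events_by_hap)) {
    hseq <- mini$contigs
    evs <- events_by_hap[[h]]
    for (ct in unique(vapply(evs, `[[`, "", "contig")))
      hseq[[ct]] <- apply_events(mini$contigs[[ct]],
                                 evs[vapply(evs, `[[`, "", "contig") == ct])$seq
    pr <- in_silico_pcr(hseq, pnl)
    if (nrow(pr)) { pr$hap <- h; prods[[length(prods) + 1L]] <- pr }
  }
  prods <- do.call(rbind, prods)
  simulate_ccs_reads(prods, depth = depth, sub_rate = sub, ins_rate = ins,
                     del_rate = del, seed = seed)
}

# oracle: all equivalent placements of a single contiguous deletion that
# turns `ref` into `read`; leftmost placement is the normalised breakpoint
del_placements <- function(read, ref) {
  D <- nchar(ref) - nchar(read)
  stopifnot(D > 0)
  out <- integer(0)
  for (b in 0:nchar(read)) {
    cand <- paste0(substr(ref, 1, b), substr(ref, b + D + 1, nchar(ref)))
    if (cand == read) out <- c(out, b)
  }
  out
}

# oracle: exhaustive minimum-error-correction cost over all bipartitions
mec_brute <- function(M, w = rep(1, nrow(M))) {
  n <- nrow(M)
  best <- Inf
  maj <- function(rows) {
    if (!length(rows)) return(rep(0L, ncol(M)))
    as.integer(colSums(M[rows, , drop = FALSE] * w[rows]) > sum(w[rows]) / 2)
  }
  for (mask in 0:(2^(n - 1) - 1)) {
    side <- c(TRUE, as.logical(bitwAnd(mask, 2^(seq_len(n - 1) - 1)) > 0))
    c1 <- maj(which(side)); c2 <- maj(which(!side))
    cost <- sum(w * pmin(colSums(abs(t(M) - c1)), colSums(abs(t(M) - c2))))
    if (cost < best) best <- cost
  }
  best
}

# oracle: step-up BH adjustment written independently of p.adjust
bh_brute <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  out
}

# oracle: r^2 between two 0/1 haplotype columns by direct counting
r2_brute <- function(x, y) {
  n <- length(x)
  pA <- sum(x) / n; pB <- sum(y) / n
  pAB <- sum(x == 1 & y == 1) / n
  D <- pAB - pA * pB
  D^2 / (pA * (1 - pA) * pB * (1 - pB))
}

# adjusted Rand index between two label vectors
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- comb2(sum(tab))
  exp_idx <- sum_a * sum_b / n
  max_idx <- (sum_a + sum_b) / 2
  (sum_ij - exp_idx) / (max_idx - exp_idx)
}

empty_sv_calls <- function() {
  data.frame(amplicon_id = character(), class = character(),
             length_shift = integer(), genotype = character(),
             supporting_reads = integer(), total_reads = integer(),
             matched_catalog_allele = character(), filter = character())
}

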