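#' Cluster full-length reads into two allele groups (MEC phasing)
#'
#' Amplicon CCS reads span the whole fragment, so within-amplicon phasing is
#' a 2-clustering of the reads' alleles at heterozygous sites under the
#' minimum-error-correction (MEC) objective: choose two consensus vectors
#' and an assignment of reads minimising the total Hamming distance of reads
#' to their consensus. When the number of distinct read vectors is small
#' (<= `exact_max_unique`) the optimum is found exactly by enumerating
#' bipartitions of the distinct vectors (the optimal consensus given a
#' partition is the column-wise weighted majority); larger instances use
#' k-modes refinement seeded from every pair of distinct vectors. Results
#' are invariant to read input order, and ties are broken by ordering the
#' two consensus vectors lexicographically (cluster 1 gets the smaller one).
#'
#' @param read_alleles 0/1 matrix, reads x het sites (rows may repeat).
#' @param weights optional read multiplicities.
#' @param min_reads_per_cluster fewer supporting reads in either cluster
#'   leaves the sample unphased.
#' @param exact_max_unique exact-enumeration ceiling on distinct vectors.
#' @return list with `consensus` (2 x sites matrix, row 1 lexicographically
#'   smaller), `assignment` (cluster index per input read), `mec_cost`,
#'   `cluster_support` (reads per cluster), `phased` (logical), `reason`.
#' @export
cluster_reads_by_hets <- function(read_alleles, weights = NULL,
                                  min_reads_per_cluster = 3L,
                                  exact_max_unique = 12L) {
  read_alleles <- as.matrix(read_alleles)
  if (ncol(read_alleles) < 1L) stop_with("need at least one het site")
  n <- nrow(read_alleles)
  if (is.null(weights)) weights <- rep(1L, n)
  key <- apply(read_alleles, 1, paste, collapse = "")
  ord_keys <- sort(unique(key))
  u <- length(ord_keys)
  U <- read_alleles[match(ord_keys, key), , drop = FALSE]
  w <- vapply(ord_keys, function(k) sum(weights[key == k]), 0)

  maj <- function(rows, ws) {
    if (length(rows) == 0L) return(rep(0L, ncol(U)))
    cs <- colSums(U[rows, , drop = FALSE] * ws[rows])
    as.integer(cs > sum(ws[rows]) / 2)   # ties -> 0 (deterministic)
  }
  cost_of <- function(side) {   # side: logical over unique vectors
    c1 <- maj(which(side), w); c2 <- maj(which(!side), w)
    d1 <- colSums(abs(t(U) - c1)); d2 <- colSums(abs(t(U) - c2))
    # each vector goes to its nearer consensus (ties to cluster of `side`)
    assign1 <- ifelse(side, d1 <= d2, d1 < d2)
    cost <- sum(w * ifelse(assign1, d1, d2))
    list(cost = cost, c1 = c1, c2 = c2, assign1 = assign1)
  }

  best <- NULL
  if (u == 1L) {
    best <- list(cost = 0, c1 = U[1, ], c2 = U[1, ],
                 assign1 = TRUE)
  } else if (u <= exact_max_unique) {
    for (mask in 0:(2^(u - 1) - 1)) {    # vector 1 always on side 1
      side <- c(TRUE, as.logical(bitwAnd(mask, 2^(seq_len(u - 1) - 1)) > 0))
      cand <- cost_of(side)
      if (is.null(best) || cand$cost < best$cost) best <- cand
    }
  } else {
    pairs <- utils::combn(u, 2)
    for (pc in seq_len(ncol(pairs))) {
      c1 <- U[pairs[1, pc], ]; c2 <- U[pairs[2, pc], ]
      for (it in 1:20) {
        d1 <- colSums(abs(t(U) - c1)); d2 <- colSums(abs(t(U) - c2))
        assign1 <- d1 <= d2
        n1 <- maj(which(assign1), w); n2 <- maj(which(!assign1), w)
        if (all(n1 == c1) && all(n2 == c2)) break
        c1 <- n1; c2 <- n2
      }
      cand <- cost_of(assign1)
      if (is.null(best) || cand$cost < best$cost) best <- cand
    }
  }

  c1 <- best$c1; c2 <- best$c2; a1 <- best$assign1
  # lexicographic tie rule: cluster 1 carries the smaller consensus
  if (paste(c1, collapse = "") > paste(c2, collapse = "")) {
    tmp <- c1; c1 <- c2; c2 <- tmp; a1 <- !a1
  }
  assignment <- ifelse(a1[match(key, ord_keys)], 1L, 2L)
  support <- c(sum(weights[assignment == 1L]), sum(weights[assignment == 2L]))
  phased <- all(support >= min_reads_per_cluster)
  list(consensus = unname(rbind(c1, c2)), assignment = assignment,
       mec_cost = best$cost, cluster_support = support, phased = phased,
       reason = if (phased) NA_character_ else
         sprintf("cluster support %d/%d below %d", support[1], support[2],
                 min_reads_per_cluster))
}

#' Phase one sample x amplicon from pileup evidence
#'
#' Builds the read x het-site allele matrix from per-read variant records,
#' runs [cluster_reads_by_hets()], and emits the two per-amplicon haplotype
#' allele vectors over all PASS variant loci (heterozygous sites from the
#' cluster consensus, homozygous-alt sites set on both haplotypes). Samples
#' with no heterozygous PASS site are trivially phased: two identical
#' haplotypes, flagged `no_het_sites`.
#'
#' @param pile a [pileup_reads()] result.
#' @param calls [call_small_variants()] output for the same pile.
#' @param min_reads_per_cluster see [cluster_reads_by_hets()].
#' @return list with `haplotypes` (2 x loci 0/1 matrix with loci key
#'   columns), `loci` (data.frame `pos`, `ref`, `alt`, `type`), `phased`,
#'   `flag`, `mec_cost`, `supporting_reads`.
#' @export
phase_amplicon <- function(pile, calls, min_reads_per_cluster = 3L) {
  pass <- calls[calls$filter == "PASS", , drop = FALSE]
  loci <- pass[, c("pos", "ref", "alt", "type")]
  nl <- nrow(loci)
  if (nl == 0L)
    return(list(haplotypes = matrix(integer(), 2, 0), loci = loci,
                phased = TRUE, flag = "no_variants", mec_cost = 0,
                supporting_reads = c(pile$depth, pile$depth)))
  het_ix <- which(pass$genotype == "0/1")
  hap <- matrix(0L, 2, nl)
  hap[, pass$genotype == "1/1"] <- 1L
  if (length(het_ix) == 0L)
    return(list(haplotypes = hap, loci = loci, phased = TRUE,
                flag = "no_het_sites", mec_cost = 0,
                supporting_reads = c(pile$depth, pile$depth)))

  recs <- pile$read_records
  keys <- paste(pass$pos[het_ix], pass$ref[het_ix], pass$alt[het_ix])
  M <- matrix(0L, length(pile$unique_reads), length(het_ix))
  if (nrow(recs)) {
    rk <- paste(recs$pos, recs$ref, recs$alt)
    hit <- which(rk %in% keys)
    for (t in hit)
      M[recs$uread[t], match(rk[t], keys)] <- 1L
  }
  cl <- cluster_reads_by_hets(M, weights = pile$weights,
                              min_reads_per_cluster = min_reads_per_cluster)
  if (!cl$phased)
    return(list(haplotypes = NULL, loci = loci, phased = FALSE,
                flag = cl$reason, mec_cost = cl$mec_cost,
                supporting_reads = cl$cluster_support))
  cons <- cl$consensus
  # genotype consistency: at every het site the two haplotypes must differ;
  # where the consensi agree, flip the side with weaker support for that call
  for (s in seq_along(het_ix)) {
    if (cons[1, s] == cons[2, s]) {
      sup <- vapply(1:2, function(g)
        sum(pile$weights[cl$assignment == g & M[, s] == cons[g, s]]), 0)
      flip <- which.min(sup)
      cons[flip, s] <- 1L - cons[flip, s]
    }
  }
  hap[, het_ix] <- cons
  list(haplotypes = hap, loci = loci, phased = TRUE, flag = NA_character_,
       mec_cost = cl$mec_cost, supporting_reads = cl$cluster_support)
}

#' Assign a variant to its paralogous unit
#'
#' @param pos 0-based contig position of the variant.
#' @param amp an [amplicon()] with annotated gene/unit intervals.
#' @return the containing unit id(s), or `"intergenic"`.
#' @export
assign_paralog <- function(pos, amp) {
  g <- amp$genes
  hit <- g$id[g$start <= pos & pos < g$end]
  if (length(hit) == 0L) "intergenic" else hit
}

#' Report variants present at homologous offsets of both paralog units
#'
#' A substitution independently called at the same offset of both units of a
#' paralog pair (same ref and alt) is reported once with label `"both"`,
#' mirroring the question of whether a variant lies in one gene copy or in
#' both.
#'
#' @param calls small-variant calls with `pos`, `ref`, `alt` on contig
#'   coordinates.
#' @param pair one element of a mini-reference's `paralog_pairs`.
#' @return data.frame `pos`, `ref`, `alt`, `unit` (unit id or `"both"`).
#' @export
paralog_duplicates <- function(calls, pair) {
  if (nrow(calls) == 0L)
    return(data.frame(pos = integer(), ref = character(), alt = character(),
                      unit = character()))
  ua <- pair$unit_a; ub <- pair$unit_b
  in_a <- calls$pos >= ua[1] & calls$pos < ua[2]
  in_b <- calls$pos >= ub[1] & calls$pos < ub[2]
  off <- ifelse(in_a, calls$pos - ua[1], ifelse(in_b, calls$pos - ub[1], NA))
  unit <- ifelse(in_a, "unit_a", ifelse(in_b, "unit_b", "intergenic"))
  key <- paste(off, calls$ref, calls$alt)
  both <- key %in% key[in_a] & key %in% key[in_b] & !is.na(off)
  unit[both] <- "both"
  data.frame(pos = calls$pos, ref = calls$ref, alt = calls$alt, unit = unit,
             stringsAsFactors = FALSE)
}

#' Detect gene-conversion tracts on a phased haplotype
#'
#' At each paralog-diagnostic position the haplotype either carries its own
#' unit's allele or the other paralog's. Maximal runs of at least `min_run`
#' consecutive diagnostic positions carrying the donor allele are reported
#' as conversion tracts; shorter runs are treated as point variants. Tract
#' resolution is limited by the spacing of diagnostic positions.
#'
#' @param hap_alleles 0/1 vector over the haplotype's variant loci.
#' @param loci the matching loci table (contig coordinates in `pos`).
#' @param pair paralog pair annotation (see [build_mini_reference()]).
#' @param unit `"unit_a"` or `"unit_b"`: which unit's haplotype to scan.
#' @param min_run minimum switched diagnostic sites per tract.
#' @return data.frame of tracts: `tract_start`, `tract_end` (0-based contig
#'   positions of the first/last switched diagnostic site, half-open),
#'   `n_diagnostic_switched`, `donor_paralog`.
#' @export
detect_conversion <- function(hap_alleles, loci, pair, unit = "unit_a",
                              min_run = 3L) {
  base <- if (unit == "unit_a") pair$unit_a[1] else pair$unit_b[1]
  own <- if (unit == "unit_a") pair$diagnostic$allele_a else pair$diagnostic$allele_b
  donor <- if (unit == "unit_a") pair$diagnostic$allele_b else pair$diagnostic$allele_a
  dpos <- base + pair$diagnostic$offset
  # switched = haplotype carries the donor allele at the diagnostic position
  switched <- vapply(seq_along(dpos), function(k) {
    j <- which(loci$pos == dpos[k] & loci$ref == own[k] & loci$alt == donor[k])
    length(j) == 1L && hap_alleles[j] == 1L
  }, TRUE)
  r <- rle(switched)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  keep <- which(r$values & r$lengths >= min_run)
  if (length(keep) == 0L)
    return(data.frame(tract_start = integer(), tract_end = integer(),
                      n_diagnostic_switched = integer(),
                      donor_paralog = character()))
  data.frame(
    tract_start = dpos[starts[keep]],
    tract_end = dpos[ends[keep]] + 1L,
    n_diagnostic_switched = r$lengths[keep],
    donor_paralog = if (unit == "unit_a") "unit_b" else "unit_a",
    stringsAsFactors = FALSE)
}
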