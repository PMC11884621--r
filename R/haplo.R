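#' Build the population 0/1 haplotype matrix for one amplicon
#'
#' Two rows per phased sample (including samples without heterozygous sites,
#' whose two haplotypes are identical); columns are the union of variant
#' loci across the cohort; cells mark the alternate allele. Samples that
#' failed phasing are excluded and counted.
#'
#' @param phase_results named list (by sample id) of [phase_amplicon()]
#'   results for one amplicon.
#' @return list with `matrix` (rows named `<sample>_h1`/`_h2`), `loci`
#'   (data.frame `pos`, `ref`, `alt`), `n_excluded`.
#' @export
build_matrix <- function(phase_results) {
  phased <- Filter(function(p) isTRUE(p$phased), phase_results)
  n_excluded <- length(phase_results) - length(phased)
  all_loci <- unique(do.call(rbind, lapply(phased, function(p)
    p$loci[, c("pos", "ref", "alt")])))
  all_loci <- all_loci[order(all_loci$pos, all_loci$alt), , drop = FALSE]
  key <- paste(all_loci$pos, all_loci$ref, all_loci$alt)
  rows <- list()
  for (s in names(phased)) {
    p <- phased[[s]]
    v1 <- v2 <- rep(0L, length(key))
    if (nrow(p$loci)) {
      ix <- match(paste(p$loci$pos, p$loci$ref, p$loci$alt), key)
      v1[ix] <- p$haplotypes[1, ]
      v2[ix] <- p$haplotypes[2, ]
    }
    rows[[paste0(s, "_h1")]] <- v1
    rows[[paste0(s, "_h2")]] <- v2
  }
  m <- do.call(rbind, rows)
  colnames(m) <- key
  list(matrix = m, loci = all_loci, n_excluded = n_excluded)
}

#' De-duplicate haplotypes and cluster them into haplogroups
#'
#' Exact duplicate rows are collapsed with multiplicity; the distinct
#' haplotypes are clustered agglomeratively with complete linkage on
#' `1 - Pearson correlation` (the distance the field's heatmap tools use on
#' 0/1 allele rows; Hamming distance is available as an option). The tree is
#' cut into `k` groups; when `k` is `NULL` it is chosen at the largest
#' relative gap between consecutive merge heights. Groups are mapped back to
#' all haplotype rows and labelled `Hap_s1`, `Hap_s2`, ... by descending
#' size.
#'
#' @param mat 0/1 haplotype matrix (rows = haplotypes).
#' @param k number of groups, or `NULL` for the merge-height-gap default.
#' @param distance `"pearson"` or `"hamming"`.
#' @param max_k ceiling considered when choosing `k` automatically.
#' @return list with `unique_haplotypes` (matrix), `multiplicity`,
#'   `groups` (factor over rows of `mat`, levels `Hap_s1...`), `k`,
#'   `hclust`, `consensus` (per-group 0/1 consensus).
#' @export
dedup_and_cluster <- function(mat, k = NULL, distance = c("pearson", "hamming"),
                              max_k = 8L) {
  distance <- match.arg(distance)
  key <- apply(mat, 1, paste, collapse = "")
  ukey <- sort(unique(key))
  U <- mat[match(ukey, key), , drop = FALSE]
  rownames(U) <- NULL
  mult <- vapply(ukey, function(kk) sum(key == kk), 0L)
  u <- nrow(U)
  if (u < 2L) {
    groups <- factor(rep("Hap_s1", nrow(mat)), levels = "Hap_s1")
    return(list(unique_haplotypes = U, multiplicity = mult, groups = groups,
                k = 1L, hclust = NULL, consensus = U))
  }
  if (distance == "pearson") {
    cc <- suppressWarnings(stats::cor(t(U)))
    undef <- !is.finite(cc)
    if (any(undef)) {
      message(sum(undef[upper.tri(undef)]),
              " haplotype pairs with undefined Pearson correlation; ",
              "distance set to maximum")
      cc[undef] <- -1
    }
    d <- stats::as.dist(1 - cc)
  } else {
    d <- stats::dist(U, method = "manhattan")
  }
  hc <- stats::hclust(d, method = "complete")
  if (is.null(k)) {
    h <- hc$height
    hmax <- max(h)
    # cut at the largest relative gap between consecutive merge heights,
    # considering cuts that give 2..max_k groups
    nh <- length(h)
    cand_k <- 2:min(max_k, u)
    gaps <- vapply(cand_k, function(kk) {
      upper <- if (kk == 1L) Inf else h[nh - kk + 2L]
      lower <- if (nh - kk + 1L >= 1L) h[nh - kk + 1L] else 0
      (upper - lower) / hmax
    }, 0)
    k <- cand_k[which.max(gaps)]
  }
  k <- min(k, u)
  cl_u <- stats::cutree(hc, k = k)
  groups_u <- cl_u[match(key, ukey)]
  sizes <- tapply(rep(1L, length(groups_u)), groups_u, sum)
  ord <- order(-sizes)
  lab <- stats::setNames(sprintf("Hap_s%d", seq_len(k)), names(sizes)[ord])
  groups <- factor(lab[as.character(groups_u)],
                   levels = sprintf("Hap_s%d", seq_len(k)))
  consensus <- do.call(rbind, lapply(seq_len(k), function(g) {
    rows <- which(cl_u == as.integer(names(lab)[lab == sprintf("Hap_s%d", g)]))
    as.integer(colSums(U[rows, , drop = FALSE] * mult[rows]) >
                 sum(mult[rows]) / 2)
  }))
  list(unique_haplotypes = U, multiplicity = mult, groups = groups, k = k,
       hclust = hc, consensus = consensus)
}

#' Pairwise linkage disequilibrium from phased haplotypes
#'
#' For loci A and B with haplotype frequencies, `D = p(AB) - p(A) p(B)` and
#' `r2 = D^2 / (p(A) p(a) p(B) p(b))`, computed directly from the 0/1
#' haplotype rows (no genotype EM is needed on phased data). Haplotype
#' blocks are maximal runs of consecutive loci whose pairwise `r2` all reach
#' the threshold.
#'
#' @param mat 0/1 haplotype matrix.
#' @param maf_min loci with minor allele frequency below this are excluded.
#' @param r2_threshold block-defining threshold.
#' @return list with `r2`, `dprime` (symmetric matrices over kept loci),
#'   `kept` (column indices), `excluded` (names), `blocks` (data.frame
#'   `start`, `end` of block runs in kept-locus indices).
#' @export
compute_ld <- function(mat, maf_min = 0.01, r2_threshold = 0.8) {
  p <- colMeans(mat)
  maf <- pmin(p, 1 - p)
  kept <- which(maf >= maf_min)
  excluded <- colnames(mat)[maf < maf_min]
  M <- mat[, kept, drop = FALSE]
  nl <- ncol(M)
  pA <- colMeans(M)
  pAB <- crossprod(M) / nrow(M)
  D <- pAB - outer(pA, pA)
  denom <- outer(pA * (1 - pA), pA * (1 - pA))
  r2 <- ifelse(denom > 0, D^2 / denom, NA_real_)
  diag(r2) <- 1
  dmax <- matrix(NA_real_, nl, nl)
  for (i in seq_len(nl)) for (j in seq_len(nl)) {
    dmax[i, j] <- if (D[i, j] < 0) min(pA[i] * pA[j], (1 - pA[i]) * (1 - pA[j]))
                  else min(pA[i] * (1 - pA[j]), (1 - pA[i]) * pA[j])
  }
  dprime <- ifelse(dmax > 0, abs(D) / dmax, NA_real_)
  diag(dprime) <- 1
  blocks <- list()
  if (nl >= 2L) {
    i <- 1L
    while (i <= nl) {
      j <- i
      while (j < nl &&
             all(r2[(i:(j + 1)), (i:(j + 1))][upper.tri(diag(j - i + 2))] >=
                   r2_threshold, na.rm = FALSE) &&
             !anyNA(r2[i:(j + 1), i:(j + 1)])) j <- j + 1L
      if (j > i) blocks[[length(blocks) + 1L]] <- data.frame(start = i, end = j)
      i <- j + 1L
    }
  }
  blocks <- if (length(blocks)) do.call(rbind, blocks) else
    data.frame(start = integer(), end = integer())
  list(r2 = r2, dprime = dprime, kept = kept, excluded = excluded,
       blocks = blocks)
}

#' Default IUPAC motifs of five key erythroid regulators
#'
#' Consensus approximations of the published binding preferences: GATA1's
#' WGATAR, the CCAAT box bound by NF-Y, the E-box bound by TAL1, the
#' CACCC box bound by KLF1, and the TGACCA half-site reported for BCL11A.
#' Shipped as a configuration table; any IUPAC table with the same columns
#' can be supplied instead.
#'
#' @return data.frame with `factor` and `iupac`.
#' @export
default_motifs <- function() {
  data.frame(factor = c("KLF1", "BCL11A", "GATA1", "NFY", "TAL1"),
             iupac = c("CCACACCCT", "TGACCA", "WGATAR", "CCAAT", "CANNTG"),
             stringsAsFactors = FALSE)
}

iupac_regex <- function(iupac) {
  map <- c(A = "A", C = "C", G = "G", T = "T", R = "[AG]", Y = "[CT]",
           S = "[CG]", W = "[AT]", K = "[GT]", M = "[AC]", B = "[CGT]",
           D = "[AGT]", H = "[ACT]", V = "[ACG]", N = "[ACGT]")
  paste(map[strsplit(iupac, "")[[1]]], collapse = "")
}

#' Scan variants for created or destroyed TF binding motifs
#'
#' For each variant, every window of motif length covering the variant
#' position is tested on both strands of the reference and the alternate
#' local sequence. A motif matched by the reference but not the alternate is
#' `destroyed`; the converse is `created`. Variants too close to the region
#' edge for a full window are skipped.
#'
#' @param region_seq reference sequence of the region (contig).
#' @param variants data.frame with `pos` (0-based on `region_seq`), `ref`,
#'   `alt` (single-base substitutions are scanned; others skipped).
#' @param motifs motif table, see [default_motifs()].
#' @return data.frame of hits: `pos`, `ref`, `alt`, `factor`, `win_start`,
#'   `win_end` (0-based half-open), `effect`, `strand`.
#' @export
scan_tfbs <- function(region_seq, variants, motifs = default_motifs()) {
  hits <- list()
  n <- nchar(region_seq)
  for (v in seq_len(nrow(variants))) {
    pos <- variants$pos[v]; ref <- variants$ref[v]; alt <- variants$alt[v]
    if (nchar(ref) != 1L || nchar(alt) != 1L) next
    for (m in seq_len(nrow(motifs))) {
      L <- nchar(motifs$iupac[m])
      rx <- paste0("^", iupac_regex(motifs$iupac[m]), "$")
      for (w0 in (pos - L + 1L):pos) {
        if (w0 < 0L || w0 + L > n) next
        refwin <- substr(region_seq, w0 + 1L, w0 + L)
        altwin <- refwin
        substr(altwin, pos - w0 + 1L, pos - w0 + 1L) <- alt
        for (strand in c("+", "-")) {
          rw <- if (strand == "+") refwin else revcomp(refwin)
          aw <- if (strand == "+") altwin else revcomp(altwin)
          ref_hit <- grepl(rx, rw); alt_hit <- grepl(rx, aw)
          if (ref_hit == alt_hit) next
          hits[[length(hits) + 1L]] <- data.frame(
            pos = pos, ref = ref, alt = alt, factor = motifs$factor[m],
            win_start = w0, win_end = w0 + L,
            effect = if (ref_hit) "destroyed" else "created",
            strand = strand, stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (length(hits) == 0L)
    return(data.frame(pos = integer(), ref = character(), alt = character(),
                      factor = character(), win_start = integer(),
                      win_end = integer(), effect = character(),
                      strand = character()))
  unique(do.call(rbind, hits))
}
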