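#' Assign reads to amplicons by terminal primer matching
#'
#' Each read end is scanned over a window (default 50 bp) against every
#' amplicon's primers, in both orientations, allowing up to the primer pair's
#' `max_mismatch` substitutions (no indels inside the primer window). A read
#' is assigned to the unique amplicon whose forward and reverse primers match
#' opposite ends in a consistent orientation; ties between amplicons leave
#' the read `UNASSIGNED` with an ambiguity flag.
#'
#' @param reads data.frame with `read_id` and `seq` (e.g. [read_fastq()]).
#' @param pnl a [panel()].
#' @param window bp scanned at each read end.
#' @return data.frame with `read_id`, `amplicon_id` (or `"UNASSIGNED"`),
#'   `orientation` (`+`/`-`/`NA`), `fwd_mismatches`, `rev_mismatches`,
#'   `read_length`, `ambiguous`, and `oriented_seq` (the read normalised to
#'   the forward strand when assigned).
#' @export
assign_reads <- function(reads, pnl, window = 50L) {
  n <- nrow(reads)
  amps <- pnl$amplicons
  pre <- Biostrings::DNAStringSet(substr(reads$seq, 1L, window))
  len <- nchar(reads$seq)
  suf <- Biostrings::DNAStringSet(substr(reads$seq, pmax(1L, len - window + 1L),
                                         len))
  # min mismatch count of a primer inside each window, by stepping thresholds
  min_mm <- function(pattern, windows, max_mm) {
    out <- rep(NA_integer_, length(windows))
    for (t in 0:max_mm) {
      hit <- Biostrings::vcountPattern(pattern, windows, max.mismatch = t) > 0L
      out[is.na(out) & hit] <- t
    }
    out
  }
  best_amp <- rep(NA_character_, n); best_orient <- rep(NA_character_, n)
  best_f <- rep(NA_integer_, n); best_r <- rep(NA_integer_, n)
  ambiguous <- rep(FALSE, n); nhits <- rep(0L, n)
  for (a in amps) {
    mm <- a$primers$max_mismatch
    # + orientation: fwd at start, revcomp(rev) at end
    fp <- min_mm(a$primers$fwd, pre, mm)
    rp <- min_mm(revcomp(a$primers$rev), suf, mm)
    # - orientation: rev at start, revcomp(fwd) at end
    fm <- min_mm(a$primers$rev, pre, mm)
    rm_ <- min_mm(revcomp(a$primers$fwd), suf, mm)
    plus <- !is.na(fp) & !is.na(rp)
    minus <- !is.na(fm) & !is.na(rm_) & !plus
    hit <- plus | minus
    nhits <- nhits + hit
    ambiguous <- ambiguous | (hit & !is.na(best_amp))
    new <- hit & is.na(best_amp)
    best_amp[new] <- a$id
    best_orient[new & plus] <- "+"; best_orient[new & minus] <- "-"
    best_f[new & plus] <- fp[new & plus]; best_r[new & plus] <- rp[new & plus]
    best_f[new & minus] <- fm[new & minus]; best_r[new & minus] <- rm_[new & minus]
  }
  best_amp[ambiguous] <- NA_character_
  oriented <- reads$seq
  flip <- !is.na(best_amp) & best_orient == "-"
  if (any(flip)) oriented[flip] <- revcomp(reads$seq[flip])
  data.frame(read_id = reads$read_id,
             amplicon_id = ifelse(is.na(best_amp), "UNASSIGNED", best_amp),
             orientation = ifelse(ambiguous, NA, best_orient),
             fwd_mismatches = ifelse(ambiguous, NA, best_f),
             rev_mismatches = ifelse(ambiguous, NA, best_r),
             read_length = len, ambiguous = ambiguous,
             oriented_seq = ifelse(is.na(best_amp), reads$seq, oriented),
             stringsAsFactors = FALSE)
}

#' Assign a single read
#' @param read DNA string.
#' @param pnl a [panel()].
#' @param window bp scanned at each end.
#' @return one-row data.frame, see [assign_reads()].
#' @export
assign_read <- function(read, pnl, window = 50L) {
  assign_reads(data.frame(read_id = "read", seq = read), pnl, window)
}

#' Call structural variants from primer-pair identity and read length
#'
#' Within each amplicon of one sample, read-length deviations from the
#' expected product length are binned into a REF-like cluster
#' (`|observed - expected| <= length_tolerance`) and shifted clusters
#' (1-D gap clustering: sorted deviations split where consecutive values are
#' more than `length_tolerance` apart). Shifted clusters are matched to the
#' panel's SV catalog by length shift; unmatched clusters are `novel`.
#' Genotype is `het` when the shifted-read fraction lies in `het_window` and
#' `hom` when it reaches `hom_min`. Covered amplicons with no reads while the
#' sample has reads elsewhere become `dropout` candidates, interpreted
#' jointly with catalog entries whose `linked_amplicon` ties a
#' deletion-spanning product to the dropout pattern (gap-PCR logic).
#' Amplicons whose expected product exceeds the panel's `max_product_len`
#' amplify only when internally deleted, so absence of product there is not
#' a dropout.
#'
#' @param assignments [assign_reads()] output for one sample.
#' @param pnl a [panel()].
#' @param length_tolerance bp.
#' @param min_depth minimum reads per amplicon to call.
#' @param het_window,hom_min shifted-read fraction thresholds.
#' @param min_sv_reads minimum reads supporting a shifted cluster.
#' @return data.frame of SV calls (`amplicon_id`, `class`, `length_shift`,
#'   `genotype`, `supporting_reads`, `total_reads`, `matched_catalog_allele`,
#'   `filter`).
#' @export
call_svs <- function(assignments, pnl, length_tolerance = 100L,
                     min_depth = 10L, het_window = c(0.25, 0.75),
                     hom_min = 0.9, min_sv_reads = 5L) {
  stopifnot(min_depth >= 1L)
  asn <- assignments[assignments$amplicon_id != "UNASSIGNED", ]
  calls <- list()
  total_assigned <- nrow(asn)
  genotype_of <- function(frac) {
    if (frac >= hom_min) "hom"
    else if (frac >= het_window[1] && frac <= het_window[2]) "het"
    else NA_character_
  }
  for (a in pnl$amplicons) {
    lens <- asn$read_length[asn$amplicon_id == a$id]
    ntot <- length(lens)
    spans_only_deleted <- a$expected_length > pnl$max_product_len
    if (ntot == 0L) {
      if (!spans_only_deleted && total_assigned >= min_depth)
        calls[[length(calls) + 1L]] <- data.frame(
          amplicon_id = a$id, class = "dropout", length_shift = NA_integer_,
          genotype = NA_character_, supporting_reads = 0L, total_reads = 0L,
          matched_catalog_allele = NA_character_, filter = "PASS")
      next
    }
    if (ntot < min_depth) {
      calls[[length(calls) + 1L]] <- data.frame(
        amplicon_id = a$id, class = "no_call", length_shift = NA_integer_,
        genotype = NA_character_, supporting_reads = ntot, total_reads = ntot,
        matched_catalog_allele = NA_character_, filter = "LOW_DEPTH")
      next
    }
    dev <- lens - a$expected_length
    shifted <- dev[abs(dev) > length_tolerance]
    if (length(shifted) == 0L) next
    sh <- sort(shifted)
    brk <- which(diff(sh) > length_tolerance)
    starts <- c(1L, brk + 1L); ends <- c(brk, length(sh))
    for (ci in seq_along(starts)) {
      cl <- sh[starts[ci]:ends[ci]]
      if (length(cl) < min_sv_reads) next
      shift <- as.integer(round(stats::median(cl)))
      frac <- length(cl) / ntot
      cat_hit <- pnl$sv_catalog[pnl$sv_catalog$amplicon_id == a$id &
                                  abs(pnl$sv_catalog$length_shift - shift) <=
                                  length_tolerance, ]
      cls <- if (nrow(cat_hit)) cat_hit$class[1]
             else if (shift < 0) "deletion" else "duplication"
      allele <- if (nrow(cat_hit)) cat_hit$allele[1] else NA_character_
      gt <- genotype_of(frac)
      # deletion-spanning product: hom/het resolved through the linked
      # amplicon's residual REF-like coverage
      if (nrow(cat_hit) && !is.na(cat_hit$linked_amplicon[1])) {
        linked <- cat_hit$linked_amplicon[1]
        n_linked <- sum(asn$amplicon_id == linked)
        gt <- if (n_linked == 0L) "hom" else "het"
      }
      cls_final <- if (nrow(cat_hit)) cls
                   else if (shift < 0) "deletion" else "duplication"
      calls[[length(calls) + 1L]] <- data.frame(
        amplicon_id = a$id,
        class = if (is.na(allele)) "novel" else cls_final,
        length_shift = shift,
        genotype = gt, supporting_reads = length(cl), total_reads = ntot,
        matched_catalog_allele = allele, filter = "PASS")
    }
  }
  out <- if (length(calls)) do.call(rbind, calls) else
    data.frame(amplicon_id = character(), class = character(),
               length_shift = integer(), genotype = character(),
               supporting_reads = integer(), total_reads = integer(),
               matched_catalog_allele = character(), filter = character())
  # a dropout explained by a linked deletion-spanning call is absorbed by it
  linked_alleles <- pnl$sv_catalog$linked_amplicon[
    match(out$matched_catalog_allele, pnl$sv_catalog$allele)]
  explained <- out$amplicon_id %in% stats::na.omit(linked_alleles) &
    out$class == "dropout"
  out <- out[!explained, , drop = FALSE]
  # when a linked deletion removes one haplotype of an amplicon, a fully
  # shifted read set there reflects the remaining single haplotype: het
  hemi <- stats::na.omit(pnl$sv_catalog$linked_amplicon[
    match(out$matched_catalog_allele[out$genotype == "het" &
                                       !is.na(out$genotype)],
          pnl$sv_catalog$allele)])
  fix <- out$amplicon_id %in% hemi & !is.na(out$genotype) &
    out$genotype == "hom"
  out$genotype[fix] <- "het"
  out
}

#' Refine a deletion breakpoint from split reads
#'
#' Each supporting read is anchored to the amplicon reference by its longest
#' common prefix and suffix; the deleted reference interval is the gap
#' between anchors. Per-read estimates are aggregated (deletion size by
#' majority, anchor lengths by maximum so sequencing errors only shorten,
#' never extend, an anchor), and the breakpoint is reported left-normalised:
#' the leftmost of all equivalent placements, with the equivalence span
#' reported as `microhomology_len`.
#'
#' @param sv_reads character vector of deletion-supporting reads, oriented to
#'   the forward strand.
#' @param amplicon_ref amplicon reference sequence.
#' @param min_reads minimum supporting reads.
#' @param max_reads reads used for the vote (deterministic head).
#' @return list with `left`, `right` (0-based; deleted interval
#'   `[left, right)` on the amplicon), `size`, `microhomology_len`,
#'   `n_split_reads`.
#' @export
refine_breakpoint <- function(sv_reads, amplicon_ref, min_reads = 3L,
                              max_reads = 6L) {
  if (length(sv_reads) < min_reads)
    stop_with("insufficient split reads: %d < %d", length(sv_reads), min_reads)
  m <- nchar(amplicon_ref)
  d_i <- m - nchar(sv_reads)
  if (stats::median(d_i) <= 0L)
    stop_with("reads are not shorter than the reference")
  d0 <- as.integer(round(stats::median(d_i)))
  use <- utils::head(sv_reads[d_i > 0L], max_reads)
  votes <- list()
  for (r in use) {
    aln <- align_read(r, amplicon_ref)
    rv <- read_variants(r, amplicon_ref, aln)
    del <- rv[rv$type == "del" &
                (nchar(rv$ref) - nchar(rv$alt)) >= max(d0 / 2, 50), ,
              drop = FALSE]
    if (nrow(del) != 1L) next
    votes[[length(votes) + 1L]] <-
      c(left = del$pos + 1L, size = nchar(del$ref) - nchar(del$alt))
  }
  if (length(votes) == 0L)
    stop_with("split-read anchors fail to place uniquely")
  vt <- do.call(rbind, votes)
  keytab <- table(paste(vt[, "left"], vt[, "size"]))
  win <- strsplit(names(keytab)[which.max(keytab)], " ")[[1]]
  left <- as.integer(win[1]); size <- as.integer(win[2])
  # equivalence span of the left-normalised breakpoint = flanking repeat
  micro <- 0L
  while (left + size + micro < m &&
         substr(amplicon_ref, left + micro + 1L, left + micro + 1L) ==
         substr(amplicon_ref, left + size + micro + 1L, left + size + micro + 1L))
    micro <- micro + 1L
  list(left = left, right = left + size, size = size,
       microhomology_len = micro, n_split_reads = length(use))
}
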