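#' Globally align a read to its amplicon reference
#'
#' Full-length amplicon CCS reads are aligned globally with affine gap
#' penalties inside a diagonal band (the band always contains the length
#' difference between read and reference, so small planted indels and
#' CCS-like indel errors are representable). Equal-length reads whose
#' ungapped identity is already high take a fast path with an all-match
#' CIGAR. Indel representation is left-normalised downstream during variant
#' extraction, so alignment tie-breaking only needs to be deterministic.
#'
#' @param read,amplicon_ref DNA strings.
#' @param band_extra band half-width beyond the length difference, bp.
#' @param min_identity alignments below this identity are flagged and
#'   excluded from pileups.
#' @param fast_path_identity ungapped identity above which an equal-length
#'   read is accepted without dynamic programming.
#' @return list with `cigar` (data.frame `op` in `M`/`I`/`D`, `len`),
#'   `nmatch`, `nmismatch`, `identity`, `flagged`.
#' @export
align_read <- function(read, amplicon_ref, band_extra = 60L,
                       min_identity = 0.7, fast_path_identity = 0.97) {
  n <- nchar(read); m <- nchar(amplicon_ref)
  if (n == m) {
    nmm <- hamming(read, amplicon_ref)
    if (1 - nmm / n >= fast_path_identity) {
      id <- 1 - nmm / n
      return(list(cigar = data.frame(op = "M", len = n),
                  nmatch = n - nmm, nmismatch = nmm, identity = id,
                  flagged = id < min_identity))
    }
  }
  # greedy anchored edit walk: linear-time for reads whose differences are
  # isolated (CCS-like); exact gap placement is restored downstream by
  # left-normalisation
  walk <- edit_walk(read, amplicon_ref)
  if (!is.null(walk) &&
      walk$nmatch / max(1L, walk$nmatch + walk$nmismatch) >= 0.9)
    return(c(walk, list(flagged = walk$identity < min_identity)))
  res <- banded_align_cpp(read, amplicon_ref,
                          band_extra = max(band_extra, 20L))
  ops <- c("M", "I", "D")[res$op + 1L]
  id <- gc_identity(res$nmatch, res$nmismatch, sum(ops != "M"))
  list(cigar = data.frame(op = ops, len = res$len),
       nmatch = res$nmatch, nmismatch = res$nmismatch,
       identity = id, flagged = id < min_identity)
}

# gap-compressed identity: a gap counts once regardless of length, the usual
# convention for long-read alignments (a single long SV gap should not sink
# the identity of an otherwise perfect read)
gc_identity <- function(nmatch, nmismatch, ngaps) {
  nmatch / max(1L, nmatch + nmismatch + ngaps)
}

# Greedy alignment for reads with isolated differences: extend exact
# matches, and at each divergence pick the edit (substitution, short indel,
# or a long deletion bridged by a unique downstream anchor) that maximises a
# short lookahead match count. Returns NULL when no edit explains a
# divergence, in which case the caller falls back to banded DP.
edit_walk <- function(read, ref, max_indel = 8L, look = 20L, anchor = 32L) {
  rr <- charToRaw(read); fr <- charToRaw(ref)
  nR <- length(rr); nF <- length(fr)
  max_jump <- max(0L, nF - nR) + 200L
  op <- integer(0); len <- integer(0)   # 0=M,1=I,2=D
  push <- function(o, l) {
    k <- length(op)
    if (k > 0L && op[k] == o) len[k] <<- len[k] + l
    else { op[k + 1L] <<- o; len[k + 1L] <<- l }
  }
  i <- 0L; j <- 0L; nmm <- 0L
  lookscore <- function(di, dj, w = look) {
    ii <- i + di; jj <- j + dj
    w <- min(w, nR - ii, nF - jj)
    if (w <= 0L) return(look)   # ran off the end: treat as clean
    sum(rr[(ii + 1L):(ii + w)] == fr[(jj + 1L):(jj + w)])
  }
  # first mismatch within the next L aligned columns, scanned in chunks so a
  # long clean stretch costs O(stretch), not O(remaining)
  first_mm <- function(L) {
    off <- 0L
    while (off < L) {
      w <- min(512L, L - off)
      d <- which(rr[(i + off + 1L):(i + off + w)] !=
                   fr[(j + off + 1L):(j + off + w)])
      if (length(d)) return(off + d[1L])
      off <- off + w
    }
    0L
  }
  while (i < nR || j < nF) {
    L <- min(nR - i, nF - j)
    if (L > 0L) {
      dm <- first_mm(L)
      k <- if (dm > 0L) dm - 1L else L
      if (k > 0L) { push(0L, k); i <- i + k; j <- j + k }
      if (dm == 0L) {
        if (i < nR) { push(1L, nR - i); i <- nR }
        if (j < nF) { push(2L, nF - j); j <- nF }
        next
      }
    } else {
      if (i < nR) { push(1L, nR - i); i <- nR }
      if (j < nF) { push(2L, nF - j); j <- nF }
      next
    }
    # divergence at the next column: a substitution explains most CCS
    # errors, so try it first and only score indel candidates when the
    # lookahead stays noisy
    w_eff <- min(look, nR - i, nF - j)
    sub_sc <- lookscore(1L, 1L)
    if (sub_sc >= w_eff - 4L) {
      push(0L, 1L); i <- i + 1L; j <- j + 1L; nmm <- nmm + 1L
      next
    }
    cand_di <- c(1L, rep(0L, max_indel), seq_len(max_indel))
    cand_dj <- c(1L, seq_len(max_indel), rep(0L, max_indel))
    pen <- c(0L, rep(2L, 2L * max_indel))
    sc <- c(sub_sc, vapply(2:length(cand_di), function(t)
      lookscore(cand_di[t], cand_dj[t]) - pen[t], 0L))
    best <- which.max(sc)
    expected_dj <- (nF - j) - (nR - i)   # remaining length difference
    jumped <- FALSE
    if (sc[best] < 0.7 * w_eff && expected_dj > max_indel &&
        nR - i >= anchor) {
      # long deletion: re-anchor the read downstream at the placement
      # consistent with the remaining length difference (paralogous repeats
      # can yield additional placements; the length constraint picks the
      # diagonal one)
      pat <- rawToChar(rr[(i + 1L):(i + anchor)])
      sub <- rawToChar(fr[(j + 1L):min(nF, j + max_jump + anchor)])
      hits <- Biostrings::matchPattern(pat, Biostrings::DNAString(sub),
                                       max.mismatch = 2)
      if (length(hits)) {
        djs <- BiocGenerics::start(hits) - 1L
        cand <- djs[which.min(abs(djs - expected_dj))]
        if (cand > max_indel && abs(cand - expected_dj) <= 64L) {
          push(2L, cand); j <- j + cand; jumped <- TRUE
        }
      }
    }
    if (!jumped && sc[best] < 0.7 * w_eff && expected_dj < -max_indel &&
        nF - j >= anchor) {
      # long insertion (tandem duplication): re-anchor the reference inside
      # the read
      max_jump_i <- -expected_dj + 200L
      pat <- rawToChar(fr[(j + 1L):(j + anchor)])
      sub <- rawToChar(rr[(i + 1L):min(nR, i + max_jump_i + anchor)])
      hits <- Biostrings::matchPattern(pat, Biostrings::DNAString(sub),
                                       max.mismatch = 2)
      if (length(hits)) {
        dis <- BiocGenerics::start(hits) - 1L
        cand <- dis[which.min(abs(dis + expected_dj))]
        if (cand > max_indel && abs(cand + expected_dj) <= 64L) {
          push(1L, cand); i <- i + cand; jumped <- TRUE
        }
      }
    }
    if (jumped) {
      # re-enter the match loop
    } else if (cand_di[best] == 1L && cand_dj[best] == 1L) {
      push(0L, 1L); i <- i + 1L; j <- j + 1L; nmm <- nmm + 1L
    } else if (cand_di[best] == 0L) {
      push(2L, cand_dj[best]); j <- j + cand_dj[best]
    } else {
      push(1L, cand_di[best]); i <- i + cand_di[best]
    }
  }
  nmatch <- sum(len[op == 0L]) - nmm
  list(cigar = data.frame(op = c("M", "I", "D")[op + 1L], len = len),
       nmatch = nmatch, nmismatch = nmm,
       identity = gc_identity(nmatch, nmm, sum(op != 0L)))
}

#' Extract variant records from a read alignment
#'
#' Walks the CIGAR and reports mismatches and indels in anchored VCF-like
#' form on 0-based amplicon coordinates. Indels are left-normalised against
#' the reference, so the representation is identical regardless of where the
#' aligner placed an equivalent gap.
#'
#' @param read,amplicon_ref DNA strings.
#' @param aln an [align_read()] result.
#' @return data.frame with `pos` (0-based; anchor base for indels), `ref`,
#'   `alt`, `type` (`SNV`/`ins`/`del`).
#' @export
read_variants <- function(read, amplicon_ref, aln, canonicalize = TRUE) {
  raw <- raw_edits_full(read, amplicon_ref, aln$cigar)
  if (nrow(raw) == 0L)
    return(data.frame(pos = integer(), ref = character(), alt = character(),
                      type = character()))
  if (canonicalize) raw <- canonicalize_edits(read, amplicon_ref, raw)
  n <- nrow(raw)
  pos <- raw$ref_pos; refs <- alts <- character(n)
  types <- ifelse(raw$type == "SNV", "SNV",
                  ifelse(raw$type == "ins", "ins", "del"))
  snv <- raw$type == "SNV"
  if (any(snv)) {
    refs[snv] <- substring(amplicon_ref, raw$ref_pos[snv] + 1L,
                           raw$ref_pos[snv] + 1L)
    alts[snv] <- substring(read, raw$read_pos[snv] + 1L,
                           raw$read_pos[snv] + 1L)
  }
  for (r in which(!snv)) {
    rec <- if (raw$type[r] == "ins")
      normalize_indel(amplicon_ref, raw$ref_pos[r],
                      substr(read, raw$read_pos[r] + 1L,
                             raw$read_pos[r] + raw$read_len[r]), "ins")
    else
      normalize_indel(amplicon_ref, raw$ref_pos[r],
                      substr(amplicon_ref, raw$ref_pos[r] + 1L,
                             raw$ref_pos[r] + raw$ref_len[r]), "del")
    pos[r] <- rec$pos; refs[r] <- rec$ref; alts[r] <- rec$alt
  }
  out <- data.frame(pos = pos, ref = refs, alt = alts, type = types,
                    stringsAsFactors = FALSE)
  out[order(out$pos), , drop = FALSE]
}

# raw, unnormalised edit sites of an alignment: one row per mismatch or gap,
# with 0-based reference and read coordinates
raw_edits_full <- function(read, ref, cigar) {
  rp <- ip <- rl <- il <- ty <- vector("list", nrow(cigar))
  i <- 0L; j <- 0L
  for (r in seq_len(nrow(cigar))) {
    op <- cigar$op[r]; len <- cigar$len[r]
    if (op == "M") {
      mp <- mismatch_positions(substr(read, i + 1L, i + len),
                               substr(ref, j + 1L, j + len))
      if (length(mp)) {
        rp[[r]] <- j + mp; ip[[r]] <- i + mp
        rl[[r]] <- rep(1L, length(mp)); il[[r]] <- rep(1L, length(mp))
        ty[[r]] <- rep("SNV", length(mp))
      }
      i <- i + len; j <- j + len
    } else if (op == "I") {
      rp[[r]] <- j; ip[[r]] <- i; rl[[r]] <- 0L; il[[r]] <- len
      ty[[r]] <- "ins"
      i <- i + len
    } else {
      rp[[r]] <- j; ip[[r]] <- i; rl[[r]] <- len; il[[r]] <- 0L
      ty[[r]] <- "del"
      j <- j + len
    }
  }
  rp <- unlist(rp)
  if (is.null(rp))
    return(data.frame(ref_pos = integer(), read_pos = integer(),
                      ref_len = integer(), read_len = integer(),
                      type = character(), stringsAsFactors = FALSE))
  out <- data.frame(ref_pos = rp, read_pos = unlist(ip),
                    ref_len = unlist(rl), read_len = unlist(il),
                    type = unlist(ty), stringsAsFactors = FALSE)
  out[order(out$ref_pos, out$read_pos), , drop = FALSE]
}

# Re-align any cluster of nearby edits with the exact banded DP so that every
# read carrying the same local haplotype yields an identical representation
# (the greedy walk can explain clustered differences ambiguously; the DP
# optimum with deterministic tie-breaking is the canonical form).
canonicalize_edits <- function(read, ref, raw, max_gap = 16L, pad = 16L) {
  if (nrow(raw) < 2L) return(raw)
  raw <- raw[order(raw$ref_pos, raw$read_pos), , drop = FALSE]
  end_ref <- raw$ref_pos + raw$ref_len
  new_grp <- raw$ref_pos[-1L] - cummax(end_ref)[-nrow(raw)] > max_gap
  if (all(new_grp)) return(raw)   # no clustered edits to re-align
  grp <- cumsum(c(1L, as.integer(new_grp)))
  multi <- as.integer(names(which(table(grp) > 1L)))
  out <- list(raw[!grp %in% multi, , drop = FALSE])
  for (g in multi) {
    ix <- which(grp == g)
    sub <- raw[ix, , drop = FALSE]
    # clusters containing an SV-scale gap keep their anchored representation
    if (any(pmax(sub$ref_len, sub$read_len) > 50L)) {
      out[[length(out) + 1L]] <- sub; next
    }
    ra <- max(0L, min(sub$ref_pos) - pad)
    rb <- min(nchar(ref), max(sub$ref_pos + sub$ref_len) + pad)
    qa <- max(0L, min(sub$read_pos) - (min(sub$ref_pos) - ra))
    qb <- min(nchar(read), max(sub$read_pos + sub$read_len) +
                (rb - max(sub$ref_pos + sub$ref_len)))
    loc <- banded_align_cpp(substr(read, qa + 1L, qb),
                            substr(ref, ra + 1L, rb), band_extra = 16L)
    cg <- data.frame(op = c("M", "I", "D")[loc$op + 1L], len = loc$len)
    re <- raw_edits_full(substr(read, qa + 1L, qb), substr(ref, ra + 1L, rb),
                         cg)
    if (nrow(re)) { re$ref_pos <- re$ref_pos + ra; re$read_pos <- re$read_pos + qa }
    out[[length(out) + 1L]] <- re
  }
  do.call(rbind, out)
}

# Left-normalise an indel whose inserted/deleted sequence `seqv` sits after
# `j` consumed reference bases, and return the anchored record.
normalize_indel <- function(ref_seq, j, seqv, type) {
  # event occupies ref [j, j+len) for del (seq = deleted bases) or is an
  # insertion before ref position j; shift left while the base preceding the
  # event equals the event's last base (classic VCF left-alignment)
  pos <- j                     # 0-based start of the deleted span / insertion point
  s <- seqv
  while (pos > 0L) {
    prev <- substr(ref_seq, pos, pos)
    last <- substr(s, nchar(s), nchar(s))
    if (prev != last) break
    s <- paste0(prev, substr(s, 1L, nchar(s) - 1L))
    pos <- pos - 1L
  }
  anchor_pos <- pos - 1L       # 0-based anchor base before the event
  anchor <- if (anchor_pos >= 0L) substr(ref_seq, anchor_pos + 1L, anchor_pos + 1L)
            else ""
  if (type == "del")
    list(pos = anchor_pos, ref = paste0(anchor, s), alt = anchor)
  else
    list(pos = anchor_pos, ref = anchor, alt = paste0(anchor, s))
}

#' Build pileup evidence for one sample x amplicon
#'
#' Aligns (deduplicated) REF-like reads to the amplicon reference and
#' aggregates variant records. Since amplicon reads are full length, depth
#' is uniform across columns and equals the number of reads that passed the
#' identity filter.
#'
#' @param reads character vector of oriented reads.
#' @param amplicon_ref amplicon reference sequence.
#' @param band_extra,min_identity see [align_read()].
#' @return list with `counts` (data.table `pos`, `ref`, `alt`, `type`,
#'   `count`), `depth` (reads used), `n_flagged`, and `read_records`
#'   (per-read variant records with read multiplicities, used for phasing).
#' @export
pileup_reads <- function(reads, amplicon_ref, band_extra = 60L,
                         min_identity = 0.7) {
  tab <- table(reads)
  uniq <- names(tab); wt <- as.integer(tab)
  per_read <- vector("list", length(uniq))
  used <- 0L; flagged <- 0L
  for (u in seq_along(uniq)) {
    aln <- align_read(uniq[u], amplicon_ref, band_extra = band_extra,
                      min_identity = min_identity)
    if (aln$flagged) { flagged <- flagged + wt[u]; next }
    used <- used + wt[u]
    rv <- read_variants(uniq[u], amplicon_ref, aln)
    if (nrow(rv)) {
      rv$uread <- u; rv$weight <- wt[u]
      per_read[[u]] <- rv
    }
  }
  recs <- data.table::rbindlist(per_read[!vapply(per_read, is.null, TRUE)])
  if (nrow(recs)) {
    counts <- recs[, list(count = sum(weight)), by = c("pos", "ref", "alt", "type")]
    counts <- cap_counts(rescue_indel_support(counts, recs, amplicon_ref),
                         used)
  } else {
    counts <- data.table::data.table(pos = integer(), ref = character(),
                                     alt = character(), type = character(),
                                     count = integer())
  }
  list(counts = counts, depth = used, n_flagged = flagged,
       read_records = recs, unique_reads = uniq, weights = wt)
}

# Local-haplotype re-genotyping of indel candidates. A sequencing error next
# to a real indel can yield an equivalent-score alignment whose records do
# not match the candidate's canonical form; such a read still supports the
# indel if the local haplotype implied by its records is closer (edit
# distance) to the alt window than to the reference window.
rescue_indel_support <- function(counts, recs, ref, w = 12L,
                                 min_count = 3L, max_span = 50L) {
  cand <- which(counts$type %in% c("ins", "del") & counts$count >= min_count &
                  pmax(nchar(counts$ref), nchar(counts$alt)) <= max_span)
  if (length(cand) == 0L) return(counts)
  reflen <- nchar(ref)
  for (ci in cand) {
    p <- counts$pos[ci]
    span <- nchar(counts$ref[ci])
    wa <- max(0L, p - w); wb <- min(reflen, p + span + w)
    refwin <- substr(ref, wa + 1L, wb)
    altwin <- apply_records_to_window(refwin, wa,
                                      counts[ci, , drop = FALSE])
    key_exact <- paste(counts$pos[ci], counts$ref[ci], counts$alt[ci])
    local <- recs[recs$pos >= wa & recs$pos < wb, ]
    if (nrow(local) == 0L) next
    rk <- paste(local$pos, local$ref, local$alt)
    have <- unique(local$uread[rk == key_exact])
    others <- setdiff(unique(local$uread), have)
    extra <- 0L
    for (u in others) {
      lr <- local[local$uread == u, ]
      readwin <- apply_records_to_window(refwin, wa, lr)
      if (utils::adist(readwin, altwin) < utils::adist(readwin, refwin))
        extra <- extra + lr$weight[1L]
    }
    counts$count[ci] <- counts$count[ci] + extra
  }
  counts
}

# guard: support can never exceed the pile depth
cap_counts <- function(counts, depth) {
  counts$count <- pmin(counts$count, depth)
  counts
}

# apply anchored variant records (columns pos/ref/alt) to a reference window
# starting at 0-based offset `off`; records are applied right to left
apply_records_to_window <- function(refwin, off, records) {
  records <- records[order(-records$pos), , drop = FALSE]
  out <- refwin
  for (r in seq_len(nrow(records))) {
    s <- records$pos[r] - off          # 0-based within window
    rl <- nchar(records$ref[r])
    if (s < 0L || s + rl > nchar(out)) next
    out <- paste0(substr(out, 1L, s), records$alt[r],
                  substr(out, s + rl + 1L, nchar(out)))
  }
  out
}

#' Call diploid SNVs and small indels from pileup evidence
#'
#' Alternate alleles with fraction at least `min_alt_frac` and support of at
#' least `min_alt_reads` are genotyped from the allele fraction: heterozygous
#' inside `het_window`, homozygous at or above `hom_min`, otherwise flagged
#' `AMBIGUOUS`. Columns where more than two alternate alleles pass threshold
#' are flagged `AMBIGUOUS`. Any alt-bearing column with depth below
#' `min_depth` is reported as a non-PASS `LOW_DEPTH` record: no PASS call is
#' ever emitted below that depth.
#'
#' @param pile a [pileup_reads()] result.
#' @param min_depth minimum read depth for a PASS call.
#' @param het_window,hom_min allele-fraction genotyping windows.
#' @param min_alt_frac,min_alt_reads alt-allele evidence floors.
#' @param max_small_indel indel records with a larger span are left to the
#'   SV caller.
#' @return data.frame with `pos` (0-based amplicon offset), `ref`, `alt`,
#'   `type`, `genotype` (`0/1` or `1/1`), `allele_fraction`, `depth`,
#'   `filter`.
#' @export
call_small_variants <- function(pile, min_depth = 20L,
                                het_window = c(0.25, 0.75), hom_min = 0.9,
                                min_alt_frac = 0.2, min_alt_reads = 5L,
                                max_small_indel = 50L) {
  counts <- pile$counts; depth <- pile$depth
  if (nrow(counts) == 0L)
    return(empty_small_calls())
  df <- as.data.frame(counts)
  # length shifts beyond the small-indel range belong to the SV caller
  df <- df[abs(nchar(df$ref) - nchar(df$alt)) <= max_small_indel, ,
           drop = FALSE]
  if (nrow(df) == 0L) return(empty_small_calls())
  df$af <- df$count / depth
  df <- df[df$af >= min_alt_frac & df$count >= min_alt_reads, , drop = FALSE]
  if (nrow(df) == 0L) return(empty_small_calls())
  out <- df
  out$genotype <- ifelse(out$af >= hom_min, "1/1",
                    ifelse(out$af >= het_window[1] & out$af <= het_window[2],
                           "0/1", NA))
  out$filter <- "PASS"
  out$filter[is.na(out$genotype)] <- "AMBIGUOUS"
  # a diploid column supports at most two alleles; flag columns where ref
  # plus passing alts exceed that
  alt_n <- stats::ave(out$af, out$pos, FUN = length)
  alt_sum <- stats::ave(out$af, out$pos, FUN = sum)
  out$filter[alt_n >= 3 | (alt_n == 2 & 1 - alt_sum >= min_alt_frac)] <-
    "AMBIGUOUS"
  out$filter[depth < min_depth] <- "LOW_DEPTH"
  data.frame(pos = out$pos, ref = out$ref, alt = out$alt, type = out$type,
             genotype = out$genotype, allele_fraction = round(out$af, 4),
             depth = depth, filter = out$filter, stringsAsFactors = FALSE)
}

empty_small_calls <- function() {
  data.frame(pos = integer(), ref = character(), alt = character(),
             type = character(), genotype = character(),
             allele_fraction = numeric(), depth = integer(),
             filter = character(), stringsAsFactors = FALSE)
}

#' Annotate calls against an allele catalog
#'
#' Matches small-variant calls by (contig, pos, ref, alt) and SV calls by
#' their matched catalog allele, attaches zygosity, and builds a composite
#' diplotype string per sample. Conflicting zygosity evidence between SV and
#' small-variant records at the same catalogued allele is flagged.
#'
#' @param small_calls small-variant calls on contig coordinates (columns
#'   `contig`, `pos`, `ref`, `alt`, `genotype`, `filter`).
#' @param sv_calls [call_svs()] output.
#' @param catalog catalog table, see [default_catalog()].
#' @return list with `annotations` (data.frame `allele`, `type`, `zygosity`,
#'   `source`, `flag`) and `diplotype` (single string, alleles sorted).
#' @export
annotate_alleles <- function(small_calls, sv_calls, catalog) {
  ann <- list()
  pass <- small_calls[small_calls$filter == "PASS", , drop = FALSE]
  smallc <- catalog[catalog$type %in% c("SNV", "indel"), , drop = FALSE]
  if (nrow(pass) && nrow(smallc)) {
    key_call <- paste(pass$contig, pass$pos, pass$ref, pass$alt)
    key_cat <- paste(smallc$contig, smallc$pos, smallc$ref, smallc$alt)
    hit <- match(key_call, key_cat)
    for (k in which(!is.na(hit)))
      ann[[length(ann) + 1L]] <- data.frame(
        allele = smallc$name[hit[k]], type = smallc$type[hit[k]],
        zygosity = if (pass$genotype[k] == "1/1") "hom" else "het",
        source = "small_variant", flag = NA_character_)
  }
  svp <- sv_calls[!is.na(sv_calls$matched_catalog_allele) &
                    sv_calls$filter == "PASS", , drop = FALSE]
  for (k in seq_len(nrow(svp)))
    ann[[length(ann) + 1L]] <- data.frame(
      allele = svp$matched_catalog_allele[k], type = svp$class[k],
      zygosity = svp$genotype[k], source = "sv", flag = NA_character_)
  if (length(ann) == 0L)
    return(list(annotations = data.frame(allele = character(),
                                         type = character(),
                                         zygosity = character(),
                                         source = character(),
                                         flag = character()),
                diplotype = ""))
  out <- do.call(rbind, ann)
  # conflicting zygosity for the same allele from different evidence
  dup <- split(seq_len(nrow(out)), out$allele)
  for (ix in dup) {
    if (length(ix) > 1L && length(unique(out$zygosity[ix])) > 1L)
      out$flag[ix] <- "zygosity_conflict"
  }
  out <- out[!duplicated(out$allele), , drop = FALSE]
  out <- out[order(out$allele), , drop = FALSE]
  dip <- paste(sprintf("%s(%s)", out$allele, out$zygosity), collapse = "/")
  list(annotations = out, diplotype = dip)
}
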