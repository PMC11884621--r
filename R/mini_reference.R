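#' Build a deterministic synthetic mini-reference with paralogous units
#'
#' Emulates the two globin-like clusters the assay targets at desk scale.
#' Contig `alphaC` carries an alpha-like cluster: two paralogous units of
#' `unit_len` bp separated by a spacer, embedded inside a long span whose
#' flanking primers only yield product when a large deletion shortens it
#' (the gap-PCR geometry used for SEA-type deletions). Contig `gammaC`
#' carries a gamma-like paralog pair with the same unit structure, and
#' contig `modC` a single-copy modifier-like gene. The two units of each
#' pair are identical except at `n_diagnostic` paralog-diagnostic positions,
#' which carry different fixed alleles and support copy assignment and
#' gene-conversion detection.
#'
#' @param seed integer seed; the same seed always yields byte-identical
#'   sequences.
#' @param unit_len paralogous unit length in bp (>= 1000).
#' @param n_diagnostic number of diagnostic positions per paralog pair
#'   (0 <= n_diagnostic < unit_len).
#' @param flank_len flank length outside each amplicon, bp.
#' @param spacer_len inter-unit spacer length, bp.
#' @return an object of class `mini_reference`: a list with `contigs`
#'   (named character), `paralog_pairs` (per cluster: unit intervals and a
#'   data.frame of diagnostic `offset`, `allele_a`, `allele_b`) and `layout`
#'   (named coordinates used by [mini_panel()]).
#' @export
build_mini_reference <- function(seed = 1L, unit_len = 4000L,
                                 n_diagnostic = 40L, flank_len = 300L,
                                 spacer_len = 800L) {
  if (unit_len < 1000) stop_with("unit_len must be >= 1000")
  if (n_diagnostic < 0 || n_diagnostic >= unit_len)
    stop_with("n_diagnostic must satisfy 0 <= n_diagnostic < unit_len")
  with_seed(seed, {
    margin <- 300L
    amp_len <- 2L * margin + 2L * unit_len + spacer_len
    sea_len <- 20000L
    sea_pad <- 200L

    make_cluster <- function(total_len, unit1_at) {
      seqv <- sample(DNA_BASES, total_len, replace = TRUE)
      # offsets are 0-based within the unit
      offs <- sort(sample(seq.int(50L, unit_len - 50L), n_diagnostic))
      a_all <- seqv[unit1_at + offs + 1L]        # unit 1 alleles
      b_all <- vapply(a_all, function(b) sample(setdiff(DNA_BASES, b), 1), "")
      unit2_at <- unit1_at + unit_len + spacer_len
      # unit 2 = copy of unit 1 with the diagnostic alleles switched
      seqv[(unit2_at + 1L):(unit2_at + unit_len)] <-
        seqv[(unit1_at + 1L):(unit1_at + unit_len)]
      seqv[unit2_at + offs + 1L] <- b_all
      list(seq = paste(seqv, collapse = ""),
           unit_a = c(unit1_at, unit1_at + unit_len),
           unit_b = c(unit2_at, unit2_at + unit_len),
           diagnostic = data.frame(offset = offs, allele_a = a_all,
                                   allele_b = b_all, row.names = NULL))
    }

    # alphaC: pad | sea span (20 kb) | pad; alpha amplicon inside the span
    alpha_amp_start <- sea_pad + 3000L
    alpha <- make_cluster(sea_pad + sea_len + sea_pad,
                          unit1_at = alpha_amp_start + margin)
    # gammaC: flank | amplicon | flank
    gamma <- make_cluster(2L * flank_len + amp_len,
                          unit1_at = flank_len + margin)
    modc <- random_dna(2L * flank_len + 3000L)

    layout <- list(
      margin = margin, unit_len = unit_len, spacer_len = spacer_len,
      flank_len = flank_len, amp_len = amp_len,
      sea_start = sea_pad, sea_end = sea_pad + sea_len,
      alpha_start = alpha_amp_start, alpha_end = alpha_amp_start + amp_len,
      gamma_start = flank_len, gamma_end = flank_len + amp_len,
      mod_start = flank_len, mod_end = flank_len + 3000L)

    structure(list(
      contigs = c(alphaC = alpha$seq, gammaC = gamma$seq, modC = modc),
      paralog_pairs = list(
        alphaC = list(contig = "alphaC", unit_a = alpha$unit_a,
                      unit_b = alpha$unit_b, diagnostic = alpha$diagnostic),
        gammaC = list(contig = "gammaC", unit_a = gamma$unit_a,
                      unit_b = gamma$unit_b, diagnostic = gamma$diagnostic)),
      layout = layout, seed = as.integer(seed)),
      class = "mini_reference")
  })
}

primer_from_ref <- function(seqs, contig, start, end, id, plen = 24L) {
  fwd <- substr(seqs[[contig]], start + 1L, start + plen)
  rev <- revcomp(substr(seqs[[contig]], end - plen + 1L, end))
  primer_pair(id, fwd, rev)
}

#' Build the default desk-scale panel over a mini-reference
#'
#' Four amplicons: `alpha_frag` and `gamma_frag` span their paralog pairs,
#' `mod_frag` a modifier-like gene, and `sea_span` a 20-kb interval whose
#' wild-type product exceeds `max_product_len` and therefore only amplifies
#' when a catalogued large deletion (SEA-like) shortens it.
#'
#' @param mini a [build_mini_reference()] result.
#' @param max_product_len see [panel()].
#' @return a [panel()] whose `sv_catalog` covers the structural alleles of
#'   [default_catalog()].
#' @export
mini_panel <- function(mini, max_product_len = 15000L) {
  L <- mini$layout
  seqs <- mini$contigs
  gene_df <- function(p) data.frame(
    id = c(paste0(p$contig, "_u1"), paste0(p$contig, "_u2")),
    start = c(p$unit_a[1], p$unit_b[1]), end = c(p$unit_a[2], p$unit_b[2]))
  amps <- list(
    amplicon("alpha_frag",
             primer_from_ref(seqs, "alphaC", L$alpha_start, L$alpha_end, "alpha_frag"),
             "alphaC", L$alpha_start, L$alpha_end,
             gene_df(mini$paralog_pairs$alphaC)),
    amplicon("gamma_frag",
             primer_from_ref(seqs, "gammaC", L$gamma_start, L$gamma_end, "gamma_frag"),
             "gammaC", L$gamma_start, L$gamma_end,
             gene_df(mini$paralog_pairs$gammaC)),
    amplicon("mod_frag",
             primer_from_ref(seqs, "modC", L$mod_start, L$mod_end, "mod_frag"),
             "modC", L$mod_start, L$mod_end,
             data.frame(id = "modG", start = L$mod_start + 200L,
                        end = L$mod_end - 200L)),
    amplicon("sea_span",
             primer_from_ref(seqs, "alphaC", L$sea_start, L$sea_end, "sea_span"),
             "alphaC", L$sea_start, L$sea_end))
  cat <- default_catalog(mini)
  sv <- cat[cat$type %in% c("deletion", "duplication"), ]
  sv_catalog <- data.frame(allele = sv$name, amplicon_id = sv$amplicon_id,
                           length_shift = sv$length_shift, class = sv$type,
                           linked_amplicon = sv$linked_amplicon,
                           stringsAsFactors = FALSE)
  panel(amps, seqs, sv_catalog, max_product_len = max_product_len)
}

#' Default 23-entry allele catalog for the mini-reference
#'
#' Emulates a routine-PCR-style thalassemia catalog: 14 SNVs, 4 small indels,
#' 4 large deletions (a 4.9-kb gamma-cluster deletion, alpha-unit deletions of
#' 3.7 and 4.2 kb, and a 19-kb SEA-like deletion detected through the
#' deletion-spanning `sea_span` product) and 1 tandem duplication. Reference
#' and alternate alleles are derived from the mini-reference sequence, so the
#' catalog is deterministic for a given seed.
#'
#' @param mini a [build_mini_reference()] result.
#' @return data.frame with one row per catalogued allele: `name`, `type`,
#'   `contig`, `pos`/`ref`/`alt` for small alleles (0-based), event interval
#'   `event_start`/`event_end`, `amplicon_id`, `length_shift`,
#'   `linked_amplicon`.
#' @export
default_catalog <- function(mini) {
  L <- mini$layout
  seqs <- mini$contigs
  base_at <- function(contig, pos) substr(seqs[[contig]], pos + 1L, pos + 1L)
  alt_for <- function(b) DNA_BASES[(match(b, DNA_BASES)) %% 4L + 1L]

  au1 <- mini$paralog_pairs$alphaC$unit_a[1]
  au2 <- mini$paralog_pairs$alphaC$unit_b[1]
  gu1 <- mini$paralog_pairs$gammaC$unit_a[1]
  gu2 <- mini$paralog_pairs$gammaC$unit_b[1]
  diag_g <- mini$paralog_pairs$gammaC$diagnostic$offset
  diag_a <- mini$paralog_pairs$alphaC$diagnostic$offset

  # SNV positions: modifier gene, gamma promoters-like offsets, alpha units.
  # Offsets are nudged off the paralog-diagnostic sites so catalogued SNVs and
  # conversion evidence never coincide.
  off_ok <- function(base, o, diag) {
    while (o %in% diag) o <- o + 1L
    base + o
  }
  snv_pos <- c(
    mod_snv1 = L$mod_start + 500L, mod_snv2 = L$mod_start + 800L,
    mod_snv3 = L$mod_start + 1200L, mod_snv4 = L$mod_start + 1600L,
    mod_snv5 = L$mod_start + 2000L, mod_snv6 = L$mod_start + 2400L,
    gamma_m158 = off_ok(gu1, 90L, diag_g), gamma_m29 = off_ok(gu2, 120L, diag_g),
    gamma_snv3 = off_ok(gu1, 2210L, diag_g), gamma_snv4 = off_ok(gu2, 3105L, diag_g),
    gamma_snv5 = L$gamma_start + L$margin + L$unit_len + 400L,  # spacer
    alpha_c369 = off_ok(au1, 1500L, diag_a), alpha_c84 = off_ok(au2, 333L, diag_a),
    alpha_snv3 = off_ok(au1, 2750L, diag_a))
  snv_contig <- c(rep("modC", 6), rep("gammaC", 5), rep("alphaC", 3))
  snv_amp <- c(rep("mod_frag", 6), rep("gamma_frag", 5), rep("alpha_frag", 3))

  snvs <- data.frame(
    name = names(snv_pos), type = "SNV", contig = snv_contig,
    pos = as.integer(snv_pos),
    ref = vapply(seq_along(snv_pos), function(i)
      base_at(snv_contig[i], snv_pos[i]), ""),
    amplicon_id = snv_amp, stringsAsFactors = FALSE)
  snvs$alt <- vapply(snvs$ref, alt_for, "")
  snvs$event_start <- snvs$pos; snvs$event_end <- snvs$pos + 1L
  snvs$length_shift <- 0L; snvs$linked_amplicon <- NA_character_

  # small indels: a 4-bp and a 2-bp deletion, two 1-bp insertions; stored in
  # left-normalised anchored form so catalog lookups match caller output
  indel <- function(name, contig, pos, del_len, ins_seq, amp) {
    if (del_len > 0) {
      rec <- normalize_indel(seqs[[contig]], pos + 1L,
                             substr(seqs[[contig]], pos + 2L, pos + 1L + del_len),
                             "del")
      data.frame(name = name, type = "indel", contig = contig, pos = rec$pos,
                 ref = rec$ref, alt = rec$alt, amplicon_id = amp,
                 event_start = rec$pos + 1L, event_end = rec$pos + 1L + del_len,
                 length_shift = 0L, linked_amplicon = NA_character_)
    } else {
      rec <- normalize_indel(seqs[[contig]], pos + 1L, ins_seq, "ins")
      data.frame(name = name, type = "indel", contig = contig, pos = rec$pos,
                 ref = rec$ref, alt = rec$alt, amplicon_id = amp,
                 event_start = rec$pos + 1L, event_end = rec$pos + 1L,
                 length_shift = 0L, linked_amplicon = NA_character_)
    }
  }
  indels <- rbind(
    indel("mod_del4", "modC", L$mod_start + 900L, 4L, "", "mod_frag"),
    indel("mod_ins1", "modC", L$mod_start + 2200L, 0L, "T", "mod_frag"),
    indel("gamma_ins1", "gammaC", off_ok(gu1, 1710L, diag_g), 0L, "G", "gamma_frag"),
    indel("alpha_del2", "alphaC", off_ok(au2, 2020L, diag_a), 2L, "", "alpha_frag"))

  # large SVs
  sv <- function(name, type, contig, start, size, amp, linked = NA_character_) {
    data.frame(name = name, type = type, contig = contig, pos = NA_integer_,
               ref = NA_character_, alt = NA_character_, amplicon_id = amp,
               event_start = start, event_end = start + size,
               length_shift = if (type == "deletion") -size else size,
               linked_amplicon = linked)
  }
  svs <- rbind(
    sv("gamma_del4.9k", "deletion", "gammaC", gu1 + 1500L, 4900L, "gamma_frag"),
    sv("alpha_del3.7k", "deletion", "alphaC", au1 + 2000L, 3700L, "alpha_frag"),
    sv("alpha_del4.2k", "deletion", "alphaC", au1 - 100L, 4200L, "alpha_frag"),
    sv("sea_del19k", "deletion", "alphaC", L$sea_start + 800L, 19000L,
       "sea_span", linked = "alpha_frag"),
    sv("alpha_dup3.7k", "duplication", "alphaC", au1 + 2000L, 3700L,
       "alpha_frag"))

  out <- rbind(snvs[, names(svs)], indels[, names(svs)], svs)
  rownames(out) <- NULL
  out
}
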