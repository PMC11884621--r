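vcf_header <- function(samples, extra = character()) {
  c("##fileformat=VCFv4.3", "##source=globintyper", extra,
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##FORMAT=<ID=AF,Number=1,Type=Float,Description=\"Allele fraction\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
}

#' Write small-variant calls of a genotyped cohort as VCF 4.3
#'
#' Multi-sample VCF on 1-based coordinates. Phased amplicons emit `|`
#' genotypes with a `PS` tag equal to the amplicon id; unphased ones use
#' `/`.
#'
#' @param geno [run_genotyping()] results.
#' @param path output path.
#' @export
write_small_vcf <- function(geno, path) {
  samples <- names(geno)
  recs <- list()
  for (s in samples) {
    sc <- geno[[s]]$small_calls
    if (nrow(sc) == 0L) next
    sc$sample <- s
    # phased genotype when the amplicon phased
    sc$gt <- sc$genotype
    sc$ps <- NA_character_
    for (aid in unique(sc$amplicon_id)) {
      ph <- geno[[s]]$phase[[aid]]
      if (is.null(ph) || !isTRUE(ph$phased) || is.null(ph$haplotypes)) next
      ix <- which(sc$amplicon_id == aid & sc$filter == "PASS")
      if (length(ix) == 0L || nrow(ph$loci) == 0L) next
      m <- match(paste(sc$pos[ix], sc$ref[ix], sc$alt[ix]),
                 paste(ph$loci$pos, ph$loci$ref, ph$loci$alt))
      ok <- !is.na(m)
      sc$gt[ix[ok]] <- sprintf("%d|%d", ph$haplotypes[1, m[ok]],
                               ph$haplotypes[2, m[ok]])
      sc$ps[ix[ok]] <- aid
    }
    recs[[s]] <- sc
  }
  hdr <- vcf_header(samples,
    "##FORMAT=<ID=PS,Number=1,Type=String,Description=\"Phase set (amplicon)\">")
  if (length(recs) == 0L) { writeLines(hdr, path); return(invisible(path)) }
  all <- do.call(rbind, recs)
  all$key <- paste(all$contig, all$pos, all$ref, all$alt, sep = "|")
  uk <- unique(all[, c("contig", "pos", "ref", "alt", "key", "filter")])
  uk <- uk[!duplicated(uk$key), ]
  uk <- uk[order(uk$contig, uk$pos), ]
  lines <- vapply(seq_len(nrow(uk)), function(r) {
    rr <- uk[r, ]
    cols <- vapply(samples, function(s) {
      hit <- all[all$sample == s & all$key == rr$key, ]
      if (nrow(hit) == 0L) return("0/0:.:.:.")
      sprintf("%s:%d:%.3f:%s", hit$gt[1], hit$depth[1],
              hit$allele_fraction[1],
              ifelse(is.na(hit$ps[1]), ".", hit$ps[1]))
    }, "")
    paste(c(rr$contig, rr$pos + 1L, ".", rr$ref, rr$alt, ".", rr$filter, ".",
            "GT:DP:AF:PS", cols), collapse = "\t")
  }, "")
  writeLines(c(hdr, lines), path)
  invisible(path)
}

#' Write structural-variant calls as symbolic-allele VCF
#'
#' Deletions and duplications are emitted as `<DEL>`/`<DUP>` records with
#' `END` and `SVLEN`, using refined breakpoints where available and the
#' amplicon interval otherwise.
#'
#' @param geno [run_genotyping()] results.
#' @param pnl the panel.
#' @param path output path.
#' @export
write_sv_vcf <- function(geno, pnl, path) {
  samples <- names(geno)
  hdr <- c("##fileformat=VCFv4.3", "##source=globintyper",
    "##ALT=<ID=DEL,Description=\"Deletion\">",
    "##ALT=<ID=DUP,Description=\"Duplication\">",
    "##INFO=<ID=END,Number=1,Type=Integer,Description=\"End position\">",
    "##INFO=<ID=SVLEN,Number=1,Type=Integer,Description=\"SV length\">",
    "##INFO=<ID=ALLELE,Number=1,Type=String,Description=\"Catalog allele\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
  recs <- list()
  for (s in samples) {
    sv <- geno[[s]]$sv_calls
    sv <- sv[!is.na(sv$length_shift) & sv$filter == "PASS", , drop = FALSE]
    for (k in seq_len(nrow(sv))) {
      a <- pnl$amplicons[[sv$amplicon_id[k]]]
      left <- if (!is.na(sv$bp_left[k])) sv$bp_left[k] else a$start
      right <- if (!is.na(sv$bp_right[k])) sv$bp_right[k] else
        left + abs(sv$length_shift[k])
      recs[[length(recs) + 1L]] <- data.frame(
        sample = s, contig = a$contig, pos = left, end = right,
        svlen = sv$length_shift[k],
        type = if (sv$length_shift[k] < 0) "DEL" else "DUP",
        allele = sv$matched_catalog_allele[k],
        gt = if (!is.na(sv$genotype[k]) && sv$genotype[k] == "hom") "1/1"
             else "0/1")
    }
  }
  if (length(recs) == 0L) { writeLines(hdr, path); return(invisible(path)) }
  all <- do.call(rbind, recs)
  all$key <- paste(all$contig, all$pos, all$type, all$svlen)
  uk <- all[!duplicated(all$key), ]
  lines <- vapply(seq_len(nrow(uk)), function(r) {
    rr <- uk[r, ]
    cols <- vapply(samples, function(s) {
      hit <- all[all$sample == s & all$key == rr$key, ]
      if (nrow(hit) == 0L) "0/0" else hit$gt[1]
    }, "")
    info <- sprintf("END=%d;SVLEN=%d%s", rr$end, rr$svlen,
                    if (is.na(rr$allele)) "" else paste0(";ALLELE=", rr$allele))
    paste(c(rr$contig, rr$pos + 1L, ".", "N", paste0("<", rr$type, ">"), ".",
            "PASS", info, "GT", cols), collapse = "\t")
  }, "")
  writeLines(c(hdr, lines), path)
  invisible(path)
}

#' Write per-amplicon haplotype allele strings as TSV
#' @param geno [run_genotyping()] results.
#' @param path output path.
#' @export
write_haplotype_tsv <- function(geno, path) {
  rows <- list()
  for (s in names(geno)) {
    for (aid in names(geno[[s]]$phase)) {
      ph <- geno[[s]]$phase[[aid]]
      if (!isTRUE(ph$phased) || is.null(ph$haplotypes)) next
      for (h in 1:2)
        rows[[length(rows) + 1L]] <- data.frame(
          sample_id = s, amplicon_id = aid, haplotype = h,
          alleles = paste(ph$haplotypes[h, ], collapse = ""),
          supporting_reads = ph$supporting_reads[h])
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(sample_id = character(), amplicon_id = character(),
               haplotype = integer(), alleles = character(),
               supporting_reads = integer())
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
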