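#' Construct a primer pair
#'
#' A long-range PCR primer pair. `fwd` is given 5'->3' on the forward strand;
#' `rev` is given 5'->3' on the reverse strand, so a forward-strand product
#' starts with `fwd` and ends with `revcomp(rev)`.
#'
#' @param name primer pair name.
#' @param fwd,rev primer sequences over A/C/G/T, length >= 18 each.
#' @param max_mismatch maximum substitutions tolerated when matching a primer
#'   inside a read-end window (no indels are allowed inside the primer window).
#' @return an object of class `primer_pair`.
#' @export
primer_pair <- function(name, fwd, rev, max_mismatch = 2L) {
  for (s in c(fwd, rev)) {
    if (!nzchar(s) || grepl("[^ACGT]", s))
      stop_with("primer '%s': sequences must be non-empty over A/C/G/T", name)
    if (nchar(s) < 18) stop_with("primer '%s': length must be >= 18", name)
  }
  if (max_mismatch < 0) stop_with("primer '%s': max_mismatch must be >= 0", name)
  structure(list(name = name, fwd = fwd, rev = rev,
                 max_mismatch = as.integer(max_mismatch)),
            class = "primer_pair")
}

#' Construct an amplicon
#'
#' @param id amplicon id, unique within a panel.
#' @param primers a [primer_pair()].
#' @param contig reference contig name.
#' @param start,end 0-based half-open reference interval of the product.
#' @param genes optional data.frame of annotated gene/unit intervals with
#'   columns `id`, `start`, `end` (0-based half-open, nested in the amplicon).
#' @return an object of class `amplicon` with `expected_length = end - start`.
#' @export
amplicon <- function(id, primers, contig, start, end, genes = NULL) {
  if (end <= start) stop_with("amplicon '%s': end must be > start", id)
  if (is.null(genes))
    genes <- data.frame(id = character(), start = integer(), end = integer())
  bad <- genes$start < start | genes$end > end | genes$end <= genes$start
  if (any(bad))
    stop_with("amplicon '%s': gene intervals must nest within [start,end)", id)
  structure(list(id = id, primers = primers, contig = contig,
                 start = as.integer(start), end = as.integer(end),
                 expected_length = as.integer(end - start), genes = genes),
            class = "amplicon")
}

#' Construct a panel
#'
#' @param amplicons list of [amplicon()] objects.
#' @param reference named character vector of reference contig sequences, or a
#'   FASTA path.
#' @param sv_catalog data.frame describing catalogued structural alleles:
#'   columns `allele`, `amplicon_id`, `length_shift` (observed - expected bp),
#'   `class` (`deletion`, `duplication` or `crossover`) and optional
#'   `linked_amplicon` (an amplicon whose dropout pattern disambiguates
#'   hom/het for deletion-spanning products, gap-PCR style).
#' @param max_product_len longest product the long-range PCR is modelled to
#'   amplify; amplicons with a larger expected length only yield product when
#'   an internal deletion shortens them.
#' @return an object of class `panel`.
#' @export
panel <- function(amplicons, reference, sv_catalog = NULL,
                  max_product_len = 15000L) {
  if (is.character(reference) && length(reference) == 1 && file.exists(reference))
    reference <- read_fasta(reference)
  ids <- vapply(amplicons, `[[`, "", "id")
  if (anyDuplicated(ids)) stop_with("amplicon ids must be unique")
  names(amplicons) <- ids
  keys <- vapply(amplicons, function(a) paste(a$primers$fwd, a$primers$rev), "")
  if (anyDuplicated(keys))
    stop_with("no two amplicons may share both primer sequences")
  miss <- setdiff(vapply(amplicons, `[[`, "", "contig"), names(reference))
  if (length(miss)) stop_with("contigs missing from reference: %s",
                              paste(miss, collapse = ", "))
  if (is.null(sv_catalog))
    sv_catalog <- data.frame(allele = character(), amplicon_id = character(),
                             length_shift = integer(), class = character(),
                             linked_amplicon = character())
  bad <- setdiff(sv_catalog$amplicon_id, ids)
  if (length(bad)) stop_with("sv_catalog references unknown amplicons: %s",
                             paste(bad, collapse = ", "))
  structure(list(amplicons = amplicons, reference = reference,
                 sv_catalog = sv_catalog,
                 max_product_len = as.integer(max_product_len)),
            class = "panel")
}

#' @export
print.panel <- function(x, ...) {
  cat(sprintf("<panel> %d amplicons over %d contigs, %d catalogued SV alleles\n",
              length(x$amplicons), length(x$reference), nrow(x$sv_catalog)))
  for (a in x$amplicons)
    cat(sprintf("  %-12s %s:%d-%d (%d bp)\n", a$id, a$contig, a$start, a$end,
                a$expected_length))
  invisible(x)
}

#' Load an amplicon panel from a TSV definition and FASTA reference
#'
#' The TSV must carry columns `amplicon_id`, `contig`, `start`, `end`
#' (0-based half-open), `fwd`, `rev` and `genes` (semicolon-separated
#' `id:start-end` entries, or empty). Validation errors are aggregated and
#' reported together, naming the offending rows.
#'
#' @param panel_tsv path to the panel TSV.
#' @param reference path to the reference FASTA.
#' @param max_product_len see [panel()].
#' @return a [panel()].
#' @export
load_panel <- function(panel_tsv, reference, max_product_len = 15000L) {
  tab <- utils::read.delim(panel_tsv, stringsAsFactors = FALSE)
  need <- c("amplicon_id", "contig", "start", "end", "fwd", "rev", "genes")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop_with("panel TSV lacks columns: %s",
                              paste(miss, collapse = ", "))
  ref <- read_fasta(reference)
  errs <- character(); amps <- list()
  for (i in seq_len(nrow(tab))) {
    row <- tab[i, ]
    ok <- TRUE
    if (!row$contig %in% names(ref)) {
      errs <- c(errs, sprintf("row %d (%s): contig '%s' missing from FASTA",
                              i, row$amplicon_id, row$contig)); ok <- FALSE
    }
    if (is.na(row$start) || is.na(row$end) || row$end <= row$start) {
      errs <- c(errs, sprintf("row %d (%s): end must be > start",
                              i, row$amplicon_id)); ok <- FALSE
    }
    genes <- parse_gene_spec(row$genes)
    if (ok) {
      a <- tryCatch(
        amplicon(row$amplicon_id,
                 primer_pair(row$amplicon_id, row$fwd, row$rev),
                 row$contig, row$start, row$end, genes),
        error = function(e) {
          errs <<- c(errs, sprintf("row %d: %s", i, conditionMessage(e)))
          NULL
        })
      if (!is.null(a)) amps[[length(amps) + 1]] <- a
    }
  }
  if (length(errs)) stop_with("panel load failed:\n  %s",
                              paste(errs, collapse = "\n  "))
  panel(amps, ref, max_product_len = max_product_len)
}

parse_gene_spec <- function(spec) {
  if (is.na(spec) || !nzchar(spec))
    return(data.frame(id = character(), start = integer(), end = integer()))
  parts <- strsplit(spec, ";", fixed = TRUE)[[1]]
  m <- regmatches(parts, regexec("^([^:]+):([0-9]+)-([0-9]+)$", parts))
  bad <- vapply(m, length, 0L) != 4L
  if (any(bad)) stop_with("malformed gene spec: %s", spec)
  data.frame(id = vapply(m, `[[`, "", 2),
             start = as.integer(vapply(m, `[[`, "", 3)),
             end = as.integer(vapply(m, `[[`, "", 4)))
}

#' Export amplicon intervals as BED
#' @param pnl a [panel()].
#' @param path output BED path.
#' @export
export_bed <- function(pnl, path) {
  rows <- vapply(pnl$amplicons, function(a)
    sprintf("%s\t%d\t%d\t%s", a$contig, a$start, a$end, a$id), "")
  writeLines(rows, path)
  invisible(path)
}

#' Write a panel definition TSV
#' @param pnl a [panel()].
#' @param path output TSV path.
#' @export
write_panel_tsv <- function(pnl, path) {
  rows <- lapply(pnl$amplicons, function(a) {
    genes <- if (nrow(a$genes)) paste(sprintf("%s:%d-%d", a$genes$id,
                                              a$genes$start, a$genes$end),
                                      collapse = ";") else ""
    data.frame(amplicon_id = a$id, contig = a$contig, start = a$start,
               end = a$end, fwd = a$primers$fwd, rev = a$primers$rev,
               genes = genes)
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
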