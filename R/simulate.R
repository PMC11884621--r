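#' Construct an allele event
#'
#' An event is a replacement of the reference interval `[start, end)` on one
#' haplotype. SNVs and insertions/deletions carry an explicit `alt_seq`;
#' duplications repeat the interval in tandem; conversions and crossovers copy
#' a same-length donor interval from the same contig.
#'
#' @param kind one of `SNV`, `small_indel`, `large_deletion`, `duplication`,
#'   `crossover`, `conversion`.
#' @param contig contig name.
#' @param start,end 0-based half-open target interval (insertions have
#'   `start == end`).
#' @param alt_seq replacement sequence for SNV/indel events.
#' @param donor_start donor interval start for conversion/crossover (same
#'   length as the target interval).
#' @param name allele name for truth bookkeeping.
#' @return an object of class `allele_event`.
#' @export
allele_event <- function(kind, contig, start, end, alt_seq = "",
                         donor_start = NA_integer_, name = "") {
  kinds <- c("SNV", "small_indel", "large_deletion", "duplication",
             "crossover", "conversion")
  if (!kind %in% kinds) stop_with("unknown event kind '%s'", kind)
  if (kind == "SNV" && (end != start + 1L || nchar(alt_seq) != 1L))
    stop_with("SNV must have end = start + 1 and a single-base alt")
  if (kind %in% c("large_deletion", "duplication", "crossover", "conversion") &&
      end <= start)
    stop_with("span event '%s' must have start < end", name)
  structure(list(kind = kind, contig = contig, start = as.integer(start),
                 end = as.integer(end), alt_seq = alt_seq,
                 donor_start = as.integer(donor_start), name = name),
            class = "allele_event")
}

event_replacement <- function(ev, ref_seq) {
  switch(ev$kind,
    SNV = ev$alt_seq,
    small_indel = ev$alt_seq,
    large_deletion = "",
    duplication = strrep(substr(ref_seq, ev$start + 1L, ev$end), 2L),
    crossover = ,
    conversion = substr(ref_seq, ev$donor_start + 1L,
                        ev$donor_start + (ev$end - ev$start)))
}

#' Apply events to a reference haplotype
#'
#' @param ref_seq reference contig sequence (character scalar).
#' @param events list of [allele_event()]s on this contig, non-overlapping.
#' @return list with `seq` (mutated haplotype) and `map`, a data.frame of
#'   segments (`ref_start`, `ref_end`, `shift`, `deleted`) mapping reference
#'   to mutated coordinates; see [map_coord()].
#' @export
apply_events <- function(ref_seq, events) {
  if (length(events) == 0)
    return(list(seq = ref_seq,
                map = data.frame(ref_start = 0L, ref_end = nchar(ref_seq),
                                 shift = 0L, deleted = FALSE)))
  ord <- order(vapply(events, `[[`, 0L, "start"))
  events <- events[ord]
  s <- vapply(events, `[[`, 0L, "start"); e <- vapply(events, `[[`, 0L, "end")
  if (any(s[-1] < e[-length(e)]))
    stop_with("overlapping events on one haplotype: %s",
              paste(vapply(events, `[[`, "", "name"), collapse = ", "))
  n <- nchar(ref_seq)
  pieces <- character(0); map <- NULL
  cur <- 0L; shift <- 0L
  for (i in seq_along(events)) {
    ev <- events[[i]]
    if (ev$start > cur) {
      pieces <- c(pieces, substr(ref_seq, cur + 1L, ev$start))
      map <- rbind(map, data.frame(ref_start = cur, ref_end = ev$start,
                                   shift = shift, deleted = FALSE))
    }
    repl <- event_replacement(ev, ref_seq)
    pieces <- c(pieces, repl)
    span <- ev$end - ev$start
    if (span > 0L)
      map <- rbind(map, data.frame(ref_start = ev$start, ref_end = ev$end,
                                   shift = shift,
                                   deleted = nchar(repl) == 0L))
    shift <- shift + nchar(repl) - span
    cur <- ev$end
  }
  if (cur < n) {
    pieces <- c(pieces, substr(ref_seq, cur + 1L, n))
    map <- rbind(map, data.frame(ref_start = cur, ref_end = n,
                                 shift = shift, deleted = FALSE))
  }
  list(seq = paste(pieces, collapse = ""), map = map)
}

#' Map a reference coordinate through an event map
#' @param map the `map` component of [apply_events()].
#' @param pos 0-based reference positions.
#' @return 0-based positions on the mutated haplotype, `NA` where deleted.
#' @export
map_coord <- function(map, pos) {
  vapply(pos, function(p) {
    i <- which(map$ref_start <= p & p < map$ref_end)
    if (length(i) == 0L || map$deleted[i[1]]) return(NA_integer_)
    as.integer(p + map$shift[i[1]])
  }, 0L)
}

#' In-silico PCR of a haplotype over a panel
#'
#' Scans the haplotype for each amplicon's forward primer and the reverse
#' complement of its reverse primer (each within `max_mismatch`
#' substitutions), and emits one product per amplicon where both sites occur
#' in the correct orientation within `max_product_len`. Internal deletions
#' shorten the product; loss of a primer site drops the amplicon (a valid
#' outcome recorded by the caller's truth set).
#'
#' @param hap_seqs named character vector of haplotype contig sequences.
#' @param pnl a [panel()].
#' @return data.frame with `amplicon_id`, `seq`, `length`.
#' @export
in_silico_pcr <- function(hap_seqs, pnl) {
  out <- list()
  subj_cache <- list()
  for (a in pnl$amplicons) {
    if (!a$contig %in% names(hap_seqs)) next
    subject <- hap_seqs[[a$contig]]
    if (is.null(subject) || is.na(subject)) next
    if (is.null(subj_cache[[a$contig]]))
      subj_cache[[a$contig]] <- Biostrings::DNAString(subject)
    subj <- subj_cache[[a$contig]]
    mm <- a$primers$max_mismatch
    f <- Biostrings::matchPattern(a$primers$fwd, subj, max.mismatch = mm)
    r <- Biostrings::matchPattern(revcomp(a$primers$rev), subj,
                                  max.mismatch = mm)
    if (length(f) == 0L || length(r) == 0L) next
    fs <- BiocGenerics::start(f); re <- BiocGenerics::end(r)
    # all orientation-consistent site pairs within the size limit; PCR
    # favours the shortest product
    cand <- expand.grid(fs = fs, re = re)
    cand <- cand[cand$re > cand$fs &
                   (cand$re - cand$fs + 1L) <= pnl$max_product_len, ]
    if (nrow(cand) == 0L) next
    len <- cand$re - cand$fs + 1L
    i <- which.min(len)
    out[[length(out) + 1L]] <- data.frame(
      amplicon_id = a$id,
      seq = substr(subject, cand$fs[i], cand$re[i]),
      length = len[i], stringsAsFactors = FALSE)
  }
  if (length(out) == 0L)
    return(data.frame(amplicon_id = character(), seq = character(),
                      length = integer()))
  do.call(rbind, out)
}

#' Simulate CCS reads from PCR products
#'
#' Reads are full-length copies of their product (amplicon sequencing) with
#' independent per-base substitution and 1-bp insertion/deletion errors at
#' CCS-like rates. Half the reads are emitted reverse-complemented. Base
#' qualities encode the total error rate.
#'
#' @param products data.frame from [in_silico_pcr()], optionally with extra
#'   grouping columns which are propagated to reads.
#' @param depth target reads per product.
#' @param sub_rate,ins_rate,del_rate per-base error probabilities in
#'   `[0, 0.05]`.
#' @param seed integer seed; same seed gives byte-identical reads.
#' @param depth_model `"fixed"` or `"poisson"`.
#' @param read_prefix prefix for read ids.
#' @return data.frame with `read_id`, `amplicon_id`, `seq`, `qual` (Phred),
#'   plus any extra product columns.
#' @export
simulate_ccs_reads <- function(products, depth = 50L, sub_rate = 0.003,
                               ins_rate = 0.001, del_rate = 0.001, seed = 1L,
                               depth_model = c("fixed", "poisson"),
                               read_prefix = "read") {
  depth_model <- match.arg(depth_model)
  stopifnot(depth >= 1)
  for (r in c(sub_rate, ins_rate, del_rate))
    if (r < 0 || r > 0.05) stop_with("error rates must lie in [0, 0.05]")
  if (nrow(products) == 0L) {
    warning("no products to sequence; emitting an empty read set")
    return(data.frame(read_id = character(), amplicon_id = character(),
                      seq = character(), qual = integer()))
  }
  tot <- sub_rate + ins_rate + del_rate
  q <- as.integer(min(40L, round(-10 * log10(max(tot, 1e-4)))))
  with_seed(seed, {
    rows <- vector("list", nrow(products))
    ctr <- 0L
    for (i in seq_len(nrow(products))) {
      nr <- if (depth_model == "fixed") depth else max(1L, stats::rpois(1, depth))
      tmpl <- products$seq[i]
      reads <- character(nr)
      for (k in seq_len(nr)) {
        reads[k] <- mutate_read(tmpl, sub_rate, ins_rate, del_rate)
        if (stats::runif(1) < 0.5) reads[k] <- revcomp(reads[k])
      }
      df <- data.frame(read_id = sprintf("%s_%04d", read_prefix, ctr + seq_len(nr)),
                       amplicon_id = products$amplicon_id[i], seq = reads,
                       qual = q, stringsAsFactors = FALSE)
      extra <- setdiff(names(products), c("amplicon_id", "seq", "length"))
      for (col in extra) df[[col]] <- products[[col]][i]
      ctr <- ctr + nr
      rows[[i]] <- df
    }
    do.call(rbind, rows)
  })
}

mutate_read <- function(tmpl, sub_rate, ins_rate, del_rate) {
  n <- nchar(tmpl)
  if (sub_rate + ins_rate + del_rate == 0) return(tmpl)
  bases <- charToRaw("ACGT")
  x <- charToRaw(tmpl)
  nsub <- stats::rbinom(1, n, sub_rate)
  if (nsub > 0) {
    pos <- sample.int(n, nsub)
    for (p in pos) x[p] <- sample(bases[bases != x[p]], 1)
  }
  ndel <- stats::rbinom(1, n, del_rate)
  nins <- stats::rbinom(1, n, ins_rate)
  if (ndel > 0) x <- x[-sample.int(length(x), min(ndel, length(x) - 1L))]
  if (nins > 0) {
    at <- sort(sample.int(length(x), nins, replace = TRUE))
    ins <- sample(bases, nins, replace = TRUE)
    # splice inserted bases after their positions in one pass
    out <- raw(length(x) + nins)
    idx <- at + seq_len(nins)        # target indices of inserted bases
    out[idx] <- ins
    out[-idx] <- x
    x <- out
  }
  rawToChar(x)
}

#' Build the event list for a catalogued allele
#' @param cat_row one row of [default_catalog()] (or a catalog TSV with the
#'   same columns).
#' @return an [allele_event()].
#' @export
catalog_event <- function(cat_row) {
  kind <- switch(cat_row$type, SNV = "SNV", indel = "small_indel",
                 deletion = "large_deletion", duplication = "duplication",
                 conversion = "conversion",
                 stop_with("unknown catalog type '%s'", cat_row$type))
  if (kind == "SNV")
    return(allele_event("SNV", cat_row$contig, cat_row$pos, cat_row$pos + 1L,
                        cat_row$alt, name = cat_row$name))
  if (kind == "small_indel") {
    # VCF-style anchored representation -> raw replacement interval
    if (nchar(cat_row$ref) > nchar(cat_row$alt))        # deletion
      return(allele_event("small_indel", cat_row$contig, cat_row$event_start,
                          cat_row$event_end, "", name = cat_row$name))
    return(allele_event("small_indel", cat_row$contig, cat_row$event_start,
                        cat_row$event_end,
                        substr(cat_row$alt, 2L, nchar(cat_row$alt)),
                        name = cat_row$name))
  }
  allele_event(kind, cat_row$contig, cat_row$event_start, cat_row$event_end,
               name = cat_row$name)
}

insertion_event <- function(ev) ev$start == ev$end
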