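#' @useDynLib globintyper, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import data.table
NULL

DNA_BASES <- c("A", "C", "G", "T")

#' Reverse complement of a DNA string
#'
#' @param x character vector of DNA sequences (A/C/G/T).
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  vapply(x, function(s)
    rawToChar(rev(charToRaw(chartr("ACGTRYKMN", "TGCAYRMKN", s)))),
    "", USE.NAMES = FALSE)
}

# Run code with a private RNG stream, restoring the caller's stream after.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# Deterministic per-item seed derived from a master seed; kept below 2^31.
derive_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(i) * 16807) %% 2147483629)
}

random_dna <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

# Hamming distance between equal-length strings.
hamming <- function(a, b) {
  stopifnot(nchar(a) == nchar(b))
  sum(charToRaw(a) != charToRaw(b))
}

# 0-based positions at which two equal-length strings differ.
mismatch_positions <- function(a, b) {
  which(charToRaw(a) != charToRaw(b)) - 1L
}

# Longest common prefix / suffix length of two strings.
lcp_len <- function(a, b) {
  ra <- charToRaw(a); rb <- charToRaw(b)
  n <- min(length(ra), length(rb))
  if (n == 0L) return(0L)
  d <- which(ra[seq_len(n)] != rb[seq_len(n)])
  if (length(d) == 0L) n else d[1L] - 1L
}

lcs_len <- function(a, b) {
  ra <- rev(charToRaw(a)); rb <- rev(charToRaw(b))
  n <- min(length(ra), length(rb))
  if (n == 0L) return(0L)
  d <- which(ra[seq_len(n)] != rb[seq_len(n)])
  if (length(d) == 0L) n else d[1L] - 1L
}

#' Read a FASTA file into a named character vector
#' @param path FASTA file.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  out <- as.character(x)
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' Write named sequences to FASTA
#' @param seqs named character vector.
#' @param path output file.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
}

#' Write reads to FASTQ (Sanger qualities)
#'
#' @param reads data.frame with columns `read_id`, `seq` and optionally `qual`
#'   (a single integer Phred score applied to every base of the read).
#' @param path output FASTQ file.
#' @export
write_fastq <- function(reads, path) {
  seqs <- Biostrings::DNAStringSet(reads$seq)
  names(seqs) <- reads$read_id
  q <- if ("qual" %in% names(reads)) reads$qual else rep(30L, nrow(reads))
  quals <- Biostrings::PhredQuality(vapply(seq_len(nrow(reads)), function(i) {
    paste(rep(rawToChar(as.raw(33L + q[i])), nchar(reads$seq[i])), collapse = "")
  }, character(1)))
  Biostrings::writeXStringSet(seqs, path, format = "fastq", qualities = quals)
}

#' Read a FASTQ file into a read table
#' @param path FASTQ file.
#' @return data.frame with `read_id` and `seq`.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  data.frame(read_id = sub("\\s.*$", "", names(x)), seq = as.character(x),
             stringsAsFactors = FALSE)
}

stop_with <- function(...) stop(sprintf(...), call. = FALSE)
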