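# Pre-alignment raw-read quality filters.
#
# Two rules are applied to each read independently of its mate:
#   (1) too many uncalled bases: more than `max_n` positions called N;
#   (2) low complexity: one of A/C/G/T making up more than `max_frac`
#       of the total read length (N never counts toward the numerator
#       but always toward the denominator).
# Both thresholds are strict ("more than"), so boundary reads are kept.

#' Count uncalled positions in reads
#'
#' @param reads read set (data frame with a `bases` column) or a
#'   character vector of base strings.
#' @return Integer vector: number of `N` positions per read.
#' @examples
#' count_uncalled(c("ACGTN", "NNN"))
#' @export
count_uncalled <- function(reads) {
  bases <- if (is.data.frame(reads)) reads$bases else reads
  nchar(bases) - nchar(gsub("N", "", bases, fixed = TRUE))
}

#' Maximum single-base fraction of reads
#'
#' For each read, the largest fraction of the total read length taken by
#' any one of A, C, G, T. `N` is excluded from the numerator but counts
#' in the denominator, so an all-`N` read scores 0.
#'
#' @inheritParams count_uncalled
#' @return Numeric vector of fractions in `[0, 1]`.
#' @export
max_base_fraction <- function(reads) {
  bases <- if (is.data.frame(reads)) reads$bases else reads
  len <- nchar(bases)
  if (any(len == 0)) stop("reads must be non-empty")
  top <- rep(0L, length(bases))
  for (b in c("A", "C", "G", "T")) {
    cnt <- len - nchar(gsub(b, "", bases, fixed = TRUE))
    top <- pmax(top, cnt)
  }
  top / len
}

#' Filter reads by uncalled-base and base-composition rules
#'
#' A read is removed iff `count_uncalled(read) > max_n` OR
#' `max_base_fraction(read) > max_frac`. The returned statistics count
#' removals per rule; a read failing both rules counts once toward each
#' rule and once toward the total.
#'
#' @param reads read set: data frame with columns `read_id`, `bases`,
#'   `quals` (as from [read_fastq()]).
#' @param max_n uncalled-base limit (default 5; strict).
#' @param max_frac single-base fraction limit (default 0.70; strict).
#' @return List with `kept` and `removed` (row subsets of `reads`, input
#'   order preserved) and `stats` (named counts `uncalled`,
#'   `base_fraction`, `total_removed`).
#' @export
filter_reads <- function(reads, max_n = 5L, max_frac = 0.70) {
  stopifnot(is.data.frame(reads))
  if (nrow(reads) == 0) {
    return(list(kept = reads, removed = reads,
                stats = c(uncalled = 0L, base_fraction = 0L, total_removed = 0L)))
  }
  fail_n <- count_uncalled(reads) > max_n
  fail_frac <- max_base_fraction(reads) > max_frac
  rm_ <- fail_n | fail_frac
  list(kept = reads[!rm_, , drop = FALSE],
       removed = reads[rm_, , drop = FALSE],
       stats = c(uncalled = sum(fail_n), base_fraction = sum(fail_frac),
                 total_removed = sum(rm_)))
}

# ---------------------------------------------------------------------------
# FASTQ I/O (Phred+33, 4-line records) via Biostrings

#' Read a FASTQ file
#'
#' @param path FASTQ path (4-line records, Phred+33 qualities).
#' @return Data frame with columns `read_id`, `bases`, `quals` (quality
#'   string, Phred+33 encoded).
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE)
  data.frame(read_id = names(x),
             bases = as.character(x),
             quals = as.character(S4Vectors::mcols(x)$qualities),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Write a FASTQ file
#'
#' @param reads read set as returned by [read_fastq()] or [gen_reads()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  x <- Biostrings::DNAStringSet(reads$bases)
  names(x) <- reads$read_id
  Biostrings::writeXStringSet(x, path, format = "fastq",
                              qualities = Biostrings::BStringSet(reads$quals))
  invisible(path)
}

# Phred score helpers (offset 33)
phred_to_chars <- function(q) {
  vapply(q, function(v) rawToChar(as.raw(v + 33L)), "")
}
chars_to_phred <- function(s) {
  lapply(s, function(v) as.integer(charToRaw(v)) - 33L)
}
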