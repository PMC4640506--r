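# Read cleanup: 5' artificial hexamer, 3' adapter, length selection,
# collapsing to unique sequences.  All operations are vectorised over
# character vectors of read sequences; qualities are carried by the
# FASTQ reader but play no role in any filter.

#' Default adapter / hexamer constants
#'
#' The Illumina small-RNA 3' adapter and the artificial 5' hexamer seen
#' on 6-8% of reads in the libraries this workflow targets.
#' @name preprocess-constants
#' @export
SRNA_ADAPTER <- "ATCTCGTATGCCGTCTTCTGCTTGC"

#' @rdname preprocess-constants
#' @export
SRNA_HEXAMER <- "ACATCG"

#' Trim a leading artificial hexamer
#'
#' Removes up to `max_trims` exact occurrences of `hexamer` from the 5'
#' terminus of each read (default: a single leading occurrence; internal
#' occurrences are never touched).
#'
#' @param sequences Character vector of read sequences.
#' @param hexamer The hexamer to strip.
#' @param max_trims Maximum number of leading occurrences removed.
#' @return Trimmed character vector.
#' @examples
#' trim_hexamer("ACATCGTCACCGGGTGGAAACTAGCAGT")
#' @export
trim_hexamer <- function(sequences, hexamer = SRNA_HEXAMER, max_trims = 1L) {
  k <- nchar(hexamer)
  for (i in seq_len(max_trims)) {
    has <- startsWith(sequences, hexamer)
    if (!any(has)) break
    sequences[has] <- substr(sequences[has], k + 1L,
                             nchar(sequences[has]))
  }
  sequences
}

#' Trim the 3' sequencing adapter
#'
#' Finds, for each read, the best un-gapped alignment of an adapter
#' prefix to the read's 3' portion (overlap of at least `min_overlap`
#' bases, mismatch rate at most `max_mm_rate`; a full internal adapter
#' match qualifies too) and cuts the read at the alignment start.  The
#' best alignment is the one with the lowest mismatch rate; ties go to
#' the earliest (longest-overlap) position.  Reads with no qualifying
#' match are returned unchanged -- the length filter decides their fate.
#'
#' @param sequences Character vector of read sequences.
#' @param adapter Adapter sequence.
#' @param min_overlap Minimum adapter prefix length that must align.
#' @param max_mm_rate Maximum tolerated mismatch fraction.
#' @return Trimmed character vector (possibly containing empty strings).
#' @export
trim_adapter <- function(sequences, adapter = SRNA_ADAPTER,
                         min_overlap = 8L, max_mm_rate = 0.1) {
  la <- nchar(adapter)
  ac <- strsplit(adapter, "", fixed = TRUE)[[1L]]
  out <- sequences
  lens <- nchar(sequences)
  for (L in unique(lens)) {
    if (L < min_overlap) next
    idx <- which(lens == L)
    sm <- matrix(unlist(strsplit(sequences[idx], "", fixed = TRUE),
                        use.names = FALSE),
                 nrow = length(idx), ncol = L, byrow = TRUE)
    best_rate <- rep(Inf, length(idx))
    best_p <- rep(NA_integer_, length(idx))
    for (p in 0:(L - min_overlap)) {
      o <- min(L - p, la)
      am <- matrix(ac[seq_len(o)], nrow = length(idx), ncol = o,
                   byrow = TRUE)
      mm <- rowSums(sm[, (p + 1L):(p + o), drop = FALSE] != am)
      rate <- mm / o
      better <- rate <= max_mm_rate & rate < best_rate
      best_rate[better] <- rate[better]
      best_p[better] <- p
    }
    hit <- !is.na(best_p)
    out[idx[hit]] <- substr(sequences[idx[hit]], 1L, best_p[hit])
  }
  out
}

#' Keep reads within a length window
#'
#' @param sequences Character vector of (trimmed) read sequences.
#' @param lo,hi Inclusive length bounds.
#' @return Logical vector: `TRUE` for reads to keep.
#' @export
length_filter <- function(sequences, lo = 16L, hi = 28L) {
  n <- nchar(sequences)
  n >= lo & n <= hi
}

#' Collapse reads to unique sequences with counts
#'
#' One record per distinct sequence; counts sum to the number of input
#' reads.  Records are ordered by descending count, then lexicographic
#' sequence, and given deterministic uids.
#'
#' @param sequences Character vector of cleaned read sequences.
#' @return Data frame with columns `uid`, `sequence`, `count`.
#' @export
collapse_reads <- function(sequences) {
  if (!length(sequences))
    return(data.frame(uid = character(0), sequence = character(0),
                      count = integer(0), stringsAsFactors = FALSE))
  r <- rle(sort(sequences))
  ord <- order(-r$lengths, r$values)
  data.frame(uid = sprintf("u%06d", seq_along(ord)),
             sequence = r$values[ord],
             count = r$lengths[ord],
             stringsAsFactors = FALSE)
}

#' Clean and collapse a small-RNA library
#'
#' Fixed pipeline: hexamer trim, adapter trim, length selection (16-28 nt
#' inclusive), N-containing-read drop, collapsing.  Returns the unique
#' reads plus a per-stage accounting report; total input reads always
#' equal collapsed counts plus the reads discarded along the way.
#'
#' @param reads A FASTQ path (plain or gzipped) or a character vector of
#'   read sequences.
#' @param hexamer,max_trims Passed to [trim_hexamer()].
#' @param adapter,min_overlap,max_mm_rate Passed to [trim_adapter()].
#' @param lo,hi Passed to [length_filter()].
#' @return A list with `reads` (data frame `uid`, `sequence`, `count`)
#'   and `report` (named list of per-stage totals).
#' @export
preprocess_reads <- function(reads, hexamer = SRNA_HEXAMER, max_trims = 1L,
                             adapter = SRNA_ADAPTER, min_overlap = 8L,
                             max_mm_rate = 0.1, lo = 16L, hi = 28L) {
  if (is.character(reads) && length(reads) == 1L && is.null(names(reads)) &&
      file.exists(reads)) {
    reads <- as.character(Biostrings::readDNAStringSet(reads,
                                                       format = "fastq"))
  }
  reads <- toupper(unname(reads))
  n_raw <- length(reads)

  # Work on unique raw sequences; expand counts at the end.
  u <- collapse_reads(reads)
  s1 <- trim_hexamer(u$sequence, hexamer = hexamer, max_trims = max_trims)
  n_hex <- sum(u$count[s1 != u$sequence])
  s2 <- trim_adapter(s1, adapter = adapter, min_overlap = min_overlap,
                     max_mm_rate = max_mm_rate)
  n_adapt <- sum(u$count[s2 != s1])
  has_n <- grepl("N", s2, fixed = TRUE)
  keep_len <- length_filter(s2, lo = lo, hi = hi)
  n_empty <- sum(u$count[nchar(s2) == 0L])
  n_with_n <- sum(u$count[keep_len & has_n])
  keep <- keep_len & !has_n
  n_len_drop <- sum(u$count[!keep_len]) - n_empty

  kept <- rep.int(s2[keep], u$count[keep])
  collapsed <- collapse_reads(kept)
  report <- list(
    n_raw = n_raw,
    n_hexamer_trimmed = n_hex,
    n_adapter_trimmed = n_adapt,
    n_empty_after_trim = n_empty,
    n_length_dropped = n_len_drop,
    n_with_n_dropped = n_with_n,
    n_kept = sum(collapsed$count),
    n_unique = nrow(collapsed),
    length_window = c(lo = lo, hi = hi))
  list(reads = collapsed, report = report)
}

#' Write / read collapsed reads in tally-dialect FASTA
#'
#' Headers are `>uid_count`, e.g. `>u000001_532`.
#'
#' @param reads Collapsed read data frame from [collapse_reads()].
#' @param path File path.
#' @return `path` invisibly (writer); collapsed data frame (reader).
#' @export
write_collapsed_fasta <- function(reads, path) {
  x <- Biostrings::DNAStringSet(setNames(reads$sequence,
                                         paste0(reads$uid, "_", reads$count)))
  Biostrings::writeXStringSet(x, path, width = 60L)
  invisible(path)
}

#' @rdname write_collapsed_fasta
#' @export
read_collapsed_fasta <- function(path) {
  x <- .as_seqvec(path, "collapsed reads")
  parts <- regmatches(names(x), regexec("^(.*)_(\\d+)$", names(x)))
  bad <- vapply(parts, length, integer(1)) != 3L
  if (any(bad))
    stop("headers are not in uid_count form: ",
         paste(head(names(x)[bad]), collapse = ", "))
  data.frame(uid = vapply(parts, `[`, character(1), 2L),
             sequence = unname(x),
             count = as.integer(vapply(parts, `[`, character(1), 3L)),
             stringsAsFactors = FALSE)
}

#' Write a preprocessing report as JSON
#'
#' @param report Report list from [preprocess_reads()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_preprocess_report <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
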