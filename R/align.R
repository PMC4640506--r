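# End-to-end multi-mapping of collapsed reads against the reference:
# every placement with at most `max_mm` substitutions (no indels) is
# reported, capped at `max_hits` locations in a deterministic order.
# The search runs over a single concatenated subject with N spacers
# between features; N never matches a read base, and hits are kept only
# when fully contained in one feature, so spacers cannot host or bridge
# placements at the allowed mismatch budget.

.EMPTY_HITS <- data.frame(feature_id = character(0), seq_class = character(0),
                          offset = integer(0), strand = character(0),
                          mismatches = integer(0), stringsAsFactors = FALSE)

#' Build a reusable alignment index from a reference
#'
#' @param ref A `mir_reference` from [build_reference()].
#' @param spacer_len Number of `N` spacer bases between features (must
#'   exceed the longest read).
#' @return An object of class `mir_align_index`.
#' @export
align_index <- function(ref, spacer_len = 30L) {
  stopifnot(inherits(ref, "mir_reference"))
  len <- nchar(ref$seqs)
  subject <- Biostrings::DNAString(
    paste(ref$seqs, collapse = strrep("N", spacer_len)))
  start1 <- cumsum(c(1L, head(len + spacer_len, -1L)))
  catalog <- data.frame(feature_id = names(ref$seqs),
                        seq_class = ref$features$seq_class,
                        start1 = start1, end1 = start1 + len - 1L,
                        stringsAsFactors = FALSE)
  structure(list(subject = subject, catalog = catalog,
                 spacer_len = spacer_len),
            class = "mir_align_index")
}

#' @noRd
.scan_hits <- function(pattern, index, max_mm) {
  m <- Biostrings::matchPattern(pattern, index$subject,
                                max.mismatch = max_mm,
                                with.indels = FALSE, fixed = TRUE)
  st <- BiocGenerics::start(m)
  if (!length(st)) return(.EMPTY_HITS)
  cat <- index$catalog
  w <- length(pattern)
  # drop placements overhanging the subject (not end-to-end)
  st <- st[st >= 1L & st + w - 1L <= length(index$subject)]
  if (!length(st)) return(.EMPTY_HITS)
  fi <- findInterval(st, cat$start1)
  ok <- fi >= 1L & st >= cat$start1[fi] & (st + w - 1L) <= cat$end1[fi]
  st <- st[ok]; fi <- fi[ok]
  if (!length(st)) return(.EMPTY_HITS)
  mm <- Biostrings::neditStartingAt(pattern, index$subject,
                                    starting.at = st,
                                    with.indels = FALSE, fixed = TRUE)
  data.frame(feature_id = cat$feature_id[fi], seq_class = cat$seq_class[fi],
             offset = st - cat$start1[fi], strand = "+",
             mismatches = as.integer(mm), stringsAsFactors = FALSE)
}

#' Map one read against the reference
#'
#' Reports every end-to-end placement of `sequence` with at most
#' `max_mm` substitutions.  Reverse-complement placements are searched
#' only for the classes in `rc_classes` (by default the genome, where
#' reads from either strand are expected; transcript-like features are
#' matched sense-only).  Hits are sorted by (mismatches, feature_id,
#' offset, strand) and truncated to `max_hits`, with an `overflow`
#' attribute flagging truncation.
#'
#' @param sequence Read sequence (single character string).
#' @param index A `mir_align_index` (or a `mir_reference`, indexed on
#'   the fly).
#' @param max_mm Maximum substitutions per placement.
#' @param max_hits Maximum number of reported locations.
#' @param rc_classes Classes searched on the reverse strand; use all
#'   five class names for a both-strands search, or `character(0)` for
#'   sense-only.
#' @return Data frame of hits (`feature_id`, `seq_class`, `offset`
#'   0-based on the feature, `strand`, `mismatches`) with attribute
#'   `overflow`; zero rows when unmapped.
#' @export
map_read <- function(sequence, index, max_mm = 2L, max_hits = 100L,
                     rc_classes = "genome") {
  if (inherits(index, "mir_reference")) index <- align_index(index)
  pat <- Biostrings::DNAString(sequence)
  hits <- .scan_hits(pat, index, max_mm)
  if (length(rc_classes)) {
    rc <- .scan_hits(Biostrings::reverseComplement(pat), index, max_mm)
    rc <- rc[rc$seq_class %in% rc_classes, , drop = FALSE]
    if (nrow(rc)) {
      rc$strand <- "-"
      hits <- rbind(hits, rc)
    }
  }
  ord <- order(hits$mismatches, hits$feature_id, hits$offset, hits$strand)
  hits <- hits[ord, , drop = FALSE]
  overflow <- nrow(hits) > max_hits
  if (overflow) hits <- hits[seq_len(max_hits), , drop = FALSE]
  rownames(hits) <- NULL
  attr(hits, "overflow") <- overflow
  hits
}

#' Map all collapsed reads
#'
#' One hit set per read, order-preserving, assembled into a single data
#' frame keyed by `uid`.  A summary of mapped / unmapped / overflowing
#' reads is attached as attributes.
#'
#' @param reads Collapsed read data frame (`uid`, `sequence`, `count`).
#' @param ref A `mir_reference` or prebuilt `mir_align_index`.
#' @inheritParams map_read
#' @return Data frame with columns `uid`, `feature_id`, `seq_class`,
#'   `offset`, `strand`, `mismatches`, `read_len`; attributes `summary`
#'   (list), `unmapped_uids` and `overflow_uids`.
#' @export
map_all <- function(reads, ref, max_mm = 2L, max_hits = 100L,
                    rc_classes = "genome") {
  index <- if (inherits(ref, "mir_align_index")) ref else align_index(ref)
  n <- nrow(reads)
  res <- vector("list", n)
  overflow <- logical(n)
  for (i in seq_len(n)) {
    h <- map_read(reads$sequence[i], index, max_mm = max_mm,
                  max_hits = max_hits, rc_classes = rc_classes)
    overflow[i] <- isTRUE(attr(h, "overflow"))
    res[[i]] <- h
  }
  nh <- vapply(res, nrow, integer(1))
  hits <- data.frame(
    uid = rep.int(reads$uid, nh),
    feature_id = unlist(lapply(res, `[[`, "feature_id"), use.names = FALSE),
    seq_class = unlist(lapply(res, `[[`, "seq_class"), use.names = FALSE),
    offset = unlist(lapply(res, `[[`, "offset"), use.names = FALSE),
    strand = unlist(lapply(res, `[[`, "strand"), use.names = FALSE),
    mismatches = unlist(lapply(res, `[[`, "mismatches"), use.names = FALSE),
    read_len = rep.int(nchar(reads$sequence), nh),
    stringsAsFactors = FALSE)
  attr(hits, "summary") <- list(
    n_reads = n,
    n_mapped = sum(nh > 0L),
    n_unmapped = sum(nh == 0L),
    n_overflow = sum(overflow),
    reads_mapped = sum(reads$count[nh > 0L]),
    reads_unmapped = sum(reads$count[nh == 0L]))
  attr(hits, "unmapped_uids") <- reads$uid[nh == 0L]
  attr(hits, "overflow_uids") <- reads$uid[overflow]
  hits
}

#' Write hits as TSV
#'
#' @param hits Hits data frame from [map_all()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hits_tsv <- function(hits, path) {
  write.table(hits, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
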