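# Hierarchical class assignment and fractional counting.
#
# Each read is assigned to the highest-preference class among its hits
# (mature > hairpin > ncRNA > coding > genome/intergenic); a hairpin hit
# lying fully inside an extended-mature interval is first promoted to
# the corresponding mature feature, so "hairpin" counts are loop reads
# that map outside the annotated mature regions.  Within the winning
# class the read's count is divided equally across its locations, and a
# read whose divided count falls below 1 contributes nothing anywhere.

.CLASS_RANK <- c(mature = 1L, hairpin = 2L, ncRNA = 3L, coding = 4L,
                 genome = 5L)
.ASSIGN_CLASSES <- c("mature", "hairpin", "ncRNA", "coding", "intergenic",
                     "unmapped")

# Promote hairpin hits contained in a single extended-mature interval to
# the mature feature, then drop duplicated locations (a mature-region
# read typically hits both the mature feature and its hairpin at the
# equivalent position).
#' @noRd
.reclassify_hairpin_hits <- function(hits, ref) {
  if (!nrow(hits)) return(hits)
  hits$.row <- seq_len(nrow(hits))
  is_hp <- hits$seq_class == "hairpin" & hits$strand == "+"
  if (any(is_hp) && nrow(ref$mature_regions)) {
    cand <- merge(hits[is_hp, , drop = FALSE], ref$mature_regions,
                  by.x = "feature_id", by.y = "hairpin_id")
    inside <- cand$offset >= cand$start &
      (cand$offset + cand$read_len) <= cand$end
    cand <- cand[inside, , drop = FALSE]
    if (nrow(cand)) {
      promoted <- data.frame(
        uid = cand$uid,
        feature_id = cand$mature_id,
        seq_class = "mature",
        offset = cand$offset - cand$start,
        strand = cand$strand,
        mismatches = cand$mismatches,
        read_len = cand$read_len,
        .row = cand$.row,
        stringsAsFactors = FALSE)
      hits <- rbind(hits[!(hits$.row %in% cand$.row), , drop = FALSE],
                    promoted)
    }
  }
  hits <- hits[order(hits$mismatches), , drop = FALSE]
  key <- paste(hits$uid, hits$feature_id, hits$offset, hits$strand,
               sep = "\r")
  hits <- hits[!duplicated(key), , drop = FALSE]
  hits$.row <- NULL
  rownames(hits) <- NULL
  hits
}

# Vectorised class assignment for a full hits table.
#' @noRd
.assign_all <- function(hits, ref) {
  hits <- .reclassify_hairpin_hits(hits, ref)
  if (!nrow(hits)) {
    return(list(hits = hits,
                assignments = data.frame(uid = character(0),
                                         assigned_class = character(0),
                                         n_hits = integer(0),
                                         stringsAsFactors = FALSE)))
  }
  rank <- .CLASS_RANK[hits$seq_class]
  best <- ave(rank, hits$uid, FUN = min)
  retained <- hits[rank == best, , drop = FALSE]
  n_hits <- ave(rep(1L, nrow(retained)), retained$uid, FUN = sum)
  first <- !duplicated(retained$uid)
  cls <- retained$seq_class[first]
  cls[cls == "genome"] <- "intergenic"
  assignments <- data.frame(uid = retained$uid[first],
                            assigned_class = cls,
                            n_hits = n_hits[first],
                            stringsAsFactors = FALSE)
  retained$n_hits <- n_hits
  list(hits = retained, assignments = assignments)
}

#' Assign one read's hit set to a sequence class
#'
#' Applies the class preference (mature > hairpin > ncRNA > coding >
#' intergenic) after promoting hairpin hits that fall entirely within an
#' extended-mature interval to the mature feature.  An empty hit set is
#' `"unmapped"`.
#'
#' @param hitset Hits data frame for a single read, as returned by
#'   [map_read()]; a `read_len` column is added from the hit widths when
#'   absent.
#' @param ref The `mir_reference` the hits were produced against.
#' @param read_len Read length; required if `hitset` has no `read_len`
#'   column and is empty of other cues.
#' @return A list with `assigned_class` (one of mature, hairpin, ncRNA,
#'   coding, intergenic, unmapped) and `hits`, the retained hits in the
#'   winning class.
#' @export
resolve_class <- function(hitset, ref, read_len = NULL) {
  if (is.null(hitset) || !nrow(hitset)) {
    return(list(assigned_class = "unmapped", hits = .EMPTY_HITS))
  }
  if (is.null(hitset$read_len)) {
    if (is.null(read_len)) stop("read_len required")
    hitset$read_len <- read_len
  }
  if (is.null(hitset$uid)) hitset$uid <- "read"
  res <- .assign_all(hitset, ref)
  list(assigned_class = res$assignments$assigned_class[1L],
       hits = res$hits)
}

#' Divide a read's count across its retained locations
#'
#' Each retained hit receives `read_count / n_locations`; when that
#' share is below 1 the whole read is ignored and contributes nothing.
#'
#' @param assignment Result of [resolve_class()].
#' @param read_count Observed count of the (collapsed) read.
#' @return Data frame `feature_id`, `seq_class`, `count` (possibly zero
#'   rows).
#' @export
partition_counts <- function(assignment, read_count) {
  hits <- assignment$hits
  if (is.null(hits) || !nrow(hits) ||
      identical(assignment$assigned_class, "unmapped"))
    return(data.frame(feature_id = character(0), seq_class = character(0),
                      count = numeric(0), stringsAsFactors = FALSE))
  share <- read_count / nrow(hits)
  if (share < 1)
    return(data.frame(feature_id = character(0), seq_class = character(0),
                      count = numeric(0), stringsAsFactors = FALSE))
  agg <- aggregate(list(count = rep(share, nrow(hits))),
                   by = list(feature_id = hits$feature_id,
                             seq_class = hits$seq_class),
                   FUN = sum)
  agg[order(agg$feature_id), c("feature_id", "seq_class", "count")]
}

# Full single-library tabulation (vectorised).
#' @noRd
.quantify_library <- function(hits, reads, ref) {
  res <- .assign_all(hits, ref)
  asn <- merge(res$assignments, reads[, c("uid", "count")], by = "uid")
  ret <- res$hits
  cnt <- reads$count[match(ret$uid, reads$uid)]
  share <- cnt / ret$n_hits
  drop <- share < 1
  first_ret <- !duplicated(ret$uid)
  ignored <- sum(cnt[first_ret & drop])
  keep <- !drop
  cls <- ret$seq_class[keep]
  cls[cls == "genome"] <- "intergenic"
  feat <- if (any(keep)) {
    aggregate(list(count = share[keep]),
              by = list(feature_id = ret$feature_id[keep],
                        seq_class = cls), FUN = sum)
  } else {
    data.frame(feature_id = character(0), seq_class = character(0),
               count = numeric(0), stringsAsFactors = FALSE)
  }
  unmapped_uids <- setdiff(reads$uid, hits$uid)
  unmapped <- sum(reads$count[reads$uid %in% unmapped_uids])
  class_totals <- setNames(numeric(length(.ASSIGN_CLASSES)),
                           .ASSIGN_CLASSES)
  ct <- tapply(asn$count, asn$assigned_class, sum)
  class_totals[names(ct)] <- ct
  class_totals["unmapped"] <- unmapped
  list(features = feat, class_totals = class_totals,
       ignored = ignored, total = sum(reads$count),
       assignments = asn)
}

#' Build the per-feature fractional count table
#'
#' Applies class assignment and fractional count division to each
#' library and assembles the per-feature count matrix, keeping every
#' feature with a nonzero value in any library.  Library labels come
#' from the names of `hits`.
#'
#' @param hits Named list of hits data frames from [map_all()], one per
#'   library.
#' @param reads Named list of collapsed read data frames (same names).
#' @param ref The `mir_reference` used for mapping.
#' @return A `mir_count_table`: data frame with `feature_id`,
#'   `seq_class` and one numeric column per library; attributes
#'   `lib_totals` (collapsed read totals), `class_totals` (full-count
#'   class composition per library, rows = mature, hairpin, ncRNA,
#'   coding, intergenic, unmapped), `ignored` (counts lost to the
#'   divided-count-below-1 rule) and `libs`.
#' @export
build_count_table <- function(hits, reads, ref) {
  libs <- names(hits)
  if (is.null(libs) || any(!nzchar(libs)) || anyDuplicated(libs))
    stop("hits must be a uniquely named list of libraries")
  if (!identical(sort(libs), sort(names(reads))))
    stop("hits and reads must carry the same library labels")
  per <- lapply(libs, function(l) .quantify_library(hits[[l]], reads[[l]],
                                                    ref))
  names(per) <- libs
  all_feat <- unique(do.call(rbind, lapply(per, function(x)
    x$features[, c("feature_id", "seq_class")])))
  all_feat <- all_feat[order(match(all_feat$seq_class,
                                   names(.CLASS_RANK)[1:4],
                                   nomatch = 5L), all_feat$feature_id), ,
                       drop = FALSE]
  rownames(all_feat) <- NULL
  tab <- all_feat
  for (l in libs) {
    f <- per[[l]]$features
    idx <- match(paste(all_feat$feature_id, all_feat$seq_class),
                 paste(f$feature_id, f$seq_class))
    tab[[l]] <- ifelse(is.na(idx), 0, f$count[idx])
  }
  attr(tab, "lib_totals") <- vapply(per, `[[`, numeric(1), "total")
  attr(tab, "class_totals") <- vapply(per, `[[`,
                                      numeric(length(.ASSIGN_CLASSES)),
                                      "class_totals")
  attr(tab, "ignored") <- vapply(per, `[[`, numeric(1), "ignored")
  attr(tab, "libs") <- libs
  class(tab) <- c("mir_count_table", "data.frame")
  tab
}

#' Per-library class composition
#'
#' Fraction of collapsed reads assigned to each class (mature, hairpin,
#' ncRNA, coding, intergenic, unmapped), computed on full read counts at
#' the assignment stage, so the six fractions sum to one per library.
#'
#' @param table A `mir_count_table`.
#' @return Matrix of fractions, classes x libraries.
#' @export
class_composition <- function(table) {
  ct <- attr(table, "class_totals")
  tot <- attr(table, "lib_totals")
  sweep(ct, 2L, tot, "/")
}

#' Shares of the top mature miRNAs
#'
#' Per-library share of each mature feature among all mature-mapped
#' counts, in descending order.
#'
#' @param table A `mir_count_table`.
#' @param n Number of top features per library.
#' @return Data frame `library`, `feature_id`, `count`, `share_pct`,
#'   `rank`.
#' @export
top_mirna_shares <- function(table, n = 10L) {
  libs <- attr(table, "libs")
  mat <- table[table$seq_class == "mature", , drop = FALSE]
  out <- lapply(libs, function(l) {
    tot <- sum(mat[[l]])
    ord <- order(-mat[[l]])
    k <- head(ord, n)
    data.frame(library = l, feature_id = mat$feature_id[k],
               count = mat[[l]][k],
               share_pct = 100 * mat[[l]][k] / tot,
               rank = seq_along(k), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Write a count table as TSV (counts rounded to 4 decimals)
#'
#' @param table A `mir_count_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_count_table <- function(table, path) {
  out <- as.data.frame(table)
  for (l in attr(table, "libs")) out[[l]] <- round(out[[l]], 4)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
print.mir_count_table <- function(x, ...) {
  cat("mir_count_table:", nrow(x), "features x",
      length(attr(x, "libs")), "libraries\n")
  cat("libraries:", paste(attr(x, "libs"), collapse = ", "), "\n")
  print(utils::head(as.data.frame(x), 10L))
  invisible(x)
}
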