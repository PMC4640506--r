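#' Extend a mature miRNA annotation on its hairpin
#'
#' Mature miRNA coordinates are widened by a few bases on each side
#' (default 3 nt at the 5' end, 5 nt at the 3' end) so that sequenced
#' isomiRs with slightly shifted ends still produce end-to-end hits
#' within the mature region.  The extension is clipped at the hairpin
#' boundaries, never wrapped.
#'
#' @param hairpin_seq Hairpin sequence, a single character string (ACGT).
#' @param ann A list or one-row data frame with fields `hairpin_id`,
#'   `mature_id`, `start`, `end` (0-based half-open coordinates on the
#'   hairpin) and optionally `arm`.
#' @param ext5,ext3 Bases added at the 5' / 3' ends.
#' @return A list describing the mature reference feature: `feature_id`,
#'   `seq_class` (`"mature"`), `sequence`, `parent_hairpin`, and the
#'   extended `start`/`end` (0-based half-open on the hairpin).
#' @examples
#' hp <- paste(rep("ACGT", 15), collapse = "")
#' extend_mature(hp, list(hairpin_id = "hp1", mature_id = "m1",
#'                        start = 10, end = 32))
#' @export
extend_mature <- function(hairpin_seq, ann, ext5 = 3L, ext3 = 5L) {
  stopifnot(is.character(hairpin_seq), length(hairpin_seq) == 1L)
  L <- nchar(hairpin_seq)
  start <- as.integer(ann$start)
  end <- as.integer(ann$end)
  if (is.na(start) || is.na(end) || start < 0L || end <= start || end > L)
    stop("invalid mature coordinates [", ann$start, ",", ann$end,
         ") on hairpin '", ann$hairpin_id, "' of length ", L)
  s <- max(0L, start - as.integer(ext5))
  e <- min(L, end + as.integer(ext3))
  list(feature_id = as.character(ann$mature_id),
       seq_class = "mature",
       sequence = substr(hairpin_seq, s + 1L, e),
       parent_hairpin = as.character(ann$hairpin_id),
       start = s, end = e)
}

#' Read mature miRNA annotations from GFF3
#'
#' Expects one record per mature miRNA with the hairpin id as the
#' sequence name and `ID` (mature id) / `Parent` attributes.  GFF3
#' coordinates are 1-based closed and are converted to the 0-based
#' half-open convention used internally.
#'
#' @param path Path to a GFF3 file.
#' @return A data frame with columns `hairpin_id`, `mature_id`, `start`,
#'   `end` (0-based half-open) and `arm` (NA when not annotated).
#' @export
read_mature_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  mc <- S4Vectors::mcols(gr)
  parent <- mc$Parent
  if (!is.null(parent) && methods::is(parent, "List"))
    parent <- vapply(parent, function(p)
      if (length(p)) as.character(p[[1L]]) else NA_character_, character(1))
  arm <- if (!is.null(mc$arm)) as.character(mc$arm) else NA_character_
  data.frame(
    hairpin_id = as.character(GenomicRanges::seqnames(gr)),
    mature_id = as.character(mc$ID),
    start = BiocGenerics::start(gr) - 1L,
    end = BiocGenerics::end(gr),
    arm = arm,
    stringsAsFactors = FALSE)
}

#' Write mature miRNA annotations to GFF3
#'
#' Inverse of [read_mature_gff3()].
#'
#' @param ann Annotation data frame (`hairpin_id`, `mature_id`, `start`,
#'   `end` in 0-based half-open coordinates).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mature_gff3 <- function(ann, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = ann$hairpin_id,
    ranges = IRanges::IRanges(start = ann$start + 1L, end = ann$end),
    strand = "+")
  S4Vectors::mcols(gr)$type <- "miRNA"
  S4Vectors::mcols(gr)$ID <- ann$mature_id
  S4Vectors::mcols(gr)$Parent <- ann$hairpin_id
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Build the class-labelled mapping reference
#'
#' Assembles the concatenated reference the reads are mapped against:
#' extended mature miRNAs, the hairpins they come from, non-coding
#' transcripts, coding transcripts and the genome, each carrying its
#' class label.  Hairpin features record their extended-mature intervals
#' so that hairpin hits falling inside a mature region can later be
#' promoted to the mature feature, and hits outside them count as
#' hairpin (loop) reads.
#'
#' @param hairpins,ncrna,coding,genome FASTA paths, `DNAStringSet`s or
#'   named character vectors.  `ncrna`, `coding` and `genome` may be
#'   `NULL` or empty.
#' @param matures Mature annotations: a data frame as returned by
#'   [read_mature_gff3()], or a GFF3 path.
#' @param ext5,ext3 Mature extension, passed to [extend_mature()].
#' @return An object of class `mir_reference`: a list with `features`
#'   (data frame: `feature_id`, `seq_class`, `length`, `parent_hairpin`),
#'   `seqs` (named character vector, same order), `mature_regions`
#'   (extended intervals per hairpin) and the original `annotations`.
#' @export
build_reference <- function(hairpins, matures, ncrna = NULL, coding = NULL,
                            genome = NULL, ext5 = 3L, ext3 = 5L) {
  hp <- .as_seqvec(hairpins, "hairpins")
  nc <- .as_seqvec(ncrna, "ncRNA")
  cd <- .as_seqvec(coding, "coding")
  gn <- .as_seqvec(genome, "genome")
  ann <- if (is.character(matures)) read_mature_gff3(matures)
         else as.data.frame(matures, stringsAsFactors = FALSE)
  req <- c("hairpin_id", "mature_id", "start", "end")
  if (!all(req %in% names(ann)))
    stop("mature annotations need columns ", paste(req, collapse = ", "))
  dangling <- setdiff(ann$hairpin_id, names(hp))
  if (length(dangling))
    stop("mature annotations reference unknown hairpins: ",
         paste(dangling, collapse = ", "))
  ext <- lapply(seq_len(nrow(ann)), function(i)
    extend_mature(hp[[ann$hairpin_id[i]]], ann[i, ], ext5 = ext5, ext3 = ext3))

  mature_seqs <- setNames(vapply(ext, `[[`, character(1), "sequence"),
                          vapply(ext, `[[`, character(1), "feature_id"))
  regions <- data.frame(
    hairpin_id = vapply(ext, `[[`, character(1), "parent_hairpin"),
    mature_id = names(mature_seqs),
    start = vapply(ext, function(x) as.integer(x$start), integer(1)),
    end = vapply(ext, function(x) as.integer(x$end), integer(1)),
    stringsAsFactors = FALSE)

  cls_df <- function(ids, cls, parent = rep(NA_character_, length(ids))) {
    data.frame(feature_id = ids, seq_class = rep(cls, length(ids)),
               parent_hairpin = parent, stringsAsFactors = FALSE)
  }
  features <- rbind(
    cls_df(names(mature_seqs), "mature", regions$hairpin_id),
    cls_df(names(hp), "hairpin"),
    cls_df(names(nc), "ncRNA"),
    cls_df(names(cd), "coding"),
    cls_df(names(gn), "genome"))
  seqs <- c(mature_seqs, hp, nc, cd, gn)
  if (anyDuplicated(features$feature_id))
    stop("duplicate feature ids across reference classes: ",
         paste(unique(features$feature_id[duplicated(features$feature_id)]),
               collapse = ", "))
  features$length <- nchar(seqs)
  rownames(features) <- NULL
  structure(list(features = features, seqs = seqs,
                 mature_regions = regions, annotations = ann,
                 ext5 = as.integer(ext5), ext3 = as.integer(ext3)),
            class = "mir_reference")
}

#' @export
print.mir_reference <- function(x, ...) {
  tab <- table(factor(x$features$seq_class,
                      levels = c("mature", "hairpin", "ncRNA", "coding",
                                 "genome")))
  cat("mir_reference with", nrow(x$features), "features\n")
  for (cl in names(tab)) cat(sprintf("  %-8s %d\n", cl, tab[[cl]]))
  invisible(x)
}

#' Export a reference to FASTA + GFF3 files
#'
#' Writes the inputs needed to rebuild the reference: one FASTA per
#' class (mature sequences are re-derivable, so only hairpins, ncRNA,
#' coding and genome are written) plus the unextended mature annotations
#' as GFF3.  [import_reference()] round-trips the object.
#'
#' @param ref A `mir_reference`.
#' @param dir Output directory (created if needed).
#' @return Named vector of file paths, invisibly.
#' @export
export_reference <- function(ref, dir) {
  stopifnot(inherits(ref, "mir_reference"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cls <- split(ref$seqs, ref$features$seq_class)
  paths <- c(hairpins = file.path(dir, "hairpins.fa"),
             matures = file.path(dir, "matures.gff3"),
             ncrna = file.path(dir, "ncrna.fa"),
             coding = file.path(dir, "coding.fa"),
             genome = file.path(dir, "genome.fa"))
  .wr <- function(seqs, path) {
    if (is.null(seqs) || !length(seqs)) return(NA_character_)
    Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path,
                                width = 60L)
    path
  }
  paths["hairpins"] <- .wr(cls$hairpin, paths[["hairpins"]])
  paths["ncrna"] <- .wr(cls$ncRNA, paths[["ncrna"]])
  paths["coding"] <- .wr(cls$coding, paths[["coding"]])
  paths["genome"] <- .wr(cls$genome, paths[["genome"]])
  write_mature_gff3(ref$annotations, paths[["matures"]])
  invisible(paths)
}

#' Rebuild a reference exported by [export_reference()]
#'
#' @param dir Directory written by [export_reference()].
#' @param ext5,ext3 Mature extension, as for [build_reference()].
#' @return A `mir_reference`.
#' @export
import_reference <- function(dir, ext5 = 3L, ext3 = 5L) {
  p <- function(f) {
    fp <- file.path(dir, f)
    if (file.exists(fp)) fp else NULL
  }
  build_reference(hairpins = p("hairpins.fa"),
                  matures = file.path(dir, "matures.gff3"),
                  ncrna = p("ncrna.fa"), coding = p("coding.fa"),
                  genome = p("genome.fa"), ext5 = ext5, ext3 = ext3)
}
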