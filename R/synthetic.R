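# Seeded synthetic data: a toy reference (hairpins with embedded
# matures, ncRNA, coding transcripts, one genome contig) and 36-cycle
# single-end read libraries with per-read provenance, negative-binomial
# count noise and known fold changes, so every pipeline stage can be
# scored offline.

#' Simulation configuration
#'
#' @param seed Mandatory RNG seed (integer).
#' @param n_mirnas,n_ncrna,n_coding Feature counts per class.
#' @param reads_per_library Sequencing depth per library.
#' @param hexamer_fraction Fraction of reads carrying the artificial 5'
#'   hexamer.
#' @param hexamer,adapter Sequences prepended/appended to inserts.
#' @param class_mix Read fractions over mature, hairpin_loop, ncRNA,
#'   coding, intergenic sources; must sum to 1.
#' @param dispersion Negative-binomial dispersion of per-feature counts
#'   (variance = mu + phi mu^2); 0 gives Poisson counts.
#' @param sub_rate Per-base substitution (sequencing error) rate; at
#'   most two substitutions are applied per read so every read stays
#'   mappable at the 2-mismatch budget.
#' @param read_length Instrument read length (cycles); inserts shorter
#'   than this read into the 3' adapter.
#' @param arms `"both"` annotates a 5p and a 3p mature on every hairpin,
#'   `"random"` annotates one or two.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed, n_mirnas = 20L, n_ncrna = 10L, n_coding = 5L,
                       reads_per_library = 20000L,
                       hexamer_fraction = 0.07,
                       hexamer = SRNA_HEXAMER, adapter = SRNA_ADAPTER,
                       class_mix = c(mature = 0.90, hairpin_loop = 0.01,
                                     ncRNA = 0.04, coding = 0.03,
                                     intergenic = 0.02),
                       dispersion = 0.1, sub_rate = 0.002,
                       read_length = 36L, arms = c("random", "both")) {
  if (missing(seed)) stop("seed is mandatory")
  arms <- match.arg(arms)
  stopifnot(abs(sum(class_mix) - 1) < 1e-9,
            all(class_mix >= 0),
            identical(sort(names(class_mix)),
                      sort(c("mature", "hairpin_loop", "ncRNA", "coding",
                             "intergenic"))),
            dispersion >= 0, hexamer_fraction >= 0, hexamer_fraction <= 1)
  structure(list(seed = as.integer(seed), n_mirnas = n_mirnas,
                 n_ncrna = n_ncrna, n_coding = n_coding,
                 reads_per_library = reads_per_library,
                 hexamer_fraction = hexamer_fraction, hexamer = hexamer,
                 adapter = adapter, class_mix = class_mix,
                 dispersion = dispersion, sub_rate = sub_rate,
                 read_length = as.integer(read_length), arms = arms),
            class = "sim_config")
}

#' Generate the toy reference with ground-truth skeleton
#'
#' Random hairpins (two ~20-23 nt arms around an 18-26 nt loop) with
#' embedded mature annotations, ncRNA (60-300 nt), coding transcripts
#' (300-1500 nt) and one genome contig containing every feature
#' separated by random intergenic spacers.  Deterministic given
#' `cfg$seed`.
#'
#' @param cfg A [sim_config()].
#' @return A list of class `mir_simref`: `hairpins`, `matures`
#'   (annotation data frame), `ncrna`, `coding`, `genome` (named
#'   character vectors), `spacers` (0-based half-open intergenic
#'   intervals on the contig), `weights` (per-class relative abundances)
#'   and `cfg`.
#' @export
make_reference <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  n <- cfg$n_mirnas
  hp <- character(n)
  ann <- vector("list", n)
  for (i in seq_len(n)) {
    m5 <- sample(20:23, 1L)
    loop <- sample(18:26, 1L)
    m3 <- sample(20:23, 1L)
    L <- m5 + loop + m3
    hp[i] <- .rand_dna(L)
    hid <- sprintf("cel-mir-%d", i)
    rows <- data.frame(
      hairpin_id = hid,
      mature_id = sprintf("cel-miR-%d-%s", i, c("5p", "3p")),
      start = c(0L, m5 + loop),
      end = c(m5, L),
      arm = c("5p", "3p"),
      stringsAsFactors = FALSE)
    if (cfg$arms == "random") {
      k <- sample(1:2, 1L)
      rows <- rows[sample(1:2, k), , drop = FALSE]
    }
    ann[[i]] <- rows
  }
  names(hp) <- sprintf("cel-mir-%d", seq_len(n))
  ann <- do.call(rbind, ann)
  rownames(ann) <- NULL

  nc <- setNames(vapply(sample(60:300, cfg$n_ncrna, replace = TRUE),
                        .rand_dna, character(1)),
                 sprintf("nc-%d", seq_len(cfg$n_ncrna)))
  cd <- setNames(vapply(sample(300:1500, cfg$n_coding, replace = TRUE),
                        .rand_dna, character(1)),
                 sprintf("cds-%d", seq_len(cfg$n_coding)))

  feats <- c(hp, nc, cd)
  spacer_seqs <- vapply(sample(60:150, length(feats) + 1L, replace = TRUE),
                        .rand_dna, character(1))
  pieces <- character(2L * length(feats) + 1L)
  pieces[seq(1L, length(pieces), by = 2L)] <- spacer_seqs
  pieces[seq(2L, length(pieces), by = 2L)] <- feats
  contig <- paste(pieces, collapse = "")
  ends <- cumsum(nchar(pieces))
  starts <- c(0L, head(ends, -1L))
  sp_idx <- seq(1L, length(pieces), by = 2L)
  spacers <- data.frame(start = starts[sp_idx], end = ends[sp_idx])

  w_mat <- exp(-0.15 * (seq_len(nrow(ann)) - 1L))
  weights <- list(
    mature = setNames(w_mat / sum(w_mat), ann$mature_id),
    hairpin_loop = setNames(rep(1 / n, n), names(hp)),
    ncRNA = {
      w <- rexp(cfg$n_ncrna) + 0.2
      setNames(w / sum(w), names(nc))
    },
    coding = {
      w <- rexp(cfg$n_coding) + 0.2
      setNames(w / sum(w), names(cd))
    })
  structure(list(hairpins = hp, matures = ann, ncrna = nc, coding = cd,
                 genome = c(chrI = contig), spacers = spacers,
                 weights = weights, cfg = cfg),
            class = "mir_simref")
}

#' @noRd
.apply_substitutions <- function(seqs, sub_rate) {
  nsub <- pmin(rbinom(length(seqs), nchar(seqs), sub_rate), 2L)
  todo <- which(nsub > 0L)
  bases <- c("A", "C", "G", "T")
  for (i in todo) {
    pos <- sample.int(nchar(seqs[i]), nsub[i])
    for (p in pos) {
      cur <- substr(seqs[i], p, p)
      substr(seqs[i], p, p) <- sample(setdiff(bases, cur), 1L)
    }
  }
  seqs
}

#' Simulate one sequencing library
#'
#' Per-source read counts are drawn negative-binomially around the
#' configured class mix and within-class weights (optionally multiplied
#' by `fold_changes` for perturbed matures, then renormalised so depth
#' is preserved -- the compositional shift this induces in null features
#' is exactly what TMM normalisation corrects downstream).  Each read is
#' an insert from its source feature (mature sequence with +/-1 nt end
#' jitter; loop windows outside the extended mature intervals; random
#' windows of ncRNA/coding/intergenic sequence), with at most two
#' substitutions at a low error rate, the artificial hexamer prepended
#' with probability `hexamer_fraction`, the 3' adapter appended, and the
#' result truncated to the instrument read length.
#'
#' @param simref A `mir_simref` from [make_reference()].
#' @param label Library label.
#' @param seed RNG seed for this library.
#' @param fold_changes Named vector of fold changes applied to mature
#'   weights (names = mature ids); unnamed features get 1.
#' @param depth Reads to generate (default from the configuration).
#' @return List of class `mir_simlib`: `label`, `sequences` (raw reads),
#'   `ids`, `provenance` (data frame `id`, `source`, `class`, `hexamer`,
#'   `insert`), `source_counts` and `n_reads`.
#' @export
simulate_library <- function(simref, label, seed, fold_changes = NULL,
                             depth = NULL) {
  stopifnot(inherits(simref, "mir_simref"))
  cfg <- simref$cfg
  depth <- depth %||% cfg$reads_per_library
  set.seed(seed)

  w <- simref$weights
  if (!is.null(fold_changes)) {
    fc <- setNames(rep(1, length(w$mature)), names(w$mature))
    unknown <- setdiff(names(fold_changes), names(fc))
    if (length(unknown)) stop("fold changes for unknown matures: ",
                              paste(unknown, collapse = ", "))
    fc[names(fold_changes)] <- fold_changes
    w$mature <- w$mature * fc
    w$mature <- w$mature / sum(w$mature)
  }
  mix <- cfg$class_mix
  mu <- c(w$mature * mix[["mature"]],
          w$hairpin_loop * mix[["hairpin_loop"]],
          w$ncRNA * mix[["ncRNA"]],
          w$coding * mix[["coding"]],
          setNames(mix[["intergenic"]], ".intergenic")) * depth
  src_class <- c(rep("mature", length(w$mature)),
                 rep("hairpin", length(w$hairpin_loop)),
                 rep("ncRNA", length(w$ncRNA)),
                 rep("coding", length(w$coding)),
                 "intergenic")
  counts <- if (cfg$dispersion > 0) {
    rnbinom(length(mu), size = 1 / cfg$dispersion, mu = mu)
  } else {
    rpois(length(mu), mu)
  }
  names(counts) <- names(mu)
  if (sum(counts) == 0L) {
    return(structure(list(label = label, sequences = character(0),
                          ids = character(0),
                          provenance = data.frame(),
                          source_counts = data.frame(
                            feature = names(mu), class = src_class,
                            count = counts, row.names = NULL),
                          n_reads = 0L),
                     class = "mir_simlib"))
  }

  ext_regions <- do.call(rbind, lapply(seq_len(nrow(simref$matures)),
    function(i) {
      a <- simref$matures[i, ]
      L <- nchar(simref$hairpins[[a$hairpin_id]])
      data.frame(hairpin_id = a$hairpin_id,
                 start = max(0L, a$start - 3L),
                 end = min(L, a$end + 5L))
    }))

  inserts <- vector("list", length(mu))
  for (j in seq_along(mu)) {
    cnt <- counts[j]
    if (cnt == 0L) next
    id <- names(mu)[j]
    inserts[[j]] <- switch(src_class[j],
      mature = {
        a <- simref$matures[simref$matures$mature_id == id, ]
        hpseq <- simref$hairpins[[a$hairpin_id]]
        L <- nchar(hpseq)
        s <- pmax(0L, a$start + sample(-1:1, cnt, replace = TRUE))
        e <- pmin(L, a$end + sample(-1:1, cnt, replace = TRUE))
        substring(hpseq, s + 1L, e)
      },
      hairpin = {
        hpseq <- simref$hairpins[[id]]
        L <- nchar(hpseq)
        reg <- ext_regions[ext_regions$hairpin_id == id, ]
        len <- sample(16:20, cnt, replace = TRUE)
        starts <- integer(cnt)
        for (k in seq_len(cnt)) {
          cand <- 0:(L - len[k])
          inside <- rep(FALSE, length(cand))
          for (r in seq_len(nrow(reg)))
            inside <- inside | (cand >= reg$start[r] &
                                  cand + len[k] <= reg$end[r])
          cand <- cand[!inside]
          starts[k] <- if (length(cand))
            cand[sample.int(length(cand), 1L)] else 0L
        }
        substring(hpseq, starts + 1L, starts + len)
      },
      ncRNA = ,
      coding = {
        fs <- if (src_class[j] == "ncRNA") simref$ncrna[[id]]
              else simref$coding[[id]]
        L <- nchar(fs)
        len <- sample(16:26, cnt, replace = TRUE)
        starts <- vapply(len, function(l) sample.int(L - l + 1L, 1L) - 1L,
                         integer(1))
        substring(fs, starts + 1L, starts + len)
      },
      intergenic = {
        sp <- simref$spacers
        widths <- sp$end - sp$start
        pick <- sample.int(nrow(sp), cnt, replace = TRUE,
                           prob = widths)
        len <- sample(16:26, cnt, replace = TRUE)
        starts <- vapply(seq_len(cnt), function(k) {
          lo <- sp$start[pick[k]]
          hi <- sp$end[pick[k]] - len[k]
          sample(lo:hi, 1L)
        }, integer(1))
        substring(simref$genome[[1L]], starts + 1L, starts + len)
      })
  }
  insert <- unlist(inserts, use.names = FALSE)
  source <- rep.int(names(mu), counts)
  cls <- rep.int(src_class, counts)

  insert <- .apply_substitutions(insert, cfg$sub_rate)
  hex <- runif(length(insert)) < cfg$hexamer_fraction
  raw <- substr(paste0(ifelse(hex, cfg$hexamer, ""), insert, cfg$adapter),
                1L, cfg$read_length)
  ids <- sprintf("%s:%07d", label, seq_along(raw))
  structure(list(
    label = label, sequences = raw, ids = ids,
    provenance = data.frame(id = ids, source = source, class = cls,
                            hexamer = hex, insert = insert,
                            stringsAsFactors = FALSE),
    source_counts = data.frame(feature = names(mu), class = src_class,
                               count = counts, row.names = NULL,
                               stringsAsFactors = FALSE),
    n_reads = length(raw)), class = "mir_simlib")
}

#' Write a simulated library as FASTQ
#'
#' @param lib A `mir_simlib`.
#' @param path Output path (`.gz` supported).
#' @return `path`, invisibly.
#' @export
write_fastq <- function(lib, path) {
  x <- Biostrings::DNAStringSet(setNames(lib$sequences, lib$ids))
  q <- Biostrings::BStringSet(strrep("I", nchar(lib$sequences)))
  Biostrings::writeXStringSet(x, path, format = "fastq", qualities = q)
  invisible(path)
}

#' Two-library scenario shaped like the starvation study
#'
#' Sixty miRNA hairpins with both arms annotated; one dominant mature
#' near a 50% share of miRNA reads and a second near 20%; a seven-member
#' cluster of matures truly upregulated 6-20 fold in the "starved"
#' library; two matures truly downregulated 8- and 13-fold; all other
#' features null.  Star (5p) arms are kept at 2% of their 3p partner's
#' abundance.
#'
#' @param seed RNG seed.
#' @param n_mirnas Number of hairpins (>= 25).
#' @param reads_per_library Depth per library.
#' @return List of class `mir_scenario`: `cfg`, `simref`,
#'   `fold_changes` (named, applied to the starved library), `perturbed`
#'   (ids with true changes), `dominant` (id of the ~50% mature) and
#'   `labels`.
#' @export
paper_shaped_scenario <- function(seed, n_mirnas = 60L,
                                  reads_per_library = 100000L) {
  stopifnot(n_mirnas >= 25L)
  cfg <- sim_config(seed = seed, n_mirnas = n_mirnas, n_ncrna = 10L,
                    n_coding = 5L, reads_per_library = reads_per_library,
                    arms = "both")
  simref <- make_reference(cfg)
  up_idx <- 10:16
  down_idx <- 20:21
  w3 <- numeric(n_mirnas)
  w3[1L] <- 0.50
  w3[2L] <- 0.198
  w3[up_idx] <- 0.004
  w3[down_idx] <- 0.006
  rest <- setdiff(seq_len(n_mirnas), c(1L, 2L, up_idx, down_idx))
  decay <- 0.85^seq_along(rest)
  w3[rest] <- decay / sum(decay) * (1 - sum(w3))
  w5 <- 0.02 * w3
  mat_w <- setNames(c(w3, w5),
                    c(sprintf("cel-miR-%d-3p", seq_len(n_mirnas)),
                      sprintf("cel-miR-%d-5p", seq_len(n_mirnas))))
  mat_w <- mat_w[simref$matures$mature_id]
  simref$weights$mature <- mat_w / sum(mat_w)

  fold_changes <- setNames(
    c(c(6, 8, 10, 12, 14, 16, 20), 1 / 8, 1 / 13),
    c(sprintf("cel-miR-%d-3p", up_idx), sprintf("cel-miR-%d-3p", down_idx)))
  structure(list(cfg = cfg, simref = simref, fold_changes = fold_changes,
                 perturbed = names(fold_changes),
                 dominant = "cel-miR-1-3p",
                 labels = c("well_fed", "starved")),
            class = "mir_scenario")
}

#' Run the full pipeline on a simulated two-library scenario
#'
#' Simulates both libraries, preprocesses, maps, tabulates fractional
#' counts and runs the differential-expression analysis, returning the
#' intermediate objects plus ground-truth recovery metrics.
#'
#' @param seed RNG seed (drives the scenario and both libraries).
#' @param reads_per_library Depth per library.
#' @param config A [de_config()].
#' @param scenario Optional pre-built `mir_scenario` (its seed wins).
#' @return List: `scenario`, `ref`, `prep` (per-library reports),
#'   `table`, `composition`, `shares`, `de` and `metrics` (list with
#'   `true_positives`, `false_positives`, `n_perturbed`,
#'   `dominant_share_pct`, `mature_fraction_pct`,
#'   `median_null_abs_log2fc`).
#' @export
run_simulated_study <- function(seed, reads_per_library = 100000L,
                                config = de_config(), scenario = NULL) {
  scn <- scenario %||% paper_shaped_scenario(seed,
                                             reads_per_library =
                                               reads_per_library)
  ref <- build_reference(scn$simref$hairpins, scn$simref$matures,
                         ncrna = scn$simref$ncrna,
                         coding = scn$simref$coding,
                         genome = scn$simref$genome)
  libA <- simulate_library(scn$simref, scn$labels[1L],
                           seed = scn$cfg$seed + 1L)
  libB <- simulate_library(scn$simref, scn$labels[2L],
                           seed = scn$cfg$seed + 2L,
                           fold_changes = scn$fold_changes)
  prepA <- preprocess_reads(libA$sequences)
  prepB <- preprocess_reads(libB$sequences)
  idx <- align_index(ref)
  hitsA <- map_all(prepA$reads, idx)
  hitsB <- map_all(prepB$reads, idx)
  hits <- setNames(list(hitsA, hitsB), scn$labels)
  reads <- setNames(list(prepA$reads, prepB$reads), scn$labels)
  tab <- build_count_table(hits, reads, ref)
  comp <- class_composition(tab)
  shares <- top_mirna_shares(tab)
  de <- run_de(tab, config)

  res <- de$results
  sig <- res$feature_id[res$fdr < config$fdr_threshold]
  tp <- sum(scn$perturbed %in% sig)
  fp <- length(setdiff(sig, scn$perturbed))
  nulls <- res[!(res$feature_id %in% scn$perturbed), ]
  dom <- shares[shares$library == scn$labels[1L] &
                  shares$feature_id == scn$dominant, "share_pct"]
  metrics <- list(
    true_positives = tp,
    false_positives = fp,
    n_perturbed = length(scn$perturbed),
    dominant_share_pct = if (length(dom)) dom else NA_real_,
    mature_fraction_pct = 100 * unname(comp["mature", ]),
    median_null_abs_log2fc = stats::median(abs(nulls$log2fc)))
  list(scenario = scn, ref = ref,
       prep = list(prepA$report, prepB$report),
       libs = list(libA["source_counts"], libB["source_counts"]),
       table = tab, composition = comp, shares = shares, de = de,
       metrics = metrics)
}
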