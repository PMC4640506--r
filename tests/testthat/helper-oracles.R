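# Independent brute-force oracles.  These deliberately share no code
# with the package internals: alignment slides the read over every
# offset of every feature; the conditional exact test enumerates the
# normalised conditional distribution directly; TMM is the literal
# textbook recipe; the count table is a naive per-read tabulation.

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                     replace = TRUE), collapse = "")

revcomp_chr <- function(s) {
  chartr("ACGT", "TGCA",
         vapply(strsplit(s, ""), function(x)
           paste(rev(x), collapse = ""), character(1)))
}

# Exhaustive scan of one read against every feature window.
oracle_scan_hits <- function(read, ref, max_mm = 2L, rc_classes = "genome") {
  rl <- nchar(read)
  rows <- list()
  pats <- list(`+` = charToRaw(read), `-` = charToRaw(revcomp_chr(read)))
  for (i in seq_along(ref$seqs)) {
    fid <- names(ref$seqs)[i]
    cls <- ref$features$seq_class[i]
    fs <- ref$seqs[[i]]
    L <- nchar(fs)
    if (L < rl) next
    fraw <- charToRaw(fs)
    for (strand in c("+", "-")) {
      if (strand == "-" && !(cls %in% rc_classes)) next
      p <- pats[[strand]]
      for (off in 0:(L - rl)) {
        mm <- sum(fraw[(off + 1):(off + rl)] != p)
        if (mm <= max_mm)
          rows[[length(rows) + 1L]] <- list(fid, cls, off, strand, mm)
      }
    }
  }
  if (!length(rows))
    return(data.frame(feature_id = character(0), seq_class = character(0),
                      offset = integer(0), strand = character(0),
                      mismatches = integer(0)))
  h <- data.frame(feature_id = vapply(rows, `[[`, character(1), 1L),
                  seq_class = vapply(rows, `[[`, character(1), 2L),
                  offset = vapply(rows, function(r) as.integer(r[[3L]]),
                                  integer(1)),
                  strand = vapply(rows, `[[`, character(1), 4L),
                  mismatches = vapply(rows, function(r) as.integer(r[[5L]]),
                                      integer(1)),
                  stringsAsFactors = FALSE)
  h <- h[order(h$mismatches, h$feature_id, h$offset, h$strand), ,
         drop = FALSE]
  rownames(h) <- NULL
  h
}

# Conditional two-sided exact p by direct enumeration.  phi = 0 uses
# the Poisson route (so it is an independent derivation of the
# binomial special case).
oracle_cond_p <- function(ka, kb, phi) {
  s <- ka + kb
  if (s == 0) return(1)
  pr <- vapply(0:s, function(k) {
    if (phi == 0) {
      dpois(k, s / 2) * dpois(s - k, s / 2)
    } else {
      dnbinom(k, size = 1 / phi, mu = s / 2) *
        dnbinom(s - k, size = 1 / phi, mu = s / 2)
    }
  }, numeric(1))
  pr <- pr / sum(pr)
  min(1, sum(pr[pr <= pr[ka + 1] * (1 + 1e-10)]))
}

# Textbook TMM: doubly trimmed, precision-weighted mean of M-values.
oracle_tmm_pair <- function(obs, ref, trim_m = 0.3, trim_a = 0.05) {
  n_o <- sum(obs)
  n_r <- sum(ref)
  ok <- obs > 0 & ref > 0
  o <- obs[ok]
  r <- ref[ok]
  m <- log2((o / n_o) / (r / n_r))
  a <- (log2(o / n_o) + log2(r / n_r)) / 2
  v <- (n_o - o) / (n_o * o) + (n_r - r) / (n_r * r)
  n <- length(m)
  keep <- rank(m) >= floor(n * trim_m) + 1 &
    rank(m) <= n - floor(n * trim_m) &
    rank(a) >= floor(n * trim_a) + 1 &
    rank(a) <= n - floor(n * trim_a)
  2^(sum(m[keep] / v[keep]) / sum(1 / v[keep]))
}

# Naive per-read class assignment + fractional tabulation.
oracle_count_table <- function(hits, reads, ref) {
  pref <- c(mature = 1, hairpin = 2, ncRNA = 3, coding = 4, genome = 5)
  feat <- list()
  ignored <- 0
  unmapped <- 0
  for (i in seq_len(nrow(reads))) {
    h <- hits[hits$uid == reads$uid[i], , drop = FALSE]
    cnt <- reads$count[i]
    if (!nrow(h)) {
      unmapped <- unmapped + cnt
      next
    }
    # promote hairpin hits contained in an extended mature region
    rows <- list()
    for (j in seq_len(nrow(h))) {
      r <- h[j, ]
      promoted <- FALSE
      if (r$seq_class == "hairpin" && r$strand == "+") {
        reg <- ref$mature_regions[ref$mature_regions$hairpin_id ==
                                    r$feature_id, , drop = FALSE]
        for (k in seq_len(nrow(reg))) {
          if (r$offset >= reg$start[k] &&
              r$offset + r$read_len <= reg$end[k]) {
            rows[[length(rows) + 1L]] <-
              c(reg$mature_id[k], "mature",
                r$offset - reg$start[k], r$strand)
            promoted <- TRUE
          }
        }
      }
      if (!promoted)
        rows[[length(rows) + 1L]] <-
          c(r$feature_id, r$seq_class, r$offset, r$strand)
    }
    u <- unique(do.call(rbind, rows))
    best <- min(pref[u[, 2L]])
    u <- u[pref[u[, 2L]] == best, , drop = FALSE]
    share <- cnt / nrow(u)
    if (share < 1) {
      ignored <- ignored + cnt
      next
    }
    for (j in seq_len(nrow(u))) {
      cls <- if (u[j, 2L] == "genome") "intergenic" else u[j, 2L]
      key <- paste(u[j, 1L], cls)
      feat[[key]] <- (feat[[key]] %||% 0) + share
    }
  }
  list(features = feat, ignored = ignored, unmapped = unmapped)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# Small deterministic reference used across tests: two hairpins with
# known arms, one ncRNA, one coding gene that embeds a mature sequence
# (to exercise the class preference), and a genome contig containing
# everything plus spacers.
tiny_ref_fixture <- function(seed = 101) {
  set.seed(seed)
  arm5 <- rand_dna(21)
  loop1 <- rand_dna(22)
  arm3 <- rand_dna(22)
  hp1 <- paste0(arm5, loop1, arm3)
  hp2 <- paste0(rand_dna(20), rand_dna(20), rand_dna(21))
  ann <- data.frame(
    hairpin_id = c("cel-mir-1", "cel-mir-1", "cel-mir-2"),
    mature_id = c("cel-miR-1-5p", "cel-miR-1-3p", "cel-miR-2-3p"),
    start = c(0L, 43L, 40L),
    end = c(21L, 65L, 61L),
    arm = c("5p", "3p", "3p"),
    stringsAsFactors = FALSE)
  nc <- c(`nc-1` = rand_dna(80))
  cds <- c(`cds-1` = paste0(rand_dna(50), arm3, rand_dna(60)))
  genome <- c(chrI = paste0(rand_dna(70), hp1, rand_dna(65), hp2,
                            rand_dna(80), nc[[1]], rand_dna(60),
                            cds[[1]], rand_dna(70)))
  list(ref = build_reference(c(`cel-mir-1` = hp1, `cel-mir-2` = hp2),
                             ann, ncrna = nc, coding = cds,
                             genome = genome),
       hp1 = hp1, hp2 = hp2, ann = ann, arm5 = arm5, arm3 = arm3,
       loop1 = loop1, nc = nc, cds = cds, genome = genome)
}

# Plant k substitutions into a sequence.
mutate_seq <- function(s, k) {
  if (k == 0) return(s)
  pos <- sample.int(nchar(s), k)
  for (p in pos) {
    cur <- substr(s, p, p)
    substr(s, p, p) <- sample(setdiff(c("A", "C", "G", "T"), cur), 1L)
  }
  s
}
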