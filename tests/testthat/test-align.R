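test_that("an exact mature read maps with zero mismatches", {
  fx <- tiny_ref_fixture()
  read <- substr(fx$arm5, 1, 18) # unique to hairpin 1 / its 5p mature
  h <- map_read(read, fx$ref)
  expect_gt(nrow(h), 0)
  m <- h[h$feature_id == "cel-miR-1-5p", ]
  expect_identical(nrow(m), 1L)
  expect_identical(m$mismatches, 0L)
  expect_identical(m$offset, 0L) # 5' arm starts at 0; extension clipped
  # also present inside the hairpin and the genome, never with fewer mm
  expect_true(all(h$mismatches >= 0 & h$mismatches <= 2))
})

test_that("a read far from every reference window is unmapped", {
  fx <- tiny_ref_fixture()
  # alternating homopolymer unlikely in random ACGT; verify with oracle
  read <- strrep("AC", 10)
  expect_identical(nrow(oracle_scan_hits(read, fx$ref)), 0L)
  expect_identical(nrow(map_read(read, fx$ref)), 0L)
})

test_that("map_read equals the exhaustive sliding-window oracle", {
  set.seed(77)
  cfg <- sim_config(seed = 78, n_mirnas = 8, n_ncrna = 4, n_coding = 2)
  sr <- make_reference(cfg)
  ref <- build_reference(sr$hairpins, sr$matures, sr$ncrna, sr$coding,
                         sr$genome)
  idx <- align_index(ref)
  feats <- ref$seqs[ref$features$seq_class != "genome"]
  for (i in 1:60) {
    src <- sample(feats, 1)
    l <- sample(16:24, 1)
    if (nchar(src) < l) next
    off <- sample.int(nchar(src) - l + 1L, 1L)
    read <- mutate_seq(substr(src, off, off + l - 1L), sample(0:3, 1))
    got <- map_read(read, idx)
    want <- oracle_scan_hits(read, ref)
    rownames(got) <- rownames(want) <- NULL
    attr(got, "overflow") <- NULL
    expect_identical(got, want, info = read)
  }
  # purely random reads too (mostly unmapped)
  for (i in 1:15) {
    read <- rand_dna(sample(16:28, 1))
    got <- map_read(read, idx)
    attr(got, "overflow") <- NULL
    rownames(got) <- NULL
    expect_identical(got, oracle_scan_hits(read, ref))
  }
})

test_that("reverse-complement hits are reported for the genome only", {
  fx <- tiny_ref_fixture()
  read <- revcomp_chr(substr(fx$nc[[1]], 20, 40))
  h <- map_read(read, fx$ref)
  expect_true(all(h$strand[h$seq_class == "genome"] == "-"))
  expect_false(any(h$seq_class == "ncRNA")) # sense-only for transcripts
  # with a both-strands search the ncRNA hit appears
  h2 <- map_read(read, fx$ref,
                 rc_classes = c("mature", "hairpin", "ncRNA", "coding",
                                "genome"))
  expect_true(any(h2$seq_class == "ncRNA" & h2$strand == "-"))
})

test_that("raising the mismatch budget never removes a hit", {
  set.seed(13)
  cfg <- sim_config(seed = 14, n_mirnas = 5)
  sr <- make_reference(cfg)
  ref <- build_reference(sr$hairpins, sr$matures, sr$ncrna, sr$coding,
                         sr$genome)
  idx <- align_index(ref)
  for (i in 1:20) {
    src <- sample(ref$seqs, 1)
    l <- min(20L, nchar(src))
    read <- mutate_seq(substr(src, 1, l), sample(0:2, 1))
    key <- function(h) paste(h$feature_id, h$offset, h$strand)
    h0 <- map_read(read, idx, max_mm = 0)
    h1 <- map_read(read, idx, max_mm = 1)
    h2 <- map_read(read, idx, max_mm = 2)
    expect_true(all(key(h0) %in% key(h1)))
    expect_true(all(key(h1) %in% key(h2)))
  }
})

test_that("hit order is invariant to feature order in the index", {
  fx <- tiny_ref_fixture()
  set.seed(3)
  perm <- sample(length(fx$ref$seqs))
  shuf <- fx$ref
  shuf$seqs <- shuf$seqs[perm]
  shuf$features <- shuf$features[perm, ]
  read <- substr(fx$hp1, 25, 44) # loop region read
  a <- map_read(read, fx$ref)
  b <- map_read(read, shuf)
  rownames(a) <- rownames(b) <- NULL
  expect_identical(a, b)
})

test_that("hit sets are capped at max_hits with an overflow flag", {
  ref <- build_reference(
    hairpins = c(`cel-mir-1` = paste0(rand_dna(20), strrep("A", 40),
                                      rand_dna(20))),
    matures = data.frame(hairpin_id = "cel-mir-1",
                         mature_id = "cel-miR-1-5p",
                         start = 0L, end = 20L, arm = "5p"),
    genome = c(chrI = strrep("A", 200)))
  h <- map_read(strrep("A", 16), ref, max_hits = 100)
  expect_identical(nrow(h), 100L)
  expect_true(attr(h, "overflow"))
  h2 <- map_read(strrep("A", 16), ref, max_hits = 1000)
  expect_false(attr(h2, "overflow"))
  expect_gt(nrow(h2), 100)
})

test_that("map_all preserves read order and summarises mapping", {
  fx <- tiny_ref_fixture()
  reads <- data.frame(
    uid = c("u1", "u2", "u3"),
    sequence = c(substr(fx$arm5, 1, 18), strrep("AC", 10),
                 substr(fx$cds[[1]], 10, 30)),
    count = c(5L, 2L, 3L), stringsAsFactors = FALSE)
  hits <- map_all(reads, fx$ref)
  s <- attr(hits, "summary")
  expect_identical(s$n_reads, 3L)
  expect_identical(s$n_unmapped, 1L)
  expect_identical(attr(hits, "unmapped_uids"), "u2")
  expect_identical(unique(hits$uid), c("u1", "u3"))

  empty <- map_all(reads[0, ], fx$ref)
  expect_identical(nrow(empty), 0L)
  expect_identical(attr(empty, "summary")$n_reads, 0L)
})
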