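test_that("class preference: mature beats coding, loop reads stay hairpin", {
  fx <- tiny_ref_fixture()
  # arm3 is embedded in cds-1, so this read hits mature, hairpin, coding
  # and genome; the assignment must be mature and only mature hits kept
  read <- substr(fx$arm3, 1, 20)
  h <- map_read(read, fx$ref)
  h$read_len <- nchar(read)
  expect_true(any(h$seq_class == "coding"))
  asn <- resolve_class(h, fx$ref)
  expect_identical(asn$assigned_class, "mature")
  expect_true(all(asn$hits$seq_class == "mature"))

  # a loop read maps outside the extended mature intervals -> hairpin
  loop_read <- substr(fx$hp1, 28, 45) # inside the 22 nt loop
  hl <- map_read(loop_read, fx$ref)
  hl$read_len <- nchar(loop_read)
  asn2 <- resolve_class(hl, fx$ref)
  expect_identical(asn2$assigned_class, "hairpin")

  # empty hit set -> unmapped
  expect_identical(resolve_class(h[0, ], fx$ref)$assigned_class,
                   "unmapped")
})

test_that("a hairpin hit inside an extended mature region is promoted", {
  fx <- tiny_ref_fixture()
  # read = first 18 nt of the extended 3p mature (starts at 43-3=40)
  read <- substr(fx$hp1, 41, 58)
  h <- map_read(read, fx$ref)
  h$read_len <- nchar(read)
  asn <- resolve_class(h, fx$ref)
  expect_identical(asn$assigned_class, "mature")
  expect_true("cel-miR-1-3p" %in% asn$hits$feature_id)
  # the promoted hairpin location and the direct mature hit collapse
  # into a single location (no double counting)
  expect_identical(sum(asn$hits$feature_id == "cel-miR-1-3p"), 1L)
})

test_that("fractional division and the below-1 drop rule", {
  mk <- function(n) list(
    assigned_class = "mature",
    hits = data.frame(uid = "u", feature_id = paste0("m", seq_len(n)),
                      seq_class = "mature", offset = 0L, strand = "+",
                      mismatches = 0L, read_len = 20L,
                      stringsAsFactors = FALSE))
  two <- partition_counts(mk(2), 10)
  expect_identical(two$count, c(5, 5))
  dropped <- partition_counts(mk(2), 1)
  expect_identical(nrow(dropped), 0L)
  one <- partition_counts(mk(1), 7)
  expect_identical(one$count, 7)
  # every per-feature contribution is either 0 or >= 1
  for (n in 1:6) for (cnt in c(1, 2, 3, 7)) {
    p <- partition_counts(mk(n), cnt)
    expect_true(nrow(p) == 0 || all(p$count * 0 + cnt / n >= 1))
  }
})

test_that("adding a lower-preference hit never changes the counts", {
  fx <- tiny_ref_fixture()
  read <- substr(fx$arm5, 1, 18)
  h <- map_read(read, fx$ref)
  h$read_len <- nchar(read)
  h$uid <- "u"
  base <- h[h$seq_class == "mature", , drop = FALSE]
  extra <- rbind(base, data.frame(feature_id = "nc-1", seq_class = "ncRNA",
                                  offset = 3L, strand = "+",
                                  mismatches = 0L, read_len = 18L,
                                  uid = "u"))
  a <- partition_counts(resolve_class(base, fx$ref), 8)
  b <- partition_counts(resolve_class(extra, fx$ref), 8)
  expect_identical(a, b)
})

test_that("count table equals the naive per-read oracle and conserves reads", {
  cfg <- sim_config(seed = 201, n_mirnas = 6, n_ncrna = 4, n_coding = 2,
                    reads_per_library = 1500)
  sr <- make_reference(cfg)
  ref <- build_reference(sr$hairpins, sr$matures, sr$ncrna, sr$coding,
                         sr$genome)
  prepA <- preprocess_reads(simulate_library(sr, "A", seed = 202)$sequences)
  prepB <- preprocess_reads(simulate_library(sr, "B", seed = 203)$sequences)
  hits <- list(A = map_all(prepA$reads, ref),
               B = map_all(prepB$reads, ref))
  reads <- list(A = prepA$reads, B = prepB$reads)
  tab <- build_count_table(hits, reads, ref)

  for (lib in c("A", "B")) {
    want <- oracle_count_table(hits[[lib]], reads[[lib]], ref)
    got <- setNames(tab[[lib]], paste(tab$feature_id, tab$seq_class))
    got <- got[got > 0]
    expect_identical(sort(names(got)), sort(names(want$features)))
    for (k in names(want$features))
      expect_equal(got[[k]], want$features[[k]], tolerance = 1e-12)
    # conservation: table + ignored + unmapped = collapsed totals
    expect_equal(sum(tab[[lib]]) + attr(tab, "ignored")[[lib]] +
                   attr(tab, "class_totals")["unmapped", lib],
                 sum(reads[[lib]]$count), tolerance = 1e-9)
    expect_equal(want$ignored, attr(tab, "ignored")[[lib]])
  }
  # a read's count never splits across classes: per-uid retained hits
  # are single-class by construction; spot-check via the class totals
  comp <- class_composition(tab)
  expect_equal(colSums(comp), c(A = 1, B = 1), tolerance = 1e-9)
})

test_that("class composition recovers a pure-mature mix exactly", {
  cfg <- sim_config(seed = 210, n_mirnas = 5, reads_per_library = 800,
                    class_mix = c(mature = 1, hairpin_loop = 0, ncRNA = 0,
                                  coding = 0, intergenic = 0))
  sr <- make_reference(cfg)
  ref <- build_reference(sr$hairpins, sr$matures, sr$ncrna, sr$coding,
                         sr$genome)
  prep <- preprocess_reads(simulate_library(sr, "A", seed = 211)$sequences)
  hits <- map_all(prep$reads, ref)
  tab <- build_count_table(list(A = hits), list(A = prep$reads), ref)
  comp <- class_composition(tab)
  expect_equal(unname(comp["mature", "A"]), 1, tolerance = 1e-9)
})

test_that("top shares rank matures by their share of miRNA counts", {
  fx <- tiny_ref_fixture()
  tab <- data.frame(feature_id = c("cel-miR-1-5p", "cel-miR-1-3p", "nc-1"),
                    seq_class = c("mature", "mature", "ncRNA"),
                    A = c(75, 25, 40))
  attr(tab, "libs") <- "A"
  attr(tab, "lib_totals") <- c(A = 140)
  class(tab) <- c("mir_count_table", "data.frame")
  s <- top_mirna_shares(tab)
  expect_identical(s$feature_id, c("cel-miR-1-5p", "cel-miR-1-3p"))
  expect_equal(s$share_pct, c(75, 25))
  expect_lte(sum(top_mirna_shares(tab, n = 1)$share_pct), 100)
})

test_that("duplicate library labels are rejected", {
  fx <- tiny_ref_fixture()
  reads <- data.frame(uid = "u1", sequence = substr(fx$arm5, 1, 18),
                      count = 2L)
  h <- map_all(reads, fx$ref)
  expect_error(build_count_table(setNames(list(h, h), c("A", "A")),
                                 setNames(list(reads, reads), c("A", "A")),
                                 fx$ref), "named")
})
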