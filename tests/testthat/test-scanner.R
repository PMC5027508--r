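test_that("sequence records enforce the ACGTN alphabet and FASTA round-trips", {
  expect_warning(r <- seq_record("x", "ACGTRYacgt"), "mapped to N")
  expect_identical(r$residues, "ACGTNNACGT")
  expect_error(seq_record("x", ""), "non-empty")

  recs <- list(seq_record("a", "ACGTACGT", description = "first"),
               seq_record("b", strrep("ACGT", 30)))
  path <- withr::local_tempfile(fileext = ".fasta")
  write_sequences(recs, path)
  back <- read_sequences(path)
  expect_equal(vapply(back, function(r) r$id, ""), c("a", "b"))
  expect_equal(vapply(back, function(r) r$residues, ""),
               vapply(recs, function(r) r$residues, ""))
  expect_equal(back[[1]]$description, "first")
})

test_that("anchor pairs enforce the non-G boundary invariant on the G-rich strand", {
  a <- toy_anchors()
  expect_identical(a$flank5, reverse_complement("TCATCA"))
  expect_identical(a$flank3, reverse_complement("ACTACT"))
  # a G abutting the tract (after strand conversion) would merge with it
  expect_error(anchor_pair("ACTACC", "TCATCA", "reference"), "non-G")
  expect_error(anchor_pair("ACTACT", "CCATCA", "reference"), "non-G")
  expect_error(anchor_pair("ACG", "TCA", "G-rich"), "non-G")
  expect_error(anchor_pair("", "TCATCA"), "non-empty")
})

test_that("packaged rCRS anchors match the reference locus", {
  a <- rcrs_anchors()
  ctx <- rcrs_context()
  # flank + tract + flank reassembles the anchor region of the context
  region <- substr(ctx$residues, 294 - 240, 325 - 240)
  expect_identical(reverse_complement(region),
                   paste0(a$flank5, tract_sequence(parse_nomenclature("G5AG7")),
                          a$flank3))
})

test_that("search-string library enumerates the grid with exclusive strings", {
  a <- toy_anchors()
  lib <- build_search_strings(a, m_range = 1:12, n_range = 1:12,
                              interrupt_set = "A")
  expect_equal(nrow(lib), 144L)  # 12 x 12 grid
  expect_true(all(nchar(lib$string) >= 25L))
  # deterministic ordering by (interrupt, m, n)
  expect_identical(lib$variant[1:3], c("G1AG1", "G1AG2", "G1AG3"))
  # no string contains another
  for (i in sample(seq_len(nrow(lib)), 20))
    expect_equal(sum(vapply(lib$string,
                            function(s) grepl(lib$string[i], s, fixed = TRUE),
                            TRUE)), 1L)

  empty <- build_search_strings(a, m_range = integer(0),
                                n_range = integer(0),
                                interrupt_set = character(0))
  expect_equal(nrow(empty), 0L)
})

test_that("short strings are extended into context and the extension is logged", {
  a <- rcrs_anchors()
  expect_message(lib <- build_search_strings(a), "extended symmetrically")
  expect_true(all(nchar(lib$string) >= 25L))
  expect_gt(sum(lib$extended > 0), 0)
  expect_true(grepl("GGGGGAGGGGGGG",
                    lib$string[lib$variant == "G5AG7"], fixed = TRUE))
  # extension fails loudly when context is exhausted
  bare <- anchor_pair("ACT", "TCA", "reference")
  expect_error(build_search_strings(bare, m_range = 1, n_range = 1),
               "context exhausted")
})

test_that("scanner finds planted variants on either strand and at the origin junction", {
  a <- toy_anchors()
  lib <- build_search_strings(a, m_range = 1:8, n_range = 1:8)
  rec <- plant_record("G6AG8", a)
  hits <- scan_record(rec, lib)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$variant, "G6AG8")
  expect_equal(hits$strand, "+")
  expect_identical(substr(rec$residues, hits$start, hits$end),
                   lib$string[lib$variant == "G6AG8"])

  # reference-strand (C-rich) record: same variant, opposite strand
  rc <- plant_record("G6AG8", a, on_reference = TRUE)
  hits_rc <- scan_record(rc, lib)
  expect_equal(hits_rc$variant, "G6AG8")
  expect_equal(hits_rc$strand, "-")

  # rotate a circular record so the cut falls inside the tract
  s <- rec$residues
  cut <- nchar(a$context5) + nchar(a$flank5) + 7L
  rot <- paste0(substring(s, cut + 1L), substring(s, 1L, cut))
  circ <- seq_record("circ", rot, circular = TRUE)
  expect_equal(scan_record(circ, lib)$variant, "G6AG8")
  # the same rotated record scanned as linear misses the split locus
  expect_equal(nrow(scan_record(seq_record("lin", rot), lib)), 0L)
})

test_that("records without the locus and N-containing windows yield no hits", {
  a <- toy_anchors()
  lib <- build_search_strings(a, m_range = 1:4, n_range = 1:4)
  expect_equal(nrow(scan_record(seq_record("no", strrep("ACGT", 30)), lib)),
               0L)
  withN <- seq_record("n", sub("AGG", "ANG",
                               plant_record("G3AG3", a)$residues))
  expect_equal(nrow(scan_record(withN, lib)), 0L)
})

test_that("classifier names planted loci, flags complex segments, reports absent", {
  a <- toy_anchors()
  expect_equal(as.character(classify_locus(plant_record("G6AG7", a), a)),
               "G6AG7")
  expect_equal(as.character(classify_locus(plant_record("G13", a), a)),
               "G13")
  mk <- function(seg) seq_record("x", paste0(a$context5, a$flank5, seg,
                                             a$flank3, a$context3))
  expect_equal(as.character(classify_locus(mk("GGAGGAGG"), a)), "complex")
  expect_equal(as.character(classify_locus(mk("GGGNGGG"), a)), "complex")
  expect_equal(as.character(classify_locus(
    seq_record("y", strrep("ACGT", 30)), a)), "absent")
  # reference-strand record classifies identically
  expect_equal(as.character(classify_locus(
    plant_record("G4AG5", a, on_reference = TRUE), a)), "G4AG5")
})

test_that("multiple loci in one record are all classified with a warning", {
  a <- toy_anchors()
  one <- paste0(a$flank5, "GGGAGG", a$flank3)
  two <- seq_record("dup", paste0(a$context5, one, "ACGTACGT", one,
                                  a$context3))
  expect_warning(cls <- classify_locus(two, a), "2 CSB 2 loci")
  expect_equal(nrow(attr(cls, "loci")), 2L)
  expect_equal(as.character(cls), "G3AG2")
})

test_that("count_hits tallies per locus and respects strict per-record counting", {
  a <- toy_anchors()
  lib <- build_search_strings(a, m_range = 1:8, n_range = 1:8)
  recs <- c(replicate(5, plant_record("G5AG5", a, id = "r"),
                      simplify = FALSE),
            list(plant_record("G2AG3", a)))
  recs <- lapply(seq_along(recs), function(i) {
    r <- recs[[i]]; r$id <- paste0("r", i); r
  })
  fm <- count_hits(recs, lib)
  expect_equal(fm$counts$A["5", "5"], 5L)
  expect_equal(fm$counts$A["2", "3"], 1L)
  expect_equal(fm$total_hits, 6L)

  # two loci in one record; tracts long enough that no flank extension is
  # involved (extended strings reach into template context that a second,
  # mid-record locus does not carry)
  dup <- seq_record("dup", paste0(
    a$context5, a$flank5, "GGGGGGAGGGGGG", a$flank3, "ACGTACGT",
    a$flank5, "GGGGGGGAGGGGGGG", a$flank3, a$context3))
  expect_warning(fm2 <- count_hits(list(dup), lib), "multiple CSB 2 loci")
  expect_equal(fm2$total_hits, 2L)
  fm3 <- count_hits(list(dup), lib, strict_per_record = TRUE)
  expect_equal(fm3$total_hits, 1L)
})

test_that("empty record sets give an all-zero matrix", {
  lib <- build_search_strings(toy_anchors(), m_range = 1:3, n_range = 1:3)
  fm <- count_hits(list(), lib)
  expect_equal(fm$total_hits, 0)
})

test_that("scanner counts are invariant under reverse-complementing every record", {
  a <- toy_anchors()
  lib <- build_search_strings(a, m_range = 1:6, n_range = 1:6)
  set.seed(21)
  variants <- sprintf("G%dAG%d", sample(1:6, 8, TRUE), sample(1:6, 8, TRUE))
  recs <- lapply(seq_along(variants), function(i)
    plant_record(variants[i], a, id = paste0("v", i)))
  flipped <- lapply(recs, function(r)
    seq_record(r$id, reverse_complement(r$residues)))
  fm1 <- count_hits(recs, lib)
  fm2 <- count_hits(flipped, lib)
  expect_equal(fm1$counts, fm2$counts)
})
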