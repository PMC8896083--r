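classes <- default_motif_classes()
strict <- anchor_alphabet("strict")

test_that("anchor enumeration reproduces known domain tallies", {
  abca7_1 <- "LQALLLKRFLLARRSRRGLF"
  h10 <- enumerate_anchor_motifs(abca7_1, classes[["1-10"]], strict)
  expect_equal(nrow(h10), 3L)
  expect_equal(h10$anchor_positions, c("1,10", "10,19", "11,20"))

  h510 <- enumerate_anchor_motifs(abca7_1, classes[["1-5-10"]], strict)
  expect_equal(nrow(h510), 1L)
  expect_equal(h510$anchor_positions, "1,5,10")

  abca7_2 <- "QGLKTKKWVNEVRYGGFSLG"
  expect_equal(nrow(enumerate_anchor_motifs(abca7_2, classes[["1-10"]])), 2L)

  cr1 <- "VVTYRCNLGSRGRKVFEL"
  h16 <- enumerate_anchor_motifs(cr1, classes[["1-16"]], strict)
  expect_equal(h16$anchor_positions, "1,16")
})

test_that("sequences without anchors, or shorter than the span, yield no hits", {
  for (k in classes) {
    expect_equal(nrow(enumerate_anchor_motifs(strrep("K", 12), k)), 0L)
    expect_equal(nrow(enumerate_anchor_motifs("", k)), 0L)
    expect_equal(nrow(enumerate_anchor_motifs("LLL", k)), 0L)
  }
  # X never anchors, even in a custom alphabet attempt
  expect_error(anchor_alphabet("custom:LX"), "non-standard")
  expect_equal(nrow(enumerate_anchor_motifs(strrep("X", 20),
                                            classes[["1-10"]])), 0L)
})

test_that("enumeration equals the brute-force oracle on random sequences", {
  set.seed(101)
  alphabets <- list(strict, anchor_alphabet("strict+M"),
                    anchor_alphabet("strict+A"))
  for (i in 1:300) {
    seq <- random_aa_seq(sample(0:40, 1), c(AA_STANDARD, "X"))
    k <- classes[[sample(length(classes), 1)]]
    ab <- alphabets[[sample(3, 1)]]
    got <- enumerate_anchor_motifs(seq, k, ab)
    expect_identical(got$start,
                     brute_anchor_motifs(seq, k$offsets, ab$residues))
  }
})

test_that("hit count is monotone in the anchor alphabet", {
  set.seed(102)
  small <- anchor_alphabet("strict")
  big <- anchor_alphabet("custom:FILVWMAY")
  for (i in 1:100) {
    seq <- random_aa_seq(sample(10:60, 1))
    for (k in classes) {
      expect_lte(nrow(enumerate_anchor_motifs(seq, k, small)),
                 nrow(enumerate_anchor_motifs(seq, k, big)))
    }
  }
})

test_that("two-anchor classes are symmetric under sequence reversal", {
  set.seed(103)
  two_anchor <- classes[c("1-10", "1-12", "1-14", "1-16")]
  for (i in 1:100) {
    seq <- random_aa_seq(sample(10:60, 1))
    rev_seq <- paste(rev(strsplit(seq, "")[[1]]), collapse = "")
    for (k in two_anchor) {
      expect_equal(nrow(enumerate_anchor_motifs(rev_seq, k)),
                   nrow(enumerate_anchor_motifs(seq, k)))
    }
  }
})

test_that("multi-anchor hits imply their two-anchor outer class", {
  set.seed(104)
  for (i in 1:100) {
    # anchor-rich alphabet subset makes sub-motif hits common
    seq <- random_aa_seq(sample(14:40, 1), c("L", "F", "V", "K", "A", "G"))
    h510 <- enumerate_anchor_motifs(seq, classes[["1-5-10"]])
    h10 <- enumerate_anchor_motifs(seq, classes[["1-10"]])
    expect_true(all(h510$start %in% h10$start))
    h5814 <- enumerate_anchor_motifs(seq, classes[["1-5-8-14"]])
    h14 <- enumerate_anchor_motifs(seq, classes[["1-14"]])
    expect_true(all(h5814$start %in% h14$start))
  }
})

test_that("a planted motif in non-anchor filler yields exactly one hit", {
  filler <- strrep("K", 30)
  rec <- protein_record("k30", filler)
  set.seed(105)
  for (k in classes) {
    planted <- plant_motif(rec, k, 5L, strict)
    hits <- enumerate_anchor_motifs(planted$record, k, strict)
    expect_equal(hits$start, 5L)
    # planted into a window, scanned with a disjoint alphabet: nothing
    disjoint <- anchor_alphabet("custom:M")
    expect_equal(nrow(enumerate_anchor_motifs(planted$record, k, disjoint)),
                 0L)
  }
})

test_that("scan_all_classes keys every class and preserves the total", {
  trem2 <- "RVVSTHNLWLLSFLRRWNG"
  roster <- classes[c("1-10", "1-12", "1-14", "1-16")]
  scans <- scan_all_classes(trem2, roster)
  expect_named(scans, names(roster))
  counts <- count_by_class(scans)
  expect_equal(unname(counts[["1-10"]]), 2L)
  expect_equal(sum(counts), sum(vapply(scans, nrow, integer(1))))

  # empty sequence: all counts zero, no error
  expect_equal(sum(count_by_class(scan_all_classes("", roster))), 0L)

  dup <- list(classes[["1-10"]], classes[["1-10"]])
  expect_error(scan_all_classes(trem2, dup), "duplicate")
})

test_that("count_by_class partitions hits and pads requested classes", {
  mixed <- rbind(enumerate_anchor_motifs("LQALLLKRFLLARRSRRGLF",
                                         classes[["1-10"]]),
                 enumerate_anchor_motifs("LQALLLKRFLLARRSRRGLF",
                                         classes[["1-5-10"]]))
  counts <- count_by_class(mixed, classes = c("1-10", "1-5-10", "1-16"))
  expect_equal(unname(counts), c(3L, 1L, 0L))
  expect_equal(sum(counts), nrow(mixed))
  empty <- count_by_class(mixed[0, , drop = FALSE], classes = c("1-10"))
  expect_equal(unname(empty), 0L)
})

test_that("IQ scanning separates canonical from relaxed variants", {
  # reported IQ-like motif: fails the canonical pattern (W at 1, L at 11)
  iq_like <- scan_iq("WQKAERGDILLSSL")
  expect_equal(nrow(iq_like), 1L)
  expect_equal(iq_like$variant, "IQ-like")
  expect_equal(iq_like$start, 1L)
  expect_false(brute_iq_canonical_at("WQKAERGDILLSSL", 1L))

  canon <- scan_iq("IQAAARGAAAKAAF")
  expect_equal(canon$variant, "IQ")
  expect_true(brute_iq_canonical_at("IQAAARGAAAKAAF", 1L))

  expect_equal(nrow(scan_iq("AAAAAAAA")), 0L)
})

test_that("IQ scanning equals the position-wise oracle on random sequences", {
  set.seed(106)
  for (i in 1:150) {
    # Q/R/K/G-rich alphabet so that matches actually occur
    seq <- random_aa_seq(sample(7:40, 1),
                         c("I", "Q", "R", "K", "G", "A", "L", "W"))
    hits <- scan_iq(seq)
    canonical <- which(vapply(seq_len(nchar(seq)), function(j) {
      brute_iq_canonical_at(seq, j)
    }, logical(1)))
    relaxed_only <- setdiff(which(vapply(seq_len(nchar(seq)), function(j) {
      brute_iq_relaxed_at(seq, j)
    }, logical(1))), canonical)
    expect_identical(hits$start[hits$variant == "IQ"], as.integer(canonical))
    expect_identical(hits$start[hits$variant == "IQ-like"],
                     as.integer(relaxed_only))
  }
})

test_that("custom motif classes are supported and validated", {
  k <- motif_class("1-8-14", c(0, 7, 13))
  expect_equal(k$span, 14L)
  expect_equal(nrow(enumerate_anchor_motifs(strrep("L", 14), k)), 1L)
  expect_error(motif_class("bad", c(1, 5)), "start at 0")
  expect_error(motif_class("bad", c(0, 5, 5)), "strictly increasing")
})
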