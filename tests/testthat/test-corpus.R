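corpus <- load_cambd_corpus()

test_that("the corpus ships 13 domain sequences across 11 proteins", {
  expect_equal(nrow(corpus), 14L)  # 13 with sequence + CD33 counts-only
  expect_equal(sum(!is.na(corpus$sequence)), 13L)
  expect_equal(length(unique(corpus$protein)), 11L)
  tab <- table(corpus$protein[!is.na(corpus$sequence)])
  expect_equal(as.vector(tab[c("ABCA7", "MS4A4E", "NLRP3")]), c(2L, 2L, 2L))

  cd33 <- corpus[corpus$protein == "CD33", ]
  expect_true(is.na(cd33$sequence))
  expect_equal(cd33$notes, "sequence-unavailable")
  expect_equal(cd33$reported_1_10, 2L)
})

test_that("fixture domain strings are byte-identical to the frozen copies", {
  keyed <- paste(corpus$protein, corpus$domain_label)
  for (nm in names(CORPUS_DOMAIN_STRINGS)) {
    expect_identical(corpus$domain_string[keyed == nm],
                     unname(CORPUS_DOMAIN_STRINGS[nm]))
  }
})

test_that("coordinate typos are flagged, consistent entries are not", {
  flag <- function(protein, label) {
    corpus$coordinate_flag[corpus$protein == protein &
                           corpus$domain_label == label]
  }
  expect_equal(flag("CLU", "CaMBD1"), "inconsistent")     # 33..352 for a 20-mer
  expect_equal(flag("MS4A4E", "CaMBD1"), "inconsistent")  # reversed 28..6
  expect_equal(flag("NLRP3", "CaMBD1"), "inconsistent")   # 26-span for a 27-mer
  expect_equal(flag("PILRA", "CaMBD1"), "inconsistent")   # 22-span for a 21-mer
  expect_equal(flag("ABCA7", "CaMBD1"), "consistent")
  expect_equal(flag("TREM2", "CaMBD1"), "consistent")
  consistent <- corpus$coordinate_flag == "consistent"
  expect_equal(sum(consistent), 9L)
})

test_that("concordance computes every stated count and matches the oracle", {
  conc <- suppressMessages(motif_concordance())
  # one row per stated (entry, class) count; no third state
  reported_cols <- paste0("reported_", gsub("-", "_", CORPUS_CLASSES))
  n_stated <- sum(!is.na(unlist(corpus[!is.na(corpus$sequence),
                                       reported_cols])))
  expect_equal(nrow(conc), n_stated)
  expect_type(conc$match, "logical")
  expect_false(anyNA(conc$match))

  # every computed value equals the independent brute-force oracle
  roster <- default_motif_classes()
  for (i in seq_len(nrow(conc))) {
    seq <- corpus$sequence[corpus$protein == conc$protein[i] &
                           corpus$domain_label == conc$domain_label[i]]
    oracle <- length(brute_anchor_motifs(seq, roster[[conc$class[i]]]$offsets,
                                         c("F", "I", "L", "V", "W")))
    expect_equal(conc$computed[i], oracle)
  }
})

test_that("known agreements hold and known disagreements are surfaced", {
  conc <- suppressMessages(motif_concordance())
  row <- function(protein, label, class) {
    conc[conc$protein == protein & conc$domain_label == label &
         conc$class == class, ]
  }
  abca7 <- row("ABCA7", "CaMBD1", "1-10")
  expect_equal(abca7$computed, 3L)
  expect_true(abca7$match)
  ms4a6a <- row("MS4A6A", "CaMBD1", "1-12")
  expect_equal(ms4a6a$computed, 2L)
  expect_true(ms4a6a$match)

  trem2 <- row("TREM2", "CaMBD1", "1-12")
  expect_equal(trem2$reported, 1L)
  expect_equal(trem2$computed, 2L)
  expect_false(trem2$match)

  # the full set of counts not attainable under the uniform strict alphabet
  mism <- conc[!conc$match, ]
  mism_keys <- paste(mism$protein, mism$domain_label, mism$class)
  for (key in c("TREM2 CaMBD1 1-12", "NLRP3 CaMBD2 1-16",
                "MS4A6A CaMBD1 1-10", "PILRA CaMBD1 1-10",
                "EPHA1 CaMBD1 1-12", "MS4A4E CaMBD2 1-12",
                "MS4A4E CaMBD2 1-14", "CH3L1 CaMBD1 1-10",
                "CH3L1 CaMBD1 1-16")) {
    expect_true(key %in% mism_keys, label = paste("mismatch surfaced:", key))
  }
})

test_that("the reported IQ-like motif is reproduced", {
  iq <- load_iq_corpus()
  expect_equal(iq$sequence, "WQKAERGDILLSSL")
  expect_equal(iq$start, 322L)
  expect_equal(iq$end, 335L)
  hits <- scan_iq(iq$sequence)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$variant, "IQ-like")
})

test_that("inventory union is 11 + 13 = 24 and order-independent", {
  inv <- cambp_inventory()
  expect_equal(inv$n_scanned, 11L)
  expect_equal(inv$n_prior, 13L)
  expect_equal(inv$n_union, 24L)
  expect_length(inv$duplicates, 0L)

  shuffled <- cambp_inventory(
    scanned = sample(unique(corpus$protein)),
    prior = sample(load_prior_cambps()$protein))
  expect_identical(shuffled$proteins, inv$proteins)

  # idempotence: repeated names collapse
  rep_inv <- cambp_inventory(scanned = rep(unique(corpus$protein), 2))
  expect_equal(rep_inv$n_scanned, 11L)

  # a protein in both lists is flagged and counted once
  dup <- cambp_inventory(scanned = c("APOE", "TREM2"),
                         prior = c("APOE", "BACE1"))
  expect_equal(dup$duplicates, "APOE")
  expect_equal(dup$n_union, 3L)
})

test_that("the disease matrix encodes exactly the stated links", {
  mat <- disease_matrix()
  expect_equal(sum(mat["APOE", c("AD", "ALS", "FTD", "LBD", "PD")]), 5L)
  expect_equal(unname(mat["APOE", c("HD", "MS")]), c(0L, 0L))
  expect_equal(colnames(mat)[mat["CLU", ] == 1], c("AD", "PD", "MS"))
  expect_equal(colnames(mat)[mat["PP2B", ] == 1],
               c("AD", "ALS", "HD", "PD", "MS"))
  expect_equal(attr(mat, "row_marginals")[["PP2B"]], 5L)

  # unverified (figure-only) links are excluded from the matrix
  links <- rbind(load_disease_links(),
                 data.frame(protein = "BIN1", disease = "AD",
                            status = "unverified"))
  mat2 <- disease_matrix(links)
  expect_false("BIN1" %in% rownames(mat2))
  expect_identical(unclass(mat2), unclass(mat))

  expect_error(disease_matrix(data.frame(protein = "X", disease = "flu",
                                         status = "stated")),
               "unknown disease")
})
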