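# Count tables, consensus and conservation summaries.

fake_screen <- function(id, counts) {
  base <- stats::setNames(integer(8),
                          c("defensins", "thionins", "cyclotides", "snakins",
                            "hevein-like", "lipid-transfer", "cysteine-rich",
                            "unknown"))
  base[names(counts)] <- counts
  structure(list(transcriptome_id = id,
                 peptides = data.frame(), hits = data.frame(),
                 rejections = data.frame(), counts = base),
            class = "cysmotif_screen")
}

test_that("family_count_table adds a totals row in fixed column order", {
  t1 <- fake_screen("s1", c(defensins = 3L, snakins = 1L))
  t2 <- fake_screen("s2", c(defensins = 4L, `cysteine-rich` = 7L))
  tab <- family_count_table(list(t1, t2))
  expect_equal(colnames(tab),
               c("transcriptome", "Defensins", "Thionins", "Cyclotides",
                 "Snakins", "Hevein-like", "LTP", "Cysteine-rich", "Unknown"))
  expect_equal(nrow(tab), 3L)
  expect_equal(tab$Defensins, c(3, 4, 7))
  expect_equal(tab$Snakins, c(1, 0, 1))
  expect_equal(tab$transcriptome[3], "total")
  empty <- fake_screen("s3", integer(0))
  expect_equal(unlist(family_count_table(empty)[1, -1]),
               stats::setNames(rep(0, 8), colnames(tab)[-1]))
})

test_that("normalized counts divide by family size and exclude small families", {
  res <- list(fake_screen("a", c(defensins = 9L)),
              fake_screen("b", c(defensins = 3L)),
              fake_screen("c", c(defensins = 5L)),
              fake_screen("d", c(defensins = 0L)),
              fake_screen("e", c(defensins = 2L)),
              fake_screen("f", c(defensins = 4L)))
  meta <- data.frame(
    transcriptome_id = c("a", "b", "c", "d", "e", "f"),
    plant_family = c("Dunaliellaceae", rep("Poaceae", 5)))
  # Dunaliellaceae has one sample -> rate 9, but excluded at min_samples 5
  out5 <- normalized_family_counts(res, meta, min_samples = 5)
  expect_equal(out5$plant_family, "Poaceae")
  expect_equal(out5$Defensins, (3 + 5 + 0 + 2 + 4) / 5)
  out1 <- normalized_family_counts(res, meta, min_samples = 1)
  expect_equal(out1$Defensins[out1$plant_family == "Dunaliellaceae"], 9)
  expect_error(normalized_family_counts(res, meta[-1, ]),
               "missing from metadata: a")
})

test_that("consensus thresholds are strict and gap-aware", {
  # 10 identical sequences: consensus is the sequence itself
  aln <- rep("MKCW", 10)
  prof <- consensus_from_alignment(aln)
  expect_equal(prof$consensus, "MKCW")

  # 6 A vs 4 G: 0.6 not > 0.7 -> z; 8 A vs 2 G: 0.8 > 0.7 -> A
  aln2 <- c(rep("AA", 6), rep("GA", 4))
  expect_equal(consensus_from_alignment(aln2)$consensus, "zA")
  aln3 <- c(rep("AA", 8), rep("GA", 2))
  expect_equal(consensus_from_alignment(aln3)$consensus, "AA")
  # exactly at threshold is z (strict)
  aln4 <- c(rep("A", 7), rep("G", 3))
  expect_equal(consensus_from_alignment(aln4, threshold = 0.7)$consensus, "z")

  # gaps are excluded from the denominator
  aln5 <- c("A-", "A-", "AG", "-G", "-G")
  expect_equal(consensus_from_alignment(aln5)$consensus, "AG")

  expect_error(consensus_from_alignment(c("AA", "AAA")), "ragged")
  expect_error(consensus_from_alignment("AA"), "at least 2")
})

test_that("conservation summary counts non-C fully conserved positions", {
  aln <- rep("ACGRCWAGRL", 4)  # identical, 2 cysteines
  prof <- consensus_from_alignment(aln)
  summ <- conservation_summary(prof)
  expect_equal(summ$n_fully_conserved, 8L)
  expect_equal(summ$fully_conserved, setdiff(1:10, c(2, 5)))
  expect_equal(summ$n_above_threshold, 10L)
  expect_equal(summ$fraction_above_threshold, 1)

  # nothing above threshold
  aln2 <- c("AG", "GA", "CT", "TC")
  summ2 <- conservation_summary(consensus_from_alignment(aln2))
  expect_equal(summ2$n_fully_conserved, 0L)
  expect_equal(summ2$n_above_threshold, 0L)
  expect_equal(summ2$fraction_above_threshold, 0)

  # exactly one unanimously conserved G at position 30
  set.seed(1)
  seqs <- vapply(1:8, function(i) {
    ch <- sample(c("A", "R", "N", "D"), 30, replace = TRUE)
    ch[30] <- "G"
    paste(ch, collapse = "")
  }, character(1))
  summ3 <- conservation_summary(consensus_from_alignment(seqs, threshold = 0.99))
  expect_true(30 %in% summ3$fully_conserved)
})

test_that("consensus is idempotent and monotone in the threshold", {
  db <- load_motif_db()
  set.seed(9)
  seqs <- vapply(1:12, function(i) {
    s <- sample_motif_realization(db$motifs$DEF06)
    # mutate a couple of gap positions to create variable columns
    ch <- strsplit(s, "")[[1]]
    idx <- which(ch != "C")
    flip <- sample(idx, 3)
    ch[flip] <- sample(setdiff(LETTERS, c("C", "B", "J", "O", "U", "X", "Z")),
                       3, replace = TRUE)
    paste(ch, collapse = "")
  }, character(1))
  prof <- consensus_from_alignment(seqs, threshold = 0.7)
  keep <- which(strsplit(prof$consensus, "")[[1]] != "z")
  sub <- substring(prof$consensus, keep, keep)
  again <- consensus_from_alignment(rep(paste(sub, collapse = ""), 3))
  expect_equal(again$consensus, paste(sub, collapse = ""))

  low <- consensus_from_alignment(seqs, threshold = 0.6)
  high <- consensus_from_alignment(seqs, threshold = 0.9)
  lo_z <- strsplit(low$consensus, "")[[1]] == "z"
  hi_z <- strsplit(high$consensus, "")[[1]] == "z"
  expect_true(all(hi_z >= lo_z))  # raising threshold never un-z's a column
})

test_that("the published defensin consensus is matched by DEF06 end to end", {
  db <- load_motif_db()
  cons <- "CESQSHRFKGzCVSzSNCANVCRTEGFzGGzCRGFRRRCFCTKzC"
  expect_equal(nchar(cons), 45L)
  for (wild in c("A", "R", "W")) {
    expect_true(matches_anywhere(db$motifs$DEF06, gsub("z", wild, cons)))
  }
})
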