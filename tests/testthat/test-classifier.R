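# Motif database, family assignment, transcriptome screen.

test_that("built-in database has the nine motifs across six families", {
  db <- load_motif_db()
  expect_length(db$motifs, 9L)
  expect_setequal(names(db$motifs),
                  c("SNA02", "LTP016", "HEVHIP02", "THI018", "CYC01",
                    "CYC02", "DEF06", "DEF32", "DEF34"))
  fams <- vapply(db$motifs, `[[`, character(1), "family")
  expect_length(unique(fams), 6L)
  expect_equal(unname(fams[c("SNA02", "LTP016", "HEVHIP02", "THI018")]),
               c("snakins", "lipid-transfer", "hevein-like", "thionins"))
  expect_equal(unname(fams[c("CYC01", "CYC02", "DEF06", "DEF32", "DEF34")]),
               c("cyclotides", "cyclotides", rep("defensins", 3)))
})

test_that("motif database files are validated line by line", {
  bad_dup <- withr::local_tempfile(lines = c("A1\tdefensins\tCXC",
                                             "A1\tdefensins\tCC"))
  expect_error(load_motif_db(bad_dup), "line 2.*duplicate motif_id 'A1'")
  empty <- withr::local_tempfile(lines = "# just a comment")
  expect_error(load_motif_db(empty), "no motifs")
  bad_pat <- withr::local_tempfile(lines = c("A1\tdefensins\tCXC",
                                             "A2\tdefensins\tCX{9,2}C"))
  expect_error(load_motif_db(bad_pat), "line 2.*minimum 9 exceeds maximum 2")
  bad_fam <- withr::local_tempfile(lines = "A1\tdragons\tCXC")
  expect_error(load_motif_db(bad_fam), "line 1.*family")
})

test_that("classification picks the most specific motif", {
  db <- load_motif_db()
  # DEF06 is fixed-span (range 0), DEF32 very loose (range 79)
  hits <- data.frame(motif_id = c("DEF32", "DEF06"),
                     start = c(1L, 1L), end = c(50L, 45L))
  expect_equal(classify_peptide(hits, db)$motif_id, "DEF06")
  expect_equal(classify_peptide(hits, db)$family, "defensins")
  # ties on span range break by family precedence, then motif id
  tie_db <- db
  tie_db$motifs$AAA <- parse_motif("CX{3}CX{4}CX{6}CX{1}CX{4}C",
                                   motif_id = "AAA", family = "snakins")
  h2 <- data.frame(motif_id = c("CYC01", "AAA"), start = 1L, end = 20L)
  expect_equal(classify_peptide(h2, tie_db)$family, "cyclotides")
})

test_that("cysteine-rich criterion counts cysteines against the threshold", {
  expect_true(cys_rich_criterion("ACACACAC"))
  expect_false(cys_rich_criterion("AAAA"))
  expect_false(cys_rich_criterion("CCC"))
  expect_true(cys_rich_criterion("CCC", min_cys = 3))
})

test_that("screen recovers planted genes and reconciles counts", {
  db <- load_motif_db()
  fx <- generate_transcriptome(2, 10, seed = 99)
  res <- screen_transcriptome(fx$records, db = db,
                              transcriptome_id = "small")
  m <- fx$manifest
  for (k in seq_len(nrow(m))) {
    match_row <- res$peptides[res$peptides$seq_id == m$contig_id[k] &
                              res$peptides$nt_start == m$nt_start[k], ]
    expect_equal(nrow(match_row), 1L, info = m$contig_id[k])
    expect_equal(match_row$family, m$family[k])
    expect_equal(match_row$nt_end, m$nt_end[k])
    expect_equal(match_row$frame, m$frame[k])
    expect_equal(match_row$precursor, m$precursor[k])
    expect_equal(match_row$mature, m$mature[k])
  }
  expect_equal(sum(res$counts), nrow(res$peptides))
  # every family key present exactly once in counts
  expect_setequal(names(res$counts),
                  c("defensins", "thionins", "cyclotides", "snakins",
                    "hevein-like", "lipid-transfer", "cysteine-rich",
                    "unknown"))
})

test_that("screen is deterministic and handles degenerate inputs", {
  fx <- generate_transcriptome(1, 5, seed = 3)
  a <- screen_transcriptome(fx$records, transcriptome_id = "x")
  b <- screen_transcriptome(fx$records, transcriptome_id = "x")
  expect_identical(a$peptides, b$peptides)
  expect_identical(a$counts, b$counts)

  empty <- screen_transcriptome(stats::setNames(character(0), character(0)),
                                transcriptome_id = "none")
  expect_equal(sum(empty$counts), 0L)
  expect_equal(nrow(empty$peptides), 0L)

  # stop-free contigs yield nothing under require_stop
  stopfree <- c(c1 = strrep("ATGGCA", 40))
  res <- screen_transcriptome(stopfree, transcriptome_id = "sf")
  expect_equal(sum(res$counts), 0L)
})

test_that("cysteine-rich fallback and no-motif rejection are separated", {
  # mature core with 6 cysteines that matches no built-in motif
  orfish <- build_precursor("CACACAWWCAWWCAWW", seed = 8)
  cds <- vapply(strsplit(orfish, "")[[1]], function(a) {
    # deterministic reverse translation: first codon of each residue
    code <- Biostrings::GENETIC_CODE
    names(code)[code == a][1]
  }, character(1))
  contig <- c(cr = paste0("TAA", paste(cds, collapse = ""), "TAA"))
  res <- screen_transcriptome(contig, transcriptome_id = "cr")
  expect_equal(unname(res$counts["cysteine-rich"]), 1L)
  # with a stricter threshold the same peptide is rejected as no_motif
  res2 <- screen_transcriptome(contig, transcriptome_id = "cr",
                               config = pipeline_config(min_cys = 7))
  expect_equal(sum(res2$counts), 0L)
  expect_true("no_motif" %in% res2$rejections$reason)
})

test_that("identical mature peptides within a contig are de-duplicated", {
  prec <- build_precursor("CAAACAAACAAAC", seed = 12)
  code <- Biostrings::GENETIC_CODE
  cds <- paste(vapply(strsplit(prec, "")[[1]],
                      function(a) names(code)[code == a][1], character(1)),
               collapse = "")
  # two copies of the same gene on one contig
  contig <- c(dup = paste0("TAA", cds, "TAATT", "TAA", cds, "TAA"))
  res <- screen_transcriptome(contig, transcriptome_id = "dup")
  pep <- res$peptides[res$peptides$family == "cysteine-rich", ]
  expect_equal(nrow(pep), 1L)
  expect_equal(pep$nt_start, 4L)  # lowest nt_start wins
})

test_that("adding a motif never decreases other families' counts except by
           precedence reassignment", {
  db <- load_motif_db()
  fx <- generate_transcriptome(2, 5, seed = 31)
  before <- screen_transcriptome(fx$records, db = db, transcriptome_id = "t")
  db2 <- db
  db2$motifs$NEW1 <- parse_motif("CX{1,40}CX{1,40}CX{1,40}C",
                                 motif_id = "NEW1", family = "unknown")
  after <- screen_transcriptome(fx$records, db = db2, transcriptome_id = "t")
  moved <- sum(after$peptides$motif_id == "NEW1", na.rm = TRUE)
  for (fam in setdiff(names(before$counts), "unknown")) {
    expect_gte(after$counts[[fam]], before$counts[[fam]] - moved)
  }
  expect_gte(sum(after$counts), sum(before$counts))
})
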