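# Synthetic transcriptome generation with planted, ground-truthed AMP
# precursors. Everything is seeded, so fixtures are built in code at test
# time rather than shipped as data.

#' Sample a random realization of a motif
#'
#' Anchors become `C`; each gap is filled with a uniformly drawn length in
#' its bounds and uniformly drawn non-cysteine residues. By construction the
#' result satisfies `matches_anywhere(motif, result)`.
#'
#' @param motif A `cys_motif`.
#' @param seed Optional integer seed.
#' @return Amino-acid string.
#' @export
sample_motif_realization <- function(motif, seed = NULL) {
  stopifnot(inherits(motif, "cys_motif"))
  if (!is.null(seed)) set.seed(seed)
  non_c <- setdiff(AA_STANDARD, "C")
  parts <- vapply(motif$elements, function(el) {
    if (el$type == "anchor") return("C")
    k <- if (el$min == el$max) el$min else sample(el$min:el$max, 1L)
    if (k == 0L) "" else paste(sample(non_c, k, replace = TRUE), collapse = "")
  }, character(1))
  paste(parts, collapse = "")
}

#' Wrap a mature core into a secretion-competent precursor
#'
#' Prepends `M`, a charged n-region (two of K/R), a hydrophobic leucine
#' h-region (10-14 residues) and an `A-Q-A` cleavage cassette. The prefix is
#' built from residues outside the small-residue set until the cassette, so
#' the (-3,-1) scan of [predict_signal_peptide()] fires exactly at the first
#' mature residue; the construction is guaranteed positive under the
#' built-in heuristic's defaults.
#'
#' @param mature_core Non-empty amino-acid string (the planted mature
#'   peptide).
#' @param seed Optional integer seed.
#' @return Precursor string of length < 150; errors if the core cannot fit
#'   under the limit.
#' @export
build_precursor <- function(mature_core, seed = NULL) {
  stopifnot(is.character(mature_core), nzchar(mature_core))
  if (!is.null(seed)) set.seed(seed)
  n_l <- sample(10:14, 1L)
  charged <- paste(sample(c("K", "R"), 2L, replace = TRUE), collapse = "")
  signal <- paste0("M", charged, strrep("L", n_l), "AQA")
  precursor <- paste0(signal, mature_core)
  if (nchar(precursor) >= 150L)
    stop("mature core too long (", nchar(mature_core),
         " aa) to fit under the 150-residue precursor limit", call. = FALSE)
  precursor
}

# Uniform synonymous reverse translation (no codon-bias model).
.reverse_translate <- function(aa_sequence) {
  code <- Biostrings::GENETIC_CODE
  by_aa <- split(names(code), unname(code))
  ch <- strsplit(aa_sequence, "", fixed = TRUE)[[1L]]
  paste(vapply(ch, function(a) {
    cods <- by_aa[[a]]
    if (is.null(cods)) stop("cannot reverse-translate residue '", a, "'",
                            call. = FALSE)
    if (length(cods) == 1L) cods else sample(cods, 1L)
  }, character(1)), collapse = "")
}

.random_nt <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                collapse = "")

#' Generate a synthetic transcriptome with planted AMP precursors
#'
#' For each family in the motif database, `n_planted_per_family` precursors
#' are planted: a motif realization becomes the mature core, is wrapped by
#' [build_precursor()], reverse-translated with uniform synonymous codons,
#' terminated by a stop codon and embedded in random UTR context on a random
#' strand. An in-frame stop is placed immediately upstream of the start
#' codon so the planted ATG is always the first of its stop-bounded segment,
#' making every planted gene recoverable under the default configuration.
#' Realizations whose most specific database match would classify outside
#' the intended family are redrawn (rejection sampling), keeping the
#' manifest's family labels unambiguous ground truth.
#'
#' @param n_planted_per_family Planted precursors per family (>= 0).
#' @param n_decoys Random decoy contigs with no planted motif (>= 0).
#' @param seed Integer seed governing all randomness.
#' @param db Motif database to plant from.
#' @param utr_range Length range (nt) of the random 5'/3' UTR context.
#' @param decoy_length_range Length range (nt) of decoy contigs.
#' @return List with `records` (a [Biostrings::DNAStringSet]) and `manifest`
#'   (`data.frame`: `contig_id`, `motif_id`, `family`, `strand`, `frame`,
#'   `nt_start`, `nt_end`, `cleavage_pos`, `precursor`, `mature`).
#' @export
generate_transcriptome <- function(n_planted_per_family = 10L, n_decoys = 50L,
                                   seed = 1L, db = load_motif_db(),
                                   utr_range = c(20L, 200L),
                                   decoy_length_range = c(150L, 600L)) {
  stopifnot(n_planted_per_family >= 0L, n_decoys >= 0L)
  set.seed(seed)
  fams <- unique(vapply(db$motifs, `[[`, character(1), "family"))
  seqs <- character(0)
  man <- list()
  for (fam in fams) {
    fam_motifs <- Filter(function(m) m$family == fam, db$motifs)
    if (n_planted_per_family == 0L) next
    for (i in seq_len(n_planted_per_family)) {
      motif <- fam_motifs[[((i - 1L) %% length(fam_motifs)) + 1L]]
      core <- .draw_unambiguous_core(motif, db)
      precursor <- build_precursor(core)
      sig <- predict_signal_peptide(precursor)
      stopifnot(isTRUE(sig$is_positive))
      cds <- .reverse_translate(precursor)
      stop_codon <- sample(c("TAA", "TAG", "TGA"), 1L)
      u5 <- sample(utr_range[1L]:utr_range[2L], 1L)
      u3 <- sample(utr_range[1L]:utr_range[2L], 1L)
      utr5 <- .random_nt(u5)
      # in-frame stop immediately upstream of ATG: the planted ATG is the
      # first of its stop-bounded segment in this frame
      substr(utr5, u5 - 2L, u5) <- "TAA"
      fwd <- paste0(utr5, cds, stop_codon, .random_nt(u3))
      cds_start <- u5 + 1L
      cds_end <- u5 + nchar(cds) + 3L
      strand <- sample(c("+", "-"), 1L)
      if (strand == "+") {
        contig <- fwd
        nt_start <- cds_start
        nt_end <- cds_end
        frame <- ((cds_start - 1L) %% 3L) + 1L
      } else {
        contig <- reverse_complement(fwd)
        L <- nchar(contig)
        nt_start <- L - cds_end + 1L
        nt_end <- L - cds_start + 1L
        frame <- -(((cds_start - 1L) %% 3L) + 1L)
      }
      cid <- sprintf("planted_%s_%02d", gsub("-", "", fam), i)
      seqs[[cid]] <- contig
      man[[length(man) + 1L]] <- data.frame(
        contig_id = cid, motif_id = motif$motif_id, family = fam,
        strand = strand, frame = frame, nt_start = nt_start, nt_end = nt_end,
        cleavage_pos = sig$cleavage_pos, precursor = precursor,
        mature = substr(precursor, sig$cleavage_pos, nchar(precursor)),
        stringsAsFactors = FALSE)
    }
  }
  for (i in seq_len(n_decoys)) {
    len <- sample(decoy_length_range[1L]:decoy_length_range[2L], 1L)
    seqs[[sprintf("decoy_%03d", i)]] <- .random_nt(len)
  }
  manifest <- if (length(man)) do.call(rbind, man) else
    data.frame(contig_id = character(0), motif_id = character(0),
               family = character(0), strand = character(0),
               frame = integer(0), nt_start = integer(0), nt_end = integer(0),
               cleavage_pos = integer(0), precursor = character(0),
               mature = character(0), stringsAsFactors = FALSE)
  records <- Biostrings::DNAStringSet(unlist(seqs, use.names = TRUE))
  if (length(seqs) == 0L) records <- Biostrings::DNAStringSet()
  list(records = records, manifest = manifest)
}

# Redraw a motif realization until classify_peptide() on its own database
# hits would keep it in the motif's family (caps at 100 draws; in practice
# cross-family collisions are rare and only arise from very loose motifs).
.draw_unambiguous_core <- function(motif, db) {
  for (i in 1:100) {
    core <- sample_motif_realization(motif)
    hits <- .scan_motifs(db, core)
    if (!nrow(hits)) next  # cannot happen: realization matches its own motif
    cls <- classify_peptide(hits, db)
    if (cls$family == motif$family) return(core)
  }
  stop("could not draw an unambiguous realization for motif ",
       motif$motif_id, call. = FALSE)
}

#' Write fixture records and manifest to files
#'
#' @param fixture Output of [generate_transcriptome()].
#' @param fasta_path,manifest_path Output paths (nucleotide FASTA and TSV).
#' @return Invisibly, a list of the two paths.
#' @export
write_fixture <- function(fixture, fasta_path, manifest_path) {
  Biostrings::writeXStringSet(fixture$records, fasta_path)
  utils::write.table(fixture$manifest, manifest_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(list(fasta = fasta_path, manifest = manifest_path))
}
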