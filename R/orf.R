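# Transcriptome input, six-frame translation and ORF extraction.

#' Read a nucleotide FASTA file
#'
#' Sequences are uppercased and RNA `U` is normalised to `T`. The sequence
#' id is the header up to the first whitespace; any following description is
#' kept in `mcols(x)$description`.
#'
#' @param path Path to a (possibly multi-line) FASTA file.
#' @return A [Biostrings::DNAStringSet] named by sequence id.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("input FASTA not found: ", path, call. = FALSE)
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop("failed to read FASTA '", path, "': ",
                                           conditionMessage(e), call. = FALSE))
  if (length(set) == 0L) stop("empty FASTA: ", path, call. = FALSE)
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop("duplicate sequence ids: ", paste(dup, collapse = ", "), call. = FALSE)
  seqs <- toupper(as.character(set))
  bad <- regexpr("[^ACGTUN]", seqs, perl = TRUE)
  if (any(bad != -1L)) {
    i <- which(bad != -1L)[1L]
    stop(sprintf("non-IUPAC character '%s' in record '%s' at position %d",
                 substr(seqs[i], bad[i], bad[i]), ids[i], bad[i]), call. = FALSE)
  }
  seqs <- chartr("U", "T", seqs)
  out <- Biostrings::DNAStringSet(seqs)
  names(out) <- ids
  S4Vectors::mcols(out)$description <- desc
  out
}

#' Reverse complement of a nucleotide string
#'
#' @param sequence IUPAC nucleotide string (character scalar).
#' @return Character scalar; `reverse_complement(reverse_complement(s)) == s`.
#' @export
reverse_complement <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  if (!nzchar(sequence)) return("")
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(sequence)))
}

#' Translate one reading frame
#'
#' Standard genetic code (translation table 1). Frames `+1..+3` read the
#' forward strand from offsets 0..2; frames `-1..-3` read the reverse
#' complement likewise. The trailing partial codon is dropped; stop codons
#' are emitted as `*`; a codon containing `N` translates to `X` unless all
#' its resolutions agree on one residue.
#'
#' @param sequence Nucleotide string.
#' @param frame One of `1, 2, 3, -1, -2, -3`.
#' @return Amino-acid string (possibly empty).
#' @export
translate_frame <- function(sequence, frame) {
  stopifnot(frame %in% c(1L, 2L, 3L, -1L, -2L, -3L))
  s <- if (frame < 0) reverse_complement(sequence) else toupper(chartr("Uu", "Tt", sequence))
  off <- abs(frame) - 1L
  ncod <- (nchar(s) - off) %/% 3L
  if (ncod <= 0L) return("")
  sub <- substr(s, off + 1L, off + 3L * ncod)
  .translate_codons(sub)
}

# Vectorised codon lookup on the standard genetic code. Codons containing N
# are resolved exhaustively: if every resolution gives the same residue that
# residue is used, otherwise the ambiguity letter X. (Biostrings::translate
# with a fuzzy-codon policy does the same but rebuilds its fuzzy code table
# on every call, which dominates six-frame scans of many contigs.)
.translate_codons <- function(s) {
  n <- nchar(s)
  starts <- seq.int(1L, n, 3L)
  cods <- substring(s, starts, starts + 2L)
  aa <- unname(Biostrings::GENETIC_CODE[cods])
  na <- which(is.na(aa))
  for (i in na) aa[i] <- .fuzzy_codon_aa(cods[i])
  paste(aa, collapse = "")
}

.fuzzy_codon_aa <- function(codon) {
  bases <- strsplit(codon, "", fixed = TRUE)[[1L]]
  opts <- lapply(bases, function(b) if (b == "N") c("A", "C", "G", "T") else b)
  grid <- expand.grid(opts, KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  res <- unique(unname(Biostrings::GENETIC_CODE[do.call(paste0, grid)]))
  if (length(res) == 1L && !is.na(res)) res else "X"
}

#' Extract methionine-initiated ORFs from all six frames
#'
#' Each stop-bounded segment of a frame's translation contributes one ORF
#' beginning at its first in-frame `ATG` (the longest candidate, the common
#' convention); with `all_starts = TRUE` every in-frame `ATG` yields an ORF,
#' which preserves sensitivity for short mature peptides behind internal
#' methionines.
#'
#' Coordinates are 1-based inclusive on the forward strand regardless of
#' frame sign and include the stop codon when present, so that
#' `nt_end - nt_start + 1 == 3 * nchar(aa_sequence) + 3 * has_stop`.
#'
#' @param seq_id Contig identifier carried into the output.
#' @param sequence Nucleotide string for the contig.
#' @param min_aa,max_aa Inclusive bounds on precursor length in residues
#'   (stop excluded); ORFs outside the bounds are discarded.
#' @param require_stop Discard ORFs that run off the contig end without a
#'   stop codon (default `TRUE`: a real precursor transcript terminates).
#' @param all_starts Enumerate every in-frame ATG instead of only the first
#'   per stop-bounded segment.
#' @return `data.frame` with columns `seq_id`, `frame`, `nt_start`,
#'   `nt_end`, `aa_sequence`, `has_stop`. The stop symbol never appears in
#'   `aa_sequence`.
#' @export
extract_orfs <- function(seq_id, sequence, min_aa = 1L, max_aa = Inf,
                         require_stop = TRUE, all_starts = FALSE) {
  stopifnot(min_aa >= 1L, max_aa >= min_aa)
  L <- nchar(sequence)
  rows <- vector("list", 0L)
  for (frame in c(1L, 2L, 3L, -1L, -2L, -3L)) {
    aa <- translate_frame(sequence, frame)
    if (!nzchar(aa)) next
    off <- abs(frame) - 1L
    chars <- strsplit(aa, "", fixed = TRUE)[[1L]]
    nres <- length(chars)
    stops <- which(chars == "*")
    seg_start <- c(1L, stops + 1L)
    seg_end <- c(stops - 1L, nres)
    terminated <- c(rep(TRUE, length(stops)), FALSE)
    for (si in seq_along(seg_start)) {
      a <- seg_start[si]
      b <- seg_end[si]
      if (a > b) next
      if (require_stop && !terminated[si]) next
      ms <- a - 1L + which(chars[a:b] == "M")
      if (!length(ms)) next
      if (!all_starts) ms <- ms[1L]
      for (m0 in ms) {
        len <- b - m0 + 1L
        if (len < min_aa || len > max_aa) next
        last_cod <- b + if (terminated[si]) 1L else 0L
        rs <- off + 3L * (m0 - 1L) + 1L
        re <- off + 3L * last_cod
        if (frame > 0) {
          nt_start <- rs
          nt_end <- re
        } else {
          nt_start <- L - re + 1L
          nt_end <- L - rs + 1L
        }
        rows[[length(rows) + 1L]] <- data.frame(
          seq_id = seq_id, frame = frame,
          nt_start = nt_start, nt_end = nt_end,
          aa_sequence = paste(chars[m0:b], collapse = ""),
          has_stop = terminated[si],
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(seq_id = character(0), frame = integer(0),
                      nt_start = integer(0), nt_end = integer(0),
                      aa_sequence = character(0), has_stop = logical(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

#' Write ORFs as an amino-acid FASTA file
#'
#' Headers follow `<seq_id>|<frame>|<nt_start>-<nt_end>`.
#'
#' @param orfs Output of [extract_orfs()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_orf_fasta <- function(orfs, path) {
  aa <- Biostrings::AAStringSet(orfs$aa_sequence)
  names(aa) <- sprintf("%s|%+d|%d-%d", orfs$seq_id, orfs$frame,
                       orfs$nt_start, orfs$nt_end)
  Biostrings::writeXStringSet(aa, path)
  invisible(path)
}
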