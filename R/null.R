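# False-positive calibration on random sequences.

#' Configuration for the random-sequence null model
#'
#' @param n_sequences Number of random sequences to draw.
#' @param seq_length Length of each sequence (nucleotides or residues).
#' @param alphabet_mode `"nucleotide"` (random contigs fed through the whole
#'   pipeline: translation, ORF extraction, filters, classification) or
#'   `"amino_acid"` (random peptides fed directly to the motif matcher).
#' @param composition Named non-negative frequency vector summing to 1; its
#'   names define the alphabet. Defaults to the uniform distribution over
#'   A/C/G/T or over the 20 amino acids.
#' @param seed Integer seed; identical configs give identical draws.
#' @return Object of class `cysmotif_null_config`.
#' @export
null_config <- function(n_sequences, seq_length,
                        alphabet_mode = c("nucleotide", "amino_acid"),
                        composition = NULL, seed = 1L) {
  alphabet_mode <- match.arg(alphabet_mode)
  n_sequences <- as.integer(n_sequences)
  seq_length <- as.integer(seq_length)
  if (is.na(n_sequences) || n_sequences < 1L)
    stop("n_sequences must be a positive integer", call. = FALSE)
  if (is.na(seq_length) || seq_length < 1L)
    stop("seq_length must be a positive integer", call. = FALSE)
  if (is.null(composition)) {
    alphabet <- if (alphabet_mode == "nucleotide") c("A", "C", "G", "T")
                else AA_STANDARD
    composition <- stats::setNames(rep(1 / length(alphabet), length(alphabet)),
                                   alphabet)
  }
  if (is.null(names(composition)) || any(composition < 0) ||
      abs(sum(composition) - 1) > 1e-9)
    stop("composition must be a named non-negative vector summing to 1",
         call. = FALSE)
  structure(list(n_sequences = n_sequences, seq_length = seq_length,
                 alphabet_mode = alphabet_mode, composition = composition,
                 seed = as.integer(seed)),
            class = "cysmotif_null_config")
}

#' Draw random sequences under a null configuration
#'
#' Positions are i.i.d. draws from `config$composition`; output is
#' reproducible given `config$seed`.
#'
#' @param config A [null_config()].
#' @return Named character vector (`null_001`, ...).
#' @export
random_sequences <- function(config) {
  stopifnot(inherits(config, "cysmotif_null_config"))
  set.seed(config$seed)
  letters <- names(config$composition)
  out <- vapply(seq_len(config$n_sequences), function(i) {
    paste(sample(letters, config$seq_length, replace = TRUE,
                 prob = config$composition), collapse = "")
  }, character(1))
  stats::setNames(out, sprintf("null_%05d", seq_along(out)))
}

#' Estimate per-motif false-positive rates on random sequences
#'
#' In amino-acid mode the hit fraction is the fraction of random peptides in
#' which the motif matches anywhere. In nucleotide mode the random contigs
#' are run through the full screen ([screen_transcriptome()]) and the hit
#' fraction is the fraction of contigs yielding at least one retained
#' peptide carrying a mature-region hit of the motif. A Wilson 95% interval
#' accompanies each estimate.
#'
#' @param db Motif database.
#' @param config A [null_config()].
#' @param screen_config A [pipeline_config()] used in nucleotide mode.
#' @param conf Confidence level for the Wilson interval.
#' @return `data.frame` with columns `motif_id`, `n`, `hits`,
#'   `hit_fraction`, `ci_low`, `ci_high`.
#' @export
estimate_fpr <- function(db, config, screen_config = pipeline_config(),
                         conf = 0.95) {
  stopifnot(inherits(db, "cysmotif_db"))
  seqs <- random_sequences(config)
  n <- length(seqs)
  if (config$alphabet_mode == "amino_acid") {
    hits <- vapply(db$motifs, function(m) sum(matches_anywhere(m, seqs)),
                   integer(1))
  } else {
    scr <- screen_transcriptome(seqs, db = db, config = screen_config,
                                transcriptome_id = "null")
    hits <- vapply(db$motifs, function(m) {
      length(unique(scr$hits$seq_id[scr$hits$motif_id == m$motif_id]))
    }, integer(1))
  }
  ci <- t(vapply(hits, function(k) wilson_ci(k, n, conf), numeric(2)))
  data.frame(motif_id = vapply(db$motifs, `[[`, character(1), "motif_id"),
             n = n, hits = as.integer(hits), hit_fraction = hits / n,
             ci_low = ci[, 1L], ci_high = ci[, 2L],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Exact match probability by exhaustive enumeration
#'
#' Cross-check oracle for small cases: enumerates every sequence over the
#' composition's alphabet and sums the probability mass of those matched by
#' the motif. Restricted to the exhaustive regime (`seq_length <= 20` and at
#' most ~2 million sequences); beyond that use [estimate_fpr()].
#'
#' @param motif A `cys_motif`.
#' @param composition Named frequency vector over the alphabet, summing to 1.
#' @param seq_length Sequence length.
#' @return Exact probability that the motif matches at least once.
#' @export
analytic_match_prob <- function(motif, composition, seq_length) {
  stopifnot(inherits(motif, "cys_motif"))
  if (is.null(names(composition)) || abs(sum(composition) - 1) > 1e-9)
    stop("composition must be a named vector summing to 1", call. = FALSE)
  alphabet <- names(composition)
  seq_length <- as.integer(seq_length)
  if (seq_length < 1L) stop("seq_length must be positive", call. = FALSE)
  if (seq_length > 20L || length(alphabet)^seq_length > 2^21)
    stop("outside the exhaustive regime; use estimate_fpr()", call. = FALSE)
  grid <- expand.grid(rep(list(seq_along(alphabet)), seq_length),
                      KEEP.OUT.ATTRS = FALSE)
  strings <- do.call(paste0, lapply(grid, function(col) alphabet[col]))
  probs <- Reduce(`*`, lapply(grid, function(col) unname(composition[col])))
  matched <- grepl(.motif_regex(motif, lazy = TRUE), strings, perl = TRUE)
  sum(probs[matched])
}
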