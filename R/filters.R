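# Filtration cascade: precursor length, signal-peptide presence, and the
# requirement that a motif lies in the mature peptide.

#' Precursor length filter
#'
#' The length restriction is strict: a precursor of exactly `limit` residues
#' fails. Length is measured on the precursor ORF (methionine included, stop
#' excluded).
#'
#' @param aa_sequence Precursor amino-acid string.
#' @param limit Length limit, default 150.
#' @return `TRUE` iff `nchar(aa_sequence) < limit`.
#' @export
check_length <- function(aa_sequence, limit = 150L) {
  stopifnot(limit >= 1L)
  nchar(aa_sequence) < limit
}

#' Built-in signal-peptide heuristic
#'
#' A transparent stand-in for a neural-network signal-peptide predictor,
#' built from the classical anatomy of a secretory signal: a positively
#' charged n-region, a hydrophobic h-region, and a (-3,-1) small-residue
#' cleavage site. A sequence is called positive iff all three hold:
#'
#' * n-region: net charge of residues 2-6 (K/R = +1, D/E = -1) is
#'   `>= charge_min` (default 0);
#' * h-region: the maximum mean Kyte-Doolittle hydropathy over windows of
#'   `kd_window` residues (default 8) lying within residues 5-25 is
#'   `>= kd_min` (default 1.6);
#' * cleavage: there is a position `p` in `[cleavage_min, cleavage_max]`
#'   (default 12-40) such that residues `p - 3` and `p - 1` both belong to
#'   the small-residue set `{A, G, S, C, T, V}`; the first such `p` is the
#'   1-based index of the first mature residue.
#'
#' The score is the logistic of the best h-region mean hydropathy and is
#' meant for ranking only. Any function with this signature and return
#' shape can be plugged into [apply_filters()] / [screen_transcriptome()]
#' in place of the built-in.
#'
#' @param aa_sequence Precursor amino-acid string starting with `M`.
#' @param charge_min,kd_min,kd_window,cleavage_min,cleavage_max Tunable
#'   thresholds described above.
#' @return List with elements `is_positive` (logical), `cleavage_pos`
#'   (1-based index of the first mature residue, `NA` when negative) and
#'   `score` (numeric in `[0, 1]`). Sequences shorter than 15 residues are
#'   negative, not an error.
#' @export
predict_signal_peptide <- function(aa_sequence, charge_min = 0, kd_min = 1.6,
                                   kd_window = 8L, cleavage_min = 12L,
                                   cleavage_max = 40L) {
  negative <- list(is_positive = FALSE, cleavage_pos = NA_integer_, score = 0)
  s <- toupper(aa_sequence)
  n <- nchar(s)
  if (n < 15L || substr(s, 1L, 1L) != "M") return(negative)
  ch <- strsplit(s, "", fixed = TRUE)[[1L]]
  charge <- sum(ch[2:6] %in% c("K", "R")) - sum(ch[2:6] %in% c("D", "E"))
  kd <- unname(KD_SCALE[ch])
  kd[is.na(kd)] <- 0
  h_last <- min(25L, n)
  hmax <- -Inf
  if (h_last - 5L + 1L >= kd_window) {
    for (w in 5L:(h_last - kd_window + 1L))
      hmax <- max(hmax, mean(kd[w:(w + kd_window - 1L)]))
  }
  small <- c("A", "G", "S", "C", "T", "V")
  cleav <- NA_integer_
  for (p in cleavage_min:min(cleavage_max, n)) {
    if (ch[p - 3L] %in% small && ch[p - 1L] %in% small) {
      cleav <- p
      break
    }
  }
  score <- if (is.finite(hmax)) 1 / (1 + exp(-hmax)) else 0
  positive <- charge >= charge_min && is.finite(hmax) && hmax >= kd_min && !is.na(cleav)
  list(is_positive = positive,
       cleavage_pos = if (positive) cleav else NA_integer_,
       score = score)
}

#' Apply the filtration cascade to one ORF
#'
#' An ORF is retained iff (1) its precursor passes [check_length()], (2) the
#' predictor calls a signal peptide, and (3) at least one motif hit begins
#' at or after the cleavage position, i.e. lies in the mature peptide
#' (cysteine scaffolds of genuine AMPs reside in the mature chain; disable
#' with `mature_region_rule = FALSE`). The three predicates are independent,
#' so the retained set does not depend on evaluation order.
#'
#' @param orf One ORF as a list or single-row `data.frame` with at least an
#'   `aa_sequence` field (as produced by [extract_orfs()]).
#' @param motif_hits `data.frame` with columns `motif_id`, `start`, `end`:
#'   motif matches on the precursor.
#' @param limit Length limit passed to [check_length()].
#' @param predictor Signal-peptide predictor function, by default the
#'   built-in [predict_signal_peptide()].
#' @param mature_region_rule Require hits to start at or after the cleavage
#'   position.
#' @return A list. When retained: `retained = TRUE`, the `orf`, the
#'   `signal` prediction, `mature_sequence` and the surviving `motif_hits`.
#'   When rejected: `retained = FALSE` and a `reason`, one of `"too_long"`,
#'   `"no_signal"`, `"motif_in_signal"`, `"no_motif"`.
#' @export
apply_filters <- function(orf, motif_hits, limit = 150L,
                          predictor = predict_signal_peptide,
                          mature_region_rule = TRUE) {
  aa <- orf$aa_sequence
  if (!check_length(aa, limit))
    return(list(retained = FALSE, reason = "too_long"))
  sig <- predictor(aa)
  if (!isTRUE(sig$is_positive))
    return(list(retained = FALSE, reason = "no_signal"))
  mature <- substr(aa, sig$cleavage_pos, nchar(aa))
  hits <- motif_hits
  keep <- if (mature_region_rule && nrow(hits)) hits$start >= sig$cleavage_pos
          else rep(TRUE, nrow(hits))
  mhits <- hits[keep, , drop = FALSE]
  if (nrow(mhits) == 0L) {
    reason <- if (nrow(hits)) "motif_in_signal" else "no_motif"
    return(list(retained = FALSE, reason = reason, signal = sig,
                mature_sequence = mature))
  }
  list(retained = TRUE, reason = NA_character_, orf = orf, signal = sig,
       mature_sequence = mature, motif_hits = mhits)
}
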