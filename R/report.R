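# Count tables and alignment-based consensus / conservation summaries.

# Mapping from internal family keys to count-table column headers.
.display_cols <- c("defensins" = "Defensins", "thionins" = "Thionins",
                   "cyclotides" = "Cyclotides", "snakins" = "Snakins",
                   "hevein-like" = "Hevein-like", "lipid-transfer" = "LTP",
                   "cysteine-rich" = "Cysteine-rich", "unknown" = "Unknown")

#' Per-transcriptome family count table
#'
#' One row per transcriptome plus a totals row; columns in the fixed order
#' Defensins, Thionins, Cyclotides, Snakins, Hevein-like, LTP,
#' Cysteine-rich, Unknown.
#'
#' @param results A `cysmotif_screen` or list of them.
#' @return `data.frame` with a `transcriptome` column and one column per
#'   peptide group; the last row (`"total"`) holds column sums.
#' @export
family_count_table <- function(results) {
  if (inherits(results, "cysmotif_screen")) results <- list(results)
  stopifnot(length(results) >= 1L,
            all(vapply(results, inherits, logical(1), "cysmotif_screen")))
  keys <- names(.display_cols)
  rows <- t(vapply(results, function(r) as.numeric(r$counts[keys]),
                   numeric(length(keys))))
  df <- data.frame(transcriptome = vapply(results, `[[`, character(1),
                                          "transcriptome_id"),
                   rows, check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df)[-1L] <- unname(.display_cols)
  totals <- data.frame(transcriptome = "total", t(colSums(rows)),
                       check.names = FALSE, stringsAsFactors = FALSE)
  colnames(totals)[-1L] <- unname(.display_cols)
  rbind(df, totals)
}

#' Per-plant-family normalised counts
#'
#' Divides each peptide-group count summed over a plant family's
#' transcriptomes by the number of transcriptomes in that family, excluding
#' plant families represented by fewer than `min_samples` transcriptomes
#' (small families make rates unstable).
#'
#' @param results List of `cysmotif_screen` objects.
#' @param family_metadata `data.frame` with columns `transcriptome_id` and
#'   `plant_family` covering every result.
#' @param min_samples Minimum transcriptomes per plant family, default 5.
#' @return `data.frame`: `plant_family`, `n_transcriptomes`, then one rate
#'   column per peptide group.
#' @export
normalized_family_counts <- function(results, family_metadata, min_samples = 5L) {
  if (inherits(results, "cysmotif_screen")) results <- list(results)
  stopifnot(is.data.frame(family_metadata),
            all(c("transcriptome_id", "plant_family") %in% names(family_metadata)))
  ids <- vapply(results, `[[`, character(1), "transcriptome_id")
  missing <- setdiff(ids, family_metadata$transcriptome_id)
  if (length(missing))
    stop("transcriptomes missing from metadata: ",
         paste(missing, collapse = ", "), call. = FALSE)
  pf <- family_metadata$plant_family[match(ids, family_metadata$transcriptome_id)]
  keys <- names(.display_cols)
  counts <- t(vapply(results, function(r) as.numeric(r$counts[keys]),
                     numeric(length(keys))))
  out <- lapply(split(seq_along(results), pf), function(idx) {
    n <- length(idx)
    rates <- colSums(counts[idx, , drop = FALSE]) / n
    c(n_transcriptomes = n, rates)
  })
  keep <- vapply(out, function(x) x[["n_transcriptomes"]] >= min_samples,
                 logical(1))
  out <- out[keep]
  if (!length(out)) {
    df <- data.frame(plant_family = character(0), n_transcriptomes = numeric(0))
    for (cn in unname(.display_cols)) df[[cn]] <- numeric(0)
    return(df)
  }
  df <- data.frame(plant_family = names(out),
                   do.call(rbind, out), check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[-(1:2)] <- unname(.display_cols)
  rownames(df) <- NULL
  df
}

#' Column-wise consensus of an amino-acid alignment
#'
#' For each column the residue observed in strictly more than `threshold` of
#' the non-gap entries becomes the consensus letter; otherwise the column is
#' written as `z` (consensus includes more than one residue). Gap characters
#' (`-` and `.`) are excluded from the denominator, so length-variable
#' termini do not dilute conservation.
#'
#' @param aligned_sequences Equal-length aligned amino-acid strings
#'   (character vector or [Biostrings::AAStringSet]), at least 2.
#' @param threshold Conservation threshold in `(0.5, 1]`, default 0.7
#'   (strictly greater than).
#' @return Object of class `consensus_profile`: list with `columns`
#'   (per-column named frequency vectors over non-gap residues),
#'   `consensus` (string over residues plus `z`) and `threshold`.
#' @export
consensus_from_alignment <- function(aligned_sequences, threshold = 0.7) {
  if (methods::is(aligned_sequences, "XStringSet"))
    aligned_sequences <- as.character(aligned_sequences)
  stopifnot(is.character(aligned_sequences), threshold > 0.5, threshold <= 1)
  if (length(aligned_sequences) < 2L)
    stop("alignment must contain at least 2 sequences", call. = FALSE)
  widths <- nchar(aligned_sequences)
  if (length(unique(widths)) != 1L)
    stop("ragged alignment: sequence lengths ",
         paste(unique(widths), collapse = ", "), call. = FALSE)
  mat <- do.call(rbind, strsplit(toupper(aligned_sequences), "", fixed = TRUE))
  ncols <- ncol(mat)
  columns <- vector("list", ncols)
  consensus <- character(ncols)
  for (j in seq_len(ncols)) {
    col <- mat[, j]
    col <- col[!col %in% c("-", ".")]
    if (!length(col)) {
      columns[[j]] <- stats::setNames(numeric(0), character(0))
      consensus[j] <- "z"
      next
    }
    freq <- table(col)
    freq <- stats::setNames(as.numeric(freq) / length(col), names(freq))
    freq <- sort(freq, decreasing = TRUE)
    columns[[j]] <- freq
    consensus[j] <- if (freq[1L] > threshold) names(freq)[1L] else "z"
  }
  structure(list(columns = columns, consensus = paste(consensus, collapse = ""),
                 threshold = threshold),
            class = "consensus_profile")
}

#' Conservation summary of a consensus profile
#'
#' Positions are 1-based from the first alignment column (by convention the
#' first motif position when the alignment is trimmed to the motif).
#'
#' @param profile A `consensus_profile`.
#' @return List with `fully_conserved` (1-based positions where a non-C
#'   residue has frequency 1), `n_fully_conserved`, `n_above_threshold`
#'   (columns whose top residue exceeds the threshold, cysteines included)
#'   and `fraction_above_threshold` (of profile length).
#' @export
conservation_summary <- function(profile) {
  stopifnot(inherits(profile, "consensus_profile"))
  ncols <- length(profile$columns)
  eps <- 1e-12
  fully <- integer(0)
  above <- 0L
  for (j in seq_len(ncols)) {
    freq <- profile$columns[[j]]
    if (!length(freq)) next
    if (freq[1L] > profile$threshold) above <- above + 1L
    if (freq[1L] >= 1 - eps && names(freq)[1L] != "C")
      fully <- c(fully, j)
  }
  list(fully_conserved = fully,
       n_fully_conserved = length(fully),
       n_above_threshold = above,
       fraction_above_threshold = if (ncols) above / ncols else 0)
}

#' @export
print.consensus_profile <- function(x, ...) {
  cat(sprintf("<consensus_profile: %d columns, threshold > %.2f>\n%s\n",
              length(x$columns), x$threshold, x$consensus))
  invisible(x)
}
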