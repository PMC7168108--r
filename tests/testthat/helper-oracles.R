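# Independent oracles used across the suite. These deliberately avoid the
# package's regex machinery: matching is done by explicit backtracking over
# gap-length assignments, and ORF scanning by walking codons from every
# start offset.

# Full-match check of a motif against an exact string: recursive
# backtracking over all gap-length assignments.
oracle_full_match <- function(motif, s) {
  chars <- strsplit(toupper(s), "", fixed = TRUE)[[1L]]
  elements <- motif$elements
  rec <- function(ei, pos) {
    if (ei > length(elements)) return(pos == length(chars) + 1L)
    el <- elements[[ei]]
    if (el$type == "anchor") {
      if (pos <= length(chars) && chars[pos] == "C") rec(ei + 1L, pos + 1L)
      else FALSE
    } else {
      for (k in el$min:el$max) {
        if (pos + k - 1L > length(chars)) break
        if (k > 0L && any(chars[pos:(pos + k - 1L)] == "C")) next
        if (rec(ei + 1L, pos + k)) return(TRUE)
      }
      FALSE
    }
  }
  rec(1L, 1L)
}

# Existence check over every substring.
oracle_match_anywhere <- function(motif, s) {
  n <- nchar(s)
  sb <- span_bounds(motif)
  for (i in seq_len(max(n - sb[["min"]] + 1L, 0L))) {
    for (j in (i + sb[["min"]] - 1L):min(n, i + sb[["max"]] - 1L)) {
      if (oracle_full_match(motif, substr(s, i, j))) return(TRUE)
    }
  }
  FALSE
}

# Enumerate every string matched exactly by a motif over the {A, C}
# alphabet: gaps can only be filled with A, so each gap-length assignment
# yields exactly one string.
oracle_realizations_AC <- function(motif) {
  parts <- lapply(motif$elements, function(el) {
    if (el$type == "anchor") "C" else strrep("A", el$min:el$max)
  })
  Reduce(function(a, b) as.vector(outer(a, b, paste0)), parts)
}

# Every motif with <= max_elements elements and gap bounds <= gmax, no two
# adjacent gaps, at least one anchor. Returned as a list of cys_motif.
enumerate_small_motifs <- function(max_elements = 4L, gmax = 4L) {
  gaps <- list()
  for (lo in 0:gmax) for (hi in lo:gmax)
    gaps[[length(gaps) + 1L]] <- motif_gap(lo, hi)
  out <- list()
  grow <- function(elements, last_gap) {
    if (length(elements)) {
      types <- vapply(elements, `[[`, character(1), "type")
      if (any(types == "anchor"))
        out[[length(out) + 1L]] <<- cys_motif(elements)
    }
    if (length(elements) == max_elements) return(invisible())
    grow(c(elements, list(motif_anchor())), FALSE)
    if (!last_gap)
      for (g in gaps) grow(c(elements, list(g)), TRUE)
  }
  grow(list(), FALSE)
  out
}

# All strings over an alphabet up to a maximum length.
enumerate_strings <- function(alphabet, max_len) {
  out <- character(0)
  cur <- ""
  for (len in seq_len(max_len)) {
    cur <- as.vector(outer(cur, alphabet, paste0))
    out <- c(out, cur)
  }
  out
}

# Random motif with n_elements elements (used by property tests).
random_motif <- function(n_elements, gmax = 5L) {
  repeat {
    elements <- list()
    last_gap <- FALSE
    for (i in seq_len(n_elements)) {
      if (!last_gap && stats::runif(1) < 0.5) {
        lo <- sample.int(gmax + 1L, 1L) - 1L
        hi <- lo + sample.int(gmax - lo + 1L, 1L) - 1L
        elements[[i]] <- motif_gap(lo, hi)
        last_gap <- TRUE
      } else {
        elements[[i]] <- motif_anchor()
        last_gap <- FALSE
      }
    }
    types <- vapply(elements, `[[`, character(1), "type")
    if (any(types == "anchor")) return(cys_motif(elements))
  }
}

random_aa_string <- function(len, alphabet = c("A", "C", "G", "R", "L")) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

# Brute-force ORF scanner: on each strand, walk codons from every ATG to
# the first stop (or contig end). Translation is a plain lookup on the
# standard genetic code; input is restricted to A/C/G/T. Coordinates and
# conventions mirror extract_orfs(all_starts = TRUE).
oracle_orfs <- function(seq_id, s, min_aa = 1L, max_aa = Inf,
                        require_stop = TRUE) {
  code <- Biostrings::GENETIC_CODE
  L <- nchar(s)
  rows <- list()
  for (strand in c("+", "-")) {
    t <- if (strand == "-") {
      chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1L]]), collapse = ""))
    } else s
    starts <- gregexpr("ATG", t, fixed = TRUE)[[1L]]
    if (starts[1L] == -1L) next
    for (a in starts) {
      aa <- character(0)
      pos <- a
      has_stop <- FALSE
      while (pos + 2L <= L) {
        res <- unname(code[substr(t, pos, pos + 2L)])
        if (res == "*") {
          has_stop <- TRUE
          pos <- pos + 3L
          break
        }
        aa <- c(aa, res)
        pos <- pos + 3L
      }
      if (require_stop && !has_stop) next
      len <- length(aa)
      if (len < min_aa || len > max_aa) next
      rs <- a
      re <- pos - 1L
      if (strand == "+") {
        nt_start <- rs; nt_end <- re
        frame <- ((a - 1L) %% 3L) + 1L
      } else {
        nt_start <- L - re + 1L; nt_end <- L - rs + 1L
        frame <- -(((a - 1L) %% 3L) + 1L)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        seq_id = seq_id, frame = frame, nt_start = nt_start, nt_end = nt_end,
        aa_sequence = paste(aa, collapse = ""), has_stop = has_stop,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(seq_id = character(0), frame = integer(0),
                      nt_start = integer(0), nt_end = integer(0),
                      aa_sequence = character(0), has_stop = logical(0)))
  do.call(rbind, rows)
}

# Canonical key for comparing ORF tables as sets.
orf_key <- function(df) {
  sort(sprintf("%s|%d|%d|%d|%s|%d", df$seq_id, df$frame, df$nt_start,
               df$nt_end, df$aa_sequence, df$has_stop))
}

random_dna <- function(len) paste(sample(c("A", "C", "G", "T"), len,
                                         replace = TRUE), collapse = "")
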