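# Motif database, family assignment and the per-transcriptome screen.

#' Recognised AMP family labels
#' @return Character vector of valid motif family labels.
#' @export
amp_families <- function() {
  c("defensins", "thionins", "cyclotides", "snakins",
    "hevein-like", "lipid-transfer", "unknown")
}

#' Default family precedence
#'
#' Used only to break ties between motifs of equal specificity; ordered
#' roughly by increasing motif looseness.
#' @return Character vector.
#' @export
default_family_order <- function() {
  c("cyclotides", "defensins", "hevein-like", "thionins",
    "lipid-transfer", "snakins", "unknown")
}

#' Load a motif database
#'
#' Plain-text format, one motif per line: `<motif_id>TAB<family>TAB<pattern>`;
#' lines starting with `#` and blank lines are ignored. With `path = NULL`
#' the database shipped with the package is loaded; it contains the nine
#' published motifs (SNA02, LTP016, HEVHIP02, THI018, CYC01, CYC02, DEF06,
#' DEF32, DEF34) with their families.
#'
#' @param path Path to a motif database file, or `NULL` for the built-in.
#' @param family_order Family precedence used for tie-breaking.
#' @return Object of class `cysmotif_db`: a list with `motifs` (named list
#'   of `cys_motif`) and `family_order`.
#' @export
load_motif_db <- function(path = NULL, family_order = default_family_order()) {
  if (is.null(path))
    path <- system.file("extdata", "cysmotif_db.tsv", package = "cysmotif",
                        mustWork = TRUE)
  if (!file.exists(path)) stop("motif database not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  keep <- which(!grepl("^\\s*(#|$)", lines))
  if (!length(keep))
    stop("motif database '", path, "' contains no motifs", call. = FALSE)
  motifs <- list()
  for (i in keep) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(f) != 3L)
      stop(sprintf("motif database line %d: expected 3 tab-separated fields", i),
           call. = FALSE)
    if (f[1L] %in% names(motifs))
      stop(sprintf("motif database line %d: duplicate motif_id '%s'", i, f[1L]),
           call. = FALSE)
    m <- tryCatch(parse_motif(f[3L], motif_id = f[1L], family = f[2L]),
                  error = function(e)
                    stop(sprintf("motif database line %d: %s", i,
                                 conditionMessage(e)), call. = FALSE))
    motifs[[f[1L]]] <- m
  }
  fams <- unique(vapply(motifs, `[[`, character(1), "family"))
  missing <- setdiff(fams, family_order)
  if (length(missing))
    stop("family_order does not cover: ", paste(missing, collapse = ", "),
         call. = FALSE)
  structure(list(motifs = motifs, family_order = family_order),
            class = "cysmotif_db")
}

#' @export
print.cysmotif_db <- function(x, ...) {
  cat(sprintf("<cysmotif_db: %d motifs, %d families>\n", length(x$motifs),
              length(unique(vapply(x$motifs, `[[`, character(1), "family")))))
  for (m in x$motifs)
    cat(sprintf("  %-10s %-15s %s\n", m$motif_id, m$family, render_motif(m)))
  invisible(x)
}

#' Generic cysteine-richness criterion
#'
#' Membership test for the artificial "cysteine-rich peptides" group:
#' peptides that are clearly cysteine-rich but match no family motif. The
#' default threshold of 4 is permissive relative to the smallest family
#' motif (CYC02 has 6 anchors).
#'
#' @param mature_sequence Mature peptide string (non-empty).
#' @param min_cys Minimum number of cysteines, default 4.
#' @return Logical scalar.
#' @export
cys_rich_criterion <- function(mature_sequence, min_cys = 4L) {
  stopifnot(nzchar(mature_sequence))
  nchar(gsub("[^C]", "", toupper(mature_sequence))) >= min_cys
}

#' Assign a family from a set of motif hits
#'
#' The most specific matching motif wins, specificity being the smallest
#' span range `max_span - min_span`; ties are broken by the database's
#' family precedence, then motif id. All hits are retained in the screen's
#' hit table regardless of which motif wins.
#'
#' @param hits `data.frame` with a `motif_id` column (>= 1 row).
#' @param db A `cysmotif_db`.
#' @return List with `family` and `motif_id` of the winning motif.
#' @export
classify_peptide <- function(hits, db) {
  stopifnot(inherits(db, "cysmotif_db"), nrow(hits) >= 1L)
  ids <- unique(hits$motif_id)
  rng <- vapply(ids, function(id) {
    sb <- span_bounds(db$motifs[[id]])
    as.numeric(sb[["max"]] - sb[["min"]])
  }, numeric(1))
  fam <- vapply(ids, function(id) db$motifs[[id]]$family, character(1))
  ord <- order(rng, match(fam, db$family_order), ids)
  best <- ids[ord[1L]]
  list(family = db$motifs[[best]]$family, motif_id = best)
}

#' Pipeline configuration
#'
#' @param length_limit Precursor length limit (strict), default 150.
#' @param require_stop Keep only stop-terminated ORFs.
#' @param all_starts Enumerate every in-frame ATG per stop-bounded segment.
#' @param min_aa Minimum precursor length; 15 is the shortest sequence the
#'   signal-peptide heuristic can call positive.
#' @param min_cys Cysteine threshold for the artificial cysteine-rich group.
#' @param mature_region_rule Require the winning motif to lie in the mature
#'   peptide.
#' @param predictor Signal-peptide predictor function.
#' @param family_order Family precedence for classification tie-breaks.
#' @param seed Seed recorded into output headers.
#' @param threshold Consensus conservation threshold (reporting).
#' @return Named list of class `cysmotif_config`.
#' @export
pipeline_config <- function(length_limit = 150L, require_stop = TRUE,
                            all_starts = FALSE, min_aa = 15L, min_cys = 4L,
                            mature_region_rule = TRUE,
                            predictor = predict_signal_peptide,
                            family_order = default_family_order(),
                            seed = 1L, threshold = 0.7) {
  structure(list(length_limit = as.integer(length_limit),
                 require_stop = isTRUE(require_stop),
                 all_starts = isTRUE(all_starts),
                 min_aa = as.integer(min_aa),
                 min_cys = as.integer(min_cys),
                 mature_region_rule = isTRUE(mature_region_rule),
                 predictor = predictor,
                 family_order = family_order,
                 seed = as.integer(seed),
                 threshold = threshold),
            class = "cysmotif_config")
}

# Count-table keys: the six motif families plus the artificial group.
.count_keys <- function() {
  c("defensins", "thionins", "cyclotides", "snakins",
    "hevein-like", "lipid-transfer", "cysteine-rich", "unknown")
}

#' Screen a transcriptome for cysteine-rich peptides
#'
#' Composition of ORF extraction, motif scanning on the translated
#' precursor, the filtration cascade and family classification, applied to
#' every contig. Candidates passing length and signal filters that match no
#' family motif in the mature region but satisfy [cys_rich_criterion()] are
#' assigned to the artificial `"cysteine-rich"` group. Multiple ORFs of one
#' contig yielding identical mature peptides collapse to the one with the
#' lowest `nt_start` (assembly redundancy otherwise inflates counts).
#'
#' @param records A [Biostrings::DNAStringSet] (e.g. from [read_fasta()]) or
#'   a named character vector of contig sequences.
#' @param db Motif database from [load_motif_db()].
#' @param config A [pipeline_config()].
#' @param transcriptome_id Label carried into results and count tables.
#' @return Object of class `cysmotif_screen`: list with `transcriptome_id`,
#'   `peptides` (one row per retained peptide: coordinates, cleavage
#'   position, assigned family/motif, precursor and mature sequences),
#'   `hits` (all mature-region motif hits of retained peptides),
#'   `rejections` (ORFs that failed, with reasons) and `counts` (named
#'   vector over families plus the cysteine-rich group).
#' @export
screen_transcriptome <- function(records, db = load_motif_db(),
                                 config = pipeline_config(),
                                 transcriptome_id = "transcriptome") {
  stopifnot(inherits(db, "cysmotif_db"), inherits(config, "cysmotif_config"))
  if (methods::is(records, "DNAStringSet")) {
    seqs <- as.character(records)
  } else {
    seqs <- records
  }
  if (length(seqs) && is.null(names(seqs)))
    stop("records must be named", call. = FALSE)
  db$family_order <- config$family_order

  pep <- list()
  hit <- list()
  rej <- list()
  for (cid in names(seqs)) {
    orfs <- extract_orfs(cid, seqs[[cid]], min_aa = config$min_aa,
                         require_stop = config$require_stop,
                         all_starts = config$all_starts)
    for (k in seq_len(nrow(orfs))) {
      orf <- orfs[k, ]
      # cheap predicates first; the retained set is order-independent, so
      # skipping the motif scan for ORFs that fail them changes nothing
      if (!check_length(orf$aa_sequence, config$length_limit)) {
        rej[[length(rej) + 1L]] <- data.frame(
          seq_id = orf$seq_id, frame = orf$frame, nt_start = orf$nt_start,
          reason = "too_long", stringsAsFactors = FALSE)
        next
      }
      if (!isTRUE(config$predictor(orf$aa_sequence)$is_positive)) {
        rej[[length(rej) + 1L]] <- data.frame(
          seq_id = orf$seq_id, frame = orf$frame, nt_start = orf$nt_start,
          reason = "no_signal", stringsAsFactors = FALSE)
        next
      }
      hits <- .scan_motifs(db, orf$aa_sequence)
      res <- apply_filters(orf, hits, limit = config$length_limit,
                           predictor = config$predictor,
                           mature_region_rule = config$mature_region_rule)
      if (res$retained) {
        cls <- classify_peptide(res$motif_hits, db)
        pep[[length(pep) + 1L]] <- data.frame(
          seq_id = orf$seq_id, frame = orf$frame,
          nt_start = orf$nt_start, nt_end = orf$nt_end,
          has_stop = orf$has_stop,
          cleavage_pos = res$signal$cleavage_pos,
          family = cls$family, motif_id = cls$motif_id,
          precursor = orf$aa_sequence, mature = res$mature_sequence,
          stringsAsFactors = FALSE)
        hit[[length(hit) + 1L]] <- data.frame(
          seq_id = orf$seq_id, frame = orf$frame, nt_start = orf$nt_start,
          motif_id = res$motif_hits$motif_id,
          start = res$motif_hits$start, end = res$motif_hits$end,
          stringsAsFactors = FALSE)
      } else if (res$reason %in% c("no_motif", "motif_in_signal") &&
                 cys_rich_criterion(res$mature_sequence, config$min_cys)) {
        pep[[length(pep) + 1L]] <- data.frame(
          seq_id = orf$seq_id, frame = orf$frame,
          nt_start = orf$nt_start, nt_end = orf$nt_end,
          has_stop = orf$has_stop,
          cleavage_pos = res$signal$cleavage_pos,
          family = "cysteine-rich", motif_id = NA_character_,
          precursor = orf$aa_sequence, mature = res$mature_sequence,
          stringsAsFactors = FALSE)
      } else {
        rej[[length(rej) + 1L]] <- data.frame(
          seq_id = orf$seq_id, frame = orf$frame, nt_start = orf$nt_start,
          reason = res$reason, stringsAsFactors = FALSE)
      }
    }
  }

  peptides <- if (length(pep)) do.call(rbind, pep) else
    data.frame(seq_id = character(0), frame = integer(0),
               nt_start = integer(0), nt_end = integer(0),
               has_stop = logical(0), cleavage_pos = integer(0),
               family = character(0), motif_id = character(0),
               precursor = character(0), mature = character(0),
               stringsAsFactors = FALSE)
  hits <- if (length(hit)) do.call(rbind, hit) else
    data.frame(seq_id = character(0), frame = integer(0),
               nt_start = integer(0), motif_id = character(0),
               start = integer(0), end = integer(0), stringsAsFactors = FALSE)
  rejections <- if (length(rej)) do.call(rbind, rej) else
    data.frame(seq_id = character(0), frame = integer(0),
               nt_start = integer(0), reason = character(0),
               stringsAsFactors = FALSE)

  # de-duplicate identical mature peptides within a contig: keep lowest nt_start
  if (nrow(peptides)) {
    peptides <- peptides[order(peptides$seq_id, peptides$mature,
                               peptides$nt_start), ]
    keep <- !duplicated(peptides[, c("seq_id", "mature")])
    peptides <- peptides[keep, ]
    peptides <- peptides[order(match(peptides$seq_id, names(seqs)),
                               peptides$nt_start), ]
    rownames(peptides) <- NULL
  }

  counts <- stats::setNames(integer(length(.count_keys())), .count_keys())
  if (nrow(peptides)) {
    tab <- table(peptides$family)
    counts[names(tab)] <- as.integer(tab)
  }

  structure(list(transcriptome_id = transcriptome_id, peptides = peptides,
                 hits = hits, rejections = rejections, counts = counts,
                 config = config),
            class = "cysmotif_screen")
}

# All motif hits of a database on one precursor sequence.
.scan_motifs <- function(db, aa_sequence) {
  out <- lapply(db$motifs, function(m) {
    fm <- find_matches(m, aa_sequence)
    if (nrow(fm)) cbind(data.frame(motif_id = m$motif_id,
                                   stringsAsFactors = FALSE), fm)
    else NULL
  })
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out))
    return(data.frame(motif_id = character(0), start = integer(0),
                      end = integer(0), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' @export
print.cysmotif_screen <- function(x, ...) {
  cat(sprintf("<cysmotif_screen '%s': %d peptides, %d rejections>\n",
              x$transcriptome_id, nrow(x$peptides), nrow(x$rejections)))
  print(x$counts)
  invisible(x)
}
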