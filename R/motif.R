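# Cysteine-motif pattern language: parsing, rendering, span arithmetic and
# matching.
#
# A motif is an ordered list of elements, each either a cysteine anchor "C"
# or a bounded wildcard gap "X{m,n}" standing for m..n residues, none of
# which may be cysteine. A bare "X" is a gap of exactly one residue and
# "X{n}" a gap of exactly n. Gaps are matched independently of each other;
# the matcher must find any consistent assignment of gap lengths.

#' Construct a gap element
#'
#' @param min_len,max_len Non-negative integer residue counts, `min_len <=
#'   max_len`.
#' @param bare Logical; `TRUE` when the gap was written as a bare `X` in the
#'   notation (affects rendering only, not semantics).
#' @return A gap element usable in [cys_motif()].
#' @export
motif_gap <- function(min_len, max_len = min_len, bare = FALSE) {
  min_len <- as.integer(min_len)
  max_len <- as.integer(max_len)
  if (is.na(min_len) || is.na(max_len) || min_len < 0 || max_len < min_len)
    stop("gap bounds must satisfy 0 <= min_len <= max_len", call. = FALSE)
  list(type = "gap", min = min_len, max = max_len,
       bare = isTRUE(bare) && min_len == 1L && max_len == 1L)
}

#' Construct a cysteine anchor element
#' @return An anchor element usable in [cys_motif()].
#' @export
motif_anchor <- function() list(type = "anchor")

#' Construct a cysteine motif from elements
#'
#' Validates the structural invariants of the pattern language: at least one
#' cysteine anchor, and no two adjacent gaps (adjacent gaps would be an
#' ambiguous way of writing a single merged gap and are rejected as likely
#' typos).
#'
#' @param elements List of elements from [motif_anchor()] / [motif_gap()].
#' @param motif_id Short identifier, e.g. `"DEF06"`.
#' @param family Family label; one of `"defensins"`, `"thionins"`,
#'   `"cyclotides"`, `"snakins"`, `"hevein-like"`, `"lipid-transfer"`,
#'   `"unknown"`.
#' @return An object of class `cys_motif`.
#' @export
cys_motif <- function(elements, motif_id = NA_character_, family = "unknown") {
  if (length(elements) == 0L) stop("motif must contain at least one element", call. = FALSE)
  types <- vapply(elements, `[[`, character(1), "type")
  if (!any(types == "anchor"))
    stop("motif must contain at least one cysteine anchor", call. = FALSE)
  adj <- which(types[-length(types)] == "gap" & types[-1L] == "gap")
  if (length(adj))
    stop("adjacent gaps are not allowed (element ", adj[1L], " and ", adj[1L] + 1L, ")",
         call. = FALSE)
  if (!family %in% amp_families())
    stop("unknown family label '", family, "'", call. = FALSE)
  structure(list(motif_id = motif_id, family = family, elements = elements),
            class = "cys_motif")
}

#' Parse cysteine-motif notation
#'
#' Accepted tokens: `C` (cysteine anchor), `X` (exactly one non-cysteine
#' residue), `X{n}` (exactly n), `X{m,n}` (between m and n inclusive).
#' Syntax errors are reported with the 1-based character offset at which
#' they were detected.
#'
#' @param text Motif notation string, e.g. `"CX{2,4}C"`.
#' @param motif_id,family Passed through to [cys_motif()].
#' @return A `cys_motif` object; `render_motif(parse_motif(text))`
#'   reproduces `text` for canonical input.
#' @examples
#' parse_motif("CX{2,4}C")
#' @export
parse_motif <- function(text, motif_id = NA_character_, family = "unknown") {
  if (!is.character(text) || length(text) != 1L || is.na(text) || !nzchar(text))
    stop("motif text must be a non-empty string", call. = FALSE)
  chars <- strsplit(text, "", fixed = TRUE)[[1L]]
  n <- length(chars)
  err <- function(msg, pos)
    stop(sprintf("motif syntax error at character %d: %s", pos, msg), call. = FALSE)
  elements <- list()
  i <- 1L
  while (i <= n) {
    ch <- chars[i]
    if (ch == "C") {
      elements[[length(elements) + 1L]] <- motif_anchor()
      i <- i + 1L
    } else if (ch == "X") {
      if (i < n && chars[i + 1L] == "{") {
        close <- i + 1L
        while (close <= n && chars[close] != "}") close <- close + 1L
        if (close > n) err("unclosed '{'", i + 1L)
        body <- paste(chars[(i + 2L):(close - 1L)], collapse = "")
        if (!grepl("^[0-9]+(,[0-9]+)?$", body))
          err(sprintf("malformed gap bound '{%s}'", body), i + 1L)
        parts <- as.integer(strsplit(body, ",", fixed = TRUE)[[1L]])
        lo <- parts[1L]
        hi <- if (length(parts) == 2L) parts[2L] else parts[1L]
        if (hi < lo)
          err(sprintf("gap minimum %d exceeds maximum %d", lo, hi), i + 1L)
        gap <- motif_gap(lo, hi)
        if (length(elements) && elements[[length(elements)]]$type == "gap")
          err("adjacent gaps are ambiguous; merge them into one", i)
        elements[[length(elements) + 1L]] <- gap
        i <- close + 1L
      } else {
        if (length(elements) && elements[[length(elements)]]$type == "gap")
          err("adjacent gaps are ambiguous; merge them into one", i)
        elements[[length(elements) + 1L]] <- motif_gap(1L, 1L, bare = TRUE)
        i <- i + 1L
      }
    } else {
      err(sprintf("unexpected character '%s'", ch), i)
    }
  }
  cys_motif(elements, motif_id = motif_id, family = family)
}

#' Render a motif back to notation
#'
#' Gaps written as a bare `X` render as `X`; gaps constructed as `X{1}` (or
#' programmatically) render as `X{n}`; ranged gaps as `X{m,n}`. This
#' preserves exact round-tripping of published motif strings, which mix the
#' bare and braced one-residue forms.
#'
#' @param motif A `cys_motif`.
#' @return Motif notation string.
#' @export
render_motif <- function(motif) {
  stopifnot(inherits(motif, "cys_motif"))
  paste(vapply(motif$elements, function(el) {
    if (el$type == "anchor") return("C")
    if (isTRUE(el$bare)) return("X")
    if (el$min == el$max) sprintf("X{%d}", el$min) else sprintf("X{%d,%d}", el$min, el$max)
  }, character(1)), collapse = "")
}

#' Minimum and maximum span of a motif match
#'
#' @param motif A `cys_motif`.
#' @return Named integer vector `c(min = , max = )`: the number of anchors
#'   plus the summed gap minima / maxima. Every match has a length within
#'   these bounds, and a motif whose `min` exceeds the target length cannot
#'   match.
#' @export
span_bounds <- function(motif) {
  stopifnot(inherits(motif, "cys_motif"))
  lo <- 0L
  hi <- 0L
  for (el in motif$elements) {
    if (el$type == "anchor") {
      lo <- lo + 1L
      hi <- hi + 1L
    } else {
      lo <- lo + el$min
      hi <- hi + el$max
    }
  }
  c(min = lo, max = hi)
}

# Translate a motif into a PCRE pattern. Anchors become literal "C"; gaps
# become a negated character class with a (lazy) bounded quantifier, so that
# regex backtracking explores all consistent gap-length assignments. The
# ambiguity letter X falls inside [^C]: an unknown residue may sit in a gap
# but never counts as a cysteine anchor.
.motif_regex <- function(motif, lazy = TRUE) {
  q <- if (lazy) "?" else ""
  paste(vapply(motif$elements, function(el) {
    if (el$type == "anchor") return("C")
    if (el$min == el$max) {
      if (el$min == 0L) return("")
      sprintf("[^C]{%d}", el$min)
    } else {
      sprintf("[^C]{%d,%d}%s", el$min, el$max, q)
    }
  }, character(1)), collapse = "")
}

# Uppercase amino-acid string(s) and reject anything outside the 20
# standard residues plus the ambiguity letter X.
.check_aa <- function(sequence) {
  stopifnot(is.character(sequence), !anyNA(sequence))
  s <- toupper(sequence)
  bad <- regexpr("[^ACDEFGHIKLMNPQRSTVWYX]", s, perl = TRUE)
  hit <- which(bad != -1L)
  if (length(hit)) {
    i <- hit[1L]
    stop(sprintf("invalid amino-acid character '%s' at position %d",
                 substr(s[i], bad[i], bad[i]), bad[i]), call. = FALSE)
  }
  s
}

#' Find motif matches in an amino-acid sequence
#'
#' A substring matches when anchors align to literal `C` and each gap
#' consumes between its minimum and maximum residues, none of which is `C`.
#' For each start position that admits at least one match, the single
#' shortest match at that start (lazy gap quantifiers) is reported, so
#' output is deterministic and minimal; overlapping starts are all reported.
#'
#' @param motif A `cys_motif`.
#' @param sequence Amino-acid string (20 standard letters plus `X`);
#'   lowercase input is uppercased.
#' @return `data.frame` with integer columns `start` and `end` (1-based,
#'   inclusive), zero rows when there is no match.
#' @examples
#' find_matches(parse_motif("CX{2,4}C"), "CARC")
#' @export
find_matches <- function(motif, sequence) {
  stopifnot(inherits(motif, "cys_motif"))
  s <- .check_aa(sequence)
  n <- nchar(s)
  empty <- data.frame(start = integer(0), end = integer(0))
  sb <- span_bounds(motif)
  if (n < sb[["min"]]) return(empty)  # min span >= 1: a motif has an anchor
  pat <- paste0("^", .motif_regex(motif, lazy = TRUE))
  starts <- seq_len(n - sb[["min"]] + 1L)
  if (motif$elements[[1L]]$type == "anchor")
    starts <- starts[substring(s, starts, starts) == "C"]
  hit_s <- integer(0)
  hit_e <- integer(0)
  for (i in starts) {
    win <- substr(s, i, min(n, i + sb[["max"]] - 1L))
    m <- regexpr(pat, win, perl = TRUE)
    if (m == 1L) {
      hit_s <- c(hit_s, i)
      hit_e <- c(hit_e, i + attr(m, "match.length") - 1L)
    }
  }
  data.frame(start = hit_s, end = hit_e)
}

#' Does a motif match anywhere in a sequence?
#'
#' Existence test used by the classifier; equivalent to
#' `nrow(find_matches(...)) > 0` but short-circuits inside the regex engine.
#' Vectorised over `sequence`.
#'
#' @param motif A `cys_motif`.
#' @param sequence Character vector of amino-acid strings.
#' @return Logical vector along `sequence`.
#' @export
matches_anywhere <- function(motif, sequence) {
  stopifnot(inherits(motif, "cys_motif"))
  s <- .check_aa(sequence)
  grepl(.motif_regex(motif, lazy = TRUE), s, perl = TRUE)
}

#' @export
print.cys_motif <- function(x, ...) {
  sb <- span_bounds(x)
  cat(sprintf("<cys_motif %s [%s] %s span %d-%d>\n",
              ifelse(is.na(x$motif_id), "(unnamed)", x$motif_id),
              x$family, render_motif(x), sb[["min"]], sb[["max"]]))
  invisible(x)
}
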