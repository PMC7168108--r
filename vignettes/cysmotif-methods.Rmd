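---
title: "Screening transcriptomes for cysteine-rich antimicrobial peptides: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening transcriptomes for cysteine-rich antimicrobial peptides}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cysmotif)
```

## The problem

Plant antimicrobial peptides (AMPs) — defensins, thionins, cyclotides,
snakins, hevein-like peptides and non-specific lipid-transfer proteins
(LTPs) — are short secreted peptides whose defining feature is a conserved
*cysteine scaffold*: a fixed number of cysteines at characteristic spacings,
stabilised by disulfide bridges. Because primary sequence between the
cysteines diverges quickly, homology search misses many family members;
the scaffold itself is the more robust signature. `cysmotif` screens
assembled transcriptomes for that signature: it translates contigs in six
frames, extracts candidate open reading frames, filters them the way a
secreted peptide precursor must look (methionine start, signal peptide,
bounded length), and classifies survivors by which cysteine motif they
carry.

## The motif language

A motif is written over two symbols: `C`, a literal cysteine, and `X`, any
single residue *except* cysteine. A braced quantifier bounds a run of
wildcards: `X{n}` is exactly *n* non-cysteine residues and `X{m,n}` between
*m* and *n*. So `CX{2,4}C` matches `CARC` and `CATFC` but neither `CACTC`
(a cysteine inside the gap) nor `CAATRFC` (too wide a gap). Each gap is
matched independently, and the matcher must find *any* consistent
assignment of gap lengths — implemented by compiling gaps to the negated
character class `[^C]` with bounded lazy quantifiers, so PCRE backtracking
explores assignments and per-start matches are deterministically the
shortest. Two points deserve emphasis:

* **The exclusion matters.** Treating `X` as "any residue" would let a gap
  swallow a cysteine and produce spurious scaffolds; `[^C]` makes
  consecutive anchors in a match correspond to consecutive cysteines in the
  sequence.
* **The ambiguity letter.** Translating codons containing `N` yields `X`
  in the peptide. An unknown residue is *not known to be* cysteine, so it
  may sit in a gap but never satisfies an anchor — conservative toward
  anchor identity, permissive toward gaps.

Width-1 gaps have two published spellings (`X` and `X{1}`), and the shipped
database uses both; parsed motifs remember the spelling so that rendering
round-trips the published strings exactly.

The built-in database holds the nine published motifs across six families
(`load_motif_db()`); its plain-text format (`id TAB family TAB pattern`)
makes extension trivial. The original tool is described as carrying 138
motifs, but only nine are published; the remainder cannot be reconstructed
and are not shipped.

## The pipeline and its parameters

For each contig, ORFs are taken per stop-bounded segment at the first
in-frame ATG (the longest-candidate convention; `all_starts = TRUE`
enumerates every ATG when short mature peptides behind internal methionines
matter). Defaults and rationale:

| parameter | default | why |
|---|---|---|
| `length_limit` | 150 aa, strict `<` | published filtration step; applied to the precursor (Met included, stop excluded) since the original limit acts on translated ORFs |
| `require_stop` | `TRUE` | a genuine precursor transcript terminates; disable for fragmented assemblies |
| `min_aa` | 15 | shortest sequence the signal heuristic can call positive |
| `min_cys` | 4 | artificial-group threshold; permissive relative to the smallest family motif (CYC02, 6 anchors) |
| `mature_region_rule` | `TRUE` | AMP scaffolds reside in the mature chain, so the motif must start at or after the cleavage point |

### Signal peptides without SignalP

The published pipeline calls SignalP, an external licensed binary. To keep
this package self-contained and auditable, the default predictor is a
transparent heuristic built from the classical tripartite anatomy of a
secretory signal, with every threshold a visible argument:

1. **n-region charge**: net charge of residues 2–6 (K/R = +1, D/E = −1)
   must be ≥ 0 — signal peptides begin positively charged;
2. **h-region**: some window of 8 residues within positions 5–25 must have
   mean Kyte–Doolittle hydropathy ≥ 1.6 — the membrane-inserting core;
3. **cleavage site**: the first position `p` in 12–40 whose residues `p−3`
   and `p−1` are small (`A G S C T V`) — the von Heijne (−3,−1) rule; `p`
   is the first mature residue.

These thresholds are *choices*, not measurements; the predictor is
deliberately pluggable (`predictor =` takes any function returning
`is_positive` / `cleavage_pos` / `score`), so a SignalP adapter can be
substituted without touching the pipeline. The heuristic's score (logistic
of the best window hydropathy) orders candidates but never gates them.

### Classification

A peptide matching several motifs is assigned to the *most specific* one:
smallest span range `max_span − min_span` (a fixed-span motif like DEF06,
range 0, always beats a loose one like DEF32, range 79), with ties broken
by a configurable family precedence and then motif id. Candidates passing
length and signal filters with ≥ `min_cys` cysteines in the mature chain
but no family motif fall into the artificial **cysteine-rich** group — a
catch-all that flags "scaffold-like but unclassified", not a biological
family. Identical mature peptides arising from several ORFs of one contig
are collapsed to the lowest-coordinate copy, since assembly redundancy
would otherwise inflate counts.

## False-positive calibration

How often would random sequence produce a "hit"? `estimate_fpr()` answers
per motif, in two modes: random peptides fed straight to the matcher
(isolates motif looseness), or random contigs fed through the *entire*
pipeline (the default; measures what the screen as a whole would report on
noise). Each fraction carries a Wilson 95% interval, chosen over the Wald
interval for its behaviour at counts near zero — exactly the regime of
interest. For small alphabets and lengths, `analytic_match_prob()`
computes the exact probability by exhaustive enumeration and serves as the
independent cross-check; a coverage test confirms the Wilson intervals
contain the analytic value in ≥ 90% of replicates.

## Consensus and conservation

Given an aligned set of family members (alignment computation is out of
scope; aligned FASTA is an input), `consensus_from_alignment()` reports
per-column residue frequencies and a consensus string in which a column is
a residue letter only when that residue exceeds the threshold (default
0.7, strictly) among *non-gap* entries, and `z` otherwise. Excluding gaps
from the denominator avoids penalising length-variable termini; the
threshold is strict because "more than 70%" reads naturally as an open
bound, and strictness is the conservative direction (fewer letters, more
`z`). `conservation_summary()` counts fully conserved non-cysteine
positions (cysteines are conserved by construction in a motif-defined
family and would only pad the count) and the above-threshold fraction.
Conservation is computed per input sequence, one vote each; if sequences
over-represent some taxa, the caller should deduplicate before aligning.

## What the synthetic generator does and does not establish

`generate_transcriptome()` builds the *stated world* the tests run in: for
each family it samples motif realizations (gaps filled with uniform non-C
residues, lengths uniform within bounds), wraps them in a precursor whose
signal region is constructed to satisfy the heuristic exactly
(charged-then-leucine prefix, `A-Q-A` cassette, no earlier small-residue
pair), reverse-translates with uniform synonymous codons, appends a stop,
and embeds the CDS in random UTR context (20–200 nt each side) on a random
strand — with an in-frame stop placed immediately upstream of the ATG so
the planted start is always the first of its segment. Decoys are uniform
random contigs.

Two deliberate design points:

* **Unambiguous ground truth.** A realization of a loose motif can, rarely
  (~0.2% of DEF32 draws), also match a more specific motif of another
  family, in which case the classifier's own precedence rule would assign
  it there. Such realizations are redrawn, so the manifest's family labels
  are correct by construction for any seed and the 100%-recall test is
  meaningful rather than seed-lucky.
* **What a green test means.** Planted genes are built to pass every
  filter, so 100% recall validates the *plumbing* — coordinates, strand
  mapping, translation, filtration, precedence — not biological
  sensitivity. Real transcriptomes have codon bias, sequencing error,
  fragmented ORFs and signal peptides the heuristic will miss; none of
  that is modelled, which is why the false-positive side is calibrated
  separately on random sequence and why recall on real data is out of
  scope.

## Numerical and convention choices

* Coordinates are 1-based inclusive on the forward strand (the
  R/Bioconductor convention), for both nucleotide spans (stop codon
  included: `width = 3·len + 3`) and motif match spans.
* Translation is a direct lookup on the standard genetic code; codons with
  `N` resolve exhaustively to a residue when unambiguous, else `X`.
* Per-start motif matches use lazy quantifiers: output is the
  deterministic shortest match at each admissible start; existence
  (`matches_anywhere()`) is what classification consumes.
* Adjacent gaps in motif notation (`X{2}X{3}`) are rejected, not merged:
  merging changes no semantics but would hide database typos.
* Degenerate inputs: empty FASTA, duplicate ids and non-IUPAC characters
  are errors with positions; stop-free contigs under `require_stop` yield
  an all-zero result, not an error; sequences shorter than 15 aa get a
  negative signal prediction, not an error.

## Known limitations

Only the nine published motifs ship. The signal heuristic trades accuracy
for transparency and will disagree with SignalP on real sequences. The
artificial group's threshold (≥ 4 cysteines) is a convention. Homology
annotation, SPADA-style profile search, and alignment construction are
explicitly out of scope. The screen is single-process and streams contig
by contig — adequate at desk scale, unoptimised for thousand-transcriptome
datasets.
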