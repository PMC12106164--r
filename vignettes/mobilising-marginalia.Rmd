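---
title: "Mobilising printed plant names and handwritten marginalia: methods"
author: "marginalia package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mobilising printed plant names and handwritten marginalia: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(marginalia)
```

## The task and its assumptions

Annotated herbals interleave two information systems: a printed list of
polynomial plant names with descriptive paragraphs, and handwritten
`H.S. [volume] [folio] [specimen]` references that index physical specimens
in a bound herbarium. `marginalia` turns word-level OCR block output of such
pages into linked records: which specimen reference belongs to which plant
name.

Everything downstream of text recognition is geometric. The package assumes:

* blocks arrive in a PAGE / LINE / WORD hierarchy with *fractional*
  bounding boxes (origin top-left, coordinates as ratios of page size) and a
  per-word PRINTED / HANDWRITING flag;
* pages come in two mirror-image layouts (odd/even parity), signalled by
  running titles, with annotations in the *outer* side margin;
* a roughly constant line pitch within a page, so spacing thresholds can be
  expressed as multiples of a robust pitch estimate;
* annotations are written beside (or just below) the entry they index, so
  vertical distance between box tops recovers the pairing.

Transcription quality is deliberately *not* assumed: all geometric stages
work on corrupted text, fuzzy matching absorbs common OCR confusions, and
reference parsing is best-effort with an explicit residue.

## Stage by stage

**Parity.** Printed lines in the top band (default top 15% of the page) are
fuzzy-matched against per-parity running-title patterns. Matching folds
case, maps `1→I` and `0→O`, strips spaces, and accepts a bounded edit
distance (default 2) computed as a partial (substring) match, which absorbs
the observed title corruptions (`H1STORIA`, `H IST OR1A`,
`H I S T O R I A`). Page-number recognition is folded into this evidence:
parity is the only thing the number is needed for. No match is the value
`UNKNOWN`, not an error.

**Margin boundary.** Word x-intervals are merged into clusters wherever the
gap between them is below `min_gap` (default 0.02 page widths). The cluster
with the most words is the printed body; on the parity-implied side the
boundary is the midpoint of the largest inter-cluster gap. If nothing is
separated by more than `min_gap`, the page simply has no margin words.
The margin side per parity (LEFT on even pages, RIGHT on odd) is the outer
margin of a bound opening; the mapping is configurable because different
volumes could bind differently, and for `UNKNOWN` parity the side with the
larger separation is used.

**Line classes.** Every line is assigned to exactly one of header, footer,
margin, body, or discarded. Headers are lines at/above the running title or
with top above `header_frac` (0.06); footers below `footer_frac` (0.92);
discarded lines ("bleed" from the adjacent page of the opening) lie entirely
more than `bleed_frac` (0.02) outside the body envelope on the *non*-margin
side. The partition property (no loss, no duplication) is tested, as is
mirror symmetry: flipping the page horizontally and swapping parity mirrors
the layout.

**Paragraphs from word boxes.** Skewed scans inflate provider *line* boxes:
a line box's top can sit far above its words, which destroys spacing-based
segmentation. Per-line tops are therefore the *median* of member word-box
tops (the median, not the minimum, because the minimum inherits the skew of
the leftmost/rightmost words). A new paragraph starts when the gap between
consecutive printed lines exceeds `para_gap_mult` (1.6) times the page's
line pitch — itself a median of consecutive gaps, so paragraph gaps do not
bias it. Handwritten lines are excluded from the gap computation entirely
(an annotation squeezed between printed lines must neither split nor glue a
paragraph) but their words are kept as flagged members of the positionally
nearest paragraph, ties toward the preceding one — consumers can thus strip
handwriting from printed transcriptions.

**Plant names.** The primary signal is typographic: a first-line indent
beyond the body's left edge by more than `indent_frac` (0.015) with at most
`max_name_lines` (3) printed lines. Names set flush with the text fall back
to any of: a leading author abbreviation from a configurable lexicon
(`J.B.`, `C.B.`, `Ger.`, ...), a leading capital with at most two lines, or
all words uppercase. The OR-combination (rather than some precedence order)
was chosen because each fallback is individually high-precision on short
segments and the features are not mutually exclusive; the classification is
deterministic given the configuration.

**Margins, headers, footers.** Margin lines open a new segment at the
`H.S.` initials (fuzzy: `H.S.`, `H. S.`, `HS`, stray commas — the pattern is
one configurable regex, since whether the original matching was exact is
unknowable from the outside) or at a gap above `margin_gap_mult` (2.0)
times the pitch. Within the header/footer bands, printed furniture is set
aside and the handwritten lines are grouped by the same gap rule.
Reference parsing accepts an optional `p`-prefixed folio
(`H.S. 114. p.29. 1.`) and returns unparsed spans as residue rather than
failing: a transcription like `82.153. 108.73.` following a reference is
real data that a curator, not the parser, should interpret.

**Association.** Each margin segment links to the plant-name segment
minimising the absolute difference of bounding-box *tops* — tops exactly,
not centroids, though a centroid variant sits behind a config flag.
Many-to-one is allowed (a folio holds many specimens of one species).
Equidistant candidates resolve toward the smaller top, because annotations
are usually written beside or just below their entry; equality is taken up
to 1e-12 so floating-point noise cannot flip a genuine tie. Header and
footer annotations are *not* distance-linked: they carry their own plant
names and are emitted as standalone records. Pages without plant names put
their margins in an explicit `unlinked` list.

**Evaluation.** CER is `100 × Levenshtein / |ground truth|` with uniform
edit costs, after NFC normalisation (composed and decomposed accents must
compare equal). Segments match one-to-one greedily by descending IoU,
strictly above the threshold (default 0.7) — "exceeded" is read as strict,
and greedy was chosen over optimal assignment for transparency, with an
enumeration oracle in the tests guarding against divergence on separated
instances. A predicted margin-to-plant pair is correct only if both
endpoints IoU-match ground-truth segments *and* the ground truth links those
segments; endpoint matching (not text identity) is the default, text
identity being a reasonable alternative reading. Reports round P/R/F1 to
2 decimals and CER to 1.

## What the synthetic generator emulates — and what it does not

`generate_page()` lays out a parity-correct page: running title and page
number, indented one-line plant names above flush-left paragraphs
(consecutive lines one pitch apart, boundaries two pitches), handwritten
`H.S.` margin annotations, optional header/footer annotations, and the
three noise processes that motivated the design:

* **skew** — line boxes inflated upward on a random half of lines while
  word boxes stay tight (`skew_inflation`, as a fraction of page height;
  0.012 ≈ 0.8 pitch in the tests, enough that line-box segmentation merges
  names into paragraphs while word-level segmentation is unaffected);
* **interruptions** — handwritten lines squeezed mid-paragraph
  (`handwritten_interruption_rate`);
* **bleed** — words beyond the non-margin edge (`bleed_word_count`);
* **character noise** — per-character substitutions at `char_noise_rate`,
  interpreted over the full transcription character stream (substitutions
  land on non-space characters, so the per-word rate is scaled by each
  line's space share); ground truth keeps the clean text, so generated
  corpora have known expected CER.

Margin tops are jittered by at most 40% of the inter-entry spacing, which
provably keeps the intended entry the nearest-top argmin — the ground-truth
pairing stays well defined under noise.

Defaults (4 entries, 3 margin annotations, 3–6-line paragraphs, pitch
0.015, one header and one footer annotation, all noise off) describe a
clean, well-separated page. Determinism is byte-level: the same spec always
yields identical JSON.

The generator does **not** emulate: rotated or warped geometry (only the
line-box symptom of skew), multi-column layouts, Gothic-font confusion
models or any realistic OCR error distribution (noise is uniform
substitution), intersecting annotations whose pairing even humans dispute,
or raster images. Perfect recovery on generated corpora therefore
demonstrates the correctness of the geometric algorithms under the stated
layout model — not expected field accuracy on scans, where transcription
quality and layout irregularity dominate.

## Numerical and degenerate-input choices

* All thresholds are fractions of page size (scale-free) and live in one
  `mobilise_config()` object; the layout features are documented in the
  source material, the numeric values are this package's own calibration.
* Box invariants tolerate ε = 1e-6 beyond [0, 1] for provider rounding.
* Fewer than two lines make the pitch undefined: `line_pitch()` returns
  `NA` and the pipeline substitutes `default_pitch` (0.015).
* Empty pages mobilise to empty records (`UNKNOWN` group); a page that
  fails outright (e.g. lines without words) is logged and skipped in corpus
  mode, never fatal.
* Words below a confidence floor are flagged, never dropped — downstream
  stages decide; by default confidence is not consumed at all, since there
  is no evidence the geometry stages should depend on it.
* Orphan WORD blocks are wrapped in synthetic one-word lines so degraded
  provider output still flows through (with a warning).
* Pixel crop boxes use floor(left/top) and ceiling(right/bottom), clipped to
  the page, so a crop always covers its fractional box.

## Problem sizes

The shipped test suite and acceptance script work at sizes chosen to
exercise every code path while keeping runs interactive: a 50-page clean
corpus (~200 plant entries, ~125 annotations) for exact recovery, 10 skewed
pages for the word-level vs line-box comparison, 20 pages at 10% character
noise (~260 segments, ~30k characters) for CER calibration, and
1,000/200/30-case oracle sweeps for CER, nearest-top linking and greedy
matching respectively.

## Known limitations

* Parity classification depends on the title lexicon; volumes with other
  running titles need a pattern file (`read_title_patterns()`).
* One margin boundary per page: layouts with annotations in *both* margins
  would need two boundaries.
* The nearest-top rule cannot resolve genuinely ambiguous intersecting
  annotations; `tie_epsilon` can flag near-ties for human review, which is
  the appropriate remedy.
* Reference parsing is a regex over noisy transcriptions; it extracts what
  matches and surfaces the rest as residue rather than guessing.
* No OCR post-correction: transcriptions pass through verbatim.
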