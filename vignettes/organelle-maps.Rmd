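---
title: "Drawing organellar genome maps: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Drawing organellar genome maps: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(orgmapr)
```

This vignette documents the models, conventions and numerical choices
behind `orgmapr`, in the spirit of a methods section: what each
computation assumes, which parameters matter, and where the design was
genuinely open.

## The map model

A map is resolved in two strictly separated stages. The **layout**
stage turns a parsed record plus a configuration into
resolution-independent geometry (angles in degrees, x-positions in
abstract map units); the **render** stage serializes that geometry to
files. Layout is a pure function — no randomness, no global state — so
identical inputs yield element-for-element identical layouts, and the
SVG writer formats every coordinate with fixed 3-decimal precision and
no timestamps, making re-renders byte-identical. This determinism is
not cosmetic: it is what makes batch output diffable and the test
suite able to assert reproducibility at the byte level.

Circular coordinates follow the field convention for organelle maps:
nucleotide 1 sits at 3 o'clock and angles increase clockwise,
`θ(p) = 360°·(p − 1)/L`. Plus-strand genes are drawn inside the circle
(transcribed clockwise), minus-strand genes outside. A feature that
spans the origin (stored as a multi-part location whose parts restart
at position 1) is drawn as one continuous arc crossing 0°. On linear
maps the same strand convention maps to above/below the axis, and
`x(p) = stretch · (p − window_start)` with
`stretch = canvas_width / window_length` by default, so the drawn
window always fills the canvas exactly; the historical behaviour of a
fixed stretch constant is available by overriding
`stretch_factor`. Zooming is a linear-map operation only; requesting
it on a circular map is an error rather than a silent reinterpretation.

Ruler ticks use the largest interval from {1, 2, 5}·10^k that yields
8–20 ticks — the usual compromise between legibility and precision
across the 2 kb–160 kb range the package targets.

## Feature classification and tidy-up

Classification is total: every drawable feature receives exactly one
class. The first match wins in this order: per-gene override (from the
XML configuration), gene-name pattern of a class, feature key of a
class, and finally the catch-all `other` class. Class tables for
plastid, mitochondrial and generic sources ship as editable
tab-separated files under `inst/extdata/`, as does the gene-name
lexicon shared by the classifier, the tidy-up pass and the synthetic
generator — shipping them as data rather than code is deliberate, so a
user can extend nomenclature without touching the package.

The tidy-up pass makes two kinds of decisions the input cannot make
for itself:

* **Rejection**: gene names longer than 20 characters (configurable,
  `tidy_max_len`) are treated as annotation errors — no legitimate
  organellar locus tag approaches that length — and the feature is
  suppressed rather than drawn with a paragraph-long label.
* **Normalization**: canonical casing is restored from the lexicon
  (`PSBA → psbA`), tRNAs are rewritten to the `trnX-ANT` form with an
  RNA-alphabet anticodon (`trnh_gug → trnH-GUG`), and unknown
  locus-tag-shaped names get a lower-case stem with capital suffix.
  The pass is idempotent and never lengthens a name; the tRNA rewrite
  therefore requires a separator to already be present.

A gene "has an intron" iff its CDS/tRNA/rRNA location has two or more
parts or an `intron` feature lies within its extent. The display rule
is then a pure style choice: an asterisk suffix on the label (default)
or empty boxes at the inter-exon gaps (`intron_style = "box"`).

## Inverted-repeat detection

Two methods, selectable per run. The **annotation** method trusts the
record: the two largest features whose key is `repeat_region` or whose
`/note` / `/rpt_type` mentions an inverted repeat are paired. The
**self-comparison** method is de novo: exact 21-mer seeds are taken
from the forward strand every `min_len − 21` bases (guaranteeing at
least one seed inside any repeat copy of the minimum length, 1000 bp
by default) and looked up in the reverse complement; each hit is
extended in both directions. With `max_mismatch_frac = 0` extension is
exact and stops at the first mismatch, which recovers planted repeat
boundaries exactly whenever the repeat is maximal. With a positive
budget, extension uses x-drop scoring (+1 match, −2 mismatch, drop
threshold 20) and the result is trimmed until the pair's overall
mismatch fraction respects the budget. The longest disjoint pair of at
least `min_len` wins; overlapping self-matches (palindromes) are
discarded.

One consequence worth stating plainly: with a positive mismatch
budget, boundaries are recovered only approximately — a flank that
happens to begin with a few matching bases can be absorbed within
budget, which is the statistically correct behaviour, not a defect.
Exactness is therefore defined, and tested, at budget zero.

The returned pair is ordered by the drawing convention: `ir_a` is the
copy whose end lies closest upstream of position 1, i.e. the repeat
drawn on the right half of the circle ending at the map origin —
matching the convention that nucleotide 1 is the first base of the
large single-copy region flanked by IR_A.

## Sequence-level computations

**GC profile.** Windows start every `step_bp` bases and wrap the
origin on circular records (exactly `⌈L/step⌉` windows). Ambiguity
handling is a documented rule rather than an accident: S (G|C) counts
toward GC, W (A|T) toward AT, and every other ambiguity code (N, R, Y,
K, M, B, D, H, V) is excluded from numerator *and* denominator. A
window with no counting bases reports 0. The drawn ring carries a
dashed reference circle at exactly 50%.

**Restriction scanning.** Recognition patterns are expanded to their
IUPAC base sets on the pattern side only; a character class built this
way contains only A/C/G/T, so an ambiguity code in the genome can
never satisfy a match — conservative and reproducible. Matching runs
on the doubled prefix of circular sequences so origin-spanning sites
are reported at their wrapped start. Palindromic sites (the majority
of type II enzymes) are reported once on the plus strand; for
asymmetric sites the minus-strand position is the genome coordinate of
the site's leftmost base, which makes the strand-mirror property hold
exactly: scanning the reverse complement maps positions by
`p ↦ L − p − m + 2` with strands swapped.

## Transcript mode

Expression values arrive as a two-column table (gene, signed value;
tab or comma separated, optional header, last-wins on duplicates with
a warning). Colour is a ramp from white toward the configured up/down
hue with saturation `min(|v|/max_abs, 1)`; `max_abs` defaults to the
dataset's largest absolute value, zero maps to a neutral grey, and the
ramp is symmetric in sign and monotone in magnitude. Expression is an
*overlay* ring: geometry is never altered, genes missing from the
dataset get a neutral box, and genes deselected in the configuration
get none. Drawing the overlay as recoloured gene bodies instead would
be a one-line change in the element kind; the overlay form was chosen
so the functional class colouring stays visible alongside the
expression signal.

## The synthetic-genome generator

`make_fixture()` exists so that every pipeline stage can be tested
against known ground truth with no external data. Its defaults are the
realistic study conditions: a 150 kb quadripartite plastome with 25 kb
inverted repeats and genes drawn from the real plastid name lexicon; a
16.5 kb mitogenome with a compact gene set and an origin-spanning
D-loop; a 10 kb generic replicon. Two details are deliberate:

* **Repeat maximality.** After planting `IR` and `revcomp(IR)`, the
  generator forces the flanking bases to break the repeat (the first
  SSC base must differ from the complement of the last). Without this,
  one time in four the "true" repeat would extend past the planted
  boundary and exact-recovery assertions would be ill-posed.
* **Noise placement.** IUPAC ambiguity noise is never injected inside
  a planted repeat (it would silently break the revcomp identity);
  repeat mismatch noise (`ir_noise_frac`) mutates interior bases of
  one copy only, leaving the boundaries intact.

What the generator does *not* emulate: codon-valid coding sequences,
realistic intergenic composition, gene order conservation, or
sequencing artefacts. Tests passing on fixtures therefore demonstrate
the correctness of parsing, geometry and detection algorithms — not
robustness to the full messiness of public GenBank records (fuzzy
positions and conflicting topology evidence are covered by dedicated
hand-written records instead).

## Numerical and degenerate-input choices

* Coordinates are 1-based inclusive throughout the data model;
  half-open arithmetic exists only inside the geometry code
  (`x1 = stretch·(end + 1 − start)`).
* Fuzzy positions (`<`, `>`) are clamped to their numeric bounds with
  a logged warning; a record whose LOCUS says linear but which carries
  an origin-wrapping feature keeps the LOCUS topology, with a warning.
* Records without an ORIGIN block are accepted; GC, restriction and de
  novo IR computations raise a structured "sequence required" error
  only when actually requested.
* Label placement is a greedy pass in coordinate order: a colliding
  label moves outward one tier (circular) or up one stack level
  (linear) until free, gaining a leader line; labels are never
  dropped. Greedy is deliberate — it is deterministic, order-stable
  and fast, at the cost of occasionally using one more tier than an
  optimal packing would.
* All formats are drawn from the same layout: SVG through the
  package's own writer (the only path that guarantees byte
  determinism), PDF/PostScript/PNG/TIFF/JPEG through R's graphics
  devices with shared geometry code, so the formats agree visually.
  Zip bundles use a store-only writer with fixed timestamps, again for
  reproducibility.

## Problem sizes used in the checks

The automated checks run the full pipeline on 1000 seeded genomes
spread log-uniformly over 2–160 kb, compare the three scanners against
brute-force oracles on 1000 random 2–5 kb sequences, and verify exact
repeat recovery on 200 full-size plastome architectures plus 30 noisy
ones — sizes chosen to exercise the whole realistic range while
keeping a complete run in a few minutes on one core.

## Known limitations

* EMBL/GFF3 input, network fetch by accession, and validation against
  the full INSDC feature-key vocabulary are out of scope.
* Only the single canonical IR pair is detected; dispersed or nested
  repeat families are not.
* Multi-record composite figures (several genomes on one canvas) are
  not supported; batches produce one map per record.
* The label pass avoids overlaps among labels but not between labels
  and unrelated decorations (e.g. ruler numbers) in extremely dense
  regions.
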