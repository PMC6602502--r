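# orgmapr

Publication-grade physical maps of organellar genomes — plastomes,
mitogenomes and other small replicons — drawn directly from GenBank
flat-file annotations.

Organellar genome papers almost universally open with a circular gene
map: coding regions coloured by functional class (photosystems,
ATP synthase, respiratory complexes, tRNAs, rRNAs, ...), a GC-content
ring, the pair of large inverted repeats of a plastome, and optionally
a restriction map or an expression overlay. `orgmapr` produces these
maps reproducibly from the command line or from R, for single records
or whole batches of multi-GenBank files, with no server round-trip.

## What it draws, and how

* **Input**: NCBI GenBank flat files (single- or multi-record).
  Topology (circular/linear) and sequence source (plastid,
  mitochondrial, other) are taken from the record itself; compound
  `join(...)`/`complement(...)` locations, origin-spanning features and
  IUPAC ambiguity characters are all handled.
* **Coordinate convention**: on circular maps, position 1 sits at
  3 o'clock and angles grow clockwise, `θ(p) = 360°·(p − 1)/L`. Genes
  inside the circle are transcribed clockwise (plus strand), genes
  outside counter-clockwise. On linear maps the stretch factor is
  `canvas_width / window_length`, so the drawn window always fills the
  canvas.
* **Gene classes**: features are classified by gene-name pattern first,
  then by feature key, against built-in class tables for plastid /
  mitochondrial / generic sources; an XML file can override colours,
  per-gene products and drawable keys. A tidy-up pass rejects over-long
  gene names and normalizes casing (`PSBA → psbA`, `trnh_gug →
  trnH-GUG`). Intron-containing genes are starred (`rps16*`) or drawn
  with empty intron boxes.
* **Inverted repeats**: either read from `repeat_region` annotations or
  found de novo by seed-and-extend between the sequence and its
  reverse complement (exact 21-mer seeds; exact extension at mismatch
  budget 0, x-drop extension otherwise). IR_A is the repeat ending at
  the map origin — the right-hand repeat on the map.
* **GC ring**: sliding windows (wrapping the origin on circular
  records), `GC = (G + C + S) / (A + C + G + T + S + W)`; a dashed
  reference circle marks the 50% threshold.
* **Restriction map**: degenerate recognition sites (IUPAC on the
  pattern side only; ambiguity codes in the genome never match) on both
  strands, origin-spanning matches included, palindromic sites reported
  once.
* **Transcript mode**: a two-column gene/value table recolours genes on
  a white→hue ramp (up- and down-regulation hues configurable).
* **Output**: deterministic SVG (byte-identical re-runs), plus PDF,
  PostScript, PNG, TIFF and JPEG at any resolution, and a zip bundle
  for batches.

A seeded synthetic-genome generator (`make_fixture()`) emits realistic
plastome-like (LSC + IR + SSC + inverted IR), mitogenome-like (with an
origin-spanning D-loop) and generic records with full ground truth, so
the whole pipeline is testable offline.

## Worked example

```r
library(orgmapr)

fx  <- make_fixture(fixture_spec("plastome_like", seed = 42))
rec <- read_genbank(fx$text)[[1]]
rec
#> <genome_record> SYNP000042: 150,000 bp, circular, plastid, 93 features

find_inverted_repeats(rec, "self_comparison")
#> <repeat_pair> IR_A 125001..150000, IR_B 80001..105000 (25,000 bp, self_comparison, 0 mismatches)

layout <- draw_genome_map(rec)
layout
#> <map_layout> circular, 90 elements, rings: scale, gc, ir_bracket

render_all(render_job(layout, c("svg", "png"), dpi = 150,
                      output_basename = "plastome42"))
#> [1] "plastome42.svg" "plastome42.png"
```

The record prints its resolved topology and source category; the
repeat pair reports the two 25 kb copies with IR_A ending at the map
origin (nucleotide 150,000, adjacent to position 1); the layout holds
the resolution-independent geometry that both the SVG writer and the
raster devices consume.

From a shell, the same pipeline runs over whole directories:

```sh
inst/cli/orgmapr --format svg,pdf --enzymes EcoRI,HindIII --zip \
    --out maps/ plastomes/*.gb
```

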