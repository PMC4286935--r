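---
title: "Circular AP-MS diagrams: model, layout and design choices"
author: "baitring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Circular AP-MS diagrams: model, layout and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(baitring)
```

## The problem and the model

An affinity-purification mass-spectrometry (AP-MS) experiment yields,
after contaminant filtering, a list of high-confidence preys for one
bait protein, optionally classed by evidence type: protein–protein
interaction (`ppi`) versus in vitro kinase substrate (`ivtk`). The
question this package answers visually is *where those preys fall*
within a second, independently structured dataset — functional
sub-complexes of a molecular machine, or the prey lists of other baits
or conditions. `baitring` assumes the filtering has already happened
upstream; it performs no scoring, no identifier translation and no
fuzzy matching, because silently merging two UniProt accessions that
differ in case or by an isoform suffix would fabricate interactions.

The model is purely combinatorial and geometric:

1. **Occurrence mapping.** Each experiment prey is matched by exact,
   case-sensitive string equality against the reference's protein
   identifiers. A prey may occur in several sets; the ordered list of
   its occurrences (set index, then entry index — reference-file order)
   is the only ordering both the tool and the user can see, so "first
   occurrence" is defined as first in file order. Reappearance ON draws
   one arc per occurrence; OFF draws only the first. Preys absent from
   the reference are never an error: they go to a machine-readable
   unmatched report and raise a classed warning, since an interactome
   routinely extends beyond any one annotation.
2. **Proportional angular layout.** With set sizes $n_1,\dots,n_k$,
   bait width $b$ and spacer width $s$ in protein units, the unit angle
   is $u = 360^\circ/(\sum_i n_i + b + 2s)$. The circle is tiled, from
   the bait segment outward in the layout direction:
   bait ($b\,u$, black), spacer ($s\,u$, white), the sets in file order
   ($n_i u$ each), spacer. With the defaults $b = s = 3$ each white
   spacer spans exactly three protein widths, so the spacers double as
   a visual scale bar, and sector widths are proportional to set sizes
   by construction.
3. **Arc geometry.** Entry $j$ of set $i$ anchors at the midpoint of
   its one-unit slot, $(j - \tfrac12)u$ into the sector; all arcs
   originate at the bait segment midpoint. An arc is a quadratic Bézier
   between the two anchor points on the ring's inner edge, with the
   control point at the circle center displaced toward the chord
   midpoint by the *tension* fraction.

## Tunable parameters

| parameter | unit | default | why |
|---|---|---|---|
| `spacer_units` | protein widths | 3 | spacer = scale bar of three proteins |
| `bait_units` | protein widths | 3 | no canonical value exists; matching the spacer keeps the black block visually comparable to the scale bars |
| `radius` | fraction of canvas half-extent | 0.85 | leaves a margin for labels |
| `ring_thickness` | fraction of radius | 0.06 | thin annulus; arcs attach to its inner edge |
| `bait_center_angle` | degrees | 90 | bait at the top; purely conventional, configurable |
| `clockwise` | flag | `TRUE` | reading order of the sets; applied as a sign flip at layout time |
| `arc_tension` | 0–1 | 0 | 0 routes every arc through the center ("arcs in the center of the circle"); raising it flattens arcs toward the chord, which disentangles dense diagrams |
| `arc_opacity` (render) | 0–1 | 0.8 | overdrawn arcs stay distinguishable |

Angles are stored in degrees, mathematical convention
(counterclockwise positive, 0° east), normalized to $[0^\circ,
360^\circ)$; the clockwise default is a sign flip, not a second code
path, which keeps the two orientations exact mirrors.

## Numerical and degenerate-input choices

* Widths are computed as `n_units * unit_angle` from exact cumulative
  offsets, so the tiling sum is $360^\circ$ to floating-point accuracy
  and segments abut without gaps; tests assert $10^{-9}$-degree
  agreement.
* An **empty protein set** (legal, warned about at parse and layout
  time) occupies a zero-width segment rather than being dropped, so
  set indices stay aligned between the reference, the legend and the
  mapping.
* **Coincident arc endpoints** (angular separation below $10^{-3}$
  degrees, which cannot happen between the bait and a set slot under
  the layout above but can be fed to `arc_path()` directly) degenerate
  to a short stub toward the center with a classed warning rather than
  a zero-length path.
* **Duplicate experiment rows** (identical bait, class, prey) are
  collapsed to their first occurrence by default — a second identical
  arc would overdraw the first invisibly — with each removal warned and
  reported; `dedupe = FALSE` restores verbatim behaviour.
* Exact **duplicates across classes** are kept: the same prey as `ppi`
  and as `ivtk` is two distinct pieces of evidence and draws two arcs.
* The bait's own identifier is only ever a mapping *source*; if it also
  appears in the reference it is mapped like any prey only when listed
  in the prey column.

## Rendering determinism

SVG is the canonical backend, emitted directly with fixed four-decimal
coordinate formatting (negative zero folded into zero), one element per
scene object; identical diagrams therefore produce byte-identical
files, and tests count elements against the scene rather than comparing
screenshots. The PDF backend draws the *same scene* through grid onto
an uncompressed `grDevices::pdf()` device — sectors as densely sampled
polygons, arcs as densely sampled Bézier polylines, all vector — and
then pins the PDF creation/modification dates to an epoch constant
(same byte length, so cross-reference offsets stay valid), making PDF
output byte-stable too. PDF is deliberately not produced by converting
the SVG file, so a converter can never introduce drift between the two.
The scene itself serializes to a documented JSON file at full numeric
precision, which is both the golden-file format of the test suite and
the input of the CLI's renderer-only mode.

## The synthetic fixture generator

`generate_fixture()` makes the whole pipeline testable with no external
data. It emulates the tabular shape of a filtered AP-MS study: a
reference of `n_sets` protein sets with fresh unique identifiers, a
chosen fraction of entries duplicated into *another* set (the cross-set
redundancy that the reappearance mode exposes; never duplicated within
a set, mirroring real annotations where a complex lists a protein
once), an experiment whose preys are sampled without replacement from
the reference apart from a chosen fraction of guaranteed-absent
identifiers, optional exact duplicate rows, and a random color scheme
shorter than the set list so color cycling is exercised. The defaults —
four sets of eight, twelve `ppi` plus four `ivtk` records, 20 %
cross-set duplication, 10 % unmatched — are the scale of a
single-kinase experiment projected onto a handful of sub-complexes.

Ground truth (`expected_on_arcs`, `expected_off_arcs`,
`expected_unmatched`, `duplicate_rows_injected`) is recorded **at
generation time** by tallying the identifier multiset directly, so
tests compare the mapping pipeline against construction, not against
itself; an independent brute-force quadratic scan provides a second,
implementation-free oracle. What the generator does *not* emulate:
realistic identifier structure (isoforms, obsolete accessions), set
size distributions of real annotation databases, or any correlation
between arc class and set membership. Passing tests therefore certify
the combinatorics and geometry, not robustness to dirty real-world
identifier lists — that robustness rests on the strict parser, which
rejects rather than guesses.

The bundled `inst/extdata/` files are a *synthetic* stand-in for a
four-kinase lenticular comparison (SRPK1-style bait with 26 distinct
interactors over four overlapping prey sets); they are labelled
synthetic in name and here, and exist so the non-redundant-mapping
count and the multi-set overlap behaviour can be exercised on a
realistic shape without shipping third-party data.

## Problem sizes in the test suite

Property suites run on deliberately small inputs — up to 8 sets of up
to 40 entries for tiling (100 random layouts), 2–6 sets of 10 for the
mapping oracle (50 random fixtures), since the mapping oracle is an
intentionally quadratic scan and the properties checked are
size-independent. These sizes were chosen as the smallest that still
exercise every branch (cycling, redundancy, absence, duplicates,
empty sets).

## Design choices where the design was open

* **Single bait per experiment file.** The layout has exactly one bait
  segment; a file with two distinct bait identifiers is a hard error
  rather than a silent first-wins.
* **No CSV quoting dialect.** Fields are split on literal commas;
  identifiers or descriptions containing commas are rejected on write
  and unrepresentable on read. Guessing a quoting convention the format
  does not define would corrupt identifiers silently.
* **"RBG" color rows are read as red, green, blue** integers 0–255 —
  the standard convention.
* **Both arc classes pass through the reappearance filter
  identically**; nothing in the semantics of a substrate arc suggests
  it should map differently.
* **Spacers render as gaps** (background shows through) rather than
  white-filled sectors, so diagrams composite onto slides; a flag
  restores filled white.
* **`ivtk` arcs draw after `ppi` arcs**, so the sparser black substrate
  evidence is never buried under the denser interaction arcs.
* **1-based indices** throughout (`set_index`, `entry_index`,
  `record_index`), following R convention, including in the scene JSON.

## Known limitations

* No multi-ring or edge-bundled layouts; one bait per diagram (use
  `compare` for series).
* No identifier mapping/translation; inputs must share an identifier
  namespace.
* SVG labels use a simple radial placement with readability flipping in
  the lower half; long set names can collide on crowded diagrams
  (disable with `draw_labels = FALSE` and annotate downstream).
* PDF arcs are densely sampled polylines rather than native Bézier
  operators; at the default 65 samples the deviation is far below
  visual and print resolution, but the file is larger than a native
  curve would be.

## A minimal end-to-end run

```{r example}
fx <- generate_fixture(fixture_spec(seed = 7))
e <- parse_experiment(fx$experiment_text)
r <- parse_reference(fx$reference_text)
s <- parse_color_scheme(fx$colors_text)
d <- suppressWarnings(build_diagram(e, r, s, reappearance = TRUE))
glance(d)
ggplot2::autoplot(d)
```
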