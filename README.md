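# baitring

Circular bait–prey interaction diagrams for affinity purification mass
spectrometry (AP-MS) data.

An AP-MS experiment enriches one tagged or antibody-bound *bait* protein
and identifies every protein that co-purifies with it (the *preys*, or
interactors). The resulting high-confidence interaction lists are hard
to read as node-and-edge graphs, and harder still to relate to
orthogonal knowledge such as the functional sub-complexes of a large
machine like the spliceosome. `baitring` draws these experiments as
circular diagrams: named *protein sets* from a reference file are laid
out around a ring, each colored sector's angular width proportional to
the number of proteins it contains, with the black bait sector flanked
by two white spacers that each span exactly three protein widths and so
double as a scale bar. Every interaction is an arc from the bait to the
prey's slot in the reference: colored for a protein–protein interaction
(`ppi`), black for an in vitro kinase substrate (`ivtk`).

Two mapping modes control redundancy. With the **reappearance function
ON**, a prey that belongs to several protein sets gets one arc per
occurrence — the right view for projecting an interactome onto
overlapping functional annotations or for comparing several baits'
prey lists (the *lenticular* layout). With reappearance **OFF**, only
the first occurrence in reference-file order is drawn, which shows what
is *new* relative to the first set (e.g. a control condition).

Formally, with set sizes \(n_1, \dots, n_k\), bait width \(b\) and
spacer width \(s\) (both in protein units, default 3), the unit angle is

```
u = 360° / (Σᵢ nᵢ + b + 2s)
```

set *i* spans \(n_i \cdot u\) degrees, the prey in slot *j* of set *i*
anchors at the slot midpoint \((j - \tfrac12)\,u\) into its sector, and
each arc is a quadratic Bézier from the bait anchor to the prey anchor
whose control point sits at the circle center (tunable via a tension
parameter). Output is deterministic SVG or single-page vector PDF, plus
a renderer-agnostic scene JSON.

For whom: proteomics researchers who want publication-quality,
scriptable circular summaries of AP-MS experiments, and tool builders
who want the layout engine (pure geometry, tibbles in and out) without
the renderer.

## Worked example

Four classed interactions of the splicing kinase SRPK1 are projected
onto two spliceosomal sub-complexes. SRSF1 (Q07955) is annotated in
both sets, so redundant mapping draws it twice; U1-70K (P08621) appears
both as an interactor and as a kinase substrate, giving one colored and
one black arc to the same slot.

```r
library(baitring)

experiment <- parse_experiment(
  "SRPK1,ppi,Q07955\nSRPK1,ppi,P08621\nSRPK1,ivtk,P08621\nSRPK1,ppi,Q15459\n")
reference <- parse_reference(paste0(
  ">U1 snRNP\n-,P08621,U1-70K\n-,Q07955,SRSF1\n-,P09012,U1A\n",
  ">17S U2\n-,Q15459,SF3A1\n-,Q07955,SRSF1\n-,O75533,SF3B1\n"))
scheme <- parse_color_scheme("228,26,28\n55,126,184\n")

diagram <- build_diagram(experiment, reference, scheme, reappearance = TRUE)
diagram
#> <apms_diagram> bait 'SRPK1': 5 segments (2 protein sets), 5 arcs, 0 unmatched prey

glance(diagram)
#> # A tibble: 1 × 8
#>   bait  n_sets n_segments n_arcs n_ppi_arcs n_ivtk_arcs n_unmatched reappearance
#>   <chr>  <int>      <int>  <int>      <int>       <int>       <int> <lgl>
#> 1 SRPK1      2          5      5          4           1           0 TRUE

tidy(diagram)[, c("arc_class", "prey_id", "set_index", "from_angle", "to_angle")]
#> # A tibble: 5 × 5
#>   arc_class prey_id set_index from_angle to_angle
#>   <chr>     <chr>       <int>      <dbl>    <dbl>
#> 1 ppi       Q07955          1         90      306
#> 2 ppi       Q07955          2         90      234
#> 3 ppi       P08621          1         90      330
#> 4 ppi       Q15459          2         90      258
#> 5 ivtk      P08621          1         90      330
```

Six reference proteins plus the three-unit bait and two three-unit
spacers give fifteen units of 24° each; every segment here spans three
units, i.e. 72°:

```r
diagram$segments[, c("kind", "label", "n_units", "width_deg")]
#> # A tibble: 5 × 4
#>   kind   label      n_units width_deg
#>   <chr>  <chr>        <dbl>     <dbl>
#> 1 bait   "SRPK1"          3        72
#> 2 spacer ""               3        72
#> 3 set    "U1 snRNP"       3        72
#> 4 set    "17S U2"         3        72
#> 5 spacer ""               3        72
```

The five arcs read: SRSF1 drawn redundantly in both sub-complexes
(reappearance ON), and U1-70K receiving both a red interaction arc and
a black substrate arc — the binds-here, phosphorylates-there pattern
that this projection is designed to expose. Render with:

```r
render_svg(diagram, "srpk1.svg")
render_pdf(diagram, "srpk1.pdf")
ggplot2::autoplot(diagram)      # quick look in an R session
diagram_to_json(diagram, "srpk1.scene.json")  # renderer-agnostic scene
```

## Command line

```sh
inst/cli/baitring draw experiment.csv reference.csv colors.csv -o out.svg \
    --reappearance off --unmatched-report unmatched.csv
inst/cli/baitring compare srpk1.csv srpk2.csv reference.csv colors.csv -o cmp
inst/cli/baitring fixture --out-dir fixtures --seed 7
inst/cli/baitring validate experiment.csv reference.csv colors.csv
```

`compare` renders one diagram per experiment over a shared reference,
so the segment geometry is identical across the series and only the
arcs differ — the multi-bait (or multi-condition) comparison view.

## Input formats

* **Experiment** — `bait,arc_class,prey` per line; `arc_class` is `ppi`
  or `ivtk`; one bait per file.
* **Reference** — FASTA-like: `>Set name` opens a set, followed by
  `description,protein_id,description` rows. The same identifier may
  occur in several sets.
* **Colors** — `R,G,B` integers 0–255 per line, cycled over the sets
  when there are more sets than colors.

All files are plain comma-delimited text (no quoting), UTF-8, LF or
CRLF. Matching between experiment preys and reference column 2 is
exact, case-sensitive string equality.

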