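---
title: "Laying out genome-wide multiple sequence alignment graphs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Laying out genome-wide multiple sequence alignment graphs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gmsalayout)
```

## The data model

A genome-wide multiple sequence alignment (gMSA) cuts a set of genomes into
aligned blocks. Each block holds one *sequence interval* `(genome, contig, i,
j, sigma)` per participating contig occurrence, with 1-based inclusive
coordinates and a strand `sigma` of +1 or −1. For every contig a total order
over the blocks it traverses can be recovered from the interval coordinates;
that order is the contig's *vertex sequence*. The collection of vertex
sequences is a directed multi-graph — the gMSA graph — in which one vertex may
stand for several blocks merged into one (a *merged block*) when no traversal
information is lost by doing so.

The first vertex sequence is the *guide*: the reference all others are
compared to. Every *comparative* sequence must start and end on a guide
vertex, so no loose ends dangle off the comparison; `gmsa_trim_to_guide()`
enforces this by cutting each comparative to its maximal guide-anchored
sub-path. The remaining order of the sequence list is the *genome order* — it
is supplied by the user (typically by phylogenetic proximity to the guide) and
strongly shapes the final drawing, because cycle removal processes sequences
in exactly that order.

Two modelling decisions deserve a note:

* **Duplications.** A vertex sequence is defined as a path of *distinct*
  vertices. A contig that really revisits a block (a duplication) therefore
  cannot be represented; `gmsa_validate()` rejects such input with a
  `path-distinct` violation rather than silently altering it. Splitting the
  revisited block into per-visit copies would be a consistent alternative,
  but it changes the alignment semantics, so it is left to the data producer.
* **Merged blocks and the single-hit rule.** Unmerged blocks may contain at
  most one row per contig (alignments are restricted to single hits). A
  merged block keeps the constituent rows of the blocks it absorbed — several
  rows of one contig, possibly on both strands. This is deliberate: the
  renderer needs the per-constituent strands to draw a double-headed
  direction glyph when a merged vertex contains both orientations, so the
  single-hit check applies to unmerged blocks only.

Merging itself (`gmsa_merge_colinear()`) uses the strictest reading of
"no information is lost": a run of blocks merges only when the identical set
of sequences traverses the whole run consecutively and in the same order.
Runs traversed in reverse order by some contig are *not* merged, although
that would arguably also be lossless; the strict rule keeps every entry and
exit point of every sequence visible. Merging is capped so no sequence drops
below two vertices, and runs to a fixpoint, which makes it idempotent.

## The layout pipeline

`gmsa_layout()` runs an extended Sugiyama pipeline. The stages, with the
design choices that were genuinely open:

### Cycle removal

Each contig is acyclic on its own, but their union rarely is. Instead of a
minimum-feedback heuristic — which can create spurious sources and sinks and
thereby break the left-to-right reading of the guide — whole *bypaths* are
inserted into a growing DAG. A bypath is a sub-path of a comparative sequence
whose endpoints are already processed and whose interior is new. With `σ`
(successors) and `τ` (predecessors) maintained incrementally over the
processed part, the rule is:

* `vn ∈ σ(v0)`: the bypath is added in its original direction;
* `v0 ∈ σ(vn)`: adding it forward would close a cycle, so the whole bypath is
  reversed;
* endpoints unrelated: this package adds the bypath **forward** by default.
  The reversal rule exists to avoid cycles, and no cycle threatens here;
  keeping the original reading direction preserves the left-to-right
  convention. `strict_otherwise_reverse = TRUE` switches to reversing in this
  case as well, for comparison.

Between two vertices at most one DAG edge ever exists. The multiple-edge map
`ε` attaches one `(direction, sequence)` tuple per original adjacency to its
DAG edge, so nothing is lost: `Σ_e |ε(e)|` always equals the total adjacency
count `Σ_S (|S| − 1)`, and reversed edges never need to be flipped back —
drawing reads the original directions out of `ε`. Internally `σ` and `τ` are
the rows and columns of one logical reachability matrix; the update on edge
insertion is the published two-step propagation, and the test suite replays
every insertion against a from-scratch depth-first-search oracle.

The result has exactly one source (the guide's first vertex) and one sink
(the guide's last).

### Layering

The longest-path algorithm assigns each vertex the length of the longest
source path; layers become drawing columns. Guide layers strictly increase,
but they are *not* always `0 … |GS|−1`: an insertion between adjacent guide
vertices pushes the downstream guide vertex to the right, which is precisely
how inserted material ends up drawn *between* its neighbours. Edges spanning
more than one layer are cut into chains of dummy vertices; every dummy edge
of a chain inherits the long edge's `ε` set unchanged.

### Crossing reduction

Global sifting is adapted to move whole *block-sets* — the run of blocks
(real vertices and dummy chains) contributed by one bypath, plus one set for
the guide — so that a bypath's vertices can later share one horizontal track.
A length-2 bypath contributes a block-set only if its single edge became a
long edge (its dummy chain must live somewhere); otherwise it contributes
nothing. Each set is tried at every vertical position and kept where the
crossing count is lowest, ties resolved toward the topmost position.

Because every layer holds at most one block per block-set, the per-layer
vertex order is fully determined by the block-set order, and moving one set
only affects crossings of edge pairs touching that set. The sifter exploits
this: the invariant remainder is carried as a running total and only the
varying part is re-evaluated per candidate position. Rounds default to 10 and
stop early when a full round neither moves a set nor lowers the count —
continuing would only rotate equal-cost ties. Crossings are monotonically
non-increasing over rounds, and inner–inner (Type 2) crossings cannot occur
at all since each dummy chain sits inside a single block. On instances small
enough to enumerate every permutation, the sifted order reaches the
exhaustive optimum in well over 80% of seeded trials (the fraction is logged
by the test suite); it is a heuristic, so the occasional one-crossing gap is
expected and tolerated.

The guide block-set takes part in sifting like any other set — pinning it is
unnecessary because a block-set occupies a single position, so the guide
stays linear regardless.

### Vertical tracks

Block-sets are stacked onto integer tracks (guide = 0, negative above,
positive below), walking the sifted order away from the guide and placing
each set on the nearest free track where it does not intersect an already
placed set. "Intersect" is interpreted as overlap of the layer hulls
`[min layer, max layer]` — the main text leaves this open, and the hull
reading is the conservative one: it can waste a track on a set with a hole in
its layer coverage, but it can never interleave two sets in a way that
creates a new crossing. Because placement proceeds guide-outwards in sifted
order, relative orders in shared columns are preserved and no crossings are
added.

### Routing and drawing

Dummy chains collapse back into one drawable edge each, remembering the track
of their chain as the elevation of the long edge's horizontal run. Parallel
edges with the same endpoints and direction bundle into one line whose width
encodes the number of bundled sequences (at most two bundles per DAG edge:
forward and backward). Connection points sit on the left/right vertex borders
in three zones — up, straight, down — by the edge's vertical orientation;
within a zone, stacking uses `fs` free space between lines and `bs_border`
border space, and the two borders facing one gap share one rank space (left
vertex first) so facing runs cannot overlap. Every vertical segment receives
a unique x slot in its inter-layer gap, ordered by the vertical position of
the horizontal runs it connects — the slot-ordering rule is a documented
heuristic; the uniqueness is the guarantee. From these the two global space
parameters are computed: the *needed vertex height* (every vertex can stack
its zones) and the *needed inter-layer space* (the busiest gap fits all its
slots).

Direct (span-1) edges are drawn with at most two bends — zero when straight.
Collapsed long edges use at most four (two at each end around the horizontal
run), and exactly two when the run's track equals an endpoint's track. The
final drawing places vertices on a grid: columns as wide as the widest
vertex, a uniform vertex height, vertices centered in their column. Vertex
width encodes block length as `min + (max − min) · log10(L) / log10(L_max)`,
clamped to the configured `[min, max]` — log scaling keeps multi-kilobase
blocks on screen next to hundred-base ones. Every bundled member is drawn as
its own parallel polyline in its sequence's color, so a single contig can be
traced through the whole drawing; small arrowheads mark the original
direction, in-vertex arrows show each contig's strand (double-headed for
merged vertices containing both), and triangular flags mark each contig's
first and last vertex. Defaults: `fs = 4` px, `bs_border = 6` px, 1 px of
line width per bundled member capped at 6 px, vertex width 30–90 px.

## The synthetic generator

`gmsa_synth()` emulates the block-order structure of a gMSA of closely
related bacterial genomes: a guide of `n_guide_vertices` blocks with lengths
drawn from 100–2000 nt, and comparatives derived from the guide by interior
deletions (`p_deletion = 0.15` per block), insertions of private block runs
(`p_insertion = 0.15` per gap, run length 1–`max_insert_len = 3`) and at most
one strand-flipping inversion of an interior run (`p_inversion = 0.10`).
Those default rates sit in the realistic mid-range for structural variation
between closely related bacterial strains — frequent enough that every
pipeline stage is exercised (long edges, reversed bypaths, merged runs),
sparse enough that the guide remains the backbone. Endpoints stay on the
guide, so anchoring holds by construction, and a fixed seed reproduces the
graph exactly.

What the generator does *not* emulate: duplications (excluded by the data
model), translocations between contigs, shared insertions between two
comparatives, and alignment noise such as spurious micro-blocks from
low-quality alignments. Passing tests therefore demonstrate the layout
machinery on clean, well-anchored block orders; heavily fragmented real
alignments will mainly stress drawing size, not correctness.

## Numerical and procedural choices

* Determinism everywhere: bypaths are inserted left-to-right in sequence
  order, the initial block-set order is guide-first then creation order,
  sifting ties go to the topmost position, slot and zone orders use fixed
  sort keys, and SVG coordinates are formatted with two decimals — the same
  seed and configuration reproduce the output byte for byte.
* Degenerate inputs: a guide-only graph yields one track, zero crossings and
  an all-straight drawing; range extraction refuses to leave fewer than two
  guide vertices; comparatives that lose their anchor are dropped with a
  warning rather than drawn loose.
* Merging is applied after range extraction in `gmsa_layout()` (merge what
  you actually draw); both operations are exported, so the opposite order is
  available by composing them manually.
* The test-suite problem sizes are the package's own choice: sweeps of 500
  seeded graphs with 5–60 guide vertices and 0–8 comparatives for the
  structural guarantees, 200 graphs for the reachability oracle replay, and
  exhaustive permutation checks on instances with at most 6 block-sets.

## Known limitations

* Crossing reduction and slot ordering are heuristics; no optimality claim is
  made beyond the logged exhaustive comparison on small instances.
* The vertical-position refinement of occasional aesthetically displeasing
  stackings (a post-compaction pass) is not implemented; the greedy stacking
  is local-optimal per set but not globally minimal in height.
* Genome order is taken as given; the package does not order comparatives by
  phylogenetic distance.
* Very large or highly fragmented graphs produce wide drawings with many long
  edges; runtime is kept in check (quadratic-ish stages are vectorized), but
  readability of such drawings is inherently limited.

```{r example}
g <- gmsa_synth(n_guide_vertices = 10, n_comparative = 3, seed = 7)
ly <- gmsa_layout(g)
glance(ly)
```

```{r plot, fig.width = 7, fig.height = 3}
autoplot(ly)
```
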