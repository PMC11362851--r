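# gmsalayout

Layered, guide-anchored drawings of **genome-wide multiple sequence alignment
(gMSA) graphs** for the visual comparison of genome orders.

## The problem

When whole genomes are aligned, the alignment is cut into blocks, and the
order context of each original sequence is easily lost. Representing the
alignment as a graph keeps it: every vertex is an alignment block (or a run
of blocks merged losslessly into one), and every contig contributes a
*vertex sequence* — its total order over the blocks it traverses. The union
of these sequences is a directed multi-graph. Drawn well, such a graph makes
insertions, deletions and inversions between genomes visible at a
semi-global scale, including against artificial reference orders such as a
supergenome coordinate system.

The package implements a complete layout pipeline for these graphs, an
extension of the Sugiyama framework for layered graph drawing. One sequence
is the *guide* `GS`; all comparative sequences `S` are anchored on it (they
start and end on guide vertices). The pipeline:

1. **Cycle removal.** Sequences are processed in genome order. Each
   comparative sequence is split into *bypaths* — sub-paths whose endpoints
   are already processed — and each bypath is inserted whole into a growing
   DAG, reversed only when its endpoints satisfy `v0 ∈ σ(vn)` (the last
   vertex already reaches the first), where `σ`/`τ` are incrementally
   maintained successor/predecessor maps. A multiple-edge map `ε` attaches
   every original adjacency, with its direction, to the single DAG edge that
   carries it, so that `Σ_e |ε(e)| = Σ_S (|S| − 1)` holds end to end. The DAG
   has exactly one source (the guide's first block) and one sink (its last).
2. **Layering** by the longest-path algorithm; long edges are properized
   with dummy-vertex chains.
3. **Crossing reduction** by global sifting of whole *block-sets* (the
   blocks contributed by one bypath), keeping bypath runs alignable and
   ruling out inner–inner (Type 2) crossings by construction.
4. **Vertical coordinates**: block-sets stack greedily onto integer tracks
   as close to the guide (track 0) as possible without intersections.
5. **Orthogonal routing** of the bundled multi-edges: up/straight/down
   connection zones on the vertex borders, one unique vertical slot per
   segment and gap, and the two global space parameters (needed vertex
   height, needed inter-layer space).
6. **SVG rendering**: grid-placed rectangles (orange = merged blocks), one
   colored polyline per sequence adjacency, strand glyphs and start/end
   flags.

Direct edges are drawn with at most two bends; a fixed seed and
configuration reproduce the SVG byte for byte.

## Worked example

```r
library(gmsalayout)

g <- gmsa_synth(n_guide_vertices = 10, n_comparative = 3, seed = 7)
g
#> <gmsa_graph> 10 blocks (0 merged), 4 sequences (guide: gs)
#>   gs: 10 vertices
#>   cs1: 9 vertices
#>   cs2: 10 vertices
#>   cs3: 7 vertices

ly <- gmsa_layout(g)
ly
#> <gmsa_layout> 6 vertices on 6 layers / 3 tracks; 12 bypaths (0 reversed), 3 dummies
#>   crossings 1 -> 0; 17 drawn edges; max bends direct 0, long 4
```

The four contigs share most of their block order, so merging collapses the
co-linear runs: 10 blocks become 6 drawn vertices, 3 of them merged, leaving
17 sequence adjacencies across 12 bypaths. Cycle removal reversed no bypath,
layering inserted 3 dummy vertices for the long edges, and sifting removed
the single crossing. The drawing uses 3 vertical tracks (the guide plus one
above and one below) and draws 17 individual edge polylines — one per
adjacency — with every direct edge perfectly straight (`max_bends_direct`
is 0).

```r
glance(ly)      # one-row tibble with the counts above
tidy(ly)        # vertex coordinates; tidy(ly, "edges") for the polylines
autoplot(ly)    # ggplot2 view of the drawing
gmsa_render_svg(ly$geometry, ly$graph, path = "example.svg")
```

Files work the same way: `read_gmsa()` loads the native JSON dialect or MAF
(deriving each contig's vertex sequence by sorting its intervals),
`write_gmsa()` writes canonical JSON or a flat TSV, and
`gmsa_pipeline("in.maf", "out.svg", report = "report.json")` runs file to
file. A thin command line front end ships in `inst/cli/`:

```sh
Rscript $(Rscript -e 'cat(system.file("cli", "gmsa", package = "gmsalayout"))') \
    layout in.json -o out.svg --rounds 10
```

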