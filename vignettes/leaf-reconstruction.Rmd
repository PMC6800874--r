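---
title: "Leaf decks, removal, and reconstruction counter-examples"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Leaf decks, removal, and reconstruction counter-examples}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(leafdeck)
```

## The reconstruction question

An unrooted phylogenetic network on a taxon set $X$ ($|X| \ge 2$) is a
simple connected graph whose degree-1 vertices are bijectively labelled by
$X$, with no degree-2 vertices, and such that contracting every *blob*
(maximal 2-edge-connected subgraph with at least two edges) yields a
phylogenetic tree — equivalently, every cut-edge induces a distinct
bipartition of $X$.  Removing a leaf $x$ means deleting the labelled vertex
and its pendant edge and then suppressing any unlabelled degree-2 vertices
(each suppression replaces a vertex's two edges by one edge joining its
neighbours, possibly creating parallel edges or loops — removal therefore
lands in the larger world of partially labelled multigraphs).  The
*X-deck* of $N$ is the indexed family $\{N_x : x \in X\}$, and $N'$ is an
*X-reconstruction* of $N$ when $N'_x \sim N_x$ for every $x$, where $\sim$
is label- and multiplicity-preserving isomorphism.  The package's purpose
is to construct and verify pairs $N \not\sim N'$ that are nevertheless
X-reconstructions of each other, so that neither is determined by its deck.

Two conventions make removal total without affecting any case arising in
the constructions: labelled vertices are never suppressed even at degree 2
(labels only ever sit on degree-1 leaves here), and a degree-2 vertex whose
only incidence is a loop is left alone, so an unlabelled cycle component
collapses to a single loop vertex and stops.  Each suppression deletes
exactly one vertex and one edge, so $|E| - |V|$ is invariant and the result
does not depend on processing order; both facts are exercised by
randomized tests.

## Parity classes of binary sequences

Everything rests on a simple observation about the set
$\mathcal{B}_r^{\mathrm{even}}$ (resp. $\mathcal{B}_r^{\mathrm{odd}}$) of
length-$r$ binary sequences with an even (odd) number of 1s: you must see
*every* position of $w$ to know its parity.  Masking any one position $i$
(replacing $w_i$ by `*`) maps both classes onto the *same* set of masked
sequences, because flipping position $i$ is a bijection between the
classes that masking cannot detect.  `parity_sequences()`, `flip_at()`,
`mask_at()` and `restrict_seqs()` implement this machinery (1-based
positions, sequences printed most-significant-first); the masked-set
identity is asserted for all $r \le 7$ and all $i$.

The counter-example families are graph-shaped versions of this identity:
an "even" graph encodes $\mathcal{B}_r^{\mathrm{even}}$, an "odd" graph
encodes $\mathcal{B}_r^{\mathrm{odd}}$, and removing leaf $x_i$ acts like
masking position $i$.

## The non-binary family

`build_M(r, p)` places a vertex `u:w` for each $w$ of parity $p$, hub pairs
`v:i:0` / `v:i:1` for each position $i$, a leaf `x:i` (taxon `xi`) pendant
on `v:i:0`, and joins `u:w` to `v:i:h` iff $w_i = h$.  So
$|V| = 2^{r-1} + 3r$ and $|E| = r\,2^{r-1} + r$.  For the deck: deleting
$x_i$ leaves no degree-2 vertices (each hub keeps $2^{r-2} \ge 4$ sequence
neighbours, each `u:w` has degree $r \ge 4$), and the explicit bijection
$u_w \mapsto u_{w^{\neg i}}$, $v_{i,0} \leftrightarrow v_{i,1}$, identity
elsewhere, is an isomorphism between the two removed graphs
(`deck_isomorphism_M()`).  For non-equivalence: the all-0 vertex of the
even graph is adjacent to every `v:i:0`, hence at distance 2 from every
leaf; in the odd graph every sequence has a 1 somewhere, and the graph is
bipartite with hubs on one side, so no vertex has the all-2 profile
(`nonequivalence_certificate_M()` checks this by exhaustive scan).
Distance profiles are isomorphism invariants, so the certificate is a
proof.  Incidentally, the M graphs satisfy the network definition (one
blob, no degree-2 vertices) — they are valid, though far from binary,
networks; the package reports this rather than assuming it.

## The binary family

To make the construction binary, `build_G(r, p)` expands each `u:w` into a
*caterpillar* `Cat(w)` — spine `u:w`, `y:w:1..(r-3)`, leaves `z:w:1..r`,
all internal degrees 3 (`build_caterpillar()`; at $r = 4$ the single spine
vertex carries both end roles) — and each hub `v:i:h` into a
*lexicographic tree*: a fully balanced binary tree with a degree-2 root
whose leaves are the shared vertices `z:w:i` for the $2^{r-2}$ sequences
$w$ of parity $p$ with $w_i = h$ (`build_lex_tree()`).  The tree is built
by recursive bisection of the lexicographically sorted leaf set, which
realises deterministically the defining property that some depth-first
search visits the leaves in lexicographic order, and fixes the tree
uniquely.  A caterpillar and a lex tree share `z:w:i` exactly when
$w_i = h$, mirroring the adjacency of M.  The leaf `x:i` hangs on the root
`v:i:0`.  Shared `z` vertices and the roots `v:i:1` have degree 2;
`build_N(r, p)` suppresses them (and nothing else — a degree audit is part
of the tests) to obtain a binary network with
$|E| - |V| = 2^{r-1}(r-1) - 2r$.  Surviving vertices keep their
pre-suppression identifiers so that lemma-level witnesses remain
addressable by name.

The deck argument glues per-piece witnesses (`deck_isomorphism_G()`):
caterpillars map by $Cat(w) \to Cat(w^{\neg i})$ preserving leaf indices;
for $j \ne i$, $Lex(j,h)$ of the even graph maps onto $Lex(j,h)$ of the
odd graph, and for the removed position, $Lex(i,h)$ maps onto
$Lex(i,1-h)$.  Internal lex-tree vertices map via shared ancestors: the
image of the depth-$d$ vertex above a leaf block is the depth-$d$ ancestor
of the image of any leaf in the block — well-defined because flipping
position $i$ preserves which leaves share ancestors (positions other than
$j$ determine the tree shape).  All pieces agree on the shared `z`
vertices, and the glued map restricted to vertices surviving suppression
is the deck witness for the networks (`deck_isomorphism_N()`); vertices of
degree ≠ 2 map to vertices of degree ≠ 2, so the restriction is total.
Every witness is validated by `verify_isomorphism()` rather than trusted.

Non-equivalence again comes from a distance certificate: in the even
network the all-0 spine vertex `u:0000` (at $r = 4$) has leaf profile
$(3, 3, 4, 4)$ — one pendant edge, $r-2$ lex-tree levels, one caterpillar
edge, minus one for the suppressed `z` — and an exhaustive scan finds no
vertex of the odd network with that profile
(`nonequivalence_certificate_N()`).  A four-caterpillar cycle through the
lex trees shows all non-leaf vertices share one blob, which is what makes
the suppressed graphs genuine single-blob networks.

## Exact isomorphism testing

`find_isomorphism()` must be exact in both directions: it certifies deck
equivalence (by finding witnesses independently of the constructed ones)
and non-equivalence (by exhausting the search space).  Vertices are first
partitioned by an invariant signature — label, degree, loop multiplicity,
sorted incident-multiplicity multiset, and the distance profile to the
labelled leaves — and the partition is refined by neighbour-class
multisets to a fixpoint.  If the two graphs' class multisets differ there
is no isomorphism; otherwise backtracking assigns vertices in order of
increasing class size, checking edge multiplicities against all previous
assignments in both directions.  On the family graphs the
profile-refinement is decisive (distinct sequences have distinct
profiles), which is why exhaustive non-equivalence checks at $r = 4$
complete in well under a minute.  Two independent cross-checks guard the
implementation: a hand-rolled brute-force enumeration of all
label-respecting bijections on graphs small enough to enumerate, and
igraph's VF2 on simple unlabelled fixtures.  Canonical forms and graph
hashing are deliberately out of scope — witnesses that can be re-verified
are worth more here than a fast yes/no.

## Scale choices and the random generator

Tests verify the complete lemma chain at $r = 4$ and $5$ (constructed
witnesses, generic search, certificates) and the counting identities and
certificates at $r = 6$ ($N$ has 308 vertices; generic search is pointless
there and the validated witnesses carry the argument).  These sizes were
chosen because the constructions grow like $r\,2^{r-1}$: desk scale ends
around $r = 6$, and nothing new happens beyond it — every lemma is
parameterised by the same masking identity.

`random_binary_network(n_leaves, extra_edges, seed)` supplies fuzz
fixtures: a random binary tree grown by leaf insertion, then
`extra_edges` rounds of subdividing two distinct edges and joining the
subdivision points (draws breaking simplicity are rejected; infeasible
parameter combinations error after bounded retries).  It emulates the
*shape* of small reticulate networks — every output is a certified binary
network — but not any biological process: there is no model of
hybridisation rates or branch lengths, and passing fuzz tests says the
graph machinery is correct, not that real data would behave this way.
All randomness flows through explicit integer seeds; the family
constructions themselves are fully deterministic.

## Degenerate inputs and known limitations

Removal requires the input to have no unlabelled degree-2 vertices (true
of every network); `suppress_degree2()` itself accepts anything, with the
totalising conventions above.  `build_M`/`build_G`/`build_N` reject
$r < 4$: at $r = 3$ the caterpillar has no spine and the hub degree bound
$2^{r-2} \ge 4$ fails, and small-taxon cases are already settled
elsewhere.  The LGF format is deliberately minimal (vertices before
edges, repeated lines for multiplicity) and round-trips byte-identically;
unrooted networks with blobs have no faithful Newick form, which is why a
plain edge list is the interchange format and GraphML the export.  The
package searches for nothing: it builds and checks the known families, and
does not attempt to enumerate smaller counter-examples or ones with
$|E| - |V|$ growing slower than $2^{r-1}(r-1) - 2r$.
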