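# leafdeck

Tools for studying **leaf-reconstruction of unrooted phylogenetic
networks**: can a network on a taxon set *X* be recovered from its
*X-deck*, the collection of subnetworks obtained by removing one labelled
leaf at a time?  For phylogenetic trees the answer is yes once |X| ≥ 5, and
the same was conjectured for all unrooted phylogenetic networks.  The
conjecture is false: for every r ≥ 4 there are pairs of networks on r taxa
— even binary ones — with identical decks that are not isomorphic.  This
package implements the machinery needed to build, manipulate and verify
such counter-examples, for researchers in phylogenetics and graph
reconstruction.

## What it computes

* **Labelled multigraphs and leaf removal.** `lmg()` stores partially
  labelled undirected multigraphs (loops and parallel edges as
  multiplicities).  `remove_leaf()` implements removal: delete the leaf
  labelled *x*, then suppress unlabelled degree-2 vertices.  `compute_deck()`
  assembles the X-deck \{N_x : x ∈ X\}.
* **Networks.** `is_phylo_network()` certifies the standard definition:
  simple, leaves bijectively labelled by X, no degree-2 vertices, and
  contracting every blob (maximal 2-edge-connected subgraph with ≥ 2 edges)
  yields a phylogenetic tree — equivalently, each cut-edge induces a
  distinct taxon bipartition.  Both characterisations are computed and must
  agree.  `is_binary()` checks that all degrees are 1 or 3.
* **Exact isomorphism with witnesses.** `find_isomorphism()` is an exact
  backtracking search over vertices, pruned by label / degree /
  leaf-distance-profile classes; any witness it returns (a vertex
  bijection f with G ≃ H via f) is independently checkable with
  `verify_isomorphism()`, and a brute-force enumeration method serves as an
  oracle on small graphs.
* **The counter-example families.** For each parity p ∈ {even, odd} and
  r ≥ 4, `build_M(r, p)` constructs the non-binary parity graph M^p on the
  2^(r−1) binary sequences of parity p (u_w adjacent to v\_{i,h} iff
  w_i = h), and `build_N(r, p)` constructs the binary network N^p by
  expanding each u_w into a caterpillar Cat(w) and each hub v\_{i,h} into a
  lexicographic tree Lex(i,h), then suppressing degree-2 vertices.  The
  explicit deck isomorphisms (`deck_isomorphism_M/G/N`, built from
  `caterpillar_isomorphism` and `lex_isomorphism` by flipping position i of
  every sequence) prove the decks identical, while
  `nonequivalence_certificate_M/N` exhibit a leaf-distance profile realised
  in the even graph by no vertex of the odd graph.
  `verify_counterexample()` runs the whole argument end to end.

Also included: a plain-text edge-list format (`read_lgf()`/`write_lgf()`),
GraphML export, a seeded random binary network generator for fuzzing, and a
command-line interface (`inst/exec/leafdeck`) with subcommands `generate`,
`deck`, `iso`, `verify`, `stats`.

## Worked example

```r
library(leafdeck)

n_even <- build_N(4, "even")
n_even
#> binary network N^even, r = 4: 40 vertices, 56 edges, |E|-|V| = 16

distance_profile(n_even$graph, "u:0000", n_even$taxa)
#> x1 x2 x3 x4
#>  3  3  4  4

verify_counterexample(4, "binary")
#> counter-example verification: family binary, r = 4
#>   deck member x1: equivalent
#>   deck member x2: equivalent
#>   deck member x3: equivalent
#>   deck member x4: equivalent
#>   graphs equivalent overall: FALSE
#>   certificate profile: 3 3 4 4 (matches in other graph: 0 )
#>   PASS: same deck, non-isomorphic graphs
```

The 40-vertex binary network N^even on four taxa has a vertex (`u:0000`,
the spine of the all-0 caterpillar) at distances 3, 3, 4, 4 from the leaves
x1..x4.  No vertex of N^odd realises that profile, so the two networks are
not isomorphic — yet for every taxon the two leaf-removed subnetworks are
equivalent (each check verifies an explicit witness and re-finds one by
generic search).  N^even therefore cannot be reconstructed from its deck.

The same machinery scales: `verify_counterexample(6, "binary",
generic_check = FALSE)` verifies the constructed witnesses and certificate
at r = 6 (308 vertices, |E|−|V| = 2^(r−1)(r−1) − 2r = 148).

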