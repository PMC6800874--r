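#' Bridges (cut-edges) of a multigraph
#'
#' All edges whose removal disconnects their component.  A pair of parallel
#' edges is never a bridge, and loops are never bridges.
#'
#' @param g an `lmg`.
#' @param method `"dfs"` (low-link search via igraph) or `"bruteforce"`
#'   (delete each edge and test connectivity); the two agree and the slow
#'   route is kept as a cross-check.
#' @return A two-column character matrix of bridge endpoints.
#' @export
bridges_of <- function(g, method = c("dfs", "bruteforce")) {
  method <- match.arg(method)
  empty <- matrix(character(), ncol = 2, dimnames = list(NULL, c("a", "b")))
  if (length(g$edges) == 0) return(empty)
  if (method == "dfs") {
    ig <- as_igraph(g)
    br <- igraph::bridges(ig)
    if (length(br) == 0) return(empty)
    ends <- igraph::ends(ig, br, names = TRUE)
    colnames(ends) <- c("a", "b")
    return(ends)
  }
  # brute force: single-multiplicity non-loop edges only
  ep <- edge_endpoints(names(g$edges))
  out <- empty
  for (k in seq_along(g$edges)) {
    a <- ep[k, 1]; b <- ep[k, 2]
    if (a == b || g$edges[[k]] > 1) next
    g2 <- g
    g2$edges <- g2$edges[-k]
    if (!same_component(g2, a, b)) out <- rbind(out, c(a, b))
  }
  out
}

same_component <- function(g, a, b) {
  is.finite(graph_distance(g, a, b))
}

#' Blobs: maximal 2-edge-connected subgraphs with at least two edges
#'
#' Computed as the connected components remaining after deleting all
#' bridges, kept when the induced subgraph has two or more edges.  Blob
#' vertex sets are pairwise disjoint and contain no degree-1 vertices of the
#' original graph.
#'
#' @param g an `lmg`.
#' @return List of character vectors (vertex sets), possibly empty.
#' @export
blobs_of <- function(g) {
  if (length(g$edges) == 0) return(list())
  br <- bridges_of(g)
  bridge_keys <- if (nrow(br)) edge_key(br[, 1], br[, 2]) else character()
  g2 <- g
  g2$edges <- g2$edges[!names(g2$edges) %in% bridge_keys]
  ig <- as_igraph(g2)
  comp <- igraph::components(ig)
  out <- list()
  for (ci in seq_len(comp$no)) {
    vs <- g2$vertices[comp$membership == ci]
    # count edges induced in g on vs (equivalently edges of g2 inside vs)
    ne <- 0L
    if (length(g2$edges)) {
      ep <- edge_endpoints(names(g2$edges))
      inside <- ep[, 1] %in% vs & ep[, 2] %in% vs
      ne <- sum(g2$edges[inside])
    }
    if (ne >= 2) out[[length(out) + 1]] <- vs
  }
  out
}

#' Test whether a graph is an unrooted phylogenetic network
#'
#' A graph is a network on taxon set `X` (|X| >= 2) when it is simple
#' (no loops or parallel edges), connected, its degree-1 vertices are
#' exactly the vertices bijectively labelled by `X`, it has no degree-2
#' vertices, and contracting each blob to a single vertex yields a
#' phylogenetic tree — equivalently, each cut-edge induces a distinct
#' bipartition of the taxa.  Both characterisations are evaluated and must
#' agree.
#'
#' @param g an `lmg`.
#' @param taxa character vector: the taxon set X.
#' @return Logical; attribute `"reasons"` lists failed checks (empty when
#'   `TRUE`).
#' @export
is_phylo_network <- function(g, taxa) {
  reasons <- character()
  taxa <- as.character(taxa)
  if (length(taxa) < 2) reasons <- c(reasons, "taxa_too_few")
  if (anyDuplicated(taxa)) reasons <- c(reasons, "taxa_duplicated")
  ep <- edge_endpoints(names(g$edges))
  if (any(ep[, 1] == ep[, 2])) reasons <- c(reasons, "has_loops")
  if (any(g$edges > 1)) reasons <- c(reasons, "has_parallel_edges")
  deg <- all_degrees(g)
  leaves <- names(deg)[deg == 1]
  if (!setequal(leaves, names(g$labels))) {
    reasons <- c(reasons, "leaves_not_exactly_labelled")
  }
  if (!setequal(unname(g$labels), taxa)) {
    reasons <- c(reasons, "labels_not_bijective_with_taxa")
  }
  if (any(deg == 2)) reasons <- c(reasons, "has_degree2_vertices")
  if (n_vertices(g) >= 1) {
    comp <- igraph::components(as_igraph(g))
    if (comp$no != 1) reasons <- c(reasons, "disconnected")
  }
  if (length(reasons) == 0) {
    a <- contraction_is_tree(g)
    b <- cut_partitions_unique(g)
    if (a != b) stop("internal: blob-contraction and cut-edge checks disagree")
    if (!a) reasons <- c(reasons, "blob_contraction_not_tree")
  }
  structure(length(reasons) == 0, reasons = reasons)
}

# contract every blob to one vertex; test the result is a phylogenetic tree
# (connected, acyclic, leaves bijectively labelled, no degree-2 vertices).
# A single-blob network contracts to a star, which qualifies.
contraction_is_tree <- function(g) {
  bl <- blobs_of(g)
  rep_of <- stats::setNames(g$vertices, g$vertices)
  for (k in seq_along(bl)) {
    rep_of[bl[[k]]] <- paste0("blob#", k)
  }
  verts <- unique(unname(rep_of))
  if (length(g$edges)) {
    ep <- edge_endpoints(names(g$edges))
    a <- unname(rep_of[ep[, 1]]); b <- unname(rep_of[ep[, 2]])
    keep <- a != b
    em <- cbind(a[keep], b[keep])
    em <- em[rep(seq_len(nrow(em)), unname(g$edges)[keep]), , drop = FALSE]
  } else {
    em <- NULL
  }
  ct <- lmg(verts, edges = em)
  if (length(ct$edges) && any(ct$edges > 1)) return(FALSE)   # cycle via blobs
  if (n_edges(ct) != n_vertices(ct) - 1) return(FALSE)
  comp <- igraph::components(as_igraph(ct))
  if (comp$no != 1) return(FALSE)
  deg <- all_degrees(ct)
  if (any(deg == 2)) return(FALSE)
  # leaves of the contracted tree must be exactly the labelled vertices
  setequal(names(deg)[deg == 1], names(g$labels))
}

# every cut-edge induces a distinct bipartition of the taxa with both sides
# nonempty
cut_partitions_unique <- function(g) {
  taxa <- sort(unname(g$labels))
  br <- bridges_of(g)
  seen <- character()
  if (nrow(br)) {
    for (k in seq_len(nrow(br))) {
      parts <- edge_bipartition(g, br[k, 1], br[k, 2])
      if (length(parts$left) == 0 || length(parts$right) == 0) return(FALSE)
      key <- paste(paste(parts$left, collapse = ","),
                   paste(parts$right, collapse = ","), sep = "/")
      if (key %in% seen) return(FALSE)
      seen <- c(seen, key)
    }
  }
  TRUE
}

# taxon sets of the two components after removing edge {a,b}; canonical order
edge_bipartition <- function(g, a, b) {
  g2 <- g
  key <- edge_key(a, b)
  g2$edges <- g2$edges[names(g2$edges) != key]
  ig <- as_igraph(g2)
  comp <- igraph::components(ig)
  side_a <- g2$vertices[comp$membership == comp$membership[match(a, g2$vertices)]]
  lab <- g$labels
  left <- sort(unname(lab[names(lab) %in% side_a]))
  right <- sort(setdiff(unname(lab), left))
  if (length(right) && (length(left) == 0 || right[1] < left[1])) {
    tmp <- left; left <- right; right <- tmp
  }
  list(left = left, right = right)
}

#' Construct a certified phylogenetic network
#'
#' Wraps a labelled multigraph that passes [is_phylo_network()] together
#' with its taxon set.
#'
#' @param g an `lmg`.
#' @param taxa taxon set; defaults to the labels present in `g`.
#' @return Object of class `"phylo_network"` with components `graph`, `taxa`.
#' @export
phylo_network <- function(g, taxa = sort(unname(g$labels))) {
  ok <- is_phylo_network(g, taxa)
  if (!ok) {
    stop("not a phylogenetic network: ",
         paste(attr(ok, "reasons"), collapse = ", "))
  }
  structure(list(graph = g, taxa = sort(as.character(taxa))),
            class = "phylo_network")
}

#' @export
print.phylo_network <- function(x, ...) {
  cat(sprintf("phylogenetic network on %d taxa: %d vertices, %d edges%s\n",
              length(x$taxa), n_vertices(x$graph), n_edges(x$graph),
              if (is_binary(x)) ", binary" else ""))
  invisible(x)
}

#' Is a network binary?
#'
#' @param n a `phylo_network`.
#' @return `TRUE` iff every vertex has degree 1 or 3.
#' @export
is_binary <- function(n) {
  all(all_degrees(n$graph) %in% c(1L, 3L))
}

#' Taxon bipartition induced by a cut-edge
#'
#' @param n a `phylo_network`.
#' @param a,b endpoints of a bridge of the network.
#' @return List with components `left`, `right`: the two nonempty taxon sets.
#' @export
cut_edge_partition <- function(n, a, b) {
  br <- bridges_of(n$graph)
  keys <- if (nrow(br)) edge_key(br[, 1], br[, 2]) else character()
  if (!edge_key(a, b) %in% keys) stop("edge {", a, ",", b, "} is not a bridge")
  edge_bipartition(n$graph, a, b)
}

#' Structural summary of a graph
#'
#' @param g an `lmg`.
#' @return List with vertex/edge counts, `|E|-|V|`, blob and bridge counts,
#'   the degree histogram, and whether all degrees are in {1,3}.
#' @export
graph_stats <- function(g) {
  deg <- all_degrees(g)
  hist <- table(deg)
  list(
    n_vertices = n_vertices(g),
    n_edges = n_edges(g),
    excess = n_edges(g) - n_vertices(g),
    n_blobs = length(blobs_of(g)),
    n_bridges = nrow(bridges_of(g)),
    degree_histogram = stats::setNames(as.integer(hist), names(hist)),
    binary = all(deg %in% c(1L, 3L))
  )
}
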