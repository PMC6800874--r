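#' Delete a vertex and its incident edges
#'
#' @param g an `lmg`.
#' @param v vertex identifier to delete.
#' @return The graph without `v`, its label (if any) and all incident edges.
#' @export
delete_vertex <- function(g, v) {
  stopifnot(length(v) == 1)
  if (!v %in% g$vertices) stop("unknown vertex: ", v)
  keep_v <- setdiff(g$vertices, v)
  labels <- g$labels[names(g$labels) != v]
  edges <- g$edges
  if (length(edges)) {
    ep <- edge_endpoints(names(edges))
    edges <- edges[ep[, 1] != v & ep[, 2] != v]
  }
  structure(list(vertices = keep_v, labels = labels, edges = edges),
            class = "lmg")
}

#' Suppress unlabelled degree-2 vertices
#'
#' Repeatedly removes any unlabelled vertex `v` of degree 2 whose two
#' edge-endpoints are two distinct edge slots (i.e. not a single loop at
#' `v`), replacing its two edges by one edge joining its neighbours.  The
#' neighbours may coincide (producing a loop) or may already be adjacent
#' (producing a parallel edge).  Iterates to a fixpoint; the result is
#' independent of processing order.  Labelled degree-2 vertices and vertices
#' whose only incidence is a loop are left in place, so the operation is
#' total.
#'
#' @param g an `lmg`.
#' @param order optional character vector of vertex ids giving a processing
#'   preference (used to exercise confluence); vertices listed earlier are
#'   suppressed first.
#' @return The suppressed graph; each suppression step removes exactly one
#'   vertex and one edge, so `|E| - |V|` is preserved.
#' @export
suppress_degree2 <- function(g, order = NULL) {
  vertices <- g$vertices
  labels <- g$labels
  edges <- g$edges
  rank <- stats::setNames(seq_along(vertices), vertices)
  if (!is.null(order)) {
    pref <- intersect(order, vertices)
    rank[pref] <- seq_along(pref) - length(vertices) - 1L
  }
  repeat {
    gg <- structure(list(vertices = vertices, labels = labels, edges = edges),
                    class = "lmg")
    deg <- all_degrees(gg)
    adj <- adjacency_of(gg)
    cand <- character()
    for (v in vertices) {
      if (deg[[v]] != 2L) next
      if (v %in% names(labels)) next
      nb <- adj[[v]]
      if (length(nb) == 1 && names(nb) == v) next  # single loop: leave
      cand <- c(cand, v)
    }
    if (length(cand) == 0) break
    v <- cand[which.min(rank[cand])]
    nb <- adj[[v]]
    nb <- nb[names(nb) != v]
    if (length(nb) == 1) {            # double edge to one neighbour -> loop
      a <- names(nb); b <- a
    } else {                          # two single edges
      a <- names(nb)[1]; b <- names(nb)[2]
    }
    # drop v's edges, add the bypass edge
    ep <- edge_endpoints(names(edges))
    edges <- edges[ep[, 1] != v & ep[, 2] != v]
    key <- edge_key(a, b)
    if (key %in% names(edges)) {
      edges[[key]] <- edges[[key]] + 1L
    } else {
      edges[[key]] <- 1L
    }
    vertices <- setdiff(vertices, v)
  }
  structure(list(vertices = vertices, labels = labels, edges = edges),
            class = "lmg")
}

#' Remove a leaf by taxon name
#'
#' Deletes the vertex labelled `taxon` together with its incident edges and
#' then suppresses any unlabelled degree-2 vertices.  This is the removal
#' operation whose results make up a network's X-deck.
#'
#' @param g an `lmg` with a vertex labelled `taxon`.
#' @param taxon a taxon name.
#' @return The removed graph `G_x` as an `lmg` with labels `X \ {x}`.
#' @export
remove_leaf <- function(g, taxon) {
  v <- vertex_of_taxon(g, taxon)
  suppress_degree2(delete_vertex(g, v))
}

#' Shortest-path distance between two vertices
#'
#' Unit edge weights; `Inf` if the vertices lie in different components.
#'
#' @param g an `lmg`.
#' @param a,b vertex identifiers.
#' @return A nonnegative number (possibly `Inf`).
#' @export
graph_distance <- function(g, a, b) {
  for (v in c(a, b)) if (!v %in% g$vertices) stop("unknown vertex: ", v)
  ig <- as_igraph(g)
  as.numeric(igraph::distances(ig, v = a, to = b))
}

#' Distances from a vertex to a set of labelled leaves
#'
#' The vector of shortest-path distances from `v` to the vertex labelled by
#' each taxon, in the given order.  Distance profiles are isomorphism
#' invariants and serve as certificates of non-equivalence: a profile
#' realised in one graph but by no vertex of another proves the two are not
#' isomorphic.
#'
#' @param g an `lmg`.
#' @param v a vertex identifier.
#' @param taxa character vector of taxon names, each labelling a vertex of `g`.
#' @return Named numeric vector of distances, one per taxon.
#' @export
distance_profile <- function(g, v, taxa) {
  if (!v %in% g$vertices) stop("unknown vertex: ", v)
  leaves <- vapply(taxa, function(x) vertex_of_taxon(g, x), "")
  ig <- as_igraph(g)
  d <- igraph::distances(ig, v = v, to = leaves)
  stats::setNames(as.numeric(d), taxa)
}

# distance profiles for all vertices at once: matrix vertices x taxa
all_profiles <- function(g, taxa) {
  leaves <- vapply(taxa, function(x) vertex_of_taxon(g, x), "")
  ig <- as_igraph(g)
  d <- igraph::distances(ig, v = g$vertices, to = leaves)
  dimnames(d) <- list(g$vertices, taxa)
  d
}
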