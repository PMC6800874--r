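#' Partially labelled undirected multigraphs
#'
#' `lmg()` constructs an undirected multigraph with opaque string vertex
#' identifiers, optional injective taxon labels on vertices, and edges stored
#' as multiplicity counts on unordered vertex pairs.  Loops (`{v,v}`) are
#' permitted and contribute 2 to the degree of `v`.  This is the common
#' substrate for phylogenetic networks and for the members of their decks,
#' which after leaf removal may contain parallel edges.
#'
#' @param vertices character vector of distinct vertex identifiers
#'   (whitespace-free strings).
#' @param labels named character vector mapping vertex id -> taxon name for
#'   the labelled vertices; must be injective in its values.
#' @param edges a two-column character matrix/data.frame, one row per edge
#'   (repeat a row for parallel edges; equal entries for a loop), or `NULL`
#'   for an edgeless graph.
#' @return An object of class `"lmg"`: a list with components `vertices`,
#'   `labels` and `edges` (a named integer vector of multiplicities, names
#'   are canonical `"a b"` pairs with `a <= b`).
#' @examples
#' g <- lmg(c("a", "b", "c"), labels = c(a = "x1"),
#'          edges = rbind(c("a", "b"), c("b", "c"), c("b", "c")))
#' degree_of(g, "b")  # 3: one edge to a, a double edge to c
#' @export
lmg <- function(vertices = character(), labels = character(), edges = NULL) {
  vertices <- as.character(vertices)
  if (anyDuplicated(vertices)) {
    stop("duplicate vertex identifiers: ",
         paste(unique(vertices[duplicated(vertices)]), collapse = ", "))
  }
  labels <- validate_labels(labels, vertices)
  emult <- edge_table(edges, vertices)
  structure(list(vertices = vertices, labels = labels, edges = emult),
            class = "lmg")
}

validate_labels <- function(labels, vertices) {
  if (length(labels) == 0) return(stats::setNames(character(), character()))
  labels <- stats::setNames(as.character(labels), names(labels))
  if (is.null(names(labels)) || any(names(labels) == "")) {
    stop("labels must be a named character vector (vertex -> taxon)")
  }
  missing <- setdiff(names(labels), vertices)
  if (length(missing)) {
    stop("labelled vertices not in vertex set: ", paste(missing, collapse = ", "))
  }
  if (anyDuplicated(labels)) {
    stop("labels must be injective; duplicated taxon: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "))
  }
  labels
}

edge_table <- function(edges, vertices) {
  if (is.null(edges) || NROW(edges) == 0) {
    return(stats::setNames(integer(), character()))
  }
  edges <- as.matrix(edges)
  if (ncol(edges) != 2) stop("edges must have two columns")
  mode(edges) <- "character"
  bad <- setdiff(c(edges[, 1], edges[, 2]), vertices)
  if (length(bad)) {
    stop("edge endpoint not in vertex set: ", paste(unique(bad), collapse = ", "))
  }
  keys <- edge_key(edges[, 1], edges[, 2])
  tab <- table(keys)
  stats::setNames(as.integer(tab), names(tab))
}

# canonical unordered-pair key; vertex ids are whitespace-free so " " is safe
edge_key <- function(a, b) {
  ifelse(a <= b, paste(a, b), paste(b, a))
}

edge_endpoints <- function(keys) {
  if (length(keys) == 0) {
    return(matrix(character(), ncol = 2, dimnames = list(NULL, c("a", "b"))))
  }
  parts <- strsplit(keys, " ", fixed = TRUE)
  matrix(c(vapply(parts, `[`, "", 1L), vapply(parts, `[`, "", 2L)),
         ncol = 2, dimnames = list(NULL, c("a", "b")))
}

#' @export
print.lmg <- function(x, ...) {
  cat(sprintf("labelled multigraph: %d vertices, %d edges, %d labelled\n",
              n_vertices(x), n_edges(x), length(x$labels)))
  if (length(x$labels)) {
    cat("  taxa:", paste(sort(unname(x$labels)), collapse = " "), "\n")
  }
  invisible(x)
}

#' Vertex and edge counts
#'
#' `n_edges()` counts edges with multiplicity (a double edge counts twice,
#' a loop once).
#'
#' @param g an `lmg`.
#' @return An integer.
#' @export
n_vertices <- function(g) length(g$vertices)

#' @rdname n_vertices
#' @export
n_edges <- function(g) sum(g$edges)

#' Vertex degree
#'
#' Number of edge-endpoints incident to `v`; a loop at `v` contributes 2.
#'
#' @param g an `lmg`.
#' @param v a vertex identifier.
#' @return Nonnegative integer degree.
#' @export
degree_of <- function(g, v) {
  stopifnot(length(v) == 1)
  if (!v %in% g$vertices) stop("unknown vertex: ", v)
  all_degrees(g)[[v]]
}

# degrees of every vertex as a named integer vector
all_degrees <- function(g) {
  deg <- stats::setNames(integer(length(g$vertices)), g$vertices)
  if (length(g$edges)) {
    ep <- edge_endpoints(names(g$edges))
    m <- unname(g$edges)
    for (k in seq_along(m)) {
      deg[[ep[k, 1]]] <- deg[[ep[k, 1]]] + m[k]
      deg[[ep[k, 2]]] <- deg[[ep[k, 2]]] + m[k]  # loop: both endpoints equal -> +2m
    }
  }
  deg
}

# adjacency as named list: vertex -> named integer vector (neighbour -> mult);
# a loop appears as the vertex itself with its multiplicity
adjacency_of <- function(g) {
  adj <- stats::setNames(vector("list", length(g$vertices)), g$vertices)
  for (v in g$vertices) adj[[v]] <- stats::setNames(integer(), character())
  if (length(g$edges)) {
    ep <- edge_endpoints(names(g$edges))
    m <- unname(g$edges)
    for (k in seq_along(m)) {
      a <- ep[k, 1]; b <- ep[k, 2]
      adj[[a]][[b]] <- m[k]
      adj[[b]][[a]] <- m[k]
    }
  }
  adj
}

# multiplicity of the edge {a,b} (0 if absent)
edge_mult <- function(g, a, b) {
  key <- edge_key(a, b)
  if (key %in% names(g$edges)) g$edges[[key]] else 0L
}

#' Vertex label lookup
#'
#' @param g an `lmg`.
#' @param taxon a taxon name.
#' @return The vertex id carrying `taxon`, or an error if absent.
#' @export
vertex_of_taxon <- function(g, taxon) {
  hit <- names(g$labels)[g$labels == taxon]
  if (length(hit) != 1) stop("no vertex labelled: ", taxon)
  hit
}

#' Convert to an igraph object
#'
#' Parallel edges are expanded to repeated edges; the taxon label is attached
#' as the vertex attribute `"label"` (NA for unlabelled vertices).
#'
#' @param g an `lmg`.
#' @return An [igraph::graph] object.
#' @export
as_igraph <- function(g) {
  ig <- igraph::make_empty_graph(n = 0, directed = FALSE)
  ig <- igraph::add_vertices(ig, length(g$vertices), name = g$vertices)
  if (length(g$edges)) {
    ep <- edge_endpoints(names(g$edges))
    reps <- rep(seq_len(nrow(ep)), unname(g$edges))
    el <- rbind(ep[reps, 1], ep[reps, 2])
    ig <- igraph::add_edges(ig, as.vector(el))
  }
  lab <- rep(NA_character_, length(g$vertices))
  lab[match(names(g$labels), g$vertices)] <- unname(g$labels)
  igraph::set_vertex_attr(ig, "label", value = lab)
}

# structural equality (same ids, labels, multiplicities); not isomorphism
lmg_identical <- function(g, h) {
  setequal(g$vertices, h$vertices) &&
    identical(g$labels[order(names(g$labels))], h$labels[order(names(h$labels))]) &&
    identical(g$edges[order(names(g$edges))], h$edges[order(names(h$edges))])
}
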