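#' Build a caterpillar tree for a binary sequence
#'
#' The caterpillar `Cat(w)` for a length-`r` sequence `w` has spine vertices
#' `u:w` and `y:w:1 .. y:w:(r-3)`, leaf vertices `z:w:1 .. z:w:r`, and edges
#' `u-z1`, `u-z2`, `u-y1`, `y(r-3)-z(r-1)`, `y(r-3)-zr`, plus `yk-z(k+2)`
#' and `yk-y(k+1)` for `k = 1 .. r-4`.  All internal (spine) vertices have
#' degree 3.  For `r = 4` the single spine vertex `y:w:1` plays both end
#' roles.
#'
#' @param w a binary sequence string of length `r >= 4`.
#' @return Object of class `"caterpillar"`: list with `graph` (an `lmg`),
#'   `w`, `r`, `u` (spine head id), `z_leaves` (ids in position order).
#' @export
build_caterpillar <- function(w) {
  check_binseq(w)
  r <- nchar(w)
  if (r < 4) stop("caterpillars require sequences of length >= 4")
  u <- paste0("u:", w)
  ys <- sprintf("y:%s:%d", w, seq_len(r - 3))
  zs <- sprintf("z:%s:%d", w, seq_len(r))
  edges <- list(c(u, zs[1]), c(u, zs[2]), c(u, ys[1]),
                c(ys[r - 3], zs[r - 1]), c(ys[r - 3], zs[r]))
  if (r >= 5) {
    for (k in seq_len(r - 4)) {
      edges <- c(edges, list(c(ys[k], zs[k + 2]), c(ys[k], ys[k + 1])))
    }
  }
  g <- lmg(c(u, ys, zs), edges = do.call(rbind, edges))
  structure(list(graph = g, w = w, r = r, u = u, z_leaves = zs),
            class = "caterpillar")
}

# t-bit binary expansion of a 0-based index, most significant bit first
index_bits <- function(idx, t) {
  bits <- integer(t)
  for (k in seq_len(t)) {
    bits[t - k + 1] <- idx %% 2L
    idx <- idx %/% 2L
  }
  paste(bits, collapse = "")
}

lex_node_id <- function(root_id, prefix, path) {
  if (nchar(path) == 0) root_id else paste0(prefix, ":", path)
}

#' Build a lexicographic tree on a set of binary sequences
#'
#' `Lex(i, S)` is the fully balanced binary tree whose leaves are the shared
#' vertices `z:w:i` for `w` in `S` (|S| = 2^t), with a degree-2 root and all
#' leaves at depth exactly `t`.  It is built by recursive bisection of the
#' lexicographically sorted `S`: the root's two subtrees carry the lower and
#' upper halves.  A depth-first search that always descends into the
#' lower-half child first traverses the leaves in lexicographic order of
#' `w`, which determines the tree uniquely.
#'
#' @param i the shared-leaf position (determines leaf ids `z:w:i`).
#' @param S character vector of equal-length binary sequences; `|S|` must be
#'   a power of two, at least 2.
#' @param root_id identifier for the root vertex.
#' @param prefix prefix for internal-vertex identifiers; an internal vertex
#'   at depth `d` is named `<prefix>:<p>` where `p` is its 0/1 path from the
#'   root.
#' @return Object of class `"lex_tree"`: list with `graph`, `root`, `i`,
#'   `S` (sorted), `depth`, `leaves` (ids in depth-first lexicographic
#'   order).
#' @export
build_lex_tree <- function(i, S,
                           root_id = sprintf("lexroot:%d", i),
                           prefix = sprintf("lex:%d", i)) {
  S <- sort(unique(as.character(S)))
  n <- length(S)
  t <- round(log2(n))
  if (n < 2 || 2^t != n) stop("|S| must be a power of two, at least 2")
  lens <- unique(nchar(S))
  if (length(lens) != 1) stop("sequences must have equal length")
  i <- check_position(S[1], i)
  leaves <- sprintf("z:%s:%d", S, i)
  verts <- root_id
  edges <- list()
  rec <- function(path, lo, hi) {
    # block [lo, hi] of the sorted leaf list, handled by the internal vertex
    # at `path`; emit edges to its two half-blocks
    me <- lex_node_id(root_id, prefix, path)
    mid <- (lo + hi) %/% 2
    for (half in list(c(lo, mid), c(mid + 1, hi))) {
      bit <- if (half[1] == lo) "0" else "1"
      if (half[1] == half[2]) {
        child <- leaves[half[1]]
      } else {
        child <- lex_node_id(root_id, prefix, paste0(path, bit))
        verts <<- c(verts, child)
      }
      edges[[length(edges) + 1]] <<- c(me, child)
      if (half[1] < half[2]) rec(paste0(path, bit), half[1], half[2])
    }
  }
  rec("", 1, n)
  g <- lmg(c(verts, leaves), edges = do.call(rbind, edges))
  structure(list(graph = g, root = root_id, i = i, S = S, depth = t,
                 leaves = leaves),
            class = "lex_tree")
}

#' Build the pre-suppression parity graph G
#'
#' The graph contains the caterpillar `Cat(w)` for every length-`r` sequence
#' `w` of the chosen parity, the lexicographic tree on the sequences with
#' value `h` at position `i` (rooted at `v:i:h`) for every position `i` and
#' `h` in {0,1}, and a labelled leaf `x:i` pendant on `v:i:0`.  Caterpillars
#' and lexicographic trees share the vertices `z:w:i`, which therefore have
#' degree 2, as do the roots `v:i:1`; all other non-leaf vertices have
#' degree 3, and all non-leaf vertices lie in a single blob.
#'
#' @param r number of leaves, `r >= 4`.
#' @param parity `"even"` or `"odd"`.
#' @return Object of class `"g_graph"`: list with `graph`, `r`, `parity`,
#'   `taxa`.
#' @export
build_G <- function(r, parity = c("even", "odd")) {
  parity <- match.arg(parity)
  if (!(is.numeric(r) && length(r) == 1 && r == as.integer(r) && r >= 4)) {
    stop("r must be an integer >= 4")
  }
  r <- as.integer(r)
  key <- sprintf("G:%d:%s", r, parity)
  if (!is.null(got <- family_cache_get(key))) return(got)
  ws <- parity_sequences(r, parity)
  verts <- character()
  labels <- character()
  edges <- list()
  add_graph <- function(g) {
    verts <<- c(verts, setdiff(g$vertices, verts))
    if (length(g$edges)) {
      ep <- edge_endpoints(names(g$edges))
      edges[[length(edges) + 1]] <<- ep[rep(seq_len(nrow(ep)),
                                            unname(g$edges)), , drop = FALSE]
    }
  }
  for (w in ws) add_graph(build_caterpillar(w)$graph)
  for (i in seq_len(r)) {
    for (h in 0:1) {
      S <- restrict_seqs(ws, i, h)
      lex <- build_lex_tree(i, S,
                            root_id = sprintf("v:%d:%d", i, h),
                            prefix = sprintf("lex:%d:%d", i, h))
      add_graph(lex$graph)
    }
  }
  x_ids <- sprintf("x:%d", seq_len(r))
  taxa <- sprintf("x%d", seq_len(r))
  verts <- c(verts, x_ids)
  edges[[length(edges) + 1]] <- cbind(x_ids, sprintf("v:%d:0", seq_len(r)))
  g <- lmg(verts, labels = stats::setNames(taxa, x_ids),
           edges = do.call(rbind, edges))
  out <- structure(list(graph = g, r = r, parity = parity, taxa = taxa),
                   class = "g_graph")
  family_cache_set(key, out)
}

# memoisation for the (deterministic) family builders; the construction for
# a given (r, parity) is a pure function, so caching is observationally
# transparent and keeps repeated certificate/deck computations cheap
.family_cache <- new.env(parent = emptyenv())

family_cache_get <- function(key) {
  if (exists(key, envir = .family_cache, inherits = FALSE)) {
    get(key, envir = .family_cache, inherits = FALSE)
  } else {
    NULL
  }
}

family_cache_set <- function(key, value) {
  assign(key, value, envir = .family_cache)
  value
}

#' @export
print.g_graph <- function(x, ...) {
  cat(sprintf("pre-suppression graph G^%s, r = %d: %d vertices, %d edges\n",
              x$parity, x$r, n_vertices(x$graph), n_edges(x$graph)))
  invisible(x)
}

#' Build the binary network N
#'
#' Suppresses all degree-2 vertices of the graph from [build_G()] (the
#' shared `z:w:i` vertices and the roots `v:i:1`) and certifies the result
#' as a binary phylogenetic network on `x1 .. xr` with a single blob.
#' Surviving vertices keep their pre-suppression identifiers, so named
#' vertices such as `u:000...0` remain addressable.  The resulting networks
#' satisfy `|E| - |V| = 2^(r-1) (r-1) - 2 r`.
#'
#' @param r number of leaves, `r >= 4`.
#' @param parity `"even"` or `"odd"`.
#' @return Object of class `c("n_network", "phylo_network")`: list with
#'   `graph`, `taxa`, `r`, `parity`.
#' @export
build_N <- function(r, parity = c("even", "odd")) {
  parity <- match.arg(parity)
  key <- sprintf("N:%d:%s", r, parity)
  if (!is.null(got <- family_cache_get(key))) return(got)
  gg <- build_G(r, parity)
  ng <- suppress_degree2(gg$graph)
  ok <- is_phylo_network(ng, gg$taxa)
  if (!ok) {
    stop("suppressed graph failed network validation: ",
         paste(attr(ok, "reasons"), collapse = ", "))
  }
  n <- structure(list(graph = ng, taxa = gg$taxa, r = gg$r, parity = parity),
                 class = c("n_network", "phylo_network"))
  if (!is_binary(n)) stop("suppressed graph is not binary")
  family_cache_set(key, n)
}

#' @export
print.n_network <- function(x, ...) {
  cat(sprintf("binary network N^%s, r = %d: %d vertices, %d edges, |E|-|V| = %d\n",
              x$parity, x$r, n_vertices(x$graph), n_edges(x$graph),
              n_edges(x$graph) - n_vertices(x$graph)))
  invisible(x)
}

#' Witness between two caterpillars
#'
#' Any two caterpillars on equal-length sequences are isomorphic via the
#' role-preserving map `u -> u`, `y:k -> y:k`, `z:k -> z:k`.
#'
#' @param w,w2 binary sequence strings of equal length `>= 4`.
#' @return A witness mapping `Cat(w)` onto `Cat(w2)`.
#' @export
caterpillar_isomorphism <- function(w, w2) {
  check_binseq(w); check_binseq(w2)
  if (nchar(w) != nchar(w2)) stop("sequences must have equal length")
  r <- nchar(w)
  f <- stats::setNames(paste0("u:", w2), paste0("u:", w))
  f[sprintf("y:%s:%d", w, seq_len(r - 3))] <- sprintf("y:%s:%d", w2, seq_len(r - 3))
  f[sprintf("z:%s:%d", w, seq_len(r))] <- sprintf("z:%s:%d", w2, seq_len(r))
  f
}

# ancestor id at depth d of the leaf with 0-based index idx in a lex tree
lex_ancestor_id <- function(root_id, prefix, idx, t, d) {
  lex_node_id(root_id, prefix, substr(index_bits(idx, t), 1, d))
}

#' Witness between even and odd lexicographic trees
#'
#' For `j != i`, maps `Lex(j,h)^even` onto `Lex(j,h)^odd` (root to root);
#' for `j == i`, maps `Lex(i,h)^even` onto `Lex(i,1-h)^odd`.  Leaves map by
#' flipping position `i` of their sequence; an internal vertex at depth `d`
#' maps to the depth-`d` ancestor of the image of any of its descendant
#' leaves (well-defined because flipping position `i` preserves which
#' leaves share ancestors).
#'
#' @param r sequence length, `r >= 4`.
#' @param j tree position in `1..r`.
#' @param h 0 or 1.
#' @param i the position being flipped (the removed taxon), in `1..r`.
#' @return A witness between the two lexicographic trees (with the vertex
#'   ids used inside [build_G()]).
#' @export
lex_isomorphism <- function(r, j, h, i) {
  stopifnot(r >= 4, j >= 1, j <= r, i >= 1, i <= r, h %in% c(0, 1))
  src_S <- sort(restrict_seqs(parity_sequences(r, "even"), j, h))
  h2 <- if (j == i) 1 - h else h
  dst_S <- sort(restrict_seqs(parity_sequences(r, "odd"), j, h2))
  t <- round(log2(length(src_S)))
  src_root <- sprintf("v:%d:%d", j, h)
  src_pref <- sprintf("lex:%d:%d", j, h)
  dst_root <- sprintf("v:%d:%d", j, h2)
  dst_pref <- sprintf("lex:%d:%d", j, h2)
  f <- character()
  # leaves: z:w:j -> z:flip(w,i):j
  imgs <- vapply(src_S, flip_at, "", i = i)
  f[sprintf("z:%s:%d", src_S, j)] <- sprintf("z:%s:%d", imgs, j)
  # internal vertices (depths 0 .. t-1): image via the flipped first leaf of
  # the vertex's block
  for (d in 0:(t - 1)) {
    for (blk in seq_len(2^d)) {
      lo <- (blk - 1) * 2^(t - d)          # 0-based index of first leaf
      src_id <- lex_ancestor_id(src_root, src_pref, lo, t, d)
      w <- src_S[lo + 1]
      idx2 <- match(flip_at(w, i), dst_S) - 1L
      f[src_id] <- lex_ancestor_id(dst_root, dst_pref, idx2, t, d)
    }
  }
  f
}

#' Glued deck witness between the leaf-deleted G graphs
#'
#' Combines the caterpillar witnesses (`Cat(w)` onto `Cat(w')` with
#' position `i` flipped) and the lexicographic-tree witnesses into a single
#' witness between `G^even - x_i` and `G^odd - x_i` (leaf deleted, not
#' suppressed); the pieces agree on the shared vertices `z:w:j`.  Leaves
#' `x_j`, `j != i`, are fixed.
#'
#' @param r number of leaves, `r >= 4`.
#' @param i the removed position, in `1..r`.
#' @return A witness passing [verify_isomorphism()] on the two leaf-deleted
#'   graphs.
#' @export
deck_isomorphism_G <- function(r, i) {
  stopifnot(r >= 4, i >= 1, i <= r)
  f <- character()
  for (w in parity_sequences(r, "even")) {
    f <- c(f, caterpillar_isomorphism(w, flip_at(w, i)))
  }
  for (j in seq_len(r)) {
    for (h in 0:1) {
      lf <- lex_isomorphism(r, j, h, i)
      f[names(lf)] <- lf            # z entries coincide with caterpillar map
    }
  }
  for (j in setdiff(seq_len(r), i)) {
    f[sprintf("x:%d", j)] <- sprintf("x:%d", j)
  }
  f
}

#' Deck witness between the network deck members
#'
#' Restricts the glued witness of [deck_isomorphism_G()] to the vertices
#' surviving suppression, yielding a witness between the deck members
#' `(N^even)_{x_i}` and `(N^odd)_{x_i}`.  Vertices of degree other than 2
#' map to vertices of degree other than 2, so the restriction is
#' well-defined.
#'
#' @param r number of leaves, `r >= 4`.
#' @param i the removed position, in `1..r`.
#' @return A witness between the two removed networks.
#' @export
deck_isomorphism_N <- function(r, i) {
  fg <- deck_isomorphism_G(r, i)
  surv <- remove_leaf(build_N(r, "even")$graph, sprintf("x%d", i))$vertices
  fg[surv]
}

#' Distance-profile certificate that the two N networks differ
#'
#' The all-0 spine vertex of `N^even` has a leaf-distance profile (for
#' `r = 4`: 3, 3, 4, 4) realised by no vertex of `N^odd`; the report
#' carries the profile and the exhaustive scan count.
#'
#' @param r number of leaves, `r >= 4`.
#' @return List of class `"noneq_certificate"`; see
#'   [nonequivalence_certificate_M()].
#' @export
nonequivalence_certificate_N <- function(r) {
  n_even <- build_N(r, "even")
  n_odd <- build_N(r, "odd")
  u0 <- paste0("u:", strrep("0", r))
  prof <- distance_profile(n_even$graph, u0, n_even$taxa)
  other <- all_profiles(n_odd$graph, n_odd$taxa)
  matches <- sum(apply(other, 1, function(p) all(p == prof)))
  structure(list(vertex = u0, profile = prof,
                 matches_in_other = as.integer(matches),
                 valid = matches == 0),
            class = "noneq_certificate")
}
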