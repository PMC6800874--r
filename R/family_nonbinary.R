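#' Build the non-binary parity graph M
#'
#' For `r >= 4` leaves, the graph contains a vertex `u:w` for every length-r
#' binary sequence `w` of the chosen parity, a pair of vertices `v:i:0`,
#' `v:i:1` per position `i`, and a leaf `x:i` labelled `x<i>` pendant on
#' `v:i:0`.  Each `u:w` is adjacent to `v:i:h` exactly when position `i` of
#' `w` equals `h`.  The even and odd graphs have the same X-deck but are not
#' isomorphic: flipping position `i` of every sequence maps one deck member
#' onto the other, yet the all-0 vertex of the even graph sits at distance 2
#' from every leaf while no vertex of the odd graph does.
#'
#' @param r number of leaves, `r >= 4`.
#' @param parity `"even"` or `"odd"`.
#' @return Object of class `"m_graph"`: list with `graph` (an `lmg`), `r`,
#'   `parity`, `taxa`.  `|V| = 2^(r-1) + 3r`, `|E| = r 2^(r-1) + r`, and no
#'   vertex has degree 2.
#' @export
build_M <- function(r, parity = c("even", "odd")) {
  parity <- match.arg(parity)
  if (!(is.numeric(r) && length(r) == 1 && r == as.integer(r) && r >= 4)) {
    stop("r must be an integer >= 4")
  }
  r <- as.integer(r)
  ws <- parity_sequences(r, parity)
  u_ids <- paste0("u:", ws)
  v_ids <- as.vector(t(outer(seq_len(r), 0:1,
                             function(i, h) sprintf("v:%d:%d", i, h))))
  x_ids <- sprintf("x:%d", seq_len(r))
  taxa <- sprintf("x%d", seq_len(r))
  edges <- matrix(character(), ncol = 2)
  for (w in ws) {
    bits <- seq_bits(w)
    edges <- rbind(edges,
                   cbind(paste0("u:", w), sprintf("v:%d:%d", seq_len(r), bits)))
  }
  edges <- rbind(edges, cbind(x_ids, sprintf("v:%d:0", seq_len(r))))
  g <- lmg(c(u_ids, v_ids, x_ids),
           labels = stats::setNames(taxa, x_ids),
           edges = edges)
  structure(list(graph = g, r = r, parity = parity, taxa = taxa),
            class = "m_graph")
}

#' @export
print.m_graph <- function(x, ...) {
  cat(sprintf("parity graph M^%s, r = %d: %d vertices, %d edges\n",
              x$parity, x$r, n_vertices(x$graph), n_edges(x$graph)))
  invisible(x)
}

#' Explicit deck isomorphism for the M family
#'
#' The witness between the deck members `(M^even)_{x_i}` and
#' `(M^odd)_{x_i}`: each `u:w` maps to `u:w'` with position `i` flipped,
#' `v:i:0` and `v:i:1` swap, everything else is fixed.  Removing `x_i` from
#' an M graph never triggers suppression (all remaining degrees exceed 2),
#' so the deck members are the leaf-deleted graphs.
#'
#' @param r number of leaves, `r >= 4`.
#' @param i position in `1..r`.
#' @return A witness (named character vector) passing
#'   [verify_isomorphism()] on the two deck members.
#' @export
deck_isomorphism_M <- function(r, i) {
  if (!(is.numeric(i) && length(i) == 1 && i >= 1 && i <= r)) {
    stop("i out of range")
  }
  i <- as.integer(i)
  ws <- parity_sequences(r, "even")
  f <- stats::setNames(paste0("u:", vapply(ws, flip_at, "", i = i)),
                       paste0("u:", ws))
  f[sprintf("v:%d:0", i)] <- sprintf("v:%d:1", i)
  f[sprintf("v:%d:1", i)] <- sprintf("v:%d:0", i)
  for (j in setdiff(seq_len(r), i)) {
    f[sprintf("v:%d:0", j)] <- sprintf("v:%d:0", j)
    f[sprintf("v:%d:1", j)] <- sprintf("v:%d:1", j)
    f[sprintf("x:%d", j)] <- sprintf("x:%d", j)
  }
  f
}

#' Distance-profile certificate that the two M graphs differ
#'
#' Reports (a) the profile of the all-0 vertex of `M^even`, which is 2 for
#' every leaf, and (b) an exhaustive scan showing that no vertex of
#' `M^odd` has distance 2 to every leaf.  Since distance profiles are
#' preserved by isomorphism, a valid certificate proves the graphs are not
#' equivalent.
#'
#' @param r number of leaves, `r >= 4`.
#' @return List of class `"noneq_certificate"` with fields `vertex`,
#'   `profile`, `matches_in_other`, `valid`.
#' @export
nonequivalence_certificate_M <- function(r) {
  m_even <- build_M(r, "even")
  m_odd <- build_M(r, "odd")
  u0 <- paste0("u:", strrep("0", r))
  prof <- distance_profile(m_even$graph, u0, m_even$taxa)
  other <- all_profiles(m_odd$graph, m_odd$taxa)
  matches <- sum(apply(other, 1, function(p) all(p == prof)))
  structure(list(vertex = u0, profile = prof,
                 matches_in_other = as.integer(matches),
                 valid = matches == 0),
            class = "noneq_certificate")
}

#' @export
print.noneq_certificate <- function(x, ...) {
  cat("non-equivalence certificate\n")
  cat("  vertex:", x$vertex, "\n")
  cat("  leaf-distance profile:", paste(x$profile, collapse = " "), "\n")
  cat("  matching vertices in the other graph:", x$matches_in_other, "\n")
  cat("  valid:", x$valid, "\n")
  invisible(x)
}
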