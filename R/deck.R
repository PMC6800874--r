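#' Compute the X-deck of a network or graph
#'
#' The deck maps each taxon `x` to the removed graph obtained by deleting
#' the leaf labelled `x` and suppressing any unlabelled degree-2 vertices.
#' Deck members are multigraphs (removal can create parallel edges), each
#' carrying the labels `X \ {x}`.
#'
#' @param x a `phylo_network`, `m_graph`, or plain `lmg` with labelled
#'   leaves.
#' @return Named list of `lmg` graphs, one per taxon.
#' @export
compute_deck <- function(x) {
  g <- if (inherits(x, "lmg")) x else x$graph
  taxa <- sort(unname(g$labels))
  if (length(taxa) < 2) stop("deck requires at least two taxa")
  stats::setNames(lapply(taxa, function(tx) remove_leaf(g, tx)), taxa)
}

#' Test whether one network is an X-reconstruction of another
#'
#' `n2` is an X-reconstruction of `n` when, for every taxon `x`, the deck
#' members `n_x` and `n2_x` are equivalent.  Equivalence is checked
#' per-label (the member for `x` against the member for the same `x`) with
#' the generic isomorphism search; witnesses are returned.
#'
#' @param n,n2 networks (or family graphs) on the same taxon set.
#' @return Logical; attribute `"witnesses"` holds the per-taxon witness
#'   list (`NULL` entries where no isomorphism exists).
#' @export
is_reconstruction <- function(n, n2) {
  g1 <- if (inherits(n, "lmg")) n else n$graph
  g2 <- if (inherits(n2, "lmg")) n2 else n2$graph
  t1 <- sort(unname(g1$labels)); t2 <- sort(unname(g2$labels))
  if (!identical(t1, t2)) stop("taxon sets differ")
  d1 <- compute_deck(g1)
  d2 <- compute_deck(g2)
  wit <- lapply(t1, function(tx) find_isomorphism(d1[[tx]], d2[[tx]]))
  names(wit) <- t1
  ok <- all(!vapply(wit, is.null, TRUE))
  structure(ok, witnesses = wit)
}

#' End-to-end verification of a counter-example family
#'
#' Builds the even and odd graphs of the requested family, checks that
#' every pair of same-taxon deck members is equivalent using the explicit
#' constructed witnesses, checks that the two graphs themselves are not
#' equivalent using the family's distance-profile certificate, and (when
#' `generic_check` is `TRUE`) re-derives both verdicts independently with
#' the generic isomorphism search.  The overall verdict passes iff all deck
#' pairs are equivalent and the full graphs are not.
#'
#' @param r number of leaves, `r >= 4`.
#' @param family `"binary"` (the caterpillar/lexicographic-tree networks)
#'   or `"nonbinary"` (the parity graphs).
#' @param generic_check also run the generic search; defaults to `TRUE` at
#'   `r = 4`, where it is cheap.
#' @return Object of class `"counterexample_report"`: list with `r`,
#'   `family`, `deck` (per-taxon list of `taxon`, `equivalent`,
#'   `witness_size`), `equivalent_overall`, `certificate`, `pass`.
#' @export
verify_counterexample <- function(r, family = c("binary", "nonbinary"),
                                  generic_check = (r == 4)) {
  family <- match.arg(family)
  if (!(is.numeric(r) && length(r) == 1 && r == as.integer(r) && r >= 4)) {
    stop("r must be an integer >= 4")
  }
  r <- as.integer(r)
  if (family == "binary") {
    even <- build_N(r, "even"); odd <- build_N(r, "odd")
    wit_fun <- function(i) deck_isomorphism_N(r, i)
    cert <- nonequivalence_certificate_N(r)
  } else {
    even <- build_M(r, "even"); odd <- build_M(r, "odd")
    wit_fun <- function(i) deck_isomorphism_M(r, i)
    cert <- nonequivalence_certificate_M(r)
  }
  taxa <- even$taxa
  deck <- vector("list", r)
  for (i in seq_len(r)) {
    a <- remove_leaf(even$graph, taxa[i])
    b <- remove_leaf(odd$graph, taxa[i])
    f <- wit_fun(i)
    equivalent <- verify_isomorphism(a, b, f)
    if (generic_check) {
      found <- find_isomorphism(a, b)
      equivalent <- equivalent && !is.null(found) &&
        verify_isomorphism(a, b, found)
    }
    deck[[i]] <- list(taxon = taxa[i], equivalent = equivalent,
                      witness_size = length(f))
  }
  equivalent_overall <- !cert$valid
  if (generic_check) {
    equivalent_overall <- equivalent_overall ||
      !is.null(find_isomorphism(even$graph, odd$graph))
  }
  pass <- all(vapply(deck, `[[`, TRUE, "equivalent")) && !equivalent_overall
  structure(list(r = r, family = family, deck = deck,
                 equivalent_overall = equivalent_overall,
                 certificate = list(vertex = cert$vertex,
                                    profile = unname(cert$profile),
                                    matches_in_other = cert$matches_in_other),
                 pass = pass),
            class = "counterexample_report")
}

#' @export
print.counterexample_report <- function(x, ...) {
  cat(sprintf("counter-example verification: family %s, r = %d\n",
              x$family, x$r))
  for (d in x$deck) {
    cat(sprintf("  deck member %s: %s\n", d$taxon,
                if (d$equivalent) "equivalent" else "NOT equivalent"))
  }
  cat("  graphs equivalent overall:", x$equivalent_overall, "\n")
  cat("  certificate profile:", paste(x$certificate$profile, collapse = " "),
      "(matches in other graph:", x$certificate$matches_in_other, ")\n")
  cat(if (x$pass) "  PASS: same deck, non-isomorphic graphs\n"
      else "  FAIL\n")
  invisible(x)
}

#' Random binary phylogenetic network
#'
#' Seeded deterministic fuzz-fixture generator: grows a random binary tree
#' on `n_leaves` leaves by repeated leaf attachment to a random edge, then
#' `extra_edges` times picks two distinct edges, subdivides each and joins
#' the two subdivision vertices.  Draws that would break simplicity are
#' rejected and retried a bounded number of times.  The output passes
#' [is_phylo_network()] and [is_binary()].
#'
#' @param n_leaves number of taxa, `>= 2`.
#' @param extra_edges number of added cross edges, `>= 0`; each raises
#'   `|E| - |V|` by one from the tree's -1.
#' @param seed integer seed; the same seed yields the identical graph.
#' @return A `phylo_network` on taxa `t1 .. t<n_leaves>`.
#' @export
random_binary_network <- function(n_leaves, extra_edges = 0, seed = 1) {
  stopifnot(n_leaves >= 2, extra_edges >= 0)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  for (attempt in 1:50) {
    g <- random_binary_attempt(n_leaves, extra_edges)
    if (!is.null(g)) {
      taxa <- sprintf("t%d", seq_len(n_leaves))
      if (isTRUE(is_phylo_network(g, taxa))) return(phylo_network(g, taxa))
    }
  }
  stop("could not generate a valid network for these parameters")
}

random_binary_attempt <- function(n_leaves, extra_edges) {
  taxa <- sprintf("t%d", seq_len(n_leaves))
  counter <- 0L
  fresh <- function() {
    counter <<- counter + 1L
    sprintf("i%d", counter)
  }
  verts <- c("L1", "L2")
  labels <- c(L1 = "t1", L2 = "t2")
  edges <- list(c("L1", "L2"))
  subdivide <- function(k) {
    # replace edge k by two edges through a fresh vertex; returns its id
    e <- edges[[k]]
    v <- fresh()
    verts <<- c(verts, v)
    edges[[k]] <<- c(e[1], v)
    edges[[length(edges) + 1]] <<- c(v, e[2])
    v
  }
  if (n_leaves >= 3) {
    for (li in 3:n_leaves) {
      v <- subdivide(sample.int(length(edges), 1))
      leaf <- sprintf("L%d", li)
      verts <- c(verts, leaf)
      labels[leaf] <- sprintf("t%d", li)
      edges[[length(edges) + 1]] <- c(v, leaf)
    }
  }
  for (k in seq_len(extra_edges)) {
    if (length(edges) < 2) return(NULL)
    picks <- sample.int(length(edges), 2)
    a <- subdivide(picks[1])
    b <- subdivide(picks[2])
    edges[[length(edges) + 1]] <- c(a, b)
  }
  em <- do.call(rbind, edges)
  if (anyDuplicated(edge_key(em[, 1], em[, 2]))) return(NULL)
  lmg(verts, labels = labels, edges = em)
}
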