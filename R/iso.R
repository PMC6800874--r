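#' Verify a proposed isomorphism witness
#'
#' A witness is a named character vector `f` mapping every vertex of `g` to
#' a vertex of `h`.  It is a valid isomorphism iff it is a bijection
#' V(g) -> V(h), label-preserving (a vertex has taxon label `l` iff its image
#' does) and edge-preserving (the number of edges, counted with multiplicity
#' and including loops, between `a` and `b` equals that between `f(a)` and
#' `f(b)`).  Malformed witnesses return `FALSE` rather than erroring, so a
#' witness can be checked independently of how it was produced.
#'
#' @param g,h `lmg` graphs.
#' @param f named character vector: names are vertices of `g`, values
#'   vertices of `h`.
#' @return `TRUE` or `FALSE`.
#' @export
verify_isomorphism <- function(g, h, f) {
  if (is.null(f)) return(FALSE)
  if (length(f) != length(g$vertices)) return(FALSE)
  if (is.null(names(f))) return(FALSE)
  if (!setequal(names(f), g$vertices)) return(FALSE)
  if (anyDuplicated(f)) return(FALSE)
  if (!setequal(unname(f), h$vertices)) return(FALSE)
  # label preservation, both directions
  gl <- g$labels
  hl <- h$labels
  if (!setequal(unname(gl), unname(hl))) return(FALSE)
  mapped_lab <- stats::setNames(unname(gl), unname(f[names(gl)]))
  if (length(mapped_lab) != length(hl)) return(FALSE)
  if (!identical(mapped_lab[sort(names(mapped_lab))],
                 hl[sort(names(hl))])) return(FALSE)
  # edge multiplicity preservation: map g's edge table and compare
  if (sum(g$edges) != sum(h$edges)) return(FALSE)
  if (length(g$edges)) {
    ep <- edge_endpoints(names(g$edges))
    keys <- edge_key(unname(f[ep[, 1]]), unname(f[ep[, 2]]))
    mapped <- stats::setNames(unname(g$edges), keys)
    if (length(mapped) != length(h$edges)) return(FALSE)
    if (!setequal(names(mapped), names(h$edges))) return(FALSE)
    if (!identical(mapped[sort(names(mapped))],
                   h$edges[sort(names(h$edges))])) return(FALSE)
  } else if (length(h$edges)) {
    return(FALSE)
  }
  TRUE
}

# isomorphism-invariant vertex signature: label, degree, loop multiplicity,
# sorted multiset of incident multiplicities, distance profile to labelled
# vertices (sorted by taxon name)
vertex_signatures <- function(g) {
  deg <- all_degrees(g)
  adj <- adjacency_of(g)
  taxa <- sort(unname(g$labels))
  prof <- if (length(taxa)) all_profiles(g, taxa) else
    matrix(0, nrow = length(g$vertices), ncol = 0,
           dimnames = list(g$vertices, NULL))
  lab <- stats::setNames(rep("", length(g$vertices)), g$vertices)
  lab[names(g$labels)] <- unname(g$labels)
  vapply(g$vertices, function(v) {
    nb <- adj[[v]]
    loop <- if (v %in% names(nb)) nb[[v]] else 0L
    paste(lab[[v]], deg[[v]], loop,
          paste(sort(unname(nb)), collapse = ","),
          paste(prof[v, ], collapse = ","),
          sep = "|")
  }, "")
}

# refine signature classes by multisets of neighbour classes until stable
refine_classes <- function(g, sig) {
  adj <- adjacency_of(g)
  repeat {
    cls <- match(sig, sort(unique(sig)))
    names(cls) <- names(sig)
    new_sig <- vapply(g$vertices, function(v) {
      nb <- adj[[v]]
      nbsig <- sort(paste(cls[names(nb)], unname(nb), sep = "x"))
      paste(sig[[v]], paste(nbsig, collapse = ";"), sep = "#")
    }, "")
    if (length(unique(new_sig)) == length(unique(sig))) return(sig)
    sig <- new_sig
  }
}

#' Search for an isomorphism between two multigraphs
#'
#' Exact search: returns a witness passing [verify_isomorphism()] iff one
#' exists, otherwise `NULL` (no false negatives).  The default method is
#' backtracking over vertices, pruned by equivalence classes built from
#' label, degree, loop/parallel structure and distance profiles to labelled
#' leaves (iteratively refined by neighbour classes); candidate classes are
#' explored smallest first.  The `"bruteforce"` method enumerates all
#' label-respecting bijections and is intended as an independent oracle on
#' small graphs.
#'
#' @param g,h `lmg` graphs.
#' @param method `"backtracking"` (default) or `"bruteforce"`.
#' @return A witness (named character vector) or `NULL`.
#' @export
find_isomorphism <- function(g, h, method = c("backtracking", "bruteforce")) {
  method <- match.arg(method)
  if (length(g$vertices) != length(h$vertices)) return(NULL)
  if (sum(g$edges) != sum(h$edges)) return(NULL)
  if (!setequal(unname(g$labels), unname(h$labels))) return(NULL)
  if (method == "bruteforce") return(iso_bruteforce(g, h))
  iso_backtrack(g, h)
}

iso_backtrack <- function(g, h) {
  sg <- refine_classes(g, vertex_signatures(g))
  sh <- refine_classes(h, vertex_signatures(h))
  # class multisets must agree
  tg <- table(sg); th <- table(sh)
  if (length(tg) != length(th)) return(NULL)
  if (!setequal(names(tg), names(th))) return(NULL)
  if (!identical(as.integer(tg[sort(names(tg))]),
                 as.integer(th[sort(names(th))]))) return(NULL)

  adj_g <- adjacency_of(g)
  adj_h <- adjacency_of(h)
  # order g's vertices: smallest class first, then prefer vertices adjacent
  # to already-ordered ones (simple connectivity-aware ordering)
  cls_size <- as.integer(tg[sg])
  ord <- g$vertices[order(cls_size, sg, g$vertices)]
  n <- length(ord)
  f <- stats::setNames(rep(NA_character_, n), ord)
  used <- stats::setNames(rep(FALSE, length(h$vertices)), h$vertices)

  consistent <- function(v, w) {
    # loop multiplicity
    lv <- if (v %in% names(adj_g[[v]])) adj_g[[v]][[v]] else 0L
    lw <- if (w %in% names(adj_h[[w]])) adj_h[[w]][[w]] else 0L
    if (lv != lw) return(FALSE)
    # edges to already-assigned vertices must match in multiplicity
    nbv <- adj_g[[v]]
    for (u in names(nbv)) {
      if (u == v) next
      fu <- f[[u]]
      if (!is.na(fu) && (!fu %in% names(adj_h[[w]]) ||
                         adj_h[[w]][[fu]] != nbv[[u]])) return(FALSE)
    }
    # reverse direction: assigned neighbours of w must be images of
    # neighbours of v with same multiplicity
    nbw <- adj_h[[w]]
    assigned_imgs <- f[!is.na(f)]
    inv <- stats::setNames(names(assigned_imgs), unname(assigned_imgs))
    for (u2 in names(nbw)) {
      if (u2 == w) next
      if (u2 %in% names(inv)) {
        pre <- inv[[u2]]
        if (!pre %in% names(nbv) || nbv[[pre]] != nbw[[u2]]) return(FALSE)
      }
    }
    TRUE
  }

  recurse <- function(k) {
    if (k > n) return(TRUE)
    v <- ord[k]
    cands <- h$vertices[sh == sg[[v]] & !used[h$vertices]]
    for (w in cands) {
      if (consistent(v, w)) {
        f[[v]] <<- w
        used[[w]] <<- TRUE
        if (recurse(k + 1)) return(TRUE)
        f[[v]] <<- NA_character_
        used[[w]] <<- FALSE
      }
    }
    FALSE
  }

  if (!recurse(1)) return(NULL)
  f[g$vertices]
}

# independent oracle: enumerate every label-respecting bijection
iso_bruteforce <- function(g, h) {
  gl_lab <- names(g$labels)
  hl_lab <- names(h$labels)
  # labelled vertices are forced: same taxon -> same image
  forced <- stats::setNames(
    vapply(unname(g$labels), function(tx) vertex_of_taxon(h, tx), ""),
    gl_lab)
  gu <- setdiff(g$vertices, gl_lab)
  hu <- setdiff(h$vertices, hl_lab)
  if (length(gu) != length(hu)) return(NULL)
  perms <- permutations_of(length(hu))
  for (p in perms) {
    f <- c(forced, stats::setNames(hu[p], gu))
    f <- f[g$vertices]
    if (verify_isomorphism(g, h, f)) return(f)
  }
  NULL
}

permutations_of <- function(n) {
  if (n == 0) return(list(integer()))
  if (n == 1) return(list(1L))
  out <- list()
  for (i in seq_len(n)) {
    rest <- permutations_of(n - 1)
    for (p in rest) {
      q <- integer(n)
      q[1] <- i
      q[-1] <- setdiff(seq_len(n), i)[p]
      out[[length(out) + 1]] <- q
    }
  }
  out
}
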