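# fixtures built in code; all randomness goes through explicit seeds

# random labelled multigraph: n vertices, ~1.3n edge draws (loops and
# parallel edges allowed), a few labelled vertices
random_lmg <- function(n, seed, n_labels = min(2L, n), multi = TRUE) {
  set.seed(seed)
  verts <- sprintf("v%d", seq_len(n))
  m <- max(1L, round(1.3 * n))
  a <- sample(verts, m, replace = TRUE)
  b <- sample(verts, m, replace = TRUE)
  if (!multi) {
    keep <- a != b & !duplicated(edge_key_t(a, b))
    a <- a[keep]; b <- b[keep]
  }
  labs <- character()
  if (n_labels > 0) {
    picked <- sample(verts, n_labels)
    labs <- stats::setNames(sprintf("x%d", seq_len(n_labels)), picked)
  }
  lmg(verts, labels = labs, edges = cbind(a, b))
}

edge_key_t <- function(a, b) ifelse(a <= b, paste(a, b), paste(b, a))

# structural equality of two lmg graphs (same ids, labels, multiplicities)
expect_same_graph <- function(g, h) {
  expect_setequal(g$vertices, h$vertices)
  expect_identical(g$labels[sort(names(g$labels))],
                   h$labels[sort(names(h$labels))])
  expect_identical(g$edges[sort(names(g$edges))],
                   h$edges[sort(names(h$edges))])
}

# star: centre c with labelled leaves
star_graph <- function(taxa = c("x", "y", "z")) {
  leaves <- sprintf("l%d", seq_along(taxa))
  lmg(c("c", leaves), labels = stats::setNames(taxa, leaves),
      edges = cbind("c", leaves))
}

# quartet tree ab|cd: two internal vertices, leaves a,b,c,d
quartet_tree <- function() {
  lmg(c("p", "q", "la", "lb", "lc", "ld"),
      labels = c(la = "a", lb = "b", lc = "c", ld = "d"),
      edges = rbind(c("p", "q"), c("p", "la"), c("p", "lb"),
                    c("q", "lc"), c("q", "ld")))
}

# two K4 blobs joined by a bridge, two labelled leaves on each side
two_blob_network <- function() {
  k4 <- function(vs) t(combn(vs, 2))
  lmg(c("a", "b", "c", "d", "e", "f", "g", "h", "l1", "l2", "l3", "l4"),
      labels = c(l1 = "x1", l2 = "x2", l3 = "x3", l4 = "x4"),
      edges = rbind(k4(c("a", "b", "c", "d")), k4(c("e", "f", "g", "h")),
                    c("c", "g"),
                    c("a", "l1"), c("b", "l2"), c("e", "l3"), c("f", "l4")))
}

# induced subgraph on a vertex set (keeps labels and multiplicities)
induced_sub <- function(g, vs) {
  keep_edges <- NULL
  if (length(g$edges)) {
    ep <- leafdeck:::edge_endpoints(names(g$edges))
    inside <- ep[, 1] %in% vs & ep[, 2] %in% vs
    if (any(inside)) {
      ep2 <- ep[inside, , drop = FALSE]
      keep_edges <- ep2[rep(seq_len(nrow(ep2)), unname(g$edges[inside])), ,
                        drop = FALSE]
    }
  }
  lmg(intersect(g$vertices, vs),
      labels = g$labels[names(g$labels) %in% vs],
      edges = keep_edges)
}

# rename vertices of g by a random bijection (labels follow their vertices)
shuffled_copy <- function(g, seed) {
  set.seed(seed)
  new_ids <- stats::setNames(sprintf("s%d", sample(length(g$vertices))),
                             g$vertices)
  em <- NULL
  if (length(g$edges)) {
    ep <- leafdeck:::edge_endpoints(names(g$edges))
    em <- cbind(unname(new_ids[ep[, 1]]), unname(new_ids[ep[, 2]]))
    em <- em[rep(seq_len(nrow(em)), unname(g$edges)), , drop = FALSE]
  }
  lmg(unname(new_ids), labels = stats::setNames(unname(g$labels),
                                                unname(new_ids[names(g$labels)])),
      edges = em)
}
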