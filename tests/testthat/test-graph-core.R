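test_that("multigraph construction validates vertices, labels and endpoints", {
  expect_error(lmg(c("a", "a")), "duplicate vertex")
  expect_error(lmg(c("a", "b"), labels = c(a = "x", b = "x")), "injective")
  expect_error(lmg(c("a", "b"), labels = c(q = "x")), "not in vertex set")
  expect_error(lmg(c("a", "b"), edges = rbind(c("a", "c"))), "not in vertex set")
  g <- lmg(c("a", "b"), edges = rbind(c("a", "b"), c("a", "b"), c("a", "a")))
  expect_equal(n_edges(g), 3)
  expect_equal(n_vertices(g), 2)
})

test_that("degree counts edge-endpoints, with loops contributing 2", {
  g <- lmg(c("a", "b", "c"), edges = rbind(c("a", "b"), c("b", "b")))
  expect_equal(degree_of(g, "c"), 0)       # isolated
  expect_equal(degree_of(g, "a"), 1)
  expect_equal(degree_of(g, "b"), 3)       # one edge + one loop
  expect_equal(degree_of(lmg("v", edges = rbind(c("v", "v"))), "v"), 2)
  expect_error(degree_of(g, "zz"), "unknown vertex")
  # the position-1 hub of the even parity graph: leaf x1 plus the even
  # sequences with first element 0
  m <- build_M(4, "even")
  n_w10 <- length(restrict_seqs(parity_sequences(4, "even"), 1, 0))
  expect_equal(degree_of(m$graph, "v:1:0"), n_w10 + 1)
  expect_equal(degree_of(m$graph, "v:1:0"), 5)
})

test_that("vertex deletion drops the vertex, its label and incident edges", {
  g <- lmg(c("a", "b"), labels = c(a = "x"), edges = rbind(c("a", "b")))
  g2 <- delete_vertex(g, "a")
  expect_equal(g2$vertices, "b")
  expect_equal(n_edges(g2), 0)
  expect_length(g2$labels, 0)
  expect_error(delete_vertex(g, "zz"), "unknown vertex")
  # loops disappear with their vertex
  gl <- lmg(c("a", "b"), edges = rbind(c("a", "a"), c("a", "b")))
  expect_equal(n_edges(delete_vertex(gl, "a")), 0)
  # deleting a leaf of the parity graph removes one vertex and one edge
  m <- build_M(4, "even")
  md <- delete_vertex(m$graph, "x:1")
  expect_equal(n_vertices(md), 19)
  expect_equal(n_edges(md), 35)
})

test_that("suppression splices out unlabelled degree-2 vertices", {
  # path x-a-y with a unlabelled -> single edge x-y
  p <- lmg(c("x", "a", "y"), labels = c(x = "tx", y = "ty"),
           edges = rbind(c("x", "a"), c("a", "y")))
  s <- suppress_degree2(p)
  expect_setequal(s$vertices, c("x", "y"))
  expect_equal(unname(s$edges[leafdeck:::edge_key("x", "y")]), 1L)
  # fixpoint on a graph with nothing to suppress
  q <- quartet_tree()
  expect_same_graph(suppress_degree2(q), q)
  # 4-cycle with two opposite labelled vertices -> parallel pair
  c4 <- lmg(c("x", "a", "y", "b"), labels = c(x = "tx", y = "ty"),
            edges = rbind(c("x", "a"), c("a", "y"), c("y", "b"), c("b", "x")))
  s4 <- suppress_degree2(c4)
  expect_setequal(s4$vertices, c("x", "y"))
  expect_equal(unname(s4$edges[leafdeck:::edge_key("x", "y")]), 2L)
  # labelled degree-2 vertices stay
  lab2 <- lmg(c("x", "m", "y"), labels = c(m = "tm"),
              edges = rbind(c("x", "m"), c("m", "y")))
  expect_setequal(suppress_degree2(lab2)$vertices, c("x", "m", "y"))
  # a vertex whose only incidence is a loop stays
  lv <- lmg("v", edges = rbind(c("v", "v")))
  expect_same_graph(suppress_degree2(lv), lv)
  # an unlabelled pure cycle collapses to a single vertex with a loop
  cyc <- lmg(c("a", "b", "c"),
             edges = rbind(c("a", "b"), c("b", "c"), c("c", "a")))
  sc <- suppress_degree2(cyc)
  expect_equal(n_vertices(sc), 1)
  expect_equal(n_edges(sc), 1)
  ep <- leafdeck:::edge_endpoints(names(sc$edges))
  expect_true(ep[1, 1] == ep[1, 2])
})

test_that("suppression is confluent and preserves |E| - |V|", {
  for (seed in 1:25) {
    g <- random_lmg(sample(4:10, 1), seed = seed)
    base <- suppress_degree2(g)
    expect_equal(n_edges(base) - n_vertices(base), n_edges(g) - n_vertices(g))
    for (k in 1:4) {
      set.seed(seed * 100 + k)
      alt <- suppress_degree2(g, order = sample(g$vertices))
      expect_equal(n_vertices(alt), n_vertices(base))
      expect_equal(n_edges(alt), n_edges(base))
      # identical up to vertex identity of survivors
      expect_false(is.null(find_isomorphism(base, alt)))
    }
  }
})

test_that("leaf removal deletes then suppresses", {
  s <- remove_leaf(star_graph(), "x")
  expect_equal(n_vertices(s), 2)    # centre suppressed, edge y-z remains
  expect_equal(n_edges(s), 1)
  expect_setequal(unname(s$labels), c("y", "z"))
  expect_error(remove_leaf(star_graph(), "nope"), "no vertex labelled")
  # parity graphs never need suppression after leaf deletion
  m <- build_M(4, "even")
  expect_same_graph(remove_leaf(m$graph, "x1"), delete_vertex(m$graph, "x:1"))
  # binary networks lose one vertex to deletion and one to suppression
  n <- build_N(4, "even")
  nx <- remove_leaf(n$graph, "x1")
  expect_equal(n_vertices(nx), 38)
  expect_equal(n_edges(nx), 54)
  expect_false("v:1:0" %in% nx$vertices)
})

test_that("distances are unit-weight shortest paths, Inf across components", {
  g <- lmg(c("a", "b", "c"), edges = rbind(c("a", "b")))
  expect_equal(graph_distance(g, "a", "a"), 0)
  expect_equal(graph_distance(g, "a", "b"), 1)
  expect_equal(graph_distance(g, "a", "c"), Inf)
  expect_error(graph_distance(g, "a", "zz"), "unknown vertex")
  m <- build_M(4, "even")
  expect_equal(graph_distance(m$graph, "u:0000", "x:1"), 2)
  n <- build_N(4, "even")
  expect_equal(graph_distance(n$graph, "u:0000", "x:3"), 4)
})

test_that("distance profiles report leaf distances in taxon order", {
  n <- build_N(4, "even")
  expect_equal(unname(distance_profile(n$graph, "u:0000", n$taxa)),
               c(3, 3, 4, 4))
  m <- build_M(4, "even")
  expect_equal(unname(distance_profile(m$graph, "u:0000", m$taxa)),
               rep(2, 4))
  prof <- distance_profile(m$graph, "x:1", m$taxa)
  expect_equal(unname(prof[1]), 0)
})
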