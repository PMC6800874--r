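test_that("caterpillars have the prescribed spine and leaves", {
  c5 <- build_caterpillar("00000")
  expect_equal(n_vertices(c5$graph), 8)    # u, y1, y2, z1..z5
  expect_equal(n_edges(c5$graph), 7)
  c4 <- build_caterpillar("0000")
  expected <- rbind(c("u:0000", "z:0000:1"), c("u:0000", "z:0000:2"),
                    c("u:0000", "y:0000:1"), c("y:0000:1", "z:0000:3"),
                    c("y:0000:1", "z:0000:4"))
  expect_same_graph(c4$graph,
                    lmg(c("u:0000", "y:0000:1", sprintf("z:0000:%d", 1:4)),
                        edges = expected))
  for (w in c("0000", "10110", "110101")) {
    ct <- build_caterpillar(w)
    deg <- leafdeck:::all_degrees(ct$graph)
    internal <- setdiff(ct$graph$vertices, ct$z_leaves)
    expect_true(all(deg[internal] == 3))
    expect_true(all(deg[ct$z_leaves] == 1))
  }
  expect_error(build_caterpillar("000"), ">= 4")
})

test_that("lexicographic trees are balanced with DFS-lex leaf order", {
  S <- restrict_seqs(parity_sequences(4, "even"), 2, 0)
  lt <- build_lex_tree(2, S)
  expect_equal(n_vertices(lt$graph), 7)
  expect_equal(n_edges(lt$graph), 6)
  expect_equal(degree_of(lt$graph, lt$root), 2)
  expect_equal(lt$depth, 2)
  expect_equal(lt$leaves,
               sprintf("z:%s:2", c("0000", "0011", "1001", "1010")))
  # all leaves at depth exactly t; leaf order is lexicographic in w
  for (r in 4:5) {
    for (i in seq_len(r)) {
      S2 <- restrict_seqs(parity_sequences(r, "odd"), i, 1)
      lt2 <- build_lex_tree(i, S2)
      d <- vapply(lt2$leaves, function(z)
        graph_distance(lt2$graph, lt2$root, z), 0)
      expect_true(all(d == lt2$depth))
      expect_equal(lt2$S, sort(lt2$S))
      # one DFS (low half first) traverses leaves in lex order by design;
      # equivalently consecutive leaves share deeper ancestors than distant
      deg <- leafdeck:::all_degrees(lt2$graph)
      expect_true(all(deg[setdiff(lt2$graph$vertices,
                                  c(lt2$root, lt2$leaves))] == 3))
    }
  }
  two <- build_lex_tree(1, c("01", "10"))
  expect_equal(n_vertices(two$graph), 3)
  expect_error(build_lex_tree(1, c("001", "010", "100")), "power of two")
})

test_that("pre-suppression graph G matches the construction tally", {
  g <- build_G(4, "even")
  expect_equal(n_vertices(g$graph), 76)
  expect_equal(n_edges(g$graph), 92)
  deg <- leafdeck:::all_degrees(g$graph)
  # shared z vertices and the 1-side roots have degree 2
  zs <- grep("^z:", g$graph$vertices, value = TRUE)
  expect_length(zs, 32)
  expect_true(all(deg[zs] == 2))
  v1 <- sprintf("v:%d:1", 1:4)
  expect_true(all(deg[v1] == 2))
  xs <- sprintf("x:%d", 1:4)
  expect_true(all(deg[xs] == 1))
  others <- setdiff(g$graph$vertices, c(zs, v1, xs))
  expect_true(all(deg[others] == 3))
})

test_that("the four-caterpillar cycle ties the hub trees into one blob", {
  g <- build_G(4, "even")$graph
  quad <- c("0000", "0101", "1100", "1001")
  keep <- character()
  for (w in quad) keep <- c(keep, build_caterpillar(w)$graph$vertices)
  for (ih in list(c(1, 0), c(2, 1), c(1, 1), c(2, 0))) {
    S <- restrict_seqs(parity_sequences(4, "even"), ih[1], ih[2])
    keep <- c(keep, build_lex_tree(ih[1], S,
                                   root_id = sprintf("v:%d:%d", ih[1], ih[2]),
                                   prefix = sprintf("lex:%d:%d", ih[1], ih[2])
                                   )$graph$vertices)
  }
  sub <- induced_sub(g, unique(keep))
  bl <- blobs_of(sub)
  us <- paste0("u:", quad)
  hit <- vapply(bl, function(vs) all(us %in% vs), TRUE)
  expect_equal(sum(hit), 1)
})

test_that("suppression of G removes exactly the z and 1-side hub vertices", {
  for (r in 4:5) {
    for (p in c("even", "odd")) {
      g <- build_G(r, p)
      n <- build_N(r, p)
      gone <- setdiff(g$graph$vertices, n$graph$vertices)
      expected <- c(grep("^z:", g$graph$vertices, value = TRUE),
                    sprintf("v:%d:1", seq_len(r)))
      expect_setequal(gone, expected)
      expect_length(gone, r * 2^(r - 1) + r)
    }
  }
})

test_that("suppressed networks are valid binary single-blob networks", {
  for (r in 4:6) {
    ne <- build_N(r, "even")
    no <- build_N(r, "odd")
    expect_true(is_binary(ne))
    expect_true(isTRUE(is_phylo_network(ne$graph, ne$taxa)))
    # even and odd are count-identical; the printed excess formula holds
    expect_equal(n_vertices(ne$graph), n_vertices(no$graph))
    expect_equal(n_edges(ne$graph), n_edges(no$graph))
    excess <- n_edges(ne$graph) - n_vertices(ne$graph)
    expect_equal(excess, 2^(r - 1) * (r - 1) - 2 * r)
    bl <- blobs_of(ne$graph)
    expect_length(bl, 1)
    expect_setequal(bl[[1]],
                    setdiff(ne$graph$vertices, sprintf("x:%d", seq_len(r))))
  }
  n4 <- build_N(4, "even")
  expect_equal(n_vertices(n4$graph), 40)
  expect_equal(n_edges(n4$graph), 56)
  # all-0 spine vertex survives under its original name
  expect_true("u:0000" %in% n4$graph$vertices)
})

test_that("spine-to-leaf distances drop by one under suppression", {
  g <- build_G(4, "even")$graph
  n <- build_N(4, "even")$graph
  expect_equal(graph_distance(g, "u:0000", "x:1"), 4)   # 1 + (r-2) + 1
  expect_equal(graph_distance(n, "u:0000", "x:1"), 3)
  expect_equal(unname(distance_profile(n, "u:0000", sprintf("x%d", 1:4))),
               c(3, 3, 4, 4))
})

test_that("caterpillar witnesses preserve roles", {
  f <- caterpillar_isomorphism("0000", "1001")
  a <- build_caterpillar("0000")$graph
  b <- build_caterpillar("1001")$graph
  expect_true(verify_isomorphism(a, b, f))
  expect_equal(unname(f[sprintf("z:0000:%d", 1:4)]), sprintf("z:1001:%d", 1:4))
  ident <- caterpillar_isomorphism("0101", "0101")
  expect_true(all(names(ident) == unname(ident)))
  f5 <- caterpillar_isomorphism("00000", "11011")
  expect_true(verify_isomorphism(build_caterpillar("00000")$graph,
                                 build_caterpillar("11011")$graph, f5))
  expect_error(caterpillar_isomorphism("0000", "00000"), "equal length")
})

test_that("lexicographic-tree witnesses map roots to roots and verify", {
  mk <- function(r, j, h, parity) {
    S <- restrict_seqs(parity_sequences(r, parity), j, h)
    build_lex_tree(j, S, root_id = sprintf("v:%d:%d", j, h),
                   prefix = sprintf("lex:%d:%d", j, h))$graph
  }
  # distinct position: even (j,h) onto odd (j,h)
  f <- lex_isomorphism(4, 2, 0, i = 1)
  expect_true(verify_isomorphism(mk(4, 2, 0, "even"), mk(4, 2, 0, "odd"), f))
  expect_equal(unname(f["v:2:0"]), "v:2:0")
  # removed position: even (i,h) onto odd (i,1-h)
  f2 <- lex_isomorphism(4, 1, 0, i = 1)
  expect_true(verify_isomorphism(mk(4, 1, 0, "even"), mk(4, 1, 1, "odd"), f2))
  expect_equal(unname(f2["v:1:0"]), "v:1:1")
  # leaves flip position i
  expect_equal(unname(f2["z:0000:1"]), "z:1000:1")
  # a larger case
  f3 <- lex_isomorphism(5, 4, 1, i = 2)
  expect_true(verify_isomorphism(mk(5, 4, 1, "even"), mk(5, 4, 1, "odd"), f3))
})

test_that("glued witnesses identify the leaf-deleted G graphs", {
  for (r in 4:5) {
    ge <- build_G(r, "even")$graph
    go <- build_G(r, "odd")$graph
    is_set <- if (r == 4) 1:4 else 1
    for (i in is_set) {
      a <- delete_vertex(ge, sprintf("x:%d", i))
      b <- delete_vertex(go, sprintf("x:%d", i))
      f <- deck_isomorphism_G(r, i)
      expect_true(verify_isomorphism(a, b, f))
      expect_equal(unname(f[sprintf("v:%d:0", i)]), sprintf("v:%d:1", i))
    }
  }
})

test_that("restricted witnesses identify the network deck members", {
  for (r in 4:5) {
    ne <- build_N(r, "even")$graph
    no <- build_N(r, "odd")$graph
    is_set <- if (r == 4) 1:4 else 3
    for (i in is_set) {
      a <- remove_leaf(ne, sprintf("x%d", i))
      b <- remove_leaf(no, sprintf("x%d", i))
      f <- deck_isomorphism_N(r, i)
      expect_true(verify_isomorphism(a, b, f))
      # surviving vertices map to surviving vertices
      expect_true(all(names(f) %in% a$vertices))
      expect_true(all(unname(f) %in% b$vertices))
    }
  }
})

test_that("the all-0 profile certificate separates the binary networks", {
  cert <- nonequivalence_certificate_N(4)
  expect_equal(unname(cert$profile), c(3, 3, 4, 4))
  expect_equal(cert$matches_in_other, 0)
  expect_true(cert$valid)
  expect_true(nonequivalence_certificate_N(5)$valid)
  expect_null(find_isomorphism(build_N(4, "even")$graph,
                               build_N(4, "odd")$graph))
})
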