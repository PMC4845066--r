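test_that("modularity matches the direct double-sum evaluation", {
  g <- two_triangle_bridge()
  expect_equal(modularity_q(g, setNames(rep(1, 6), igraph::V(g)$name)), 0)
  part <- setNames(c(1, 1, 1, 2, 2, 2), c("a1", "a2", "a3", "b1", "b2", "b3"))
  expect_equal(modularity_q(g, part), 5 / 14)
  a <- adjacency_of(g)
  expect_equal(modularity_q(g, part),
               oracle_modularity(a, part[igraph::V(g)$name]))
  # any 2+2 bipartition of K4 has negative modularity
  k4 <- igraph::make_full_graph(4)
  expect_lt(modularity_q(k4, c(1, 1, 2, 2)), 0)
  expect_equal(modularity_q(k4, c(1, 1, 2, 2)),
               oracle_modularity(adjacency_of(k4), c(1, 1, 2, 2)))
  expect_error(modularity_q(igraph::make_empty_graph(3), c(1, 1, 1)),
               "undefined")
})

test_that("leading-eigenvector split finds planted bisections and refuses K4", {
  k4 <- igraph::make_full_graph(4)
  expect_true(leading_eigen_split(k4)$indivisible)

  g <- two_triangle_bridge()
  sp <- leading_eigen_split(g)
  expect_false(sp$indivisible)
  expect_equal(length(unique(sp$membership)), 2)
  expect_equal(length(unique(sp$membership[c("a1", "a2", "a3")])), 1)
  expect_equal(length(unique(sp$membership[c("b1", "b2", "b3")])), 1)
  expect_equal(sp$q, modularity_q(g, sp$membership))
  expect_equal(sp$q, 5 / 14)

  cl <- igraph::make_full_graph(8) + igraph::make_full_graph(8)
  cl <- igraph::add_edges(cl, c(1, 9))
  igraph::V(cl)$name <- paste0("n", 1:16)
  sp2 <- leading_eigen_split(cl)
  expect_equal(length(unique(sp2$membership)), 2)
  expect_equal(length(unique(sp2$membership[paste0("n", 1:8)])), 1)
  a <- adjacency_of(cl)
  expect_equal(sp2$q, oracle_best_bipartition_q(a), tolerance = 1e-12)
  expect_error(leading_eigen_split(igraph::make_empty_graph(2)), "no edges")
})

test_that("split modularity is near the exhaustive bipartition optimum", {
  set.seed(31)
  done <- 0
  while (done < 25) {
    rg <- random_graph(sample(5:9, 1), runif(1, 0.25, 0.7))
    if (igraph::components(rg$g)$no != 1 || igraph::ecount(rg$g) == 0) next
    done <- done + 1
    sp <- leading_eigen_split(rg$g)
    expect_gte(sp$q, oracle_best_bipartition_q(rg$a) - 0.02)
    expect_gte(sp$q, 0)
  }
})

test_that("split agrees with igraph's leading-eigenvector implementation", {
  set.seed(77)
  for (rep in 1:5) {
    rg <- random_graph(20, 0.25)
    if (igraph::components(rg$g)$no != 1) next
    sp <- leading_eigen_split(rg$g)
    qi <- tryCatch(
      igraph::modularity(igraph::cluster_leading_eigen(rg$g)),
      error = function(e) NA_real_)
    if (!is.na(qi)) expect_gte(sp$q, qi - 0.05)
  }
})

test_that("decomposition terminates at motifs and conserves nodes", {
  tri <- igraph::make_full_graph(3)
  tr <- decompose_graph(tri)
  expect_equal(nrow(tr), 1)
  expect_true(tr$terminal[[1]])
  expect_equal(tree_depth(tr), 0)

  g <- two_triangle_bridge()
  tr2 <- decompose_graph(g)
  expect_equal(tree_depth(tr2), 1)
  lvl1 <- tr2[tr2$level == 1, ]
  expect_equal(nrow(lvl1), 2)
  expect_true(all(lvl1$terminal))
  expect_true(all(lvl1$n_nodes == 3 & lvl1$n_edges == 3))

  # node conservation at every level: modules at L plus terminals above L
  set.seed(41)
  sb <- nested_sbm(2, 2, 12, c(0.9, 0.15, 0.02))
  tr3 <- decompose_graph(sb$graph)
  root_nodes <- sort(igraph::V(sb$graph)$name)
  for (L in seq_len(tree_depth(tr3))) {
    at_l <- unlist(tr3$nodes[tr3$level == L])
    froz <- unlist(tr3$nodes[tr3$level < L & tr3$terminal])
    expect_setequal(c(at_l, froz), root_nodes)
    expect_equal(anyDuplicated(c(at_l, froz)), 0)
  }
})

test_that("modules_at_level returns induced subgraphs in stable order", {
  g <- two_triangle_bridge()
  tr <- decompose_graph(g)
  mods <- modules_at_level(tr, 1)
  expect_length(mods, 2)
  expect_equal(vapply(mods, igraph::vcount, numeric(1)),
               setNames(c(3, 3), names(mods)))
  # deterministic order by smallest member label
  expect_equal(sort(igraph::V(mods[[1]])$name)[1], "a1")
  expect_error(modules_at_level(tr, 5), "out of range")
  expect_error(modules_at_level(tr, 0), "out of range")
})

test_that("planted nested-SBM blocks are recovered by the decomposition", {
  # The modularity-optimal leading-eigenvector partition resolves the
  # finest planted tier; compare the level-1 membership to the leaf blocks.
  set.seed(19)
  hits <- 0
  for (s in 1:5) {
    sb <- nested_sbm(2, 2, 16, c(0.9, 0.15, 0.02))
    tr <- decompose_graph(sb$graph)
    td <- tidy(tr)
    leaf <- sb$membership[[length(sb$membership)]][td$node]
    ari <- mclust::adjustedRandIndex(td$level_1, leaf)
    if (ari >= 0.9) hits <- hits + 1
  }
  expect_gte(hits, 4)
})

test_that("module tree tidiers report structure", {
  tr <- decompose_graph(two_triangle_bridge())
  td <- tidy(tr)
  expect_equal(nrow(td), 6)
  expect_equal(length(unique(td$level_1)), 2)
  gl <- glance(tr)
  expect_equal(gl$n_triangle_motifs, 2)
  expect_equal(gl$depth, 1)
})
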