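two_k3_bridge <- function() {
  net_from(c("A", "A", "B", "D", "D", "E", "C"),
           c("B", "C", "C", "E", "F", "F", "D"))
}

test_that("modularity matches closed-form values", {
  tri2 <- net_from(c("A", "B", "A", "D", "E", "D"),
                   c("B", "C", "C", "E", "F", "F"))
  expect_equal(modularity_q(tri2, c(A = 1, B = 1, C = 1, D = 2, E = 2, F = 2)),
               0.5)
  expect_equal(modularity_q(tri2, rep(1, 6)), 0)  # single module
  set.seed(61)
  net <- random_connected_net(10, 18)
  expect_equal(modularity_q(net, rep(1, 10)), 0)
  expect_error(modularity_q(net, c(A = 1)), "cover")
})

test_that("modularity agrees with an independent implementation", {
  skip_if_not_installed("igraph")
  set.seed(67)
  for (rep in 1:8) {
    net <- random_connected_net(10, 16)
    memb <- sample(3, 10, replace = TRUE)
    names(memb) <- net$nodes
    g <- as_igraph(net)
    ref <- igraph::modularity(g, memb[igraph::V(g)$name])
    expect_equal(modularity_q(net, memb), ref, tolerance = 1e-12)
  }
})

test_that("exhaustively enumerated 6-node partitions bound the greedy result", {
  ## the enumeration oracle (Bell(6) = 203 partitions) gives the global max;
  ## greedy can never exceed it, and attains it on modular graphs
  expect_length(enumerate_partitions(6), 203L)
  net <- two_k3_bridge()
  best <- oracle_max_q(net)
  part <- greedy_modules(net)
  expect_equal(part$Q, best, tolerance = 1e-12)
  expect_equal(part$n_modules, 2L)
  set.seed(71)
  for (rep in 1:6) {
    rnet <- random_connected_net(6, sample(6:10, 1))
    expect_lte(greedy_modules(rnet)$Q, oracle_max_q(rnet) + 1e-12)
  }
})

test_that("greedy clustering separates cliques and keeps K5 whole", {
  ## two K4s joined by one bridge edge -> exactly the cliques
  k4a <- t(combn(c("A", "B", "C", "D"), 2))
  k4b <- t(combn(c("E", "F", "G", "H"), 2))
  net <- net_from(c(k4a[, 1], k4b[, 1], "D"), c(k4a[, 2], k4b[, 2], "E"))
  part <- greedy_modules(net)
  expect_equal(part$n_modules, 2L)
  m <- part$membership
  expect_length(unique(m[c("A", "B", "C", "D")]), 1L)
  expect_length(unique(m[c("E", "F", "G", "H")]), 1L)

  k5 <- t(combn(LETTERS[1:5], 2))
  expect_equal(greedy_modules(net_from(k5[, 1], k5[, 2]))$n_modules, 1L)

  ## edgeless network: warning, singleton modules, Q = 0
  lonely <- hf_network(NULL, nodes = c("A", "B", "C"))
  expect_warning(p0 <- greedy_modules(lonely), "edgeless")
  expect_equal(p0$n_modules, 3L)
  expect_equal(p0$Q, 0)
})

test_that("merge history replays to the reported modularity at every step", {
  set.seed(73)
  for (rep in 1:5) {
    net <- random_connected_net(sample(10:14, 1), sample(18:26, 1))
    part <- greedy_modules(net)
    ## replay: merge label groups step by step, recompute Q from scratch
    memb <- stats::setNames(net$nodes, net$nodes)  # label = own symbol
    for (s in seq_len(nrow(part$history))) {
      gi <- part$history$module_i[s]
      gj <- part$history$module_j[s]
      memb[memb == gj] <- gi
      expect_equal(modularity_q(net, memb), part$history$Q_after[s],
                   tolerance = 1e-10)
    }
    ## final Q consistent with its own membership
    expect_equal(modularity_q(net, part$membership), part$Q, tolerance = 1e-10)
    ## greedy Q >= trivial baselines
    expect_gte(part$Q, modularity_q(net, rep(1, length(net$nodes))) - 1e-12)
    singletons <- stats::setNames(seq_along(net$nodes), net$nodes)
    expect_gte(part$Q, modularity_q(net, singletons) - 1e-12)
  }
})

test_that("greedy clustering recovers planted partitions and is relabeling-invariant", {
  pp <- sim_planted_partition(sizes = rep(15, 4), p_in = 0.4, p_out = 0.02,
                              seed = 101)
  part <- greedy_modules(pp$network)
  expect_gte(partition_agreement(part, pp$membership), 0.9)

  ## disconnected components never merge
  tri2 <- net_from(c("A", "B", "A", "D", "E", "D"),
                   c("B", "C", "C", "E", "F", "F"))
  p2 <- greedy_modules(tri2)
  expect_equal(p2$n_modules, 2L)

  ## permuting node names permutes the partition identically
  net <- pp$network
  perm <- stats::setNames(sample(net$nodes), net$nodes)
  relabelled <- hf_network(data.frame(a = unname(perm[net$edges$a]),
                                      b = unname(perm[net$edges$b])))
  p_orig <- greedy_modules(net)$membership
  p_rel <- greedy_modules(relabelled)$membership
  expect_equal(partition_agreement(stats::setNames(p_orig, unname(perm[names(p_orig)])),
                                   p_rel), 1)
})

test_that("module profiles match an edge-by-edge classification oracle", {
  net <- two_k3_bridge()
  memb <- c(A = 1, B = 1, C = 1, D = 2, E = 2, F = 2)
  prof <- profile_modules(net, memb)
  expect_equal(prof$n_proteins, c(3L, 3L))
  expect_equal(prof$n_intra_edges, c(3L, 3L))
  expect_equal(prof$n_imi, c(1L, 1L))
  expect_equal(prof$partner_modules, c("2", "1"))

  expect_equal(profile_modules(net, rep(1, 6))$n_imi, 0L)

  set.seed(79)
  for (rep in 1:5) {
    rnet <- random_connected_net(12, 24)
    m <- sample(4, 12, replace = TRUE)
    names(m) <- rnet$nodes
    prof <- profile_modules(rnet, m)
    ## direct per-edge recount
    ma <- m[rnet$edges$a]
    mb <- m[rnet$edges$b]
    for (c_id in prof$module) {
      expect_equal(prof$n_intra_edges[prof$module == c_id],
                   sum(ma == c_id & mb == c_id))
      expect_equal(prof$n_imi[prof$module == c_id],
                   sum(xor(ma == c_id, mb == c_id)))
    }
    ## conservation identities
    inter_total <- sum(ma != mb)
    expect_equal(sum(prof$n_intra_edges) + inter_total, rnet$n_edges)
    expect_equal(sum(prof$n_imi), 2L * inter_total)
    ct <- node_centrality(rnet)
    for (c_id in prof$module) {
      expect_equal(prof$median_traffic[prof$module == c_id],
                   stats::median(ct$traffic[m[ct$symbol] == c_id]))
    }
  }
})

test_that("partition agreement equals the reference adjusted Rand index", {
  skip_if_not_installed("mclust")
  set.seed(83)
  for (rep in 1:5) {
    a <- sample(4, 30, replace = TRUE)
    b <- sample(3, 30, replace = TRUE)
    expect_equal(partition_agreement(a, b), mclust::adjustedRandIndex(a, b),
                 tolerance = 1e-12)
  }
})
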