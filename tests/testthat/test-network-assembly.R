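test_that("symbol normalization is idempotent and alias-aware", {
  x <- c(" fn1", "Itgb1 ", "TNF")
  expect_identical(normalize_symbol(x), c("FN1", "ITGB1", "TNF"))
  expect_identical(normalize_symbol(normalize_symbol(x)), normalize_symbol(x))
  expect_identical(normalize_symbol("nt-probnp", alias = c("NT-PROBNP" = "NPPB")),
                   "NPPB")
})

test_that("interaction tables load with normalization, dedup and self-pair removal", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("FN1\tITGB1\thprd"), f)
  tab <- read_interactions(f)
  expect_equal(nrow(tab), 1L)
  expect_equal(tab$sources, "hprd")

  writeLines(c("a\tb", "b\ta"), f)   # unordered duplicates collapse
  expect_equal(nrow(suppressMessages(read_interactions(f))), 1L)

  writeLines(c("a\ta", "a\tb"), f)   # self-pair dropped and counted
  expect_message(tab <- read_interactions(f), "1 self-pair")
  expect_equal(nrow(tab), 1L)
  expect_equal(attr(tab, "n_self_dropped"), 1L)

  writeLines(c("protein_a\tprotein_b\tsource", "x\ty\tdb"), f)  # header detected
  expect_equal(read_interactions(f)$a, "X")

  writeLines(c("a\tb", "only-one-field"), f)
  expect_error(read_interactions(f), "line\\(s\\): 2")
  expect_error(read_interactions("/nonexistent/file.tsv"), "not found")
})

test_that("merge_union has set-union semantics and merges provenance", {
  t1 <- data.frame(a = "A", b = "B", sources = "db1")
  t2 <- data.frame(a = "B", b = "A", sources = "db2")
  t3 <- data.frame(a = "B", b = "C", sources = "db2")
  net <- merge_union(list(t1, t2, t3))
  expect_equal(length(net$nodes), 3L)
  expect_equal(net$n_edges, 2L)
  expect_equal(net$edges$sources[net$edges$a == "A"], "db1,db2")

  k3 <- data.frame(a = c("A", "A", "B"), b = c("B", "C", "C"))
  expect_equal(merge_union(list(k3))$n_edges, 3L)
  expect_error(merge_union(list()), "at least one")
})

test_that("union of random overlapping tables matches a set-union oracle", {
  set.seed(11)
  pairs <- t(combn(LETTERS[1:8], 2))
  shared <- pairs[sample(nrow(pairs), 4), , drop = FALSE]
  rest <- pairs[!paste(pairs[, 1], pairs[, 2]) %in%
                  paste(shared[, 1], shared[, 2]), , drop = FALSE]
  own1 <- rest[sample(nrow(rest), 6), , drop = FALSE]
  rest2 <- rest[!paste(rest[, 1], rest[, 2]) %in%
                  paste(own1[, 1], own1[, 2]), , drop = FALSE]
  own2 <- rest2[sample(nrow(rest2), 6), , drop = FALSE]
  tab1 <- data.frame(a = c(shared[, 1], own1[, 1]), b = c(shared[, 2], own1[, 2]))
  tab2 <- data.frame(a = c(shared[, 1], own2[, 1]), b = c(shared[, 2], own2[, 2]))
  expected <- unique(rbind(tab1, tab2))  # canonical a<b already
  expect_equal(merge_union(list(tab1, tab2))$n_edges, nrow(expected))  # 16
  ## idempotence
  expect_identical(merge_union(list(tab1, tab1))$edges,
                   merge_union(list(tab1))$edges)
})

test_that("seed subnetworks honour induced and seed-incident modes", {
  path <- net_from(c("A", "B"), c("B", "C"))
  expect_equal(seed_subnetwork(path, "B", "induced")$n_edges, 2L)
  expect_equal(seed_subnetwork(path, "B", "seed-incident")$n_edges, 2L)

  ## triangle A-B-C plus edge C-D, seed A
  tri <- net_from(c("A", "A", "B", "C"), c("B", "C", "C", "D"))
  ind <- seed_subnetwork(tri, "A", "induced")
  expect_setequal(ind$nodes, c("A", "B", "C"))
  expect_equal(ind$n_edges, 3L)
  inc <- seed_subnetwork(tri, "A", "seed-incident")
  expect_equal(inc$n_edges, 2L)
  expect_true(all(inc$edges$a == "A"))

  expect_error(seed_subnetwork(tri, "ZZZ"), "no seed")
  expect_message(sub <- seed_subnetwork(tri, c("A", "ZZZ")), "absent")
  expect_identical(attr(sub, "missing_seeds"), "ZZZ")
})

test_that("seed-incident edges are a subset of induced edges on random graphs", {
  set.seed(21)
  for (rep in 1:10) {
    net <- random_connected_net(8, 12)
    seeds <- sample(net$nodes, 2)
    ei <- seed_subnetwork(net, seeds, "induced")$edges
    es <- seed_subnetwork(net, seeds, "seed-incident")$edges
    expect_true(all(paste(es$a, es$b) %in% paste(ei$a, ei$b)))
  }
})

test_that("component decomposition finds the core, islands and singletons", {
  ## two disjoint triangles: tie broken lexicographically (smallest member)
  two_tri <- net_from(c("D", "E", "D", "A", "B", "A"),
                      c("E", "F", "F", "B", "C", "C"))
  dec <- decompose_components(two_tri)
  expect_setequal(dec$core$nodes, c("A", "B", "C"))
  expect_equal(length(dec$islands), 1L)

  ## K5 plus an isolated edge and an isolated node
  k5 <- t(combn(LETTERS[1:5], 2))
  net <- hf_network(data.frame(a = c(k5[, 1], "X"), b = c(k5[, 2], "Y")),
                    nodes = c(LETTERS[1:5], "X", "Y", "Z"))
  dec <- decompose_components(net)
  expect_equal(length(dec$core$nodes), 5L)
  expect_equal(dec$core$n_edges, 10L)
  expect_equal(vapply(dec$islands, function(i) length(i$nodes), integer(1)), 2L)
  expect_identical(dec$singletons, "Z")
})

test_that("component counts match a union-find oracle and conserve nodes/edges", {
  set.seed(5)
  for (rep in 1:8) {
    pairs <- t(combn(50, 2))
    sel <- pairs[sample(nrow(pairs), 30), , drop = FALSE]  # sub-critical
    nodes <- sprintf("N%02d", 1:50)
    net <- hf_network(data.frame(a = nodes[sel[, 1]], b = nodes[sel[, 2]]),
                      nodes = nodes)
    dec <- decompose_components(net)
    n_comp <- 1L + length(dec$islands) + length(dec$singletons)
    expect_equal(n_comp, oracle_component_count(net))
    sizes <- c(length(dec$core$nodes),
               vapply(dec$islands, function(i) length(i$nodes), integer(1)),
               rep(1L, length(dec$singletons)))
    expect_equal(sum(sizes), length(net$nodes))
    edge_counts <- c(dec$core$n_edges,
                     vapply(dec$islands, function(i) i$n_edges, integer(1)))
    expect_equal(sum(edge_counts), net$n_edges)
  }
})

test_that("assembly output is byte-identical across repeated runs", {
  f1 <- withr::local_tempfile(fileext = ".tsv")
  f2 <- withr::local_tempfile(fileext = ".tsv")
  tabs <- list(data.frame(a = c("B", "A", "C"), b = c("A", "C", "D"),
                          sources = "db1"),
               data.frame(a = c("C", "D"), b = c("A", "C"), sources = "db2"))
  write_network(merge_union(tabs), f1)
  write_network(merge_union(tabs), f2)
  expect_identical(readLines(f1), readLines(f2))
  ## canonical ordering: endpoints sorted within row, rows sorted
  e <- merge_union(tabs)$edges
  expect_true(all(e$a < e$b))
  expect_false(is.unsorted(paste(e$a, e$b)))
})
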