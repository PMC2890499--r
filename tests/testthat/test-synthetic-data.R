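test_that("generators are deterministic in their seed and leave global RNG alone", {
  a <- sim_planted_partition(seed = 201)
  b <- sim_planted_partition(seed = 201)
  expect_identical(a$network$edges, b$network$edges)
  expect_false(identical(
    a$network$edges, sim_planted_partition(seed = 202)$network$edges))

  e1 <- sim_expression(seed = 203)
  expect_identical(e1$values, sim_expression(seed = 203)$values)
  n1 <- sim_powerlaw_network(300, seed = 207)
  expect_identical(n1$edges, sim_powerlaw_network(300, seed = 207)$edges)
  r1 <- sim_rankings(30, 2, seed = 211)
  expect_identical(r1, sim_rankings(30, 2, seed = 211))

  ## global RNG stream is restored around generator calls
  set.seed(99)
  before <- .Random.seed
  invisible(sim_planted_partition(seed = 303))
  expect_identical(.Random.seed, before)
})

test_that("planted-partition networks have the configured structure", {
  ## p_out = 0, p_in = 1: modules are exactly the connected components
  pp <- sim_planted_partition(sizes = c(5, 6, 7), p_in = 1, p_out = 0, seed = 213)
  dec <- decompose_components(pp$network)
  comp <- dec$membership
  expect_equal(partition_agreement(comp, pp$membership), 1)

  ## expected edge count within 2% over replicate seeds (closed form)
  sizes <- rep(15, 4)
  expected <- sum(choose(sizes, 2)) * 0.4 +
    (sum(sizes)^2 - sum(sizes^2)) / 2 * 0.02
  mean_edges <- mean(vapply(1:200, function(s)
    sim_planted_partition(sizes, 0.4, 0.02, seed = s)$network$n_edges,
    numeric(1)))
  expect_lt(abs(mean_edges - expected) / expected, 0.02)

  ## networks are simple by construction
  e <- pp$network$edges
  expect_true(all(e$a != e$b))
  expect_false(anyDuplicated(paste(e$a, e$b)) > 0)
})

test_that("boosted biomarkers become hubs", {
  higher <- vapply(1:100, function(s) {
    pp <- sim_planted_partition(sizes = rep(12, 3), p_in = 0.4, p_out = 0.02,
                                n_biomarkers = 6, biomarker_boost = 6,
                                seed = 3000 + s)
    deg <- node_degrees(pp$network)
    is_bm <- names(deg) %in% pp$biomarkers
    mean(deg[is_bm]) > mean(deg[!is_bm])
  }, logical(1))
  expect_gte(mean(higher), 0.95)
})

test_that("configuration-model networks are simple with even stub counts", {
  net <- sim_powerlaw_network(500, gamma = 2.5, seed = 217)
  e <- net$edges
  expect_true(all(e$a != e$b))
  expect_false(anyDuplicated(paste(e$a, e$b)) > 0)
  expect_equal(sum(node_degrees(net)) %% 2, 0)
  ## a fitted exponent lands near the target on one mid-sized graph
  fit <- fit_power_law(degree_distribution(sim_powerlaw_network(2000, 2.5,
                                                                seed = 219)))
  expect_lt(abs(fit$gamma - 2.5), 0.4)
})

test_that("module-aligned term maps reflect purity exactly at purity 1", {
  pp <- sim_planted_partition(sizes = c(6, 8), p_in = 0.9, p_out = 0.05,
                              seed = 223)
  tm <- sim_term_map(pp$membership, purity = 1, n_noise_terms = 0, seed = 227)
  for (m in 1:2) {
    expect_setequal(tm$genes[[m]], names(pp$membership)[pp$membership == m])
  }
  ## with noise terms, sizes and membership are as configured
  tm2 <- sim_term_map(pp$membership, purity = 0.8, n_noise_terms = 4,
                      noise_size = 5, seed = 229)
  expect_equal(nrow(tm2), 6L)
  expect_true(all(lengths(tm2$genes[5:6]) == 5))
})

test_that("null expression matrices give calibrated DE rejection rates", {
  set.seed(231)
  ps <- unlist(lapply(1:10, function(s) {
    ex <- sim_expression(n_genes = 40, de_genes = 0, seed = 7000 + s)
    differential_expression(ex)$p
  }))
  expect_gt(mean(ps <= 0.05), 0.02)
  expect_lt(mean(ps <= 0.05), 0.08)
})

test_that("a strong planted DE gene dominates the screen", {
  best <- vapply(1:100, function(s) {
    ex <- sim_expression(n_genes = 20, de_genes = c(G001 = 3), seed = 8000 + s)
    de <- differential_expression(ex)
    de$gene[which.min(de$p)] == "G001"
  }, logical(1))
  expect_gte(mean(best), 0.95)
})

test_that("synthetic rankings plant a dominant candidate", {
  rk <- sim_rankings(n_genes = 40, n_sources = 1, planted_gene = NULL, seed = 233)
  expect_setequal(rk[[1]]$rank, 1:40)       # a permutation
  rk2 <- sim_rankings(n_genes = 40, n_sources = 4, seed = 239)
  for (r in rk2) expect_lte(r$ratio[r$gene == "G001"], 0.1)
})
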