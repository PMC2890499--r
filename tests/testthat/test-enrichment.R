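test_that("GMT files parse, merge duplicates, and round-trip", {
  f <- withr::local_tempfile(fileext = ".gmt")
  writeLines("TERM1\tdesc\tg1\tg2\tg3", f)
  tm <- read_gmt(f)
  expect_equal(nrow(tm), 1L)
  expect_equal(tm$genes[[1]], c("G1", "G2", "G3"))

  writeLines(c("T\td\tg1\tg2", "T\td\tg2\tg3"), f)
  expect_warning(tm <- read_gmt(f), "duplicate")
  expect_equal(lengths(tm$genes), 3L)

  writeLines("TERM1\tonly-two-fields", f)
  expect_error(read_gmt(f), "line\\(s\\): 1")

  ## 50-term round trip
  set.seed(91)
  genes <- sprintf("G%03d", 1:200)
  tm0 <- term_map(sprintf("T%02d", 1:50), sprintf("term %d", 1:50),
                  lapply(1:50, function(i) sample(genes, sample(3:12, 1))),
                  category = "CC")
  write_gmt(tm0, f)
  tm1 <- read_gmt(f, category = "CC")
  expect_equal(as.data.frame(tm1), as.data.frame(tm0))
})

test_that("two-tailed Fisher P matches hypergeometric enumeration", {
  expect_equal(fisher_exact_p(5, 5, 5, 5), 1)   # modal balanced table
  expect_equal(fisher_exact_p(3, 2, 2, 43), oracle_fisher_two_tailed(3, 2, 2, 43),
               tolerance = 1e-12)
  set.seed(97)
  for (rep in 1:40) {
    tb <- sample(0:12, 4, replace = TRUE)
    p <- fisher_exact_p(tb[1], tb[2], tb[3], tb[4])
    expect_equal(p, oracle_fisher_two_tailed(tb[1], tb[2], tb[3], tb[4]),
                 tolerance = 1e-9)
    ## transpose symmetry
    expect_equal(p, fisher_exact_p(tb[1], tb[3], tb[2], tb[4]),
                 tolerance = 1e-12)
  }
  expect_error(fisher_exact_p(-1, 2, 3, 4), "negative")
  expect_equal(fisher_exact_p(0, 0, 3, 4), 1)  # degenerate margin
})

test_that("BH adjustment follows the step-up formula and its invariances", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(101)
  p <- runif(30)
  adj <- bh_adjust(p)
  expect_true(all(adj >= p - 1e-15) && all(adj <= 1))
  expect_false(is.unsorted(adj[order(p)]))        # monotone in sorted order
  perm <- sample(30)
  expect_equal(bh_adjust(p[perm]), adj[perm])     # order-equivariant
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("planted signature terms enrich their own module", {
  set.seed(103)
  bg <- sprintf("G%03d", 1:500)
  memb <- c(rep(1, 12), rep(2, 12), sample(3:10, 476, replace = TRUE))
  names(memb) <- bg
  ## module 1's genes all share term X, absent elsewhere
  tm <- term_map("X", "planted", list(names(memb)[memb == 1]))
  enr <- enrich_modules(memb, tm, background = bg)
  rec <- enr[enr$module == 1 & enr$term == "X", ]
  expect_equal(nrow(rec), 1L)
  expect_lt(rec$p_adj, 1e-4)
  expect_true(rec$significant)
  ## only modules containing term genes yield records at all
  expect_true(all(enr$a > 0))
})

test_that("generator-aligned term maps are recovered by the enrichment engine", {
  pp <- sim_planted_partition(sizes = rep(15, 4), p_in = 0.5, p_out = 0.02,
                              seed = 107)
  tm <- sim_term_map(pp$membership, purity = 0.8, n_noise_terms = 10, seed = 109)
  enr <- enrich_modules(pp$membership, tm)
  top <- summarize_enrichment(enr)
  for (m in 1:4) {
    expect_equal(top$term[top$module == m], sprintf("SIG%d", m))
  }
  ## each signature's p within its own module beats its p in any other module
  for (m in 1:4) {
    sig <- sprintf("SIG%d", m)
    own <- enr$p_raw[enr$module == m & enr$term == sig]
    other <- enr$p_raw[enr$module != m & enr$term == sig]
    if (length(other)) expect_true(all(own < other))
  }
})

test_that("enrichment is calibrated under a term map independent of the partition", {
  set.seed(113)
  genes <- sprintf("G%03d", 1:300)
  fractions <- replicate(30, {
    memb <- sample(4, 300, replace = TRUE)
    names(memb) <- genes
    tm <- term_map(sprintf("T%02d", 1:40), "rnd",
                   lapply(1:40, function(i) sample(genes, 15)))
    enr <- enrich_modules(memb, tm, background = genes)
    mean(enr$p_raw <= 0.05)
  })
  ## discrete Fisher tests are conservative: reject at or below nominal rate
  expect_lt(mean(fractions), 0.08)
  expect_gt(mean(fractions), 0.005)
})

test_that("enrichment validates background and handles unannotated modules", {
  memb <- c(A = 1, B = 1, C = 2, D = 2)
  tm <- term_map("T1", "t", list(c("A", "B")))
  expect_error(enrich_modules(memb, tm, background = c("A", "B")),
               "does not contain")
  expect_message(enr <- enrich_modules(memb, tm), "module 2 has no annotated")
  expect_true(all(enr$module == 1))
  expect_error(enrich_modules(memb, tm, background = character()), "empty|contain")
})
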