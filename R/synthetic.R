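## All generators are pure functions of their arguments + seed: each call
## runs inside withr-style local RNG scoping done by hand (save/restore), so
## no global state leaks and the same seed always reproduces the output.
.with_seed <- function(seed, code) {
  if (is.null(seed)) stop("a seed is mandatory for synthetic generators")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

.node_names <- function(n, prefix = "P") {
  sprintf("%s%0*d", prefix, max(3L, nchar(n)), seq_len(n))
}

#' Planted-partition network with hub biomarkers
#'
#' Generates an undirected modular network: nodes are split into blocks
#' (modules); each within-block pair is an edge with probability `p_in`,
#' each between-block pair with probability `p_out` < `p_in`. A designated
#' set of "biomarker" nodes (spread round-robin across modules) receives on
#' average `biomarker_boost` additional edges to nodes of other modules,
#' which makes them simultaneously hubs (high degree) and bottlenecks (high
#' traffic) — the joint structure expected of disease biomarkers.
#'
#' @param sizes integer vector of module sizes (each >= 2).
#' @param p_in within-module edge probability.
#' @param p_out between-module edge probability (`0 <= p_out < p_in <= 1`).
#' @param n_biomarkers number of planted biomarker nodes.
#' @param biomarker_boost expected number of extra cross-module edges per
#'   biomarker (0 disables boosting).
#' @param seed mandatory RNG seed.
#' @param ensure_connected if `TRUE`, regenerate (bounded retries with
#'   derived sub-seeds) until the network is connected, else error.
#' @return list with `network` (`hf_network`), `membership` (named integer
#'   planted module ids), `biomarkers` (character).
#' @export
sim_planted_partition <- function(sizes = rep(15L, 4L), p_in = 0.4,
                                  p_out = 0.02, n_biomarkers = 0L,
                                  biomarker_boost = 8, seed,
                                  ensure_connected = FALSE) {
  stopifnot(all(sizes >= 2), p_out >= 0, p_in <= 1, p_out < p_in,
            n_biomarkers >= 0, biomarker_boost >= 0)
  n <- sum(sizes)
  if (n_biomarkers > n) stop("more biomarkers than nodes")
  build <- function(s) .with_seed(s, {
    nodes <- .node_names(n)
    memb <- rep(seq_along(sizes), sizes)
    names(memb) <- nodes
    idx <- t(utils::combn(n, 2L))
    same <- memb[idx[, 1]] == memb[idx[, 2]]
    prob <- ifelse(same, p_in, p_out)
    keep <- stats::runif(nrow(idx)) < prob
    a <- nodes[idx[keep, 1]]
    b <- nodes[idx[keep, 2]]
    ## biomarkers: round-robin over modules so every module hosts some
    bm <- character(0)
    if (n_biomarkers > 0) {
      by_mod <- split(nodes, memb)
      ord <- unlist(lapply(seq_len(max(sizes)), function(r)
        vapply(by_mod, function(v) if (r <= length(v)) v[r] else NA_character_,
               character(1))))
      bm <- ord[!is.na(ord)][seq_len(n_biomarkers)]
      if (biomarker_boost > 0) {
        for (v in bm) {
          others <- nodes[memb != memb[v]]
          k <- min(stats::rpois(1L, biomarker_boost), length(others))
          if (k > 0) {
            tgt <- sample(others, k)
            a <- c(a, rep(v, k))
            b <- c(b, tgt)
          }
        }
      }
    }
    if (!length(a)) stop("generated network has no edges; raise p_in")
    net <- hf_network(data.frame(a = a, b = b, sources = "synthetic",
                                 stringsAsFactors = FALSE), nodes = nodes)
    list(network = net, membership = memb, biomarkers = sort(bm, method = "radix"))
  })
  out <- build(seed)
  if (ensure_connected) {
    tries <- 0L
    while (length(decompose_components(out$network)$islands) > 0 ||
           length(decompose_components(out$network)$singletons) > 0) {
      tries <- tries + 1L
      if (tries > 25L) stop("could not generate a connected network in 25 tries")
      out <- build(seed + 1000003L * tries)
    }
  }
  out
}

#' Configuration-model network with power-law degrees
#'
#' Samples a degree sequence from a truncated power law P(k) ~ k^(-gamma),
#' k = 1..deg_max, pairs stubs uniformly at random, and discards self-loops
#' and duplicate pairs so the result is a simple graph. The default degree
#' cap, max(6, floor((n/3)^(1/gamma))), keeps the expected occupancy of the
#' rarest degree bin at a few nodes, so the empirical log-log histogram is
#' linear over its whole observed range (the regime a least-squares exponent
#' fit assumes).
#'
#' @param n number of nodes (>= 100).
#' @param gamma target exponent (> 1).
#' @param seed mandatory RNG seed.
#' @param deg_max truncation of the degree distribution.
#' @return an `hf_network`.
#' @export
sim_powerlaw_network <- function(n, gamma = 2.5, seed,
                                 deg_max = max(6L, floor((n / 3)^(1 / gamma)))) {
  stopifnot(n >= 100, gamma > 1, deg_max >= 3)
  .with_seed(seed, {
    ks <- seq_len(deg_max)
    prob <- ks^(-gamma)
    deg <- sample(ks, n, replace = TRUE, prob = prob / sum(prob))
    if (sum(deg) %% 2L == 1L) deg[which.max(deg)] <- deg[which.max(deg)] + 1L
    nodes <- .node_names(n)
    stubs <- sample(rep(seq_len(n), deg))
    a <- stubs[seq(1L, length(stubs), 2L)]
    b <- stubs[seq(2L, length(stubs), 2L)]
    keep <- a != b
    a <- a[keep]
    b <- b[keep]
    lo <- pmin(a, b)
    hi <- pmax(a, b)
    dup <- duplicated(paste(lo, hi))
    hf_network(data.frame(a = nodes[lo[!dup]], b = nodes[hi[!dup]],
                          sources = "synthetic", stringsAsFactors = FALSE),
               nodes = nodes)
  })
}

#' Module-aligned term map
#'
#' Builds one "signature" gene set per planted module — containing a
#' `purity` fraction of the module's members plus random outside genes to
#' keep the set size equal to the module size — and optionally uniform
#' noise terms unrelated to the partition. Signature terms should enrich
#' their own module and nothing else; noise terms behave as the null.
#'
#' @param membership named module assignment (gene -> module id).
#' @param purity fraction of each module included in its signature term,
#'   in (0, 1].
#' @param n_noise_terms number of random terms.
#' @param noise_size size of each noise term (default 10).
#' @param seed mandatory RNG seed.
#' @param category category label for the generated terms.
#' @return an `hf_term_map` with terms `SIG<module>` and `NOISE<i>`.
#' @export
sim_term_map <- function(membership, purity = 0.8, n_noise_terms = 0L,
                         noise_size = 10L, seed, category = "BP") {
  stopifnot(purity > 0, purity <= 1, n_noise_terms >= 0)
  genes <- names(membership)
  if (is.null(genes)) stop("membership must be named by gene symbol")
  .with_seed(seed, {
    mods <- sort(unique(membership))
    terms <- character(0)
    names_ <- character(0)
    sets <- list()
    for (m in mods) {
      members <- genes[membership == m]
      k_in <- max(1L, round(purity * length(members)))
      inside <- sample(members, k_in)
      k_out <- length(members) - k_in
      outside <- if (k_out > 0) sample(setdiff(genes, members), k_out) else character(0)
      terms <- c(terms, sprintf("SIG%d", m))
      names_ <- c(names_, sprintf("signature of module %d", m))
      sets[[length(sets) + 1L]] <- c(inside, outside)
    }
    if (n_noise_terms > 0) {
      for (i in seq_len(n_noise_terms)) {
        terms <- c(terms, sprintf("NOISE%d", i))
        names_ <- c(names_, sprintf("random term %d", i))
        sets[[length(sets) + 1L]] <- sample(genes, min(noise_size, length(genes)))
      }
    }
    term_map(terms, names_, sets, category)
  })
}

#' Two-class synthetic expression matrix
#'
#' Independent Gaussian noise N(0, 1) per gene and sample; differentially
#' expressed genes are shifted by their effect size (in within-class
#' standard-deviation units) in the case class. The default 16 + 16 design
#' mirrors a small two-arm patient study.
#'
#' @param n_genes number of genes.
#' @param n_per_class samples per class (length-2 vector or scalar).
#' @param de_genes named numeric vector: gene name -> effect size delta (in
#'   sigma units), or an unnamed length giving how many of the first genes
#'   are DE via `de_effect`.
#' @param de_effect effect size used when `de_genes` is a count.
#' @param seed mandatory RNG seed.
#' @param classes the two class labels (case first).
#' @return an `hf_expression` with attribute `de_genes` (named effect sizes).
#' @export
sim_expression <- function(n_genes = 50L, n_per_class = c(16L, 16L),
                           de_genes = 0L, de_effect = 1.0, seed,
                           classes = c("HF", "nonHF")) {
  n_per_class <- rep_len(as.integer(n_per_class), 2L)
  stopifnot(all(n_per_class >= 2), n_genes >= 1)
  if (!is.numeric(de_genes)) stop("de_genes must be numeric")
  genes <- sprintf("G%03d", seq_len(n_genes))
  if (is.null(names(de_genes))) {
    k <- as.integer(de_genes)
    stopifnot(length(de_genes) == 1L, k <= n_genes)
    de <- if (k > 0) stats::setNames(rep(de_effect, k), genes[seq_len(k)]) else
      stats::setNames(numeric(0), character(0))
  } else {
    de <- de_genes
    if (!all(names(de) %in% genes)) {
      genes <- unique(c(names(de), genes))[seq_len(max(n_genes, length(de)))]
    }
  }
  .with_seed(seed, {
    n_s <- sum(n_per_class)
    samples <- sprintf("S%02d", seq_len(n_s))
    labels <- stats::setNames(rep(classes, n_per_class), samples)
    vals <- matrix(stats::rnorm(length(genes) * n_s), length(genes), n_s,
                   dimnames = list(genes, samples))
    if (length(de)) {
      case_cols <- labels == classes[1]
      vals[names(de), case_cols] <- vals[names(de), case_cols] + de
    }
    out <- expression_matrix(vals, labels, case_class = classes[1])
    attr(out, "de_genes") <- de
    out
  })
}

#' Synthetic per-source rankings with a planted gene
#'
#' Each source ranks the genes by a random permutation, except that the
#' planted gene is forced into the top decile of every source — a candidate
#' with consistent support that order-statistics aggregation should rank
#' first or near-first.
#'
#' @param n_genes number of genes (named G001..).
#' @param n_sources number of evidence sources (>= 1).
#' @param planted_gene symbol to plant (default the first gene); `NULL`
#'   disables planting.
#' @param seed mandatory RNG seed.
#' @return list of `hf_ranking` objects.
#' @export
sim_rankings <- function(n_genes = 50L, n_sources = 3L, planted_gene = "G001",
                         seed) {
  stopifnot(n_sources >= 1, n_genes >= 2)
  genes <- sprintf("G%03d", seq_len(n_genes))
  if (!is.null(planted_gene)) {
    planted_gene <- normalize_symbol(planted_gene)
    if (!planted_gene %in% genes) stop("planted gene not among the generated genes")
  }
  .with_seed(seed, {
    lapply(seq_len(n_sources), function(s) {
      rk <- sample(n_genes)
      names(rk) <- genes
      if (!is.null(planted_gene)) {
        top <- sample(max(1L, floor(n_genes / 10)), 1L)
        holder <- names(rk)[rk == top]
        rk[holder] <- rk[planted_gene]
        rk[planted_gene] <- top
      }
      source_ranking(names(rk), unname(rk), type = "rank",
                     source = sprintf("source%d", s))
    })
  })
}
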