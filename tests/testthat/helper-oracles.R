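## Independent oracles and graph builders used across the suite. Everything
## here is deliberately brute-force and shares no code with the package
## internals it checks.

## build an hf_network from two endpoint vectors
net_from <- function(a, b, nodes = NULL) {
  hf_network(data.frame(a = a, b = b, stringsAsFactors = FALSE), nodes = nodes)
}

## an edge mask over the C(n,2) pairs of LETTERS[1:n] -> endpoint vectors
mask_to_edges <- function(mask_bits, n) {
  pairs <- t(utils::combn(n, 2L))
  sel <- pairs[mask_bits, , drop = FALSE]
  list(a = LETTERS[sel[, 1]], b = LETTERS[sel[, 2]])
}

## connectivity by repeated neighbour expansion (no package code)
edges_connected <- function(a, b, n) {
  nodes <- LETTERS[seq_len(n)]
  reach <- nodes[1]
  repeat {
    grow <- unique(c(b[a %in% reach], a[b %in% reach]))
    new <- setdiff(grow, reach)
    if (!length(new)) break
    reach <- c(reach, new)
  }
  length(reach) == n
}

random_connected_net <- function(n, m, max_tries = 200) {
  pairs <- t(utils::combn(n, 2L))
  for (i in seq_len(max_tries)) {
    sel <- pairs[sample(nrow(pairs), m), , drop = FALSE]
    a <- LETTERS[sel[, 1]]
    b <- LETTERS[sel[, 2]]
    if (edges_connected(a, b, n)) return(net_from(a, b, nodes = LETTERS[seq_len(n)]))
  }
  stop("could not draw a connected graph")
}

## brute-force betweenness: enumerate ALL simple paths for every unordered
## pair, keep the shortest, split credit equally among tied paths.
oracle_betweenness <- function(net) {
  nodes <- net$nodes
  n <- length(nodes)
  adj <- lapply(nodes, function(v)
    c(net$edges$b[net$edges$a == v], net$edges$a[net$edges$b == v]))
  names(adj) <- nodes
  bc <- stats::setNames(numeric(n), nodes)
  all_paths <- function(from, to) {
    out <- list()
    walk <- function(path) {
      last <- path[length(path)]
      if (last == to) {
        out[[length(out) + 1L]] <<- path
        return()
      }
      for (nb in adj[[last]]) if (!nb %in% path) walk(c(path, nb))
    }
    walk(from)
    out
  }
  for (i in seq_len(n - 1)) {
    for (j in seq((i + 1), n)) {
      paths <- all_paths(nodes[i], nodes[j])
      if (!length(paths)) next
      len <- vapply(paths, length, integer(1))
      shortest <- paths[len == min(len)]
      for (p in shortest) {
        interior <- p[-c(1, length(p))]
        if (length(interior)) {
          bc[interior] <- bc[interior] + 1 / length(shortest)
        }
      }
    }
  }
  bc
}

## union-find component count
oracle_component_count <- function(net) {
  parent <- stats::setNames(net$nodes, net$nodes)
  find <- function(x) {
    while (parent[[x]] != x) x <- parent[[x]]
    x
  }
  for (k in seq_len(net$n_edges)) {
    ra <- find(net$edges$a[k])
    rb <- find(net$edges$b[k])
    if (ra != rb) parent[[ra]] <- rb
  }
  length(unique(vapply(net$nodes, find, character(1))))
}

## all set partitions of 1..n (Bell-number enumeration)
enumerate_partitions <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in enumerate_partitions(n - 1)) {
    for (block in seq_len(max(p) + 1L)) {
      out[[length(out) + 1L]] <- c(p, block)
    }
  }
  out
}

## exhaustive maximum modularity over every partition
oracle_max_q <- function(net) {
  parts <- enumerate_partitions(length(net$nodes))
  max(vapply(parts, function(p) {
    names(p) <- net$nodes
    modularity_q(net, p)
  }, numeric(1)))
}

## two-tailed Fisher by direct hypergeometric enumeration over all tables
## with the observed margins
oracle_fisher_two_tailed <- function(a, b, c, d) {
  m1 <- a + b
  n1 <- a + c
  tot <- a + b + c + d
  if (m1 == 0 || m1 == tot || n1 == 0 || n1 == tot) return(1)
  as <- max(0, n1 - (tot - m1)):min(m1, n1)
  probs <- stats::dhyper(as, n1, tot - n1, m1)
  p_obs <- stats::dhyper(a, n1, tot - n1, m1)
  sum(probs[probs <= p_obs * (1 + 1e-07)])
}

## direct textbook Pearson r and its t-transform P
oracle_pearson <- function(x, y) {
  n <- length(x)
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  tt <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * stats::pt(-abs(tt), df = n - 2))
}
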