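## membership input: named integer/character vector over network nodes, or an
## hf_partition. Returns integer codes aligned with network$nodes.
.align_membership <- function(network, membership) {
  if (inherits(membership, "hf_partition")) membership <- membership$membership
  if (is.null(names(membership))) {
    if (length(membership) != length(network$nodes)) {
      stop("unnamed membership must have one entry per network node")
    }
    names(membership) <- network$nodes
  }
  miss <- setdiff(network$nodes, names(membership))
  if (length(miss)) {
    stop("membership does not cover node(s): ", paste(utils::head(miss, 5), collapse = ", "))
  }
  as.integer(factor(membership[network$nodes]))
}

#' Modularity score Q of a partition
#'
#' Q compares the number of intra-module edges with the expectation under a
#' degree-preserving random rewiring of the network:
#' Q = sum over modules c of \[ L_c / numE - (d_c / (2 numE))^2 \], where L_c
#' is the number of edges with both endpoints in c (numIME per module), d_c
#' the total degree of c's members and numE the total edge count.
#'
#' @param network an `hf_network` with at least one edge.
#' @param membership module assignment: named vector over the network's
#'   nodes, an unnamed vector aligned with `network$nodes`, or an
#'   `hf_partition`.
#' @return numeric Q in \[-1, 1\].
#' @examples
#' net <- merge_union(list(data.frame(a = c("A", "B", "C", "D", "E", "F"),
#'                                    b = c("B", "C", "A", "E", "F", "D"))))
#' modularity_q(net, c(A = 1, B = 1, C = 1, D = 2, E = 2, F = 2))  # 0.5
#' @export
modularity_q <- function(network, membership) {
  stopifnot(inherits(network, "hf_network"))
  if (network$n_edges < 1L) stop("modularity requires at least one edge")
  m <- .align_membership(network, membership)
  numE <- network$n_edges
  ia <- m[match(network$edges$a, network$nodes)]
  ib <- m[match(network$edges$b, network$nodes)]
  nmod <- max(m)
  Lc <- tabulate(ia[ia == ib], nbins = nmod)
  deg <- node_degrees(network)
  dc <- vapply(seq_len(nmod), function(c) sum(deg[m == c]), numeric(1))
  sum(Lc / numE - (dc / (2 * numE))^2)
}

#' Greedy modularity-maximizing module detection
#'
#' Agglomerative clustering in the style of Clauset, Newman and Moore: every
#' node starts as its own module; at each step the connected module pair with
#' the largest modularity gain is merged; the procedure stops when no merge
#' increases Q, and the partition at peak Q is returned. Deterministic: equal
#' gains are broken by the lexicographically smallest pair of module labels
#' (a module is labelled by its smallest member symbol). Only connected pairs
#' are merge candidates, so components of a disconnected network never merge.
#'
#' @param network an `hf_network`.
#' @return object of class `hf_partition`: list with `membership` (named
#'   integer vector; module ids 1..K ordered by decreasing size, then
#'   smallest member), `n_modules`, `Q`, and `history` (data.frame of merges:
#'   labels of the merged pair, `dQ`, `Q_after`).
#' @export
greedy_modules <- function(network) {
  stopifnot(inherits(network, "hf_network"))
  n <- length(network$nodes)
  if (network$n_edges < 1L) {
    warning("edgeless network: every node is its own module, Q = 0")
    memb <- seq_len(n)
    names(memb) <- network$nodes
    return(structure(list(membership = memb, n_modules = n, Q = 0,
                          history = data.frame(module_i = character(),
                                               module_j = character(),
                                               dQ = numeric(), Q_after = numeric())),
                     class = "hf_partition"))
  }
  numE <- network$n_edges
  ia <- match(network$edges$a, network$nodes)
  ib <- match(network$edges$b, network$nodes)
  ## W[i, j] (i != j): fraction of all edges running between current modules
  ## i and j; W[i, i]: fraction within module i. Merge gain for a connected
  ## pair is dQ = W[i, j] - 2 a_i a_j, where a_i = module degree / (2 numE).
  W <- matrix(0, n, n)
  for (k in seq_len(numE)) {
    W[ia[k], ib[k]] <- W[ia[k], ib[k]] + 1 / numE
    W[ib[k], ia[k]] <- W[ib[k], ia[k]] + 1 / numE
  }
  ## both triangles were filled, so each off-diagonal entry already holds the
  ## full between fraction; self-loops are impossible so the diagonal is 0.
  a_frac <- unname(node_degrees(network)[network$nodes]) / (2 * numE)
  label <- network$nodes          # module label = smallest member symbol
  alive <- rep(TRUE, n)
  memb <- seq_len(n)
  names(memb) <- network$nodes
  Q <- sum(diag(W)) - sum(a_frac^2)
  bestQ <- Q
  best_memb <- memb
  hist_i <- hist_j <- character(0)
  hist_dq <- hist_q <- numeric(0)
  eps <- 1e-12
  repeat {
    live <- which(alive)
    if (length(live) < 2L) break
    best_dq <- -Inf
    bi <- bj <- 0L
    for (i in live) {
      js <- live[live > i]
      js <- js[W[i, js] > 0]
      if (!length(js)) next
      dq <- W[i, js] - 2 * a_frac[i] * a_frac[js]
      for (idx in seq_along(js)) {
        j <- js[idx]
        d <- dq[idx]
        if (d > best_dq + eps) {
          best_dq <- d; bi <- i; bj <- j
        } else if (d >= best_dq - eps && bi > 0L) {
          cand <- sort(c(label[i], label[j]))
          cur <- sort(c(label[bi], label[bj]))
          if (cand[1] < cur[1] || (cand[1] == cur[1] && cand[2] < cur[2])) {
            bi <- i; bj <- j
          }
        }
      }
    }
    if (bi == 0L || best_dq <= eps) break
    ## merge: survivor is the module with the smaller label
    keep <- if (label[bi] <= label[bj]) bi else bj
    gone <- if (keep == bi) bj else bi
    hist_i <- c(hist_i, label[keep])
    hist_j <- c(hist_j, label[gone])
    others <- live[live != keep & live != gone]
    W[keep, keep] <- W[keep, keep] + W[gone, gone] + W[keep, gone]
    if (length(others)) {
      W[keep, others] <- W[keep, others] + W[gone, others]
      W[others, keep] <- W[keep, others]
    }
    W[gone, ] <- 0
    W[, gone] <- 0
    a_frac[keep] <- a_frac[keep] + a_frac[gone]
    alive[gone] <- FALSE
    memb[memb == gone] <- keep
    Q <- Q + best_dq
    hist_dq <- c(hist_dq, best_dq)
    hist_q <- c(hist_q, Q)
    if (Q > bestQ + eps) {
      bestQ <- Q
      best_memb <- memb
    }
  }
  ## renumber modules: decreasing size, then smallest member symbol
  ids <- unique(best_memb)
  sizes <- vapply(ids, function(i) sum(best_memb == i), integer(1))
  firsts <- vapply(ids, function(i) min(names(best_memb)[best_memb == i]), character(1))
  ord <- ids[order(-sizes, firsts, method = "radix")]
  final <- match(best_memb, ord)
  names(final) <- names(best_memb)
  structure(list(membership = final,
                 n_modules = length(ids),
                 Q = bestQ,
                 history = data.frame(module_i = hist_i, module_j = hist_j,
                                      dQ = hist_dq, Q_after = hist_q,
                                      stringsAsFactors = FALSE)),
            class = "hf_partition")
}

#' @export
print.hf_partition <- function(x, ...) {
  sizes <- sort(table(x$membership), decreasing = TRUE)
  cat(sprintf("hf_partition: %d modules over %d nodes, Q = %.4f\n",
              x$n_modules, length(x$membership), x$Q))
  cat("  module sizes:", paste(as.integer(sizes), collapse = ", "), "\n")
  invisible(x)
}

#' Structural profile of each module
#'
#' Per module: member count, intra-module edge count, median member traffic,
#' number of inter-module interactions (IMIs; edges with exactly one endpoint
#' in the module) and the set of partner modules (recorded once per module
#' pair regardless of how many individual interactions link them).
#'
#' @param network an `hf_network`.
#' @param partition an `hf_partition` (or membership vector).
#' @param centrality optional `hf_centrality` table; computed from the
#'   network when omitted.
#' @return data.frame with columns `module`, `n_proteins`, `n_intra_edges`,
#'   `median_traffic`, `n_imi`, `partner_modules` (comma-joined ids).
#' @export
profile_modules <- function(network, partition, centrality = NULL) {
  stopifnot(inherits(network, "hf_network"))
  m <- .align_membership(network, partition)
  if (is.null(centrality)) centrality <- node_centrality(network)
  ct <- as.data.frame(centrality)
  miss <- setdiff(network$nodes, ct$symbol)
  if (length(miss)) stop("centrality table does not cover node(s): ",
                         paste(utils::head(miss, 5), collapse = ", "))
  traffic <- ct$traffic[match(network$nodes, ct$symbol)]
  ia <- m[match(network$edges$a, network$nodes)]
  ib <- m[match(network$edges$b, network$nodes)]
  nmod <- max(m)
  intra <- tabulate(ia[ia == ib], nbins = nmod)
  inter_a <- ia[ia != ib]
  inter_b <- ib[ia != ib]
  imi <- tabulate(inter_a, nbins = nmod) + tabulate(inter_b, nbins = nmod)
  partners <- vapply(seq_len(nmod), function(c) {
    p <- sort(unique(c(inter_b[inter_a == c], inter_a[inter_b == c])))
    paste(p, collapse = ",")
  }, character(1))
  out <- data.frame(module = seq_len(nmod),
                    n_proteins = as.integer(tabulate(m, nbins = nmod)),
                    n_intra_edges = as.integer(intra),
                    median_traffic = vapply(seq_len(nmod), function(c)
                      stats::median(traffic[m == c]), numeric(1)),
                    n_imi = as.integer(imi),
                    partner_modules = partners,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Adjusted Rand agreement between two partitions
#'
#' Chance-corrected agreement between a detected partition and a reference
#' (e.g. the planted modules of a synthetic network): 1 = identical up to
#' relabelling, 0 = chance level.
#'
#' @param a,b membership vectors (named or aligned) or `hf_partition`s over
#'   the same nodes.
#' @return numeric adjusted Rand index.
#' @export
partition_agreement <- function(a, b) {
  get_m <- function(x) if (inherits(x, "hf_partition")) x$membership else x
  a <- get_m(a)
  b <- get_m(b)
  if (!is.null(names(a)) && !is.null(names(b))) {
    common <- intersect(names(a), names(b))
    if (!length(common)) stop("partitions share no nodes")
    a <- a[common]
    b <- b[common]
  }
  if (length(a) != length(b)) stop("partitions cover different node sets")
  e1071::classAgreement(table(a, b))$crand
}
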