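#' Degree distribution of a network
#'
#' Exact histogram of node degrees k >= 1. Isolated (degree-0) nodes are
#' tracked separately in the `n_isolated` attribute since they cannot enter a
#' log-log fit.
#'
#' @param network an `hf_network`.
#' @return data.frame with columns `k` (degree) and `count` (number of nodes
#'   with that degree), sorted by `k`; attribute `n_isolated`.
#' @export
degree_distribution <- function(network) {
  deg <- node_degrees(network)
  pos <- deg[deg > 0L]
  tab <- table(pos)
  out <- data.frame(k = as.integer(names(tab)), count = as.integer(tab))
  out <- out[order(out$k), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_isolated") <- sum(deg == 0L)
  out
}

#' Fit a power law to a degree distribution
#'
#' The degree frequencies are modelled as D(k) ~ k^(-gamma). Following the
#' classical log-log procedure, an ordinary least-squares line is fitted
#' through (ln k, ln D(k)) over all degrees with positive observed frequency;
#' `gamma` is minus the slope and `fit_quality` the squared correlation (R^2)
#' of the regression.
#'
#' @param dist a degree distribution from [degree_distribution()], or any
#'   data.frame with columns `k` and `count`.
#' @return object of class `hf_powerlaw`: list with `gamma`, `intercept`
#'   (ln-scale), `fit_quality`, `n_points`.
#' @examples
#' d <- data.frame(k = c(1, 2, 4, 8, 16), count = 1000 * c(1, 2, 4, 8, 16)^-2)
#' fit_power_law(d)$gamma
#' @export
fit_power_law <- function(dist) {
  dist <- as.data.frame(dist)
  stopifnot(all(c("k", "count") %in% names(dist)))
  use <- dist$count > 0 & dist$k > 0
  if (sum(use) < 3L) stop("need at least 3 degree values with positive frequency")
  lk <- log(dist$k[use])
  lc <- log(dist$count[use])
  fit <- stats::lm(lc ~ lk)
  ss_tot <- sum((lc - mean(lc))^2)
  r2 <- if (ss_tot == 0) 1 else 1 - sum(stats::resid(fit)^2) / ss_tot
  structure(list(gamma = unname(-stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 fit_quality = r2,
                 n_points = sum(use)),
            class = "hf_powerlaw")
}

#' @export
print.hf_powerlaw <- function(x, ...) {
  cat(sprintf("power-law fit: gamma = %.3f (R^2 = %.3f, %d points)\n",
              x$gamma, x$fit_quality, x$n_points))
  invisible(x)
}

## Brandes (2001) betweenness over unordered pairs, endpoints excluded,
## fractional allocation across equally short paths. Unweighted BFS variant.
.brandes <- function(adj) {
  n <- length(adj)
  bc <- numeric(n)
  for (s in seq_len(n)) {
    sigma <- numeric(n)
    sigma[s] <- 1
    dist <- rep(-1L, n)
    dist[s] <- 0L
    preds <- vector("list", n)
    order_visited <- integer(0)
    queue <- c(s)
    head <- 1L
    while (head <= length(queue)) {
      v <- queue[head]
      head <- head + 1L
      order_visited <- c(order_visited, v)
      for (w in adj[[v]]) {
        if (dist[w] < 0L) {
          dist[w] <- dist[v] + 1L
          queue <- c(queue, w)
        }
        if (dist[w] == dist[v] + 1L) {
          sigma[w] <- sigma[w] + sigma[v]
          preds[[w]] <- c(preds[[w]], v)
        }
      }
    }
    delta <- numeric(n)
    for (w in rev(order_visited)) {
      for (v in preds[[w]]) {
        delta[v] <- delta[v] + sigma[v] / sigma[w] * (1 + delta[w])
      }
      if (w != s) bc[w] <- bc[w] + delta[w]
    }
  }
  bc / 2  # undirected: each unordered pair counted from both endpoints
}

#' Degree and traffic (betweenness centrality) per node
#'
#' Traffic measures a node's share of shortest paths between all other node
#' pairs: for each unordered pair (s, t), the fraction of shortest s-t paths
#' passing through x (endpoints excluded), summed over pairs. High-traffic
#' nodes are communication bottlenecks. Computed exactly with Brandes'
#' algorithm; disconnected inputs are allowed (paths within components only).
#'
#' @param network an `hf_network`.
#' @param traffic_scale multiplier applied to the raw betweenness values
#'   (default 1); provided because published traffic magnitudes sometimes
#'   carry an unspecified scaling.
#' @return data.frame of class `hf_centrality` with columns `symbol`,
#'   `degree`, `traffic`, covering every node, sorted by symbol.
#' @export
node_centrality <- function(network, traffic_scale = 1) {
  stopifnot(inherits(network, "hf_network"))
  deg <- node_degrees(network)
  adj <- .adjacency(network)
  traffic <- if (length(adj)) .brandes(adj) else numeric(0)
  out <- data.frame(symbol = network$nodes,
                    degree = as.integer(deg),
                    traffic = traffic * traffic_scale,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("hf_centrality", "data.frame")
  out
}

#' Top-k nodes by a centrality metric
#'
#' @param centrality an `hf_centrality` table (or data.frame with `symbol`
#'   plus the metric column).
#' @param metric `"traffic"` or `"degree"`.
#' @param k number of nodes to return; truncated with a warning if larger
#'   than the table.
#' @return data.frame (`symbol`, metric value) in descending order, ties
#'   broken lexicographically by symbol.
#' @export
top_nodes <- function(centrality, metric = c("traffic", "degree"), k = 20L) {
  metric <- match.arg(metric)
  stopifnot(k >= 1)
  df <- as.data.frame(centrality)
  if (k > nrow(df)) {
    warning("k exceeds the number of nodes; returning all ", nrow(df))
    k <- nrow(df)
  }
  ord <- order(-df[[metric]], df$symbol, method = "radix")
  out <- df[ord[seq_len(k)], c("symbol", metric), drop = FALSE]
  rownames(out) <- NULL
  out
}
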