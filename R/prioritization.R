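#' Order-statistics score for combined rank ratios
#'
#' Given a candidate gene's rank ratios r_1..r_N across N evidence sources
#' (rank divided by the number of ranked genes in that source), the score is
#' the joint probability that N independent uniform(0,1) draws would have
#' each of their order statistics below the corresponding sorted observed
#' ratio: RS = P(U_(i) <= r_(i) for all i). Smaller values mean consistently
#' good ranks. Computed with the closed-form recursion over the sorted
#' ratios; for N = 1 the score reduces to r itself. The raw joint probability
#' is reported without any recalibration, so scores are comparable within one
#' analysis but are not calibrated P values.
#'
#' @param rank_ratios numeric vector of values in (0, 1].
#' @return numeric score in \[0, 1\].
#' @examples
#' order_statistic_score(0.3)           # 0.3
#' order_statistic_score(c(1, 1, 1))    # 1
#' @export
order_statistic_score <- function(rank_ratios) {
  r <- as.numeric(rank_ratios)
  if (!length(r)) stop("need at least one rank ratio")
  if (any(is.na(r)) || any(r <= 0 | r > 1)) stop("rank ratios must lie in (0, 1]")
  r <- sort(r)
  n <- length(r)
  ## V_k = sum_{i=1}^{k} (-1)^(i-1) V_{k-i} r_{n-k+1}^i / i!,  RS = n! V_n
  V <- numeric(n + 1)
  V[1] <- 1
  for (k in seq_len(n)) {
    i <- seq_len(k)
    V[k + 1] <- sum((-1)^(i - 1) * V[k - i + 1] * r[n - k + 1]^i / factorial(i))
  }
  min(max(factorial(n) * V[n + 1], 0), 1)
}

#' Fisher's omnibus combination of P values
#'
#' Combines N independent P values through the statistic X = -2 sum(ln p),
#' referred to a chi-square distribution with 2N degrees of freedom. For a
#' single P value the combined P equals the input.
#'
#' @param p numeric vector of P values in (0, 1]. Zeros are an error (floor
#'   them upstream if needed).
#' @return list with `statistic` (X), `df` (2N) and `p` (combined P).
#' @examples
#' fisher_omnibus(c(0.05, 0.05))
#' @export
fisher_omnibus <- function(p) {
  p <- as.numeric(p)
  if (!length(p)) stop("need at least one P value")
  if (any(is.na(p)) || any(p > 1)) stop("P values must lie in (0, 1]")
  if (any(p <= 0)) stop("P value of 0 cannot be combined; floor it upstream")
  x <- -2 * sum(log(p))
  list(statistic = x, df = 2L * length(p),
       p = stats::pchisq(x, df = 2 * length(p), lower.tail = FALSE))
}

#' Read a per-source ranking table
#'
#' TSV with two columns: gene and either a rank (smaller = better) or a
#' similarity score (larger = better; converted to ranks descending).
#'
#' @param path file path.
#' @param type `"rank"` or `"score"`.
#' @param source source id; defaults to the file name without extension.
#' @param alias optional alias map.
#' @return object of class `hf_ranking`: data.frame `gene`, `rank`,
#'   `ratio` with attribute `source`.
#' @export
read_ranking <- function(path, type = c("rank", "score"), source = NULL,
                         alias = NULL) {
  type <- match.arg(type)
  if (!file.exists(path)) stop("ranking file not found: ", path)
  if (is.null(source)) source <- sub("\\.[^.]*$", "", basename(path))
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE,
                          col.names = c("gene", "value"))
  source_ranking(df$gene, df$value, type = type, source = source, alias = alias)
}

#' Construct a per-source ranking
#'
#' @param gene character vector of gene symbols (unique per source).
#' @param value ranks (smaller = better) or scores (larger = better).
#' @param type `"rank"` or `"score"`.
#' @param source source id label.
#' @param alias optional alias map.
#' @return an `hf_ranking` data.frame (`gene`, `rank`, `ratio`), ratio =
#'   rank / number of ranked genes.
#' @export
source_ranking <- function(gene, value, type = c("rank", "score"),
                           source = "source", alias = NULL) {
  type <- match.arg(type)
  gene <- normalize_symbol(gene, alias)
  if (anyDuplicated(gene)) stop("duplicate gene(s) in source ranking: ",
                                paste(unique(gene[duplicated(gene)]), collapse = ", "))
  value <- as.numeric(value)
  rk <- if (type == "rank") {
    if (anyDuplicated(value)) stop("ranks must be unique per source")
    rank(value, ties.method = "first")
  } else {
    rank(-value, ties.method = "first")
  }
  out <- data.frame(gene = gene, rank = as.integer(rk),
                    ratio = rk / length(gene), stringsAsFactors = FALSE)
  out <- out[order(out$rank), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "source") <- source
  class(out) <- c("hf_ranking", "data.frame")
  out
}

#' Combine per-source rankings by order statistics
#'
#' Every gene seen in any source gets one rank ratio per source; genes
#' missing from a source are imputed the worst ratio 1 (a conservative
#' choice: absence is treated as no evidence). Ratios are combined with
#' [order_statistic_score()] and genes are returned sorted by ascending
#' score, ties broken lexicographically.
#'
#' @param rankings list of `hf_ranking` objects (or data.frames with `gene`
#'   and `ratio`).
#' @param top_n number of genes to return (default 100).
#' @return data.frame of class `hf_combined_ranking`: `gene`, one
#'   `ratio.<source>` column per source, `rs`, `rank`.
#' @export
combine_rankings <- function(rankings, top_n = 100L) {
  if (!is.list(rankings) || !length(rankings)) stop("need at least one source ranking")
  stopifnot(top_n >= 1)
  srcs <- vapply(seq_along(rankings), function(i) {
    s <- attr(rankings[[i]], "source")
    if (is.null(s)) paste0("source", i) else s
  }, character(1))
  if (anyDuplicated(srcs)) srcs <- make.unique(srcs)
  genes <- sort(unique(unlist(lapply(rankings, function(r) r$gene))), method = "radix")
  ratios <- sapply(rankings, function(r) {
    v <- r$ratio[match(genes, r$gene)]
    v[is.na(v)] <- 1
    v
  })
  ratios <- matrix(ratios, nrow = length(genes),
                   dimnames = list(NULL, paste0("ratio.", srcs)))
  rs <- apply(ratios, 1L, order_statistic_score)
  ord <- order(rs, genes, method = "radix")
  keep <- ord[seq_len(min(top_n, length(genes)))]
  out <- data.frame(gene = genes[keep], ratios[keep, , drop = FALSE],
                    rs = rs[keep], rank = seq_along(keep),
                    stringsAsFactors = FALSE, check.names = FALSE)
  rownames(out) <- NULL
  class(out) <- c("hf_combined_ranking", "data.frame")
  out
}
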