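## common container for simple test results
.stat_result <- function(statistic, value, p, n) {
  structure(list(statistic = statistic, value = unname(value),
                 p = unname(p), n = n),
            class = "hf_stat")
}

#' @export
print.hf_stat <- function(x, ...) {
  cat(sprintf("%s = %.4g, P = %.3g (n = %s)\n", x$statistic, x$value, x$p,
              paste(x$n, collapse = " + ")))
  invisible(x)
}

#' Two-sample t test
#'
#' Student's t with pooled variance by default (Welch available by flag);
#' two-sided P. The sign convention is first sample minus second: a positive
#' t means `x` has the larger mean. Degenerate data (zero variance in both
#' samples with equal means) return t = 0, P = 1 with a warning.
#'
#' @param x,y numeric samples of length >= 2.
#' @param variance `"pooled"` or `"welch"`.
#' @return an `hf_stat` (statistic `"t"`, two-sided `p`, `n` = both sizes).
#' @examples
#' two_sample_t(c(1, 2, 3), c(4, 5, 6))
#' @export
two_sample_t <- function(x, y, variance = c("pooled", "welch")) {
  variance <- match.arg(variance)
  x <- as.numeric(x[!is.na(x)])
  y <- as.numeric(y[!is.na(y)])
  if (length(x) < 2 || length(y) < 2) stop("both samples need at least 2 values")
  if (stats::var(x) == 0 && stats::var(y) == 0) {
    if (mean(x) == mean(y)) {
      warning("both samples constant and equal; t = 0, P = 1")
      return(.stat_result("t", 0, 1, c(length(x), length(y))))
    }
    stop("both samples are constant with different means; t is undefined")
  }
  ht <- stats::t.test(x, y, var.equal = (variance == "pooled"),
                      alternative = "two.sided")
  .stat_result("t", ht$statistic, ht$p.value, c(length(x), length(y)))
}

#' Pearson correlation with two-sided P
#'
#' Product-moment correlation; P from the t transform with n - 2 degrees of
#' freedom.
#'
#' @param x,y numeric vectors of equal length >= 3 with non-zero variance.
#' @return an `hf_stat` (statistic `"r_pearson"`).
#' @export
cor_pearson <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- as.numeric(x[ok])
  y <- as.numeric(y[ok])
  if (length(x) < 3) stop("need at least 3 complete pairs")
  if (stats::var(x) == 0 || stats::var(y) == 0) stop("zero variance; correlation undefined")
  ht <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  .stat_result("r_pearson", ht$estimate, ht$p.value, length(x))
}

#' Spearman rank correlation with two-sided P
#'
#' Defined as the Pearson correlation of mid-ranks (average ranks for ties),
#' with P from the same t transform. For data with many ties this mid-rank
#' definition is the quantity reported.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return an `hf_stat` (statistic `"r_spearman"`).
#' @export
cor_spearman <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- as.numeric(x[ok])
  y <- as.numeric(y[ok])
  if (length(x) < 3) stop("need at least 3 complete pairs")
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  if (stats::var(rx) == 0 || stats::var(ry) == 0) stop("zero rank variance; correlation undefined")
  res <- cor_pearson(rx, ry)
  res$statistic <- "r_spearman"
  res
}

#' Biomarker-versus-rest centrality contrast
#'
#' Tests whether known biomarkers have higher degree and higher traffic than
#' the remaining network nodes (two two-sample tests; positive t means
#' biomarkers larger).
#'
#' @param centrality an `hf_centrality` table.
#' @param biomarkers character vector of biomarker symbols (normalized).
#' @param variance variance rule passed to [two_sample_t()].
#' @return list with elements `degree` and `traffic`, each an `hf_stat`, and
#'   `n_biomarkers_in_network`.
#' @export
biomarker_centrality_contrast <- function(centrality, biomarkers,
                                          variance = c("pooled", "welch")) {
  variance <- match.arg(variance)
  ct <- as.data.frame(centrality)
  bm <- unique(normalize_symbol(
    if (inherits(biomarkers, "hf_seed_set")) biomarkers$biomarkers else biomarkers))
  is_bm <- ct$symbol %in% bm
  if (!any(is_bm)) stop("no biomarker is present in the centrality table")
  if (sum(is_bm) < 2 || sum(!is_bm) < 2) {
    stop("need at least 2 biomarkers and 2 non-biomarkers in the network")
  }
  list(degree = two_sample_t(ct$degree[is_bm], ct$degree[!is_bm], variance),
       traffic = two_sample_t(ct$traffic[is_bm], ct$traffic[!is_bm], variance),
       n_biomarkers_in_network = sum(is_bm))
}
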