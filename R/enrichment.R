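#' Read gene sets in GMT format
#'
#' One term per line: term id, description, then member genes, tab-separated.
#' Duplicate term ids are merged (set union) with a warning. Gene symbols are
#' normalized with the same rule as network nodes.
#'
#' @param path GMT file path.
#' @param category annotation category label attached to every term, e.g.
#'   `"BP"`, `"CC"`, `"TF"`, `"miRNA"`.
#' @param alias optional alias map for [normalize_symbol()].
#' @return object of class `hf_term_map`: data.frame with columns `term`,
#'   `name`, `category` and list-column `genes`.
#' @export
read_gmt <- function(path, category = "BP", alias = NULL) {
  if (!file.exists(path)) stop("GMT file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- which(nzchar(trimws(lines)))
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3L)
  if (length(bad)) {
    stop("GMT line(s) with fewer than 3 fields in ", path, " at line(s): ",
         paste(keep[bad], collapse = ", "))
  }
  term <- vapply(fields, `[`, character(1), 1L)
  name <- vapply(fields, `[`, character(1), 2L)
  genes <- lapply(fields, function(f) {
    g <- unique(normalize_symbol(f[-(1:2)], alias))
    g[nzchar(g)]
  })
  if (any(!lengths(genes))) stop("GMT term(s) with empty gene set in ", path)
  if (anyDuplicated(term)) {
    warning("duplicate GMT term id(s) merged: ",
            paste(unique(term[duplicated(term)]), collapse = ", "))
    idx <- split(seq_along(term), term)[unique(term)]
    genes <- unname(lapply(idx, function(i)
      sort(unique(unlist(genes[i])), method = "radix")))
    name <- name[vapply(idx, `[`, integer(1), 1L)]
    term <- unique(term)
  } else {
    genes <- lapply(genes, sort, method = "radix")
  }
  term_map(term, name, genes, category)
}

#' Construct a term map
#'
#' @param term character term ids.
#' @param name character term descriptions.
#' @param genes list of character gene sets (non-empty).
#' @param category category label(s), recycled.
#' @return an `hf_term_map` data.frame.
#' @export
term_map <- function(term, name, genes, category = "BP") {
  stopifnot(length(term) == length(genes), all(lengths(genes) > 0))
  out <- data.frame(term = as.character(term), name = as.character(name),
                    category = rep_len(as.character(category), length(term)),
                    stringsAsFactors = FALSE)
  out$genes <- lapply(genes, function(g) sort(unique(as.character(g)), method = "radix"))
  class(out) <- c("hf_term_map", "data.frame")
  out
}

#' @export
print.hf_term_map <- function(x, ...) {
  cat(sprintf("hf_term_map: %d terms (%s); set sizes %d-%d\n",
              nrow(x), paste(unique(x$category), collapse = ", "),
              if (nrow(x)) min(lengths(x$genes)) else 0L,
              if (nrow(x)) max(lengths(x$genes)) else 0L))
  invisible(x)
}

#' Write a term map in GMT format
#'
#' @param tm an `hf_term_map`.
#' @param path output path.
#' @export
write_gmt <- function(tm, path) {
  lines <- vapply(seq_len(nrow(tm)), function(i) {
    paste(c(tm$term[i], tm$name[i], tm$genes[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Combine term maps of several categories
#'
#' @param ... `hf_term_map` objects.
#' @return a single `hf_term_map`.
#' @export
combine_term_maps <- function(...) {
  parts <- list(...)
  if (length(parts) == 1L && is.list(parts[[1]]) && !inherits(parts[[1]], "data.frame")) {
    parts <- parts[[1]]
  }
  out <- do.call(rbind, lapply(parts, as.data.frame))
  class(out) <- c("hf_term_map", "data.frame")
  rownames(out) <- NULL
  out
}

#' Two-tailed Fisher exact P value for a 2x2 table
#'
#' Tests association in the table \{\{a, b\}, \{c, d\}\}. The two-tailed P is
#' the sum, over all tables with the observed margins, of the hypergeometric
#' point probabilities not exceeding that of the observed table. Degenerate
#' tables (a zero margin) return P = 1.
#'
#' @param a,b,c,d non-negative integer counts (typically: annotated in
#'   module, unannotated in module, annotated outside, unannotated outside).
#' @return numeric P value.
#' @examples
#' fisher_exact_p(3, 2, 2, 43)
#' @export
fisher_exact_p <- function(a, b, c, d) {
  counts <- c(a, b, c, d)
  if (any(counts < 0)) stop("negative count in 2x2 table")
  if (any(counts != round(counts))) stop("non-integer count in 2x2 table")
  tab <- matrix(as.integer(round(counts)), 2, 2, byrow = TRUE)
  if (any(rowSums(tab) == 0L) || any(colSums(tab) == 0L)) return(1)
  stats::fisher.test(tab, alternative = "two.sided")$p.value
}

#' Benjamini-Hochberg adjusted P values
#'
#' Step-up false-discovery-rate adjustment: values are returned in input
#' order, each adjusted value is at least the raw value and at most 1, and
#' the adjustment is monotone in the sorted order.
#'
#' @param p numeric vector of raw P values in \[0, 1\].
#' @return numeric vector of adjusted values, same order as the input.
#' @export
bh_adjust <- function(p) {
  p <- as.numeric(p)
  if (any(is.na(p)) || any(p < 0 | p > 1)) stop("P values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Module gene-set overrepresentation
#'
#' For every (module, term) pair with at least one annotated module gene, a
#' 2x2 table is built against the background universe and tested with a
#' two-tailed Fisher exact test; BH adjustment is applied within each
#' (module, category) family by default, or across all records with
#' `family = "global"`. The default background is the analysed network's
#' gene set; a wider annotation universe may be supplied.
#'
#' @param partition an `hf_partition` or named membership vector.
#' @param tm an `hf_term_map`.
#' @param background character vector of background genes; must contain all
#'   module genes. Default: the genes of the partition.
#' @param alpha significance level applied to the adjusted P values.
#' @param family `"module-category"` (default) or `"global"` BH family.
#' @return data.frame of class `hf_enrichment` with columns `module`,
#'   `category`, `term`, `name`, `a`, `b`, `c`, `d`, `p_raw`, `p_adj`,
#'   `significant`, sorted by module, category, `p_adj`.
#' @export
enrich_modules <- function(partition, tm, background = NULL, alpha = 0.05,
                           family = c("module-category", "global")) {
  family <- match.arg(family)
  memb <- if (inherits(partition, "hf_partition")) partition$membership else partition
  if (is.null(names(memb))) stop("membership must be named by gene symbol")
  stopifnot(inherits(tm, "data.frame"), alpha > 0, alpha < 1)
  if (is.null(background)) background <- names(memb)
  background <- unique(normalize_symbol(background))
  if (!length(background)) stop("empty background universe")
  out_mod <- setdiff(names(memb), background)
  if (length(out_mod)) {
    stop("background does not contain module gene(s): ",
         paste(utils::head(out_mod, 5), collapse = ", "))
  }
  n_bg <- length(background)
  term_sets <- lapply(tm$genes, intersect, y = background)
  rows <- list()
  for (mod in sort(unique(memb))) {
    mod_genes <- intersect(names(memb)[memb == mod], background)
    n_mod <- length(mod_genes)
    any_term <- FALSE
    for (ti in seq_len(nrow(tm))) {
      tg <- term_sets[[ti]]
      a <- length(intersect(mod_genes, tg))
      if (a == 0L) next
      any_term <- TRUE
      b <- n_mod - a
      c <- length(tg) - a
      d <- n_bg - n_mod - c
      rows[[length(rows) + 1L]] <- data.frame(
        module = mod, category = tm$category[ti], term = tm$term[ti],
        name = tm$name[ti], a = a, b = b, c = c, d = d,
        p_raw = fisher_exact_p(a, b, c, d), stringsAsFactors = FALSE)
    }
    if (!any_term) message("module ", mod, " has no annotated genes; no records")
  }
  if (!length(rows)) {
    out <- data.frame(module = integer(), category = character(),
                      term = character(), name = character(),
                      a = integer(), b = integer(), c = integer(), d = integer(),
                      p_raw = numeric(), p_adj = numeric(),
                      significant = logical(), stringsAsFactors = FALSE)
    class(out) <- c("hf_enrichment", "data.frame")
    return(out)
  }
  out <- do.call(rbind, rows)
  fam <- if (family == "global") rep(1L, nrow(out)) else
    interaction(out$module, out$category, drop = TRUE)
  out$p_adj <- stats::ave(out$p_raw, fam, FUN = bh_adjust)
  out$significant <- out$p_adj <= alpha
  out <- out[order(out$module, out$category, out$p_adj, out$term,
                   method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("hf_enrichment", "data.frame")
  out
}

#' Per-module top terms
#'
#' Extracts, for each module and category, the most significant term — the
#' shape of a module-overview table (top biological process, top cellular
#' component, ...).
#'
#' @param enrichment an `hf_enrichment` table.
#' @return data.frame with one row per (module, category): `module`,
#'   `category`, `term`, `name`, `p_adj`, `significant`.
#' @export
summarize_enrichment <- function(enrichment) {
  e <- as.data.frame(enrichment)
  if (!nrow(e)) return(e)
  key <- interaction(e$module, e$category, drop = TRUE)
  first <- !duplicated(key)  # already sorted by p_adj within module/category
  out <- e[first, c("module", "category", "term", "name", "p_adj", "significant")]
  rownames(out) <- NULL
  out
}
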