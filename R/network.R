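#' Normalize a gene/protein symbol
#'
#' Symbols are upper-cased and stripped of surrounding whitespace so that
#' identifiers from different interaction databases and seed lists meet on a
#' common form. Normalization is idempotent. An optional two-column alias map
#' (alias, canonical) is applied after case folding.
#'
#' @param x character vector of raw symbols.
#' @param alias optional named character vector mapping alias -> canonical
#'   symbol (both sides are normalized before matching), or `NULL`.
#' @return character vector of normalized symbols.
#' @examples
#' normalize_symbol(c(" fn1", "Itgb1 "))
#' @export
normalize_symbol <- function(x, alias = NULL) {
  out <- toupper(trimws(as.character(x)))
  if (!is.null(alias)) {
    key <- toupper(trimws(names(alias)))
    val <- toupper(trimws(as.character(alias)))
    hit <- match(out, key)
    out[!is.na(hit)] <- val[hit[!is.na(hit)]]
  }
  out
}

## canonical unordered pair: a < b by C-locale string comparison
.canon_pairs <- function(a, b) {
  swap <- a > b
  tmp <- a[swap]
  a[swap] <- b[swap]
  b[swap] <- tmp
  list(a = a, b = b)
}

.join_sources <- function(x) {
  paste(sort(unique(unlist(strsplit(x, ",", fixed = TRUE)))), collapse = ",")
}

#' Construct a protein-protein interaction network
#'
#' A simple undirected graph over protein symbols: no self-loops, no
#' multi-edges, per-edge provenance (comma-joined source database labels).
#' Edges are stored canonically (endpoint `a` < endpoint `b`, rows sorted),
#' so identical inputs always produce byte-identical objects.
#'
#' @param edges data.frame with character columns `a`, `b` and optionally
#'   `sources`. Duplicate unordered pairs are collapsed, merging their sources.
#' @param nodes optional character vector of node symbols; must contain all
#'   edge endpoints. Extra entries become isolated nodes.
#' @return an object of class `hf_network` with elements `nodes` (sorted
#'   character), `edges` (canonical data.frame `a`, `b`, `sources`) and
#'   `n_edges`.
#' @examples
#' net <- hf_network(data.frame(a = c("B", "A"), b = c("A", "C")))
#' net$n_edges
#' @export
hf_network <- function(edges, nodes = NULL) {
  if (is.null(edges) || nrow(as.data.frame(edges)) == 0L) {
    edges <- data.frame(a = character(), b = character(),
                        sources = character(), stringsAsFactors = FALSE)
  }
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  stopifnot(all(c("a", "b") %in% names(edges)))
  a <- as.character(edges$a)
  b <- as.character(edges$b)
  if (any(a == "" | b == "")) stop("empty symbol in edge list")
  src <- if ("sources" %in% names(edges)) as.character(edges$sources) else
    rep("unspecified", length(a))
  if (any(a == b)) stop("self-interactions are not allowed in hf_network; drop them upstream")
  cp <- .canon_pairs(a, b)
  key <- paste(cp$a, cp$b, sep = "\t")
  if (anyDuplicated(key)) {
    src <- vapply(split(src, key), .join_sources, character(1))
    first <- !duplicated(key)
    ord_key <- key[first]
    df <- data.frame(a = cp$a[first], b = cp$b[first],
                     sources = as.character(src[ord_key]),
                     stringsAsFactors = FALSE)
  } else {
    df <- data.frame(a = cp$a, b = cp$b,
                     sources = vapply(src, .join_sources, character(1), USE.NAMES = FALSE),
                     stringsAsFactors = FALSE)
  }
  df <- df[order(df$a, df$b, method = "radix"), , drop = FALSE]
  rownames(df) <- NULL
  nd <- sort(unique(c(df$a, df$b, as.character(nodes))), method = "radix")
  structure(list(nodes = nd, edges = df, n_edges = nrow(df)),
            class = "hf_network")
}

#' @export
print.hf_network <- function(x, ...) {
  cat(sprintf("hf_network: %d nodes, %d edges\n", length(x$nodes), x$n_edges))
  if (x$n_edges > 0) {
    srcs <- sort(unique(unlist(strsplit(x$edges$sources, ",", fixed = TRUE))))
    cat("  sources:", paste(srcs, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
summary.hf_network <- function(object, ...) {
  deg <- node_degrees(object)
  cat(sprintf("hf_network: %d nodes, %d edges\n", length(object$nodes), object$n_edges))
  cat(sprintf("  degree: min %d, median %.1f, max %d; isolated nodes: %d\n",
              if (length(deg)) min(deg) else 0L, stats::median(deg),
              if (length(deg)) max(deg) else 0L, sum(deg == 0L)))
  invisible(object)
}

#' Per-node degrees
#'
#' @param network an `hf_network`.
#' @return named integer vector over all nodes (isolated nodes have degree 0).
#' @export
node_degrees <- function(network) {
  stopifnot(inherits(network, "hf_network"))
  deg <- integer(length(network$nodes))
  names(deg) <- network$nodes
  if (network$n_edges > 0) {
    tab <- table(c(network$edges$a, network$edges$b))
    deg[names(tab)] <- as.integer(tab)
  }
  deg
}

## adjacency list of integer node indices (1-based into network$nodes)
.adjacency <- function(network) {
  n <- length(network$nodes)
  adj <- vector("list", n)
  for (i in seq_len(n)) adj[[i]] <- integer()
  if (network$n_edges > 0) {
    ia <- match(network$edges$a, network$nodes)
    ib <- match(network$edges$b, network$nodes)
    adj <- split(c(ib, ia), factor(c(ia, ib), levels = seq_len(n)))
    adj <- lapply(adj, function(v) sort(unname(v)))
  }
  adj
}

#' Read an interaction table
#'
#' Parses a tab-separated edge list (columns: protein A, protein B, optional
#' source database label). A header row is detected when the first two fields
#' look like column labels (`protein`, `gene`, `symbol`, `interactor`, `node`,
#' `a`, `b`, optionally suffixed). Self-pairs are dropped (counted in the
#' `n_self_dropped` attribute and reported); within-file duplicate unordered
#' pairs are collapsed. Malformed rows are a hard error naming the line.
#'
#' @param path path to a TSV file.
#' @param source default source label for rows lacking a third column;
#'   defaults to the file name without extension.
#' @param alias optional alias map passed to [normalize_symbol()].
#' @return data.frame (`a`, `b`, `sources`) of unique normalized interactions,
#'   with attributes `n_self_dropped` and `self_pairs`.
#' @export
read_interactions <- function(path, source = NULL, alias = NULL) {
  if (!file.exists(path)) stop("interaction file not found: ", path)
  if (is.null(source)) source <- sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path, warn = FALSE)
  lines_keep <- which(nzchar(trimws(lines)) & !startsWith(trimws(lines), "#"))
  if (!length(lines_keep)) stop("no interaction rows in ", path)
  fields <- strsplit(lines[lines_keep], "\t", fixed = TRUE)
  is_header <- function(f) {
    if (length(f) < 2) return(FALSE)
    lab <- tolower(trimws(f[1:2]))
    all(grepl("^(protein|gene|symbol|interactor|node|source|from|to)([._ ]?[ab12])?$", lab))
  }
  if (is_header(fields[[1]])) {
    fields <- fields[-1]
    lines_keep <- lines_keep[-1]
  }
  if (!length(fields)) stop("no interaction rows in ", path)
  bad <- which(vapply(fields, function(f) length(f) < 2 ||
                        !nzchar(trimws(f[1])) || !nzchar(trimws(f[2])), logical(1)))
  if (length(bad)) {
    stop("malformed interaction row(s) in ", path, " at line(s): ",
         paste(lines_keep[bad], collapse = ", "),
         " (need two non-empty tab-separated symbols)")
  }
  a <- normalize_symbol(vapply(fields, `[`, character(1), 1L), alias)
  b <- normalize_symbol(vapply(fields, `[`, character(1), 2L), alias)
  src <- vapply(fields, function(f)
    if (length(f) >= 3 && nzchar(trimws(f[3]))) trimws(f[3]) else source, character(1))
  self <- a == b
  if (any(self)) {
    message(sum(self), " self-pair(s) dropped from ", basename(path), ": ",
            paste(unique(a[self]), collapse = ", "))
  }
  df <- data.frame(a = a[!self], b = b[!self], sources = src[!self],
                   stringsAsFactors = FALSE)
  if (!nrow(df)) stop("no usable (non-self) interactions in ", path)
  net <- hf_network(df)  # within-file dedup via the canonical constructor
  out <- net$edges
  attr(out, "n_self_dropped") <- sum(self)
  attr(out, "self_pairs") <- unique(a[self])
  out
}

#' Merge interaction tables as a union
#'
#' Combines database-specific interaction sets into one integrated network:
#' the edge set is the union of the per-table unordered pairs, and duplicated
#' pairs merge their source labels. The merge is idempotent.
#'
#' @param tables list of interaction data.frames (from [read_interactions()])
#'   and/or `hf_network` objects.
#' @return an `hf_network`.
#' @examples
#' t1 <- data.frame(a = "A", b = "B", sources = "db1")
#' t2 <- data.frame(a = "B", b = "A", sources = "db2")
#' merge_union(list(t1, t2))$edges$sources
#' @export
merge_union <- function(tables) {
  if (!is.list(tables) || !length(tables)) stop("need at least one interaction table")
  dfs <- lapply(tables, function(t) {
    if (inherits(t, "hf_network")) t$edges else as.data.frame(t, stringsAsFactors = FALSE)
  })
  all_df <- do.call(rbind, dfs)
  if (is.null(all_df) || !nrow(all_df)) stop("union of interaction tables is empty")
  hf_network(all_df)
}

#' Construct a seed set
#'
#' The network seeds are the union of known biomarkers and candidate genes
#' (candidates may re-encode known biomarkers; the union de-duplicates them).
#'
#' @param biomarkers character vector of known biomarker symbols.
#' @param candidates character vector of candidate symbols.
#' @param alias optional alias map passed to [normalize_symbol()].
#' @return object of class `hf_seed_set` with elements `biomarkers`,
#'   `candidates`, `seeds` (the union).
#' @export
seed_set <- function(biomarkers, candidates = character(), alias = NULL) {
  bm <- unique(normalize_symbol(biomarkers, alias))
  cd <- unique(normalize_symbol(candidates, alias))
  bm <- bm[nzchar(bm)]
  cd <- cd[nzchar(cd)]
  structure(list(biomarkers = sort(bm, method = "radix"),
                 candidates = sort(cd, method = "radix"),
                 seeds = sort(unique(c(bm, cd)), method = "radix")),
            class = "hf_seed_set")
}

#' @export
print.hf_seed_set <- function(x, ...) {
  cat(sprintf("hf_seed_set: %d biomarkers, %d candidates, %d seeds (union)\n",
              length(x$biomarkers), length(x$candidates), length(x$seeds)))
  invisible(x)
}

#' Read a seed list
#'
#' One symbol per line; blank lines and `#` comments ignored.
#'
#' @param path file path.
#' @param alias optional alias map.
#' @return character vector of normalized symbols.
#' @export
read_seeds <- function(path, alias = NULL) {
  if (!file.exists(path)) stop("seed file not found: ", path)
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  unique(normalize_symbol(lines, alias))
}

#' Seed-centred subnetwork
#'
#' Restricts a network to the seeds and their first-level interaction
#' partners. In `"induced"` mode (default) all edges among that node set are
#' kept, so neighbour-neighbour edges survive; in `"seed-incident"` mode only
#' edges touching at least one seed are kept. Seeds absent from the network
#' are reported (attribute `missing_seeds`), not fatal; it is an error if no
#' seed is present at all.
#'
#' @param network an `hf_network`.
#' @param seeds an `hf_seed_set` or character vector of symbols.
#' @param mode `"induced"` or `"seed-incident"`.
#' @return an `hf_network` with attributes `missing_seeds` and
#'   `isolated_seeds` (seeds present but without partners in the result).
#' @export
seed_subnetwork <- function(network, seeds, mode = c("induced", "seed-incident")) {
  mode <- match.arg(mode)
  stopifnot(inherits(network, "hf_network"))
  sy <- if (inherits(seeds, "hf_seed_set")) seeds$seeds else
    unique(normalize_symbol(seeds))
  if (!length(sy)) stop("seed set is empty")
  present <- sy[sy %in% network$nodes]
  missing <- setdiff(sy, present)
  if (!length(present)) stop("no seed is present in the network")
  if (length(missing)) {
    message(length(missing), " seed(s) absent from the network: ",
            paste(utils::head(missing, 10), collapse = ", "),
            if (length(missing) > 10) ", ..." else "")
  }
  e <- network$edges
  touch <- e$a %in% present | e$b %in% present
  keep_nodes <- sort(unique(c(present, e$a[touch], e$b[touch])), method = "radix")
  keep <- if (mode == "induced") (e$a %in% keep_nodes & e$b %in% keep_nodes) else touch
  sub <- hf_network(e[keep, , drop = FALSE], nodes = keep_nodes)
  iso <- intersect(present, sub$nodes[node_degrees(sub) == 0L])
  if (length(iso)) {
    message(length(iso), " seed(s) have no partners in the subnetwork: ",
            paste(iso, collapse = ", "))
  }
  attr(sub, "missing_seeds") <- missing
  attr(sub, "isolated_seeds") <- iso
  sub
}

#' Decompose a network into core and islands
#'
#' Finds connected components. The largest is the "core network"; remaining
#' components with at least 2 nodes are "islands"; isolated nodes are recorded
#' separately. Ties for the core are broken by node count, then edge count,
#' then lexicographically smallest member.
#'
#' @param network an `hf_network`.
#' @return object of class `hf_decomposition` with elements `core`
#'   (`hf_network`), `islands` (list of `hf_network`, ordered by decreasing
#'   size then smallest member), `singletons` (character vector) and
#'   `membership` (named integer component ids over all nodes).
#' @export
decompose_components <- function(network) {
  stopifnot(inherits(network, "hf_network"))
  n <- length(network$nodes)
  if (n == 0L) stop("empty network")
  adj <- .adjacency(network)
  comp <- integer(n)
  cid <- 0L
  for (s in seq_len(n)) {
    if (comp[s]) next
    cid <- cid + 1L
    queue <- s
    comp[s] <- cid
    while (length(queue)) {
      v <- queue[[1]]
      queue <- queue[-1]
      nb <- adj[[v]]
      new <- nb[comp[nb] == 0L]
      comp[new] <- cid
      queue <- c(queue, new)
    }
  }
  names(comp) <- network$nodes
  e <- network$edges
  ecomp <- comp[e$a]
  sizes <- tabulate(comp, nbins = cid)
  edge_counts <- tabulate(ecomp, nbins = cid)
  first_member <- vapply(seq_len(cid), function(i) network$nodes[match(i, comp)],
                         character(1))
  ord <- order(-sizes, -edge_counts, first_member, method = "radix")
  comp_net <- function(i) {
    nodes_i <- network$nodes[comp == i]
    hf_network(e[ecomp == i, , drop = FALSE], nodes = nodes_i)
  }
  core_id <- ord[1]
  rest <- ord[-1]
  island_ids <- rest[sizes[rest] >= 2L]
  singleton_ids <- rest[sizes[rest] < 2L]
  structure(list(core = comp_net(core_id),
                 islands = lapply(island_ids, comp_net),
                 singletons = sort(network$nodes[comp %in% singleton_ids],
                                   method = "radix"),
                 membership = comp),
            class = "hf_decomposition")
}

#' @export
print.hf_decomposition <- function(x, ...) {
  cat(sprintf("core network: %d nodes, %d edges\n",
              length(x$core$nodes), x$core$n_edges))
  cat(sprintf("islands: %d (sizes: %s); isolated nodes: %d\n",
              length(x$islands),
              paste(vapply(x$islands, function(i) length(i$nodes), integer(1)),
                    collapse = ", "),
              length(x$singletons)))
  invisible(x)
}

#' Write a network as a canonical edge-list TSV
#'
#' Endpoints are already canonical (a < b) and rows sorted, so repeated runs
#' on identical inputs are byte-identical.
#'
#' @param network an `hf_network`.
#' @param path output path.
#' @export
write_network <- function(network, path) {
  stopifnot(inherits(network, "hf_network"))
  utils::write.table(network$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Convert to an igraph object
#'
#' Convenience export for visualization tools (requires the igraph package).
#'
#' @param network an `hf_network`.
#' @return an igraph undirected graph with a `sources` edge attribute.
#' @export
as_igraph <- function(network) {
  stopifnot(inherits(network, "hf_network"))
  if (!requireNamespace("igraph", quietly = TRUE)) {
    stop("the igraph package is required for as_igraph()")
  }
  g <- igraph::graph_from_data_frame(network$edges[, c("a", "b")],
                                     directed = FALSE,
                                     vertices = network$nodes)
  igraph::E(g)$sources <- network$edges$sources
  g
}
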