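#' Run the full network analysis pipeline
#'
#' Orchestrates assembly, topology, module detection, enrichment,
#' association statistics and (optionally) expression classification from a
#' single configuration, writing one artifact file per stage so any stage's
#' output can be inspected or re-used. Stages run in order; a failure stops
#' the run naming the stage; artifacts written before the failure are kept.
#'
#' Configuration entries (R list, or a YAML file path; unset entries take
#' the defaults shown and every value actually used is echoed in the
#' report):
#' \describe{
#'   \item{edge_files / network}{paths to interaction TSVs, or an
#'     `hf_network` (one of the two is required).}
#'   \item{biomarker_file, candidate_file / seeds}{seed list paths, or an
#'     `hf_seed_set`. Optional: without seeds the full merged network is
#'     analysed.}
#'   \item{mode}{subnetwork mode, `"induced"` (default) or
#'     `"seed-incident"`.}
#'   \item{traffic_scale}{multiplier on traffic values (default 1).}
#'   \item{variance}{t-test variance rule, `"pooled"` (default) or
#'     `"welch"`.}
#'   \item{alpha}{significance level (default 0.05).}
#'   \item{bh_family}{`"module-category"` (default) or `"global"`.}
#'   \item{gmt_files}{named list category -> GMT path, or `term_map` an
#'     `hf_term_map`. Optional.}
#'   \item{background}{`"core"` (default: core-network genes) or a file of
#'     symbols.}
#'   \item{expression / expression_file + labels_file}{an `hf_expression`
#'     or paths (expression TSV: gene column then samples; labels TSV:
#'     sample, class). Optional.}
#'   \item{panel}{genes for the classification stage, or `"top-traffic"`
#'     (default) to use the top `top_k` high-traffic genes present in the
#'     expression matrix.}
#'   \item{top_k}{size of the high-traffic ranking (default 20).}
#'   \item{out_dir}{artifact directory; `NULL` disables writing.}
#' }
#'
#' @param config R list or path to a YAML file.
#' @return object of class `hf_report`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("config file not found: ", config)
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("the yaml package is required to read a YAML config")
    }
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  cfg <- utils::modifyList(
    list(edge_files = NULL, network = NULL, biomarker_file = NULL,
         candidate_file = NULL, seeds = NULL, mode = "induced",
         traffic_scale = 1, variance = "pooled", alpha = 0.05,
         bh_family = "module-category", gmt_files = NULL, term_map = NULL,
         background = "core", expression = NULL, expression_file = NULL,
         labels_file = NULL, panel = "top-traffic", top_k = 20L,
         out_dir = NULL),
    config)
  if (!(cfg$alpha > 0 && cfg$alpha < 1)) stop("alpha must lie in (0, 1)")
  for (f in c(cfg$edge_files, cfg$biomarker_file, cfg$candidate_file,
              unlist(cfg$gmt_files), cfg$expression_file, cfg$labels_file)) {
    if (is.character(f) && !file.exists(f)) stop("configured path missing: ", f)
  }
  out_dir <- cfg$out_dir
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  emit <- function(df, file) {
    if (!is.null(out_dir)) {
      utils::write.table(df, file.path(out_dir, file), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    }
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  ## --- assemble ---------------------------------------------------------
  res <- stage("assemble", {
    net <- if (!is.null(cfg$network)) cfg$network else
      merge_union(lapply(cfg$edge_files, read_interactions))
    seeds <- cfg$seeds
    if (is.null(seeds) && !is.null(cfg$biomarker_file)) {
      seeds <- seed_set(read_seeds(cfg$biomarker_file),
                        if (!is.null(cfg$candidate_file))
                          read_seeds(cfg$candidate_file) else character())
    }
    sub <- if (!is.null(seeds)) seed_subnetwork(net, seeds, cfg$mode) else net
    list(global = sub, seeds = seeds, decomposition = decompose_components(sub))
  })
  core <- res$decomposition$core
  emit(core$edges, "core_edges.tsv")

  ## --- topology ---------------------------------------------------------
  topo <- stage("topology", {
    ct <- node_centrality(core, traffic_scale = cfg$traffic_scale)
    dd <- degree_distribution(core)
    fit <- tryCatch(fit_power_law(dd), error = function(e) NULL)
    list(centrality = ct, degree_dist = dd, powerlaw = fit,
         top_traffic = top_nodes(ct, "traffic", min(cfg$top_k, nrow(ct))))
  })
  emit(topo$centrality, "centrality.tsv")
  emit(topo$degree_dist, "degree_distribution.tsv")

  ## --- modules ----------------------------------------------------------
  mods <- stage("modules", {
    part <- greedy_modules(core)
    prof <- profile_modules(core, part, topo$centrality)
    list(partition = part, profiles = prof)
  })
  emit(data.frame(symbol = names(mods$partition$membership),
                  module = unname(mods$partition$membership)),
       "partition.tsv")
  emit(mods$profiles, "module_profiles.tsv")

  ## --- enrichment (optional) -------------------------------------------
  enr <- NULL
  tm <- cfg$term_map
  if (is.null(tm) && !is.null(cfg$gmt_files)) {
    tm <- combine_term_maps(lapply(names(cfg$gmt_files), function(cat)
      read_gmt(cfg$gmt_files[[cat]], category = cat)))
  }
  if (!is.null(tm)) {
    enr <- stage("enrichment", {
      bg <- if (identical(cfg$background, "core")) core$nodes else
        read_seeds(cfg$background)
      enrich_modules(mods$partition, tm, background = bg,
                     alpha = cfg$alpha, family = cfg$bh_family)
    })
    emit(enr[, setdiff(names(enr), "genes")], "enrichment.tsv")
  }

  ## --- association statistics ------------------------------------------
  assoc <- stage("stats", {
    ct <- topo$centrality
    out <- list(degree_traffic = cor_pearson(ct$degree, ct$traffic),
                imi_traffic = if (nrow(mods$profiles) >= 3)
                  cor_pearson(mods$profiles$n_imi, mods$profiles$median_traffic)
                else NULL)
    if (!is.null(res$seeds) && length(res$seeds$biomarkers)) {
      out$biomarker_contrast <- biomarker_centrality_contrast(
        ct, res$seeds$biomarkers, variance = cfg$variance)
    }
    out
  })

  ## --- expression classification (optional) ----------------------------
  cls <- NULL
  expr <- cfg$expression
  if (is.null(expr) && !is.null(cfg$expression_file)) {
    expr <- stage("expression-load", {
      vals <- utils::read.table(cfg$expression_file, sep = "\t", header = TRUE,
                                row.names = 1L, check.names = FALSE)
      lab <- utils::read.table(cfg$labels_file, sep = "\t", header = FALSE,
                               stringsAsFactors = FALSE,
                               col.names = c("sample", "class"))
      expression_matrix(as.matrix(vals),
                        stats::setNames(lab$class, lab$sample))
    })
  }
  if (!is.null(expr)) {
    cls <- stage("classify", {
      panel <- cfg$panel
      if (identical(panel, "top-traffic")) {
        panel <- topo$top_traffic$symbol
      }
      de <- differential_expression(expr, panel, alpha = cfg$alpha,
                                    variance = cfg$variance)
      present <- intersect(normalize_symbol(panel), rownames(expr$values))
      loo <- if (length(present) >= 1) loo_linear_classify(expr, present) else NULL
      list(de = de, loo = loo)
    })
    emit(cls$de, "differential_expression.tsv")
  }

  report <- structure(
    list(config = cfg[!vapply(cfg, is.null, logical(1))],
         network = list(
           n_nodes = length(res$global$nodes), n_edges = res$global$n_edges,
           core_nodes = length(core$nodes), core_edges = core$n_edges,
           n_islands = length(res$decomposition$islands),
           island_sizes = vapply(res$decomposition$islands,
                                 function(i) length(i$nodes), integer(1)),
           n_singletons = length(res$decomposition$singletons)),
         core = core,
         centrality = topo$centrality,
         degree_dist = topo$degree_dist,
         powerlaw = topo$powerlaw,
         top_traffic = topo$top_traffic,
         partition = mods$partition,
         profiles = mods$profiles,
         enrichment = enr,
         stats = assoc,
         classification = cls,
         reference_checks = reference_checks(),
         timestamp = format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
    class = "hf_report")
  if (!is.null(out_dir)) {
    writeLines(utils::capture.output(print(report)),
               file.path(out_dir, "report.txt"))
  }
  report
}

#' @export
print.hf_report <- function(x, ...) {
  nw <- x$network
  cat("== hfnet pipeline report ==\n")
  cat(sprintf("network: %d nodes, %d edges; core %d/%d; %d island(s) (%s), %d singleton(s)\n",
              nw$n_nodes, nw$n_edges, nw$core_nodes, nw$core_edges,
              nw$n_islands, paste(nw$island_sizes, collapse = ","),
              nw$n_singletons))
  if (!is.null(x$powerlaw)) {
    cat(sprintf("degree distribution: gamma = %.2f (R^2 = %.2f)\n",
                x$powerlaw$gamma, x$powerlaw$fit_quality))
  }
  cat(sprintf("modules: %d, Q = %.3f; sizes: %s\n", x$partition$n_modules,
              x$partition$Q,
              paste(sort(table(x$partition$membership), decreasing = TRUE),
                    collapse = ", ")))
  if (!is.null(x$stats$degree_traffic)) {
    cat(sprintf("degree-traffic correlation: r = %.2f (P = %.2g)\n",
                x$stats$degree_traffic$value, x$stats$degree_traffic$p))
  }
  if (!is.null(x$stats$imi_traffic)) {
    cat(sprintf("module IMI-traffic correlation: r = %.2f (P = %.2g)\n",
                x$stats$imi_traffic$value, x$stats$imi_traffic$p))
  }
  if (!is.null(x$stats$biomarker_contrast)) {
    bc <- x$stats$biomarker_contrast
    cat(sprintf("biomarkers vs rest: degree t = %.2f (P = %.2g); traffic t = %.2f (P = %.2g)\n",
                bc$degree$value, bc$degree$p, bc$traffic$value, bc$traffic$p))
  }
  if (!is.null(x$enrichment) && nrow(x$enrichment)) {
    cat(sprintf("enrichment: %d records, %d significant\n",
                nrow(x$enrichment), sum(x$enrichment$significant)))
  }
  if (!is.null(x$classification$loo)) {
    cat(sprintf("LOO classification: accuracy = %.1f%%, AUC = %.3f\n",
                100 * x$classification$loo$accuracy, x$classification$loo$auc))
  }
  rc <- x$reference_checks
  cat(sprintf("reference self-checks: core size %d; IMI-traffic r = %.2f; seed union %d\n",
              rc$core_size, rc$imi_traffic$value, rc$seed_union))
  invisible(x)
}
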