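#' Construct a two-class expression matrix
#'
#' Genes x samples expression values with a binary class label per sample
#' (e.g. heart failure vs non-failure after myocardial infarction).
#'
#' @param values numeric matrix, rows = genes (unique rownames), columns =
#'   samples (colnames).
#' @param labels class labels per sample: named character/factor or aligned
#'   with the columns; exactly 2 levels, both non-empty.
#' @param case_class which level is the "case" (positive) class for sign and
#'   ROC conventions; default `"HF"` when present, else the first level.
#' @return object of class `hf_expression`: list with `values`, `labels`
#'   (factor), `case_class`.
#' @export
expression_matrix <- function(values, labels, case_class = NULL) {
  values <- as.matrix(values)
  if (is.null(rownames(values)) || anyDuplicated(rownames(values))) {
    stop("expression matrix needs unique gene rownames")
  }
  if (is.null(colnames(values))) stop("expression matrix needs sample colnames")
  if (!is.null(names(labels))) {
    miss <- setdiff(colnames(values), names(labels))
    if (length(miss)) stop("unlabelled sample(s): ", paste(miss, collapse = ", "))
    labels <- labels[colnames(values)]
  } else if (length(labels) != ncol(values)) {
    stop("labels must cover every sample")
  }
  labels <- factor(as.character(labels))
  if (nlevels(labels) != 2L) stop("exactly two classes required")
  if (any(table(labels) == 0L)) stop("both classes must be non-empty")
  if (is.null(case_class)) {
    case_class <- if ("HF" %in% levels(labels)) "HF" else levels(labels)[1]
  }
  if (!case_class %in% levels(labels)) stop("case_class not among the labels")
  rownames(values) <- normalize_symbol(rownames(values))
  structure(list(values = values, labels = labels, case_class = case_class),
            class = "hf_expression")
}

#' @export
print.hf_expression <- function(x, ...) {
  tab <- table(x$labels)
  cat(sprintf("hf_expression: %d genes x %d samples (%s; case = %s)\n",
              nrow(x$values), ncol(x$values),
              paste(names(tab), as.integer(tab), sep = " = ", collapse = ", "),
              x$case_class))
  invisible(x)
}

#' Differential expression of a gene panel
#'
#' Per-gene two-sample t test between the two classes (case minus control
#' sign convention). Panel genes absent from the matrix are returned as NA
#' rows rather than dropped, mirroring how array panels report unmeasured
#' genes; genes not reaching `alpha` are flagged `"NS"`.
#'
#' @param expr an `hf_expression`.
#' @param panel character vector of gene symbols; default all genes.
#' @param alpha significance level for the NS flag.
#' @param variance variance rule passed to [two_sample_t()].
#' @return data.frame with columns `gene`, `t`, `p`, `flag`
#'   (`"significant"`, `"NS"` or `"NA"`), in panel order.
#' @export
differential_expression <- function(expr, panel = NULL, alpha = 0.05,
                                    variance = c("pooled", "welch")) {
  variance <- match.arg(variance)
  stopifnot(inherits(expr, "hf_expression"))
  if (is.null(panel)) panel <- rownames(expr$values)
  panel <- normalize_symbol(panel)
  case <- expr$labels == expr$case_class
  if (sum(case) < 2 || sum(!case) < 2) stop("each class needs at least 2 samples")
  absent <- setdiff(panel, rownames(expr$values))
  if (length(absent)) {
    message(length(absent), " panel gene(s) absent from the expression matrix: ",
            paste(absent, collapse = ", "))
  }
  res <- lapply(panel, function(g) {
    if (!g %in% rownames(expr$values)) {
      return(data.frame(gene = g, t = NA_real_, p = NA_real_, flag = "NA",
                        stringsAsFactors = FALSE))
    }
    v <- expr$values[g, ]
    st <- if (stats::var(v[case]) == 0 && stats::var(v[!case]) == 0 &&
              mean(v[case]) == mean(v[!case])) {
      .stat_result("t", 0, 1, c(sum(case), sum(!case)))
    } else {
      two_sample_t(v[case], v[!case], variance)
    }
    data.frame(gene = g, t = st$value, p = st$p,
               flag = if (st$p <= alpha) "significant" else "NS",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

## fold-wise z-score standardization; zero-sd features left unscaled
.standardize <- function(train, test) {
  mu <- colMeans(train)
  sdv <- apply(train, 2, stats::sd)
  sdv[sdv == 0] <- 1
  list(train = sweep(sweep(train, 2, mu), 2, sdv, "/"),
       test = sweep(sweep(test, 2, mu, "-"), 2, sdv, "/"))
}

#' Leave-one-out linear SVM classification
#'
#' Evaluates a gene panel as a patient classifier: for each sample, a linear
#' support vector machine (C = 1) is trained on all other samples — with
#' features z-scored using the training fold only, so no information from
#' the held-out sample enters preprocessing — and the held-out sample is
#' predicted. Reports LOO accuracy and the area under the ROC curve computed
#' from the held-out decision values (oriented towards the case class).
#' Deterministic for fixed inputs.
#'
#' @param expr an `hf_expression` with >= 4 samples and >= 2 per class.
#' @param panel character vector of panel genes (must be present).
#' @param cost SVM regularization constant C.
#' @return object of class `hf_classification`: list with `accuracy`, `auc`,
#'   `predictions` (data.frame: sample, truth, predicted, decision),
#'   `panel`.
#' @export
loo_linear_classify <- function(expr, panel, cost = 1) {
  stopifnot(inherits(expr, "hf_expression"))
  panel <- normalize_symbol(panel)
  if (!length(panel)) stop("empty gene panel")
  absent <- setdiff(panel, rownames(expr$values))
  if (length(absent)) stop("panel gene(s) absent from the matrix: ",
                           paste(absent, collapse = ", "))
  X <- t(expr$values[panel, , drop = FALSE])  # samples x genes
  y <- expr$labels
  n <- nrow(X)
  if (n < 4) stop("need at least 4 samples for leave-one-out evaluation")
  if (any(table(y) < 2)) stop("each class needs at least 2 samples")
  pred <- character(n)
  dec <- numeric(n)
  for (i in seq_len(n)) {
    ytr <- droplevels(y[-i])
    if (nlevels(ytr) < 2) stop("training fold has a single class")
    zs <- .standardize(X[-i, , drop = FALSE], X[i, , drop = FALSE])
    fit <- e1071::svm(zs$train, ytr, type = "C-classification",
                      kernel = "linear", cost = cost, scale = FALSE)
    p <- stats::predict(fit, zs$test, decision.values = TRUE)
    pred[i] <- as.character(p)
    dv <- drop(attr(p, "decision.values"))
    ## orient decision value towards the case class
    pair <- strsplit(colnames(attr(p, "decision.values")), "/", fixed = TRUE)[[1]]
    dec[i] <- if (pair[1] == expr$case_class) dv else -dv
  }
  truth <- as.character(y)
  acc <- mean(pred == truth)
  is_case <- truth == expr$case_class
  ## AUC by the rank (Mann-Whitney) formula on held-out decision values
  r <- rank(dec)
  auc <- (sum(r[is_case]) - sum(is_case) * (sum(is_case) + 1) / 2) /
    (sum(is_case) * sum(!is_case))
  structure(list(accuracy = acc, auc = auc,
                 predictions = data.frame(sample = rownames(X), truth = truth,
                                          predicted = pred, decision = dec,
                                          stringsAsFactors = FALSE),
                 panel = panel),
            class = "hf_classification")
}

#' @export
print.hf_classification <- function(x, ...) {
  cat(sprintf("LOO linear SVM on %d gene(s): accuracy = %.1f%%, AUC = %.3f\n",
              length(x$panel), 100 * x$accuracy, x$auc))
  invisible(x)
}
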