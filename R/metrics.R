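# Multiclass classification metrics (the Tables-style column set: macro
# precision/recall/F1, Cohen's kappa, multiclass Matthews correlation,
# accuracy) plus final-stage classification on a selected feature subset.

#' Confusion matrix
#'
#' Counts with rows = true labels and columns = predicted labels over the
#' sorted union of observed (and optionally supplied) label values.
#'
#' @param y_true,y_pred Label vectors of equal length.
#' @param labels Optional fixed label set (e.g. the global class set when
#'   some class is absent from `y_true`).
#' @return A `confusion_matrix`: integer `C x C` matrix with dimnames.
#' @export
confusion <- function(y_true, y_pred, labels = NULL) {
  if (length(y_true) != length(y_pred)) stopf("label vectors must have equal length")
  if (length(y_true) == 0) stopf("need at least one sample")
  if (is.null(labels)) labels <- sort(unique(c(y_true, y_pred)))
  f_true <- factor(y_true, levels = labels)
  f_pred <- factor(y_pred, levels = labels)
  m <- unclass(table(f_true, f_pred))
  dimnames(m) <- list(true = as.character(labels), pred = as.character(labels))
  structure(m, class = c("confusion_matrix", "matrix"))
}

#' Metrics report from a confusion matrix
#'
#' Computes accuracy (`trace/total`), macro-averaged precision, recall and
#' F1 (per-class one-vs-rest with the `0/0 := 0` convention; F1 is the mean
#' of per-class harmonic means), Cohen's kappa
#' `(p_o - p_e) / (1 - p_e)`, and the multiclass Matthews correlation
#' coefficient in the Gorodkin covariance form. A degenerate matrix whose
#' chance agreement is 1 (all mass in one row and one column) gets
#' `kappa = mcc = 0` with `degenerate = TRUE`.
#'
#' @param cm A [confusion()] matrix (any square count matrix works).
#' @return A `metrics_report` list: `accuracy`, `precision_macro`,
#'   `recall_macro`, `f1_macro`, `kappa`, `mcc`, `degenerate`.
#' @examples
#' report(confusion(c(0, 0, 1, 1), c(0, 1, 1, 1)))
#' @export
report <- function(cm) {
  m <- unclass(cm)
  if (!is.matrix(m) || nrow(m) != ncol(m)) stopf("`cm` must be square")
  s <- sum(m)
  if (s <= 0) stopf("confusion matrix must contain at least one count")
  diagm <- diag(m)
  rowt <- rowSums(m)  # true counts t_k
  colt <- colSums(m)  # predicted counts p_k
  accuracy <- sum(diagm) / s

  safe_div <- function(a, b) ifelse(b == 0, 0, a / b)
  prec <- safe_div(diagm, colt)
  rec <- safe_div(diagm, rowt)
  f1 <- safe_div(2 * prec * rec, prec + rec)

  p_o <- accuracy
  p_e <- sum(rowt * colt) / s^2
  degenerate <- (1 - p_e) <= 0
  kappa <- if (degenerate) 0 else (p_o - p_e) / (1 - p_e)

  # Gorodkin multiclass MCC: covariance of true/pred indicator matrices
  num <- sum(diagm) * s - sum(rowt * colt)
  den <- sqrt(s^2 - sum(colt^2)) * sqrt(s^2 - sum(rowt^2))
  mcc <- if (den == 0) { degenerate <- TRUE; 0 } else num / den

  structure(list(accuracy = accuracy,
                 precision_macro = mean(prec), recall_macro = mean(rec),
                 f1_macro = mean(f1), kappa = kappa, mcc = mcc,
                 degenerate = degenerate),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf(paste0("<metrics_report> accuracy %.4f | precision %.4f | ",
                     "recall %.4f | F1 %.4f | kappa %.4f | MCC %.4f\n"),
              x$accuracy, x$precision_macro, x$recall_macro, x$f1_macro,
              x$kappa, x$mcc))
  invisible(x)
}

#' Classify on a selected feature subset
#'
#' Fits an off-the-shelf classifier on the masked training columns, scores
#' the masked test columns and returns the [report()] computed over the
#' global label set of the training data. Classifiers: `"knn"`
#' (`class::knn`, param `k`, default 5), `"svm_rbf"` (`e1071::svm`, radial
#' kernel, params `cost`, `gamma`), `"mlp"` (`nnet::nnet` one-hidden-layer
#' perceptron, params `size` default 16, `maxit` default 200). Stochastic
#' fits and tie-breaks are seeded, so identical calls give identical
#' reports.
#'
#' @param train,test [feature_matrix()] objects over the same feature space.
#' @param mask Logical feature mask (at least one `TRUE`).
#' @param classifier One of `"knn"`, `"svm_rbf"`, `"mlp"`.
#' @param params Named list of classifier parameters (see above).
#' @param seed Integer seed.
#' @return A list with `report` (a `metrics_report`), `cm` (the confusion
#'   matrix) and `pred` (predicted labels).
#' @export
classify_selected <- function(train, test, mask,
                              classifier = c("knn", "svm_rbf", "mlp"),
                              params = list(), seed = 1L) {
  classifier <- match.arg(classifier)
  if (!inherits(train, "feature_matrix") || !inherits(test, "feature_matrix"))
    stopf("`train` and `test` must be feature_matrix objects")
  if (ncol(train$values) != ncol(test$values))
    stopf("train/test feature spaces differ")
  mask <- as.logical(mask)
  if (length(mask) != ncol(train$values) || !any(mask))
    stopf("`mask` must be a non-empty logical mask over the features")

  xtr <- train$values[, mask, drop = FALSE]
  xte <- test$values[, mask, drop = FALSE]
  lev <- sort(unique(train$labels))  # fixed global label set
  ytr <- factor(train$labels, levels = lev)

  pred <- with_seed_or_stream(seed, switch(classifier,
    knn = {
      k <- if (is.null(params$k)) 5L else params$k
      class::knn(xtr, xte, ytr, k = k)
    },
    svm_rbf = {
      cost <- if (is.null(params$cost)) 1 else params$cost
      gamma <- if (is.null(params$gamma)) 1 / ncol(xtr) else params$gamma
      fit <- e1071::svm(xtr, ytr, kernel = "radial", cost = cost, gamma = gamma)
      stats::predict(fit, xte)
    },
    mlp = {
      size <- if (is.null(params$size)) 16L else params$size
      maxit <- if (is.null(params$maxit)) 200L else params$maxit
      fit <- nnet::nnet(xtr, nnet::class.ind(ytr), size = size, maxit = maxit,
                        softmax = TRUE, trace = FALSE,
                        MaxNWts = 1e6)
      factor(lev[max.col(stats::predict(fit, xte))], levels = lev)
    }))

  pred <- as.integer(as.character(pred))
  cm <- confusion(test$labels, pred, labels = lev)
  list(report = report(cm), cm = cm, pred = pred)
}
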