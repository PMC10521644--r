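#' One-vs-rest confusion counts
#'
#' Computes per-class TP/FP/TN/FN on a fixed sample set. Class levels are
#' taken from `levels` or, if omitted, from the union of the truth and
#' prediction factors.
#'
#' @param truth,pred Vectors (factor, character or integer) of equal length.
#' @param levels Optional explicit class levels.
#' @return Object of class `lca_confusion` with integer vectors `tp`, `fp`,
#'   `tn`, `fn` indexed by class.
#' @export
confusion_counts <- function(truth, pred, levels = NULL) {
  if (length(truth) != length(pred)) stop("truth and pred lengths differ")
  if (is.null(levels)) {
    levels <- sort(unique(c(as.character(truth), as.character(pred))))
  }
  truth <- factor(truth, levels = levels)
  pred <- factor(pred, levels = levels)
  if (anyNA(truth) || anyNA(pred)) stop("labels outside the declared levels")
  n <- length(truth)
  tp <- fp <- fn <- integer(length(levels))
  for (i in seq_along(levels)) {
    is_t <- truth == levels[i]
    is_p <- pred == levels[i]
    tp[i] <- sum(is_t & is_p)
    fp[i] <- sum(!is_t & is_p)
    fn[i] <- sum(is_t & !is_p)
  }
  tn <- n - tp - fp - fn
  structure(list(tp = setNames(tp, levels), fp = setNames(fp, levels),
                 tn = setNames(tn, levels), fn = setNames(fn, levels),
                 classes = levels, n = n),
            class = "lca_confusion")
}

#' Assemble a confusion object from raw counts
#'
#' @param tp,fp,tn,fn Equal-length nonnegative integer vectors (per class).
#' @param classes Optional class names.
#' @return `lca_confusion`.
#' @export
confusion_from_counts <- function(tp, fp, tn, fn, classes = NULL) {
  k <- length(tp)
  if (any(c(length(fp), length(tn), length(fn)) != k)) {
    stop("count vectors must have equal length")
  }
  cnt <- c(tp, fp, tn, fn)
  if (any(cnt < 0) || any(cnt != round(cnt))) {
    stop("counts must be nonnegative integers")
  }
  tot <- tp + fp + tn + fn
  if (length(unique(tot)) != 1L) {
    stop("TP+FP+TN+FN must be identical across classes (one-vs-rest on one sample set)")
  }
  if (is.null(classes)) classes <- as.character(seq_len(k))
  structure(list(tp = setNames(as.integer(tp), classes),
                 fp = setNames(as.integer(fp), classes),
                 tn = setNames(as.integer(tn), classes),
                 fn = setNames(as.integer(fn), classes),
                 classes = classes, n = tot[1]),
            class = "lca_confusion")
}

safe_ratio <- function(num, den) ifelse(den > 0, num / den, NA_real_)

#' Per-class precision, sensitivity, specificity and accuracy
#'
#' Ratios with a zero denominator (e.g. sensitivity of a class absent from
#' the ground truth) are reported as `NA` with a warning, and are excluded
#' from macro averages downstream.
#'
#' @param confusion `lca_confusion`.
#' @return Data frame with one row per class.
#' @export
per_class_metrics <- function(confusion) {
  stopifnot(inherits(confusion, "lca_confusion"))
  with(confusion, {
    out <- data.frame(
      class = classes,
      precision = safe_ratio(tp, tp + fp),
      sensitivity = safe_ratio(tp, tp + fn),
      specificity = safe_ratio(tn, tn + fp),
      accuracy = safe_ratio(tn + tp, tn + fp + fn + tp),
      row.names = NULL, stringsAsFactors = FALSE
    )
    if (anyNA(out[-1])) {
      warning("some per-class metrics are undefined (0/0) and reported as NA")
    }
    out
  })
}

#' Balanced multiclass accuracy
#'
#' The unweighted mean of per-class sensitivities (recalls).
#'
#' @param confusion `lca_confusion`.
#' @param allow_missing If `TRUE`, classes absent from the ground truth
#'   (undefined sensitivity) are skipped from the average with a warning;
#'   if `FALSE` (default) they raise an error.
#' @return Scalar in `[0, 1]`.
#' @export
bacc <- function(confusion, allow_missing = FALSE) {
  stopifnot(inherits(confusion, "lca_confusion"))
  sens <- safe_ratio(confusion$tp, confusion$tp + confusion$fn)
  if (anyNA(sens)) {
    if (!allow_missing) {
      stop("class(es) absent from ground truth: ",
           paste(confusion$classes[is.na(sens)], collapse = ", "),
           " (set allow_missing = TRUE to macro-skip)")
    }
    warning("skipping class(es) with undefined sensitivity from BACC")
  }
  mean(sens, na.rm = TRUE)
}

#' Area under the ROC curve
#'
#' Computed as the normalized Mann-Whitney U statistic (tied scores count
#' one half), equal to the trapezoidal area under the ROC curve.
#'
#' @param scores Numeric vector of scores (higher = more positive).
#' @param labels Binary labels (logical, 0/1, or a two-level factor whose
#'   second level is positive).
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  if (is.factor(labels)) labels <- labels == levels(labels)[2]
  pos <- as.logical(labels)
  if (length(scores) != length(pos)) stop("scores and labels lengths differ")
  if (anyNA(scores) || anyNA(pos)) stop("NA in scores or labels")
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) stop("both label values must be present")
  r <- rank(scores)  # average ranks give half credit to ties
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Macro one-vs-rest multiclass AUC
#'
#' @param prob Matrix `n x C` of class probabilities (columns named or in
#'   the order of `levels`).
#' @param truth Ground-truth labels.
#' @param levels Optional class levels matching the columns of `prob`.
#' @param allow_missing Skip classes absent from the truth (with a warning)
#'   rather than erroring.
#' @return Unweighted mean of one-vs-rest AUCs.
#' @export
multiclass_auc <- function(prob, truth, levels = NULL, allow_missing = TRUE) {
  if (is.null(levels)) levels <- colnames(prob) %||% sort(unique(as.character(truth)))
  truth <- factor(truth, levels = levels)
  aucs <- rep(NA_real_, length(levels))
  for (i in seq_along(levels)) {
    y <- truth == levels[i]
    if (any(y) && any(!y)) aucs[i] <- roc_auc(prob[, i], y)
  }
  if (anyNA(aucs)) {
    if (!allow_missing) stop("class absent from ground truth")
    warning("skipping class(es) with undefined AUC")
  }
  mean(aucs, na.rm = TRUE)
}

#' Full metrics report
#'
#' Per-class metrics plus the aggregate balanced accuracy, macro AUC (when
#' probabilities are supplied), macro specificity, macro precision and
#' macro accuracy.
#'
#' @param truth,pred Label vectors.
#' @param prob Optional `n x C` probability matrix for AUC.
#' @param levels Optional class levels.
#' @param allow_missing Macro-skip classes with undefined metrics.
#' @return Object of class `lca_metrics_report`.
#' @export
metrics_report <- function(truth, pred, prob = NULL, levels = NULL,
                           allow_missing = TRUE) {
  conf <- confusion_counts(truth, pred, levels = levels)
  per_class <- suppressWarnings(per_class_metrics(conf))
  b <- suppressWarnings(bacc(conf, allow_missing = allow_missing))
  auc <- if (!is.null(prob)) {
    suppressWarnings(multiclass_auc(prob, truth, levels = conf$classes,
                                    allow_missing = allow_missing))
  } else {
    NA_real_
  }
  structure(list(
    confusion = conf,
    per_class = per_class,
    aggregate = list(
      bacc = b,
      avg_auc = auc,
      avg_specificity = mean(per_class$specificity, na.rm = TRUE),
      avg_precision = mean(per_class$precision, na.rm = TRUE),
      avg_accuracy = mean(per_class$accuracy, na.rm = TRUE)
    )
  ), class = "lca_metrics_report")
}

#' @export
print.lca_metrics_report <- function(x, ...) {
  cat("<metrics report>\n")
  print(x$per_class, digits = 4)
  agg <- x$aggregate
  cat(sprintf("BACC %.4f | avg AUC %s | avg spec %.4f | avg prec %.4f | avg acc %.4f\n",
              agg$bacc,
              ifelse(is.na(agg$avg_auc), "NA", sprintf("%.4f", agg$avg_auc)),
              agg$avg_specificity, agg$avg_precision, agg$avg_accuracy))
  invisible(x)
}

#' Serialize a metrics report
#'
#' @param report `lca_metrics_report`.
#' @param json,csv Optional output paths; JSON holds the full report, CSV
#'   one row per class plus an aggregate row.
#' @return The report, invisibly.
#' @export
write_metrics_report <- function(report, json = NULL, csv = NULL) {
  stopifnot(inherits(report, "lca_metrics_report"))
  if (!is.null(json)) {
    jsonlite::write_json(list(per_class = report$per_class,
                              aggregate = report$aggregate),
                         json, auto_unbox = TRUE, digits = NA, na = "null")
  }
  if (!is.null(csv)) {
    agg <- report$aggregate
    tab <- rbind(report$per_class,
                 data.frame(class = "macro_average",
                            precision = agg$avg_precision,
                            sensitivity = agg$bacc,
                            specificity = agg$avg_specificity,
                            accuracy = agg$avg_accuracy))
    write.csv(tab, csv, row.names = FALSE)
  }
  invisible(report)
}
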