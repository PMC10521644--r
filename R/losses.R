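#' Softmax probabilities from logits
#'
#' Row-wise numerically stable softmax: probabilities are invariant to
#' adding a constant to all logits of a row.
#'
#' @param logits Numeric matrix `batch x C` (a vector is treated as one row).
#' @return Matrix of the same shape; each row sums to 1.
#' @export
softmax_probs <- function(logits) {
  if (is.vector(logits)) logits <- matrix(logits, nrow = 1)
  if (!is.numeric(logits) || anyNA(logits) || any(!is.finite(logits))) {
    stop("logits must be finite numeric values")
  }
  z <- logits - apply(logits, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

#' Inverse-class-frequency weights
#'
#' Computes `w_i = N / n_i` from per-class sample counts, the class
#' equilibrium weights used by the weighted cross-entropy loss. Weights are
#' deliberately unnormalised: in the balanced case all weights equal the
#' number of classes.
#'
#' @param class_counts Positive integer vector of per-class sample counts,
#'   optionally named.
#' @return Object of class `lca_class_weights` with fields `weights`,
#'   `class_counts`, `total`, `num_classes`.
#' @export
class_weights <- function(class_counts) {
  n <- as.numeric(class_counts)
  if (length(n) < 1L || any(is.na(n)) || any(n < 1) || any(n != round(n))) {
    stop("class_counts must be positive integers (a zero count leaves the weight undefined)")
  }
  N <- sum(n)
  w <- N / n
  names(w) <- names(class_counts)
  structure(list(weights = w, class_counts = n, total = N,
                 num_classes = length(n)),
            class = "lca_class_weights")
}

#' @export
print.lca_class_weights <- function(x, ...) {
  cat(sprintf("<class weights: C=%d, N=%d>\n", x$num_classes, x$total))
  print(round(x$weights, 4))
  invisible(x)
}

#' Bundle logits and labels into a prediction batch
#'
#' @param logits Numeric matrix `batch x C`.
#' @param labels Integer class indices in `1..C`, or a one-hot matrix
#'   `batch x C`.
#' @return Object of class `lca_prediction_batch` with `logits`, one-hot
#'   `labels` and softmax `probabilities`.
#' @export
prediction_batch <- function(logits, labels) {
  if (is.vector(logits)) logits <- matrix(logits, nrow = 1)
  C <- ncol(logits)
  if (is.matrix(labels)) {
    if (!all(dim(labels) == dim(logits))) stop("label matrix shape mismatch")
    if (any(rowSums(labels != 0) != 1L) || !all(labels %in% c(0, 1))) {
      stop("labels must be one-hot rows")
    }
    onehot <- labels
  } else {
    idx <- as.integer(labels)
    if (length(idx) != nrow(logits) || any(idx < 1L) || any(idx > C)) {
      stop("labels must be class indices in 1..C")
    }
    onehot <- matrix(0, nrow(logits), C)
    onehot[cbind(seq_along(idx), idx)] <- 1
  }
  structure(list(logits = logits, labels = onehot,
                 probabilities = softmax_probs(logits)),
            class = "lca_prediction_batch")
}

#' Class-weighted cross-entropy loss
#'
#' `L = -sum_i w_i p_i log(phat_i)` per sample, where `p` is the one-hot
#' ground truth and `phat` the softmax probabilities; with unit weights this
#' is exactly the standard cross-entropy. Probabilities are clamped below at
#' `eps` inside the logarithm.
#'
#' @param batch An [prediction_batch()] object.
#' @param weights Optional `lca_class_weights` or numeric vector of length C;
#'   `NULL` means unit weights.
#' @param reduction `"mean"` (default) or `"sum"` over the batch.
#' @param eps Clamp for `log`; default `1e-12`.
#' @return Nonnegative scalar loss.
#' @export
weighted_cross_entropy <- function(batch, weights = NULL, reduction = "mean",
                                   eps = 1e-12) {
  if (!inherits(batch, "lca_prediction_batch")) {
    stop("batch must be an lca_prediction_batch")
  }
  C <- ncol(batch$logits)
  w <- if (is.null(weights)) {
    rep(1, C)
  } else if (inherits(weights, "lca_class_weights")) {
    weights$weights
  } else {
    as.numeric(weights)
  }
  if (length(w) != C || any(w <= 0)) {
    stop("weights must be ", C, " positive values")
  }
  reduction <- match.arg(reduction, c("mean", "sum"))
  per_sample <- -rowSums(batch$labels *
                           sweep(log(pmax(batch$probabilities, eps)),
                                 2, w, `*`))
  if (reduction == "mean") mean(per_sample) else sum(per_sample)
}
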