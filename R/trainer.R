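#' Datasets and training
#'
#' A dataset is a list with `images` (list of `H x W x 3` arrays), a
#' `manifest` data frame (`image`, `label`, `group_id`) and the class
#' `levels`.
#'
#' @name training
NULL

#' Subset a dataset by row indices
#'
#' @param dataset A dataset list.
#' @param idx Row indices into the manifest.
#' @return The subset dataset (class levels preserved).
#' @export
dataset_subset <- function(dataset, idx) {
  list(images = dataset$images[idx],
       manifest = dataset$manifest[idx, , drop = FALSE],
       levels = dataset$levels)
}

dataset_labels <- function(dataset) {
  factor(dataset$manifest$label, levels = dataset$levels)
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  for (nm in names(params)) {
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * grads[[nm]]
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * grads[[nm]]^2
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

# Assemble a batch array (crop, crop, 3, B) from dataset images,
# augmenting (optional) then randomly cropping each.
make_batch <- function(dataset, idx, crop, strategy = NULL) {
  B <- length(idx)
  x <- array(0, dim = c(crop, crop, 3, B))
  for (j in seq_len(B)) {
    img <- dataset$images[[idx[j]]]
    if (!is.null(strategy)) img <- apply_strategy(img, strategy)
    x[, , , j] <- random_crop(img, c(crop, crop))
  }
  x
}

# Batched center-crop class probabilities for a whole dataset.
predict_probs <- function(backbone, params, dataset, crop, batch_size = 64) {
  n <- length(dataset$images)
  C <- ncol(params$wd)
  probs <- matrix(0, n, C)
  for (start in seq(1, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1, n)
    x <- array(0, dim = c(crop, crop, 3, length(idx)))
    for (j in seq_along(idx)) {
      x[, , , j] <- center_crop(dataset$images[[idx[j]]], c(crop, crop))
    }
    probs[idx, ] <- softmax_probs(backbone$forward(params, x)$logits)
  }
  colnames(probs) <- dataset$levels
  probs
}

#' Train a backbone with a stochastic augmentation strategy
#'
#' Implements the reference protocol: every epoch each training image is
#' augmented by [apply_strategy()] (one random subpolicy, both ops firing
#' independently with the strategy probability), randomly cropped to the
#' configured square size, and consumed by Adam minimising the
#' inverse-class-frequency [weighted_cross_entropy()]; the learning rate
#' follows [lr_schedule()]. Class weights are computed from the training
#' split only. After each epoch the balanced accuracy on the validation
#' split (center crops) is recorded.
#'
#' @param backbone An `lca_backbone`.
#' @param train Training dataset.
#' @param strategy `lca_strategy` or `NULL` for no augmentation.
#' @param config [train_config()].
#' @param val Optional validation dataset for the BACC trace.
#' @param class_wts Optional `lca_class_weights`; default inverse class
#'   frequencies of the training split.
#' @param seed Optional seed (initialisation, shuffling, augmentation).
#' @param checkpoint_fn Optional `function(params, epoch)` evaluated every
#'   `config$checkpoint_every` epochs (and at the final epoch); its scalar
#'   results are collected in the `checkpoints` data frame of the result.
#' @return Object of class `lca_trained_model`: `params`, `trace` (data
#'   frame with epoch, lr, train_loss, val_bacc), `backbone`, `levels`,
#'   `config`, `class_weights`, and `checkpoints` when `checkpoint_fn` is
#'   given.
#' @export
train_backbone <- function(backbone, train, strategy = NULL,
                           config = train_config(), val = NULL,
                           class_wts = NULL, seed = NULL,
                           checkpoint_fn = NULL) {
  validate_backbone(backbone)
  if (!is.null(strategy) && !inherits(strategy, "lca_strategy")) {
    stop("strategy must be an lca_strategy or NULL")
  }
  if (!is.null(seed)) set.seed(seed)
  labels <- dataset_labels(train)
  C <- length(train$levels)
  if (is.null(class_wts)) {
    counts <- table(labels)
    if (any(counts == 0)) {
      # a fold can lack a class entirely; weight it as if seen once
      counts <- counts + (counts == 0)
    }
    class_wts <- class_weights(as.integer(counts))
  }
  w <- class_wts$weights
  crop <- min(config$crop_size,
              min(vapply(train$images, function(im) min(dim(im)[1:2]),
                         numeric(1))))
  params <- backbone$init(c(crop, crop, 3), C)
  opt <- adam_init(params)
  y <- as.integer(labels)
  n <- length(train$images)
  trace <- data.frame(epoch = integer(0), lr = numeric(0),
                      train_loss = numeric(0), val_bacc = numeric(0))
  checkpoints <- data.frame(epoch = integer(0), value = numeric(0))
  for (epoch in seq_len(config$max_epochs) - 1L) {
    lr <- lr_schedule(epoch, config)
    ord <- sample.int(n)
    epoch_loss <- 0; n_batches <- 0
    for (start in seq(1, n, by = config$batch_size)) {
      idx <- ord[start:min(start + config$batch_size - 1, n)]
      x <- make_batch(train, idx, crop, strategy)
      fw <- backbone$forward(params, x)
      probs <- softmax_probs(fw$logits)
      B <- length(idx)
      onehot <- matrix(0, B, C)
      onehot[cbind(seq_len(B), y[idx])] <- 1
      batch <- structure(list(logits = fw$logits, labels = onehot,
                              probabilities = probs),
                         class = "lca_prediction_batch")
      epoch_loss <- epoch_loss + weighted_cross_entropy(batch, class_wts)
      n_batches <- n_batches + 1
      dlogits <- (probs - onehot) * w[y[idx]] / B
      grads <- backbone$backward(params, fw$cache, dlogits)
      upd <- adam_step(params, grads, opt, lr)
      params <- upd$params; opt <- upd$state
    }
    val_bacc <- NA_real_
    if (!is.null(val) && length(val$images) > 0) {
      vp <- predict_probs(backbone, params, val, crop)
      pred <- val$levels[max.col(vp, ties.method = "first")]
      conf <- confusion_counts(dataset_labels(val), pred, levels = val$levels)
      val_bacc <- suppressWarnings(bacc(conf, allow_missing = TRUE))
    }
    trace <- rbind(trace, data.frame(epoch = epoch, lr = lr,
                                     train_loss = epoch_loss / n_batches,
                                     val_bacc = val_bacc))
    if (!is.null(checkpoint_fn) &&
        ((epoch + 1L) %% config$checkpoint_every == 0L ||
         epoch == config$max_epochs - 1L)) {
      checkpoints <- rbind(checkpoints,
                           data.frame(epoch = epoch,
                                      value = checkpoint_fn(params, epoch)))
    }
  }
  structure(list(params = params, trace = trace, backbone = backbone,
                 levels = train$levels, config = config, crop = crop,
                 class_weights = class_wts,
                 checkpoints = if (is.null(checkpoint_fn)) NULL else checkpoints),
            class = "lca_trained_model")
}

#' Class probabilities from a trained model
#'
#' @param model `lca_trained_model`.
#' @param dataset Dataset to score.
#' @param mode `"center"` (single center crop) or `"multicrop"`
#'   (equidistant-grid average via [multicrop_predict()]).
#' @return Matrix `n x C` of probabilities with class-level column names.
#' @export
predict_model <- function(model, dataset, mode = c("center", "multicrop")) {
  mode <- match.arg(mode)
  stopifnot(inherits(model, "lca_trained_model"))
  crop <- model$crop
  if (mode == "center") {
    return(predict_probs(model$backbone, model$params, dataset, crop))
  }
  fn <- as_predict_fun(model)
  out <- t(vapply(dataset$images, function(img) {
    multicrop_predict(fn, img, crop_size = c(crop, crop),
                      n_per_axis = model$config$eval_n_per_axis)
  }, numeric(length(model$levels))))
  colnames(out) <- model$levels
  out
}

#' Wrap a trained model as a crop-level prediction function
#'
#' @param model `lca_trained_model`.
#' @return Function mapping one crop array to a probability vector, as
#'   consumed by [multicrop_predict()].
#' @export
as_predict_fun <- function(model) {
  function(crop_img) {
    x <- array(crop_img, dim = c(dim(crop_img), 1L))
    as.vector(softmax_probs(model$backbone$forward(model$params, x)$logits))
  }
}

#' Grad-CAM++ explanation from a trained model
#'
#' @param model `lca_trained_model` whose backbone implements `gradcam`.
#' @param image `H x W x 3` array (center-cropped to the training size).
#' @param class_index Target class (index into `model$levels`).
#' @param upsample Return the normalized map upsampled to the image size.
#' @return `lca_heatmap`.
#' @export
explain_model <- function(model, image, class_index, upsample = TRUE) {
  stopifnot(inherits(model, "lca_trained_model"))
  if (!is.function(model$backbone$gradcam)) {
    stop("backbone does not provide Grad-CAM++ derivatives")
  }
  crop <- center_crop(image, c(model$crop, model$crop))
  stack <- model$backbone$gradcam(model$params, crop, class_index)
  gradcam_heatmap(stack, upsample_to = if (upsample) dim(crop)[1:2] else NULL)
}
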