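#' Grouped k-fold splits
#'
#' Partitions the distinct `group_id`s of a manifest into `k` folds by a
#' seeded random greedy assignment balancing fold sizes, so that every
#' image of one lesion (group) lies on the same side of every
#' train/validation split and each validation fold holds roughly `1/k` of
#' the samples (4:1 at the default `k = 5`).
#'
#' @param manifest Data frame with at least columns `label` and `group_id`
#'   (one row per image).
#' @param k Number of folds; default 5.
#' @param seed Optional seed for the fold shuffle.
#' @return List of `k` fold objects, each a list with `fold_index`,
#'   `train_ids`, `val_ids` (row indices into the manifest) and
#'   `val_groups`.
#' @export
make_grouped_folds <- function(manifest, k = 5, seed = NULL) {
  if (!all(c("label", "group_id") %in% names(manifest))) {
    stop("manifest needs 'label' and 'group_id' columns")
  }
  groups <- unique(as.character(manifest$group_id))
  if (k > length(groups)) {
    stop("k = ", k, " exceeds the number of distinct groups (", length(groups), ")")
  }
  if (!is.null(seed)) set.seed(seed)
  groups <- sample(groups)
  sizes <- table(as.character(manifest$group_id))[groups]
  fold_of <- integer(length(groups))
  load <- numeric(k)
  # greedy: next (shuffled) group goes to the lightest fold
  for (i in seq_along(groups)) {
    f <- which.min(load)
    fold_of[i] <- f
    load[f] <- load[f] + sizes[i]
  }
  names(fold_of) <- groups
  lapply(seq_len(k), function(f) {
    val_groups <- groups[fold_of == f]
    val <- which(as.character(manifest$group_id) %in% val_groups)
    list(fold_index = f,
         train_ids = setdiff(seq_len(nrow(manifest)), val),
         val_ids = val,
         val_groups = val_groups)
  })
}

#' Step learning-rate schedule
#'
#' Piecewise-constant schedule: the initial rate holds until the first
#' decay epoch, is divided by `1/decay_factor` there, and again every
#' `decay_every` epochs after. With the defaults (`lr = 1e-3`, first decay
#' at epoch 20, then every 10 epochs, factor 1/10) epochs 0-19 run at 1e-3,
#' 20-29 at 1e-4, 30-39 at 1e-5, and so on.
#'
#' @param epoch 0-based epoch index (vectorised).
#' @param config A [train_config()] (only the schedule fields are used).
#' @return Learning rate(s).
#' @export
lr_schedule <- function(epoch, config = train_config()) {
  if (any(epoch < 0)) stop("epoch must be >= 0")
  n_decays <- ifelse(epoch < config$first_decay_epoch, 0,
                     1 + (epoch - config$first_decay_epoch) %/% config$decay_every)
  config$initial_lr * config$decay_factor^n_decays
}

#' Training configuration
#'
#' Defaults reproduce the reference protocol: Adam, starting learning rate
#' 1e-3 decayed by a factor of 1/10 after 20 epochs and every 10 epochs
#' thereafter, 70 epochs, batch size 32, 224 x 224 random crops from images
#' up to 600 x 450.
#'
#' @param initial_lr Starting learning rate.
#' @param decay_factor Multiplicative decay.
#' @param first_decay_epoch Epoch (0-based) of the first decay.
#' @param decay_every Epochs between subsequent decays.
#' @param max_epochs Training epochs.
#' @param optimizer Optimizer name (only `"adam"` is implemented).
#' @param batch_size Minibatch size (a power of two by convention).
#' @param crop_size Side of the square training/evaluation crop.
#' @param eval_n_per_axis Crops per axis for multi-crop test evaluation.
#' @param checkpoint_every Epoch interval between test-set evaluations in
#'   the network-match stage.
#' @return Object of class `lca_train_config`.
#' @export
train_config <- function(initial_lr = 1e-3, decay_factor = 0.1,
                         first_decay_epoch = 20, decay_every = 10,
                         max_epochs = 70, optimizer = "adam",
                         batch_size = 32, crop_size = 224,
                         eval_n_per_axis = 4, checkpoint_every = 5) {
  optimizer <- match.arg(optimizer, "adam")
  structure(list(initial_lr = initial_lr, decay_factor = decay_factor,
                 first_decay_epoch = first_decay_epoch,
                 decay_every = decay_every, max_epochs = max_epochs,
                 optimizer = optimizer, batch_size = batch_size,
                 crop_size = crop_size, eval_n_per_axis = eval_n_per_axis,
                 checkpoint_every = checkpoint_every),
            class = "lca_train_config")
}
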