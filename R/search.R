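#' Two-stage augmentation search and network match
#'
#' Stage 1 selects the execution probability of the augmentation space by
#' grouped 5-fold cross-validation: for every candidate probability and
#' every candidate backbone, the per-fold score is the best validation
#' balanced accuracy over epochs and the screening criterion is the mean
#' of the five per-fold scores. Stage 2 retrains each backbone on the full
#' training set with the selected strategy and recommends the backbone
#' with the best multi-crop test balanced accuracy.
#'
#' @name search-pipeline
NULL

# Deterministic 31-bit substream seeds derived from a base seed.
derive_seed <- function(seed, ...) {
  ix <- c(...)
  s <- as.double(seed %% 2147483647L)
  for (i in ix) s <- (s * 1009 + i * 9973 + 1) %% 2147483647
  as.integer(s)
}

#' Stage 1: cross-validated augmentation search
#'
#' @param dataset Training dataset (list with `images`, `manifest`,
#'   `levels`); the manifest must carry `group_id`.
#' @param space `lca_search_space`.
#' @param backbones List of `lca_backbone` objects (or a single one).
#' @param config [train_config()].
#' @param k Folds; default 5.
#' @param seed Base seed; folds, initialisation and augmentation streams
#'   are derived from it, and training seeds are shared across candidate
#'   probabilities so backbones compare candidates on identical folds and
#'   initialisations.
#' @param trainer Training function with the signature of
#'   [train_backbone()]; injectable for testing.
#' @return List of class `lca_stage1_result`: `fold_scores` (long data
#'   frame), `candidates` (one row per backbone x probability with the
#'   criterion), `per_backbone_best`, `selected_probability`,
#'   `combinatorial_size`, `folds`, `seed`.
#' @export
stage1_augmentation_search <- function(dataset, space, backbones,
                                       config = train_config(), k = 5,
                                       seed = 1, trainer = train_backbone) {
  if (inherits(backbones, "lca_backbone")) backbones <- list(backbones)
  stopifnot(length(backbones) >= 1)
  cands <- enumerate_candidates(space)
  probs <- vapply(cands, function(s) s$probability, numeric(1))
  folds <- make_grouped_folds(dataset$manifest, k = k,
                              seed = derive_seed(seed, 1))
  fold_scores <- data.frame()
  for (bi in seq_along(backbones)) {
    for (ci in seq_along(cands)) {
      for (fi in seq_len(k)) {
        tr <- dataset_subset(dataset, folds[[fi]]$train_ids)
        va <- dataset_subset(dataset, folds[[fi]]$val_ids)
        fit <- trainer(backbones[[bi]], tr, strategy = cands[[ci]],
                       config = config, val = va,
                       seed = derive_seed(seed, bi, fi))
        best <- max(fit$trace$val_bacc, na.rm = TRUE)
        fold_scores <- rbind(fold_scores, data.frame(
          backbone = backbones[[bi]]$name, probability = probs[ci],
          fold = fi, best_val_bacc = best))
      }
    }
  }
  candidates <- stats::aggregate(best_val_bacc ~ backbone + probability,
                                 data = fold_scores, FUN = mean)
  names(candidates)[names(candidates) == "best_val_bacc"] <- "criterion"
  sel <- select_probability(candidates)
  structure(list(fold_scores = fold_scores, candidates = candidates,
                 per_backbone_best = sel$per_backbone,
                 selected_probability = sel$probability,
                 combinatorial_size = attr(cands, "combinatorial_size"),
                 folds = folds, seed = seed),
            class = "lca_stage1_result")
}

# Majority vote of per-backbone argmax probabilities; ties broken by the
# higher mean criterion across backbones, then by the lower probability.
select_probability <- function(candidates) {
  per_backbone <- do.call(rbind, lapply(split(candidates, candidates$backbone),
                                        function(d) d[which.max(d$criterion), ]))
  votes <- table(per_backbone$probability)
  winners <- as.numeric(names(votes)[votes == max(votes)])
  if (length(winners) > 1) {
    mean_crit <- stats::aggregate(criterion ~ probability, data = candidates,
                                  FUN = mean)
    mean_crit <- mean_crit[mean_crit$probability %in% winners, ]
    mean_crit <- mean_crit[order(-mean_crit$criterion, mean_crit$probability), ]
    winners <- mean_crit$probability[1]
  }
  list(probability = winners[1], per_backbone = per_backbone)
}

#' Stage 2: network match on the full training set
#'
#' @param train Full training dataset.
#' @param test Held-out test dataset (non-empty).
#' @param strategy The selected `lca_strategy` (e.g. the stage-1 winner).
#' @param backbones List of `lca_backbone` objects.
#' @param config [train_config()]; test balanced accuracy is evaluated by
#'   multi-crop averaging every `checkpoint_every` epochs.
#' @param seed Base seed.
#' @param trainer Injectable training function.
#' @return List of class `lca_stage2_result`: `models` (per-backbone fit),
#'   `summary` (backbone, best test BACC, best epoch), `selected_backbone`.
#' @export
stage2_network_match <- function(train, test, strategy, backbones,
                                 config = train_config(), seed = 1,
                                 trainer = train_backbone) {
  if (inherits(backbones, "lca_backbone")) backbones <- list(backbones)
  if (is.null(test) || length(test$images) == 0) stop("empty test set")
  models <- list()
  summary <- data.frame()
  for (bi in seq_along(backbones)) {
    bb <- backbones[[bi]]
    ckpt <- function(params, epoch) {
      model <- structure(list(params = params, backbone = bb,
                              levels = train$levels, config = config,
                              crop = min(config$crop_size,
                                         min(vapply(test$images, function(im)
                                           min(dim(im)[1:2]), numeric(1))))),
                         class = "lca_trained_model")
      probs <- predict_model(model, test, mode = "multicrop")
      pred <- test$levels[max.col(probs, ties.method = "first")]
      conf <- confusion_counts(dataset_labels(test), pred,
                               levels = test$levels)
      suppressWarnings(bacc(conf, allow_missing = TRUE))
    }
    fit <- trainer(bb, train, strategy = strategy, config = config,
                   seed = derive_seed(seed, 100 + bi),
                   checkpoint_fn = ckpt)
    models[[bb$name]] <- fit
    best_i <- which.max(fit$checkpoints$value)
    summary <- rbind(summary, data.frame(
      backbone = bb$name,
      best_test_bacc = fit$checkpoints$value[best_i],
      best_epoch = fit$checkpoints$epoch[best_i]))
  }
  structure(list(models = models, summary = summary,
                 selected_backbone = summary$backbone[which.max(summary$best_test_bacc)]),
            class = "lca_stage2_result")
}

#' Full two-stage search
#'
#' Runs [stage1_augmentation_search()] then [stage2_network_match()] with
#' the winning probability and assembles a serializable search report.
#'
#' @param train,test Training and test datasets.
#' @param space `lca_search_space`.
#' @param backbones List of backbones.
#' @param config [train_config()].
#' @param k Stage-1 folds.
#' @param seed Base seed recorded in the report.
#' @param trainer Injectable training function.
#' @return Object of class `lca_search_report`.
#' @export
lca_search <- function(train, test, space, backbones,
                       config = train_config(), k = 5, seed = 1,
                       trainer = train_backbone) {
  s1 <- stage1_augmentation_search(train, space, backbones, config = config,
                                   k = k, seed = seed, trainer = trainer)
  strategy <- augmentation_strategy(space, s1$selected_probability)
  s2 <- stage2_network_match(train, test, strategy, backbones,
                             config = config, seed = seed, trainer = trainer)
  search_report(s1, s2, config, seed)
}

#' Assemble a search report
#'
#' @param stage1 `lca_stage1_result`.
#' @param stage2 `lca_stage2_result` (optional).
#' @param config The [train_config()] used.
#' @param seed Base seed of the run.
#' @return Object of class `lca_search_report`.
#' @export
search_report <- function(stage1, stage2 = NULL, config = train_config(),
                          seed = NA_integer_) {
  structure(list(
    stage1 = list(
      candidates = stage1$candidates,
      fold_scores = stage1$fold_scores,
      per_backbone_best = stage1$per_backbone_best,
      selected_probability = stage1$selected_probability,
      combinatorial_size = stage1$combinatorial_size
    ),
    stage2 = if (is.null(stage2)) NULL else list(
      summary = stage2$summary,
      checkpoints = lapply(stage2$models, function(m) m$checkpoints),
      selected_backbone = stage2$selected_backbone
    ),
    selected_probability = stage1$selected_probability,
    selected_backbone = if (is.null(stage2)) NA_character_
                        else stage2$selected_backbone,
    seed = seed,
    config = unclass(config)
  ), class = "lca_search_report")
}

#' @export
print.lca_search_report <- function(x, ...) {
  cat("<search report>\n")
  cat("stage 1 criteria (mean over folds of best validation BACC):\n")
  print(x$stage1$candidates, digits = 4)
  cat(sprintf("selected probability: %g\n", x$selected_probability))
  if (!is.null(x$stage2)) {
    cat("stage 2 test BACC:\n")
    print(x$stage2$summary, digits = 4)
    cat(sprintf("recommended backbone: %s\n", x$selected_backbone))
  }
  invisible(x)
}

#' Write a search report to JSON
#'
#' @param report `lca_search_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_search_report <- function(report, path) {
  stopifnot(inherits(report, "lca_search_report"))
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       na = "null", dataframe = "rows", pretty = TRUE)
  invisible(path)
}

#' Validate the schema of a search report read back from JSON
#'
#' @param x A list as produced by reading the JSON report.
#' @return `TRUE` (invisibly) or an error describing the violation.
#' @export
validate_search_report <- function(x) {
  need <- c("stage1", "selected_probability", "seed", "config")
  missing <- setdiff(need, names(x))
  if (length(missing)) stop("report lacks fields: ",
                            paste(missing, collapse = ", "))
  s1 <- x$stage1
  for (f in c("candidates", "selected_probability", "combinatorial_size")) {
    if (is.null(s1[[f]])) stop("stage1 lacks field: ", f)
  }
  if (!is.null(x$stage2)) {
    for (f in c("summary", "selected_backbone")) {
      if (is.null(x$stage2[[f]])) stop("stage2 lacks field: ", f)
    }
  }
  invisible(TRUE)
}
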