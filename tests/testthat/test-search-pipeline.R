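# A mock trainer that returns prescribed validation traces lets the
# selection logic be tested without any real optimisation.
mock_trainer <- function(bacc_of) {
  # bacc_of: function(backbone_name, probability, fold) -> numeric vector
  function(backbone, train, strategy = NULL, config = train_config(),
           val = NULL, class_wts = NULL, seed = NULL, checkpoint_fn = NULL) {
    p <- if (is.null(strategy)) 0 else strategy$probability
    fold <- attr(train, "fold_index") %||% seed %||% 1
    vals <- bacc_of(backbone$name, p, fold)
    trace <- data.frame(epoch = seq_along(vals) - 1, lr = 1e-3,
                        train_loss = rev(seq_along(vals)), val_bacc = vals)
    checkpoints <- NULL
    if (!is.null(checkpoint_fn)) {
      checkpoints <- data.frame(epoch = c(0, 1),
                                value = bacc_of(backbone$name, p, 0)[1:2])
    }
    structure(list(params = list(), trace = trace, backbone = backbone,
                   levels = train$levels, config = config, crop = 8,
                   class_weights = NULL, checkpoints = checkpoints),
              class = "lca_trained_model")
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

fake_backbone <- function(name) {
  structure(list(name = name, init = function(...) list(),
                 forward = function(...) list(),
                 backward = function(...) list()),
            class = "lca_backbone")
}

small_manifest_dataset <- function(n = 40, classes = c("a", "b")) {
  list(images = replicate(n, constant_rgb(8, 8), simplify = FALSE),
       manifest = data.frame(image = paste0("i", 1:n),
                             label = rep(classes, length.out = n),
                             group_id = paste0("g", 1:n)),
       levels = classes)
}

test_that("stage 1 selects the dominant probability from mock traces", {
  ds <- small_manifest_dataset()
  space <- search_space(build_default_space()$subpolicies, c(0.3, 0.7))
  tr <- mock_trainer(function(bb, p, fold) {
    if (p == 0.3) rep(0.8, 3) else rep(0.7, 3)
  })
  s1 <- stage1_augmentation_search(ds, space, fake_backbone("m1"),
                                   k = 5, seed = 1, trainer = tr)
  expect_equal(s1$selected_probability, 0.3)
  expect_equal(s1$candidates$criterion[s1$candidates$probability == 0.3], 0.8)
  expect_equal(s1$combinatorial_size, 24)
  # criterion equals mean over folds of the per-fold maxima (brute force)
  for (p in c(0.3, 0.7)) {
    sub <- s1$fold_scores[s1$fold_scores$probability == p, ]
    expect_equal(mean(sub$best_val_bacc),
                 s1$candidates$criterion[s1$candidates$probability == p])
  }
})

test_that("majority vote across backbones decides, ties broken by mean criterion", {
  ds <- small_manifest_dataset()
  space <- search_space(build_default_space()$subpolicies,
                        c(0.1, 0.3, 0.5, 0.7, 0.9))
  # eight backbones, five prefer 0.3 (a Table-1-like pattern)
  prefs <- c(m1 = 0.3, m2 = 0.3, m3 = 0.3, m4 = 0.3, m5 = 0.3,
             m6 = 0.1, m7 = 0.5, m8 = 0.9)
  tr <- mock_trainer(function(bb, p, fold) {
    base <- if (abs(p - prefs[[bb]]) < 1e-9) 0.85 else 0.75
    rep(base, 3)
  })
  bbs <- lapply(names(prefs), fake_backbone)
  s1 <- stage1_augmentation_search(ds, space, bbs, k = 5, seed = 1,
                                   trainer = tr)
  expect_equal(s1$selected_probability, 0.3)
  expect_equal(nrow(s1$per_backbone_best), 8)

  # two backbones voting for different probabilities: the higher mean
  # criterion across backbones wins the tie
  tr2 <- mock_trainer(function(bb, p, fold) {
    if (bb == "m1") {
      if (p == 0.1) rep(0.9, 3) else rep(0.6, 3)
    } else {
      if (p == 0.5) rep(0.7, 3) else rep(0.65, 3)
    }
  })
  s1b <- stage1_augmentation_search(ds, space,
                                    list(fake_backbone("m1"),
                                         fake_backbone("m2")),
                                    k = 5, seed = 1, trainer = tr2)
  # mean criterion: P=0.1 -> (0.9 + 0.65)/2 = 0.775; P=0.5 -> (0.6+0.7)/2 = 0.65
  expect_equal(s1b$selected_probability, 0.1)
})

test_that("stage 2 recommends the backbone with the best test BACC", {
  ds <- small_manifest_dataset()
  space <- build_default_space()
  strategy <- augmentation_strategy(space, 0.3)
  tr <- mock_trainer(function(bb, p, fold) {
    if (bb == "weak") c(0.6, 0.6, 0.6) else c(0.7, 0.7, 0.7)
  })
  s2 <- stage2_network_match(ds, ds, strategy,
                             list(fake_backbone("weak"),
                                  fake_backbone("strong")),
                             seed = 1, trainer = tr)
  expect_equal(s2$selected_backbone, "strong")
  expect_equal(nrow(s2$summary), 2)
  expect_true(all(c("epoch", "value") %in% names(s2$models$weak$checkpoints)))

  # single backbone still yields a complete report
  s2s <- stage2_network_match(ds, ds, strategy, fake_backbone("only"),
                              seed = 1, trainer = tr)
  expect_equal(s2s$selected_backbone, "only")
  expect_error(stage2_network_match(ds, list(images = list()), strategy,
                                    fake_backbone("x"), trainer = tr),
               "empty test set")
})

test_that("reports serialize to JSON and validate against the schema", {
  ds <- small_manifest_dataset()
  space <- search_space(build_default_space()$subpolicies, c(0.3, 0.7))
  tr <- mock_trainer(function(bb, p, fold) rep(ifelse(p == 0.7, 0.9, 0.5), 3))
  rep1 <- lca_search(ds, ds, space, fake_backbone("m"), k = 5, seed = 3,
                     trainer = tr)
  expect_s3_class(rep1, "lca_search_report")
  expect_equal(rep1$selected_probability, 0.7)
  path <- tempfile(fileext = ".json")
  write_search_report(rep1, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_true(validate_search_report(back))
  expect_equal(back$selected_probability, 0.7)
  expect_error(validate_search_report(list(stage1 = list())), "lacks")
})

test_that("group integrity holds in every fold of a real stage-1 run", {
  set.seed(71)
  ds <- small_manifest_dataset(n = 40)
  ds$manifest$group_id <- paste0("g", rep(1:10, each = 4))
  space <- search_space(build_default_space()$subpolicies, c(0.5))
  tr <- mock_trainer(function(bb, p, fold) rep(0.5, 2))
  s1 <- stage1_augmentation_search(ds, space, fake_backbone("m"), k = 5,
                                   seed = 9, trainer = tr)
  for (f in s1$folds) {
    gtrain <- unique(ds$manifest$group_id[f$train_ids])
    gval <- unique(ds$manifest$group_id[f$val_ids])
    expect_length(intersect(gtrain, gval), 0)
  }
})
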