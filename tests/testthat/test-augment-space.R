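test_that("the default space has the documented combinatorics", {
  space <- build_default_space()
  expect_s3_class(space, "lca_search_space")
  expect_length(space$subpolicies, 12)
  expect_equal(space$ladder_probabilities, c(0.1, 0.3, 0.5, 0.7, 0.9))

  color_ops <- vapply(space$subpolicies, function(s) s$color_op$name, "")
  geom_ops <- vapply(space$subpolicies, function(s) s$geometric_op$name, "")
  # 12 pairwise distinct color ops, 6 geometric ops used exactly twice
  expect_length(unique(color_ops), 12)
  expect_equal(sort(unique(as.vector(table(geom_ops)))), 2)
  expect_length(unique(geom_ops), 6)
  # every subpolicy pairs one op of each category
  for (s in space$subpolicies) {
    expect_equal(s$color_op$category, "color")
    expect_equal(s$geometric_op$category, "geometric")
  }

  cands <- enumerate_candidates(space)
  expect_length(cands, 5)
  expect_equal(attr(cands, "combinatorial_size"), 60)
})

test_that("candidate enumeration follows the product rule", {
  space <- build_default_space()
  one <- search_space(space$subpolicies, 0.5)
  expect_length(enumerate_candidates(one), 1)
  three <- search_space(space$subpolicies, c(0.2, 0.5, 0.8))
  expect_equal(attr(enumerate_candidates(three), "combinatorial_size"), 36)
  expect_error(search_space(space$subpolicies, numeric(0)), "ladder")
})

test_that("subpolicy sampling is uniform and seed-reproducible", {
  space <- build_default_space()
  single <- search_space(space$subpolicies[1], c(0.5))
  for (i in 1:5) expect_equal(sample_subpolicy(single)$id, 1L)

  set.seed(101)
  n <- 24000
  ids <- vapply(seq_len(n), function(i) sample_subpolicy(space)$id, 1L)
  freq <- tabulate(ids, 12) / n
  # binomial 5 sigma around 1/12
  tol <- 5 * sqrt((1 / 12) * (11 / 12) / n)
  expect_true(all(abs(freq - 1 / 12) < tol))
  expect_gt(chisq.test(tabulate(ids, 12))$p.value, 0.01)

  set.seed(77)
  a <- vapply(1:50, function(i) sample_subpolicy(space)$id, 1L)
  set.seed(77)
  b <- vapply(1:50, function(i) sample_subpolicy(space)$id, 1L)
  expect_identical(a, b)
})

test_that("transform ops stay in range, keep the frame, and validate magnitudes", {
  img <- gradient_rgb(20, 24)
  tab <- list_transform_ops()
  set.seed(5)
  for (i in seq_len(nrow(tab))) {
    op <- transform_op(tab$name[i])
    for (m in c(tab$lo[i], (tab$lo[i] + tab$hi[i]) / 2, tab$hi[i])) {
      out <- apply_op(img, op, m)
      expect_equal(dim(out), dim(img), info = tab$name[i])
      expect_true(all(out >= 0 & out <= 1), info = tab$name[i])
    }
    expect_error(apply_op(img, op, tab$hi[i] + 1), "outside range")
  }
  expect_error(transform_op("warp_speed"), "unknown")
})

test_that("geometric ops honour involution and neutral-magnitude identities", {
  img <- random_rgb(17, 23, seed = 6)
  hf <- transform_op("hflip")
  vf <- transform_op("vflip")
  expect_identical(apply_op(apply_op(img, hf, 0.5), hf, 0.5), img)
  expect_identical(apply_op(apply_op(img, vf, 0.5), vf, 0.5), img)
  expect_equal(apply_op(img, transform_op("rotate"), 0), img)
  expect_equal(apply_op(img, transform_op("scale"), 1), img)
  expect_equal(apply_op(img, transform_op("translate"), 0), img)
  expect_equal(apply_op(img, transform_op("shear"), 0), img)
  # neutral color magnitudes
  expect_equal(apply_op(img, transform_op("brightness"), 1), img)
  expect_equal(apply_op(img, transform_op("gamma"), 1), img)
  expect_equal(apply_op(img, transform_op("sharpness"), 1), img,
               tolerance = 1e-12)
})

test_that("gaussian noise has the requested standard deviation", {
  img <- constant_rgb(96, 96, 0.5)
  op <- transform_op("gaussian_noise", magnitude_range = c(0, 10 / 255))
  set.seed(8)
  out <- apply_op(img, op, 10 / 255)
  expect_equal(sd(out - img), 10 / 255, tolerance = 0.05)
})

test_that("strategies execute ops independently with probability P", {
  space <- build_default_space()
  img <- gradient_rgb(8, 8)

  # P = 0: pixel-identical, no RNG consumed
  s0 <- augmentation_strategy(space, 0)
  set.seed(1); r1 <- runif(1)
  set.seed(1); out <- apply_strategy(img, s0); r2 <- runif(1)
  expect_identical(out, img)
  expect_identical(r1, r2)

  # involution through the strategy path: identity color op + hflip at P = 1
  sp_flip <- search_space(list(subpolicy(
    transform_op("gamma", c(1, 1)), transform_op("hflip"))), 0.5)
  s1 <- augmentation_strategy(sp_flip, 1)
  twice <- apply_strategy(apply_strategy(img, s1), s1)
  expect_equal(twice, img, tolerance = 1e-12)

  # empirical execution frequency matches P within binomial 5 sigma
  set.seed(9)
  n <- 6000
  P <- 0.5
  s <- augmentation_strategy(space, P)
  ex <- t(vapply(seq_len(n), function(i) {
    apply_strategy(img, s, return_info = TRUE)$info$executed
  }, logical(2)))
  tol <- 5 * sqrt(P * (1 - P) / n)
  expect_lt(abs(mean(ex[, 1]) - P), tol)
  expect_lt(abs(mean(ex[, 2]) - P), tol)
  # unchanged fraction approximates (1-P)^2 (ops that may act as identity
  # at some magnitudes make the observed fraction an upper bound)
  expect_lt(abs(mean(!ex[, 1] & !ex[, 2]) - (1 - P)^2), tol)

  expect_error(augmentation_strategy(space, 1.2), "\\[0, 1\\]")
})

test_that("identical seeds reproduce augmented images bit for bit", {
  space <- build_default_space()
  img <- random_rgb(16, 16, seed = 10)
  s <- augmentation_strategy(space, 0.9)
  set.seed(123); a <- apply_strategy(img, s)
  set.seed(123); b <- apply_strategy(img, s)
  expect_identical(a, b)
})

test_that("spaces round-trip through YAML with custom ranges", {
  space <- search_space(list(
    subpolicy(transform_op("brightness", c(0.8, 1.2)),
              transform_op("rotate", c(-15, 15))),
    subpolicy(transform_op("hue_shift"), transform_op("hflip"))),
    ladder_probabilities = c(0.25, 0.75))
  path <- tempfile(fileext = ".yaml")
  space_to_yaml(space, path)
  back <- space_from_yaml(path)
  expect_equal(back$ladder_probabilities, c(0.25, 0.75))
  expect_equal(back$subpolicies[[1]]$color_op$magnitude_range, c(0.8, 1.2))
  expect_equal(back$subpolicies[[1]]$geometric_op$magnitude_range, c(-15, 15))
  expect_equal(back$subpolicies[[2]]$color_op$name, "hue_shift")

  bad <- tempfile(fileext = ".yaml")
  yaml::write_yaml(list(subpolicies = list(list(color_op = "rotate",
                                                geometric_op = "hflip"))),
                   bad)
  expect_error(space_from_yaml(bad), "not a color op")
})
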