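test_that("the 1x1x1 closed-form case gives alpha = 1/2, w = a, L = a^2", {
  a <- 1.7
  # score Z = A^2: dZ/dA = 2a, d2 = 2, d3 = 0
  stack <- feature_map_stack(A = array(a, c(1, 1, 1)),
                             grads1 = array(2 * a, c(1, 1, 1)),
                             grads2 = array(2, c(1, 1, 1)),
                             grads3 = array(0, c(1, 1, 1)))
  al <- alpha_weights(stack)
  expect_equal(as.vector(al), 0.5)
  w <- channel_weights(stack, al)
  expect_equal(w, a)
  hm <- gradcam_heatmap(stack, w)
  expect_equal(as.vector(hm$L), a^2)
})

test_that("a linear score degrades to zero alpha under the denominator guard", {
  stack <- feature_map_stack(A = array(1.3, c(2, 2, 1)),
                             grads1 = array(0.7, c(2, 2, 1)),
                             grads2 = array(0, c(2, 2, 1)),
                             grads3 = array(0, c(2, 2, 1)))
  expect_true(all(alpha_weights(stack) == 0))
  # all-negative first gradients are killed by the relu
  stack2 <- feature_map_stack(A = array(1, c(2, 2, 3)),
                              grads1 = array(-1, c(2, 2, 3)),
                              grads2 = array(rnorm(12), c(2, 2, 3)),
                              grads3 = array(rnorm(12), c(2, 2, 3)))
  expect_equal(channel_weights(stack2), rep(0, 3))
})

test_that("alpha, channel weights and heatmap match brute-force loops", {
  # independent oracle: literal triple-loop transcription of the formulas
  oracle <- function(A, g1, g2, g3, eps = 1e-8) {
    K <- dim(A)[3]; M <- dim(A)[1]; N <- dim(A)[2]
    alpha <- array(0, dim(A)); w <- numeric(K)
    for (k in 1:K) {
      glob <- 0
      for (m in 1:M) for (n in 1:N) glob <- glob + A[m, n, k] * g3[m, n, k]
      for (m in 1:M) for (n in 1:N) {
        den <- 2 * g2[m, n, k] + glob
        if (abs(den) < eps) den <- 1
        alpha[m, n, k] <- g2[m, n, k] / den
      }
      for (m in 1:M) for (n in 1:N) {
        w[k] <- w[k] + alpha[m, n, k] * max(g1[m, n, k], 0)
      }
    }
    L <- matrix(0, M, N)
    for (m in 1:M) for (n in 1:N) {
      s <- 0
      for (k in 1:K) s <- s + w[k] * A[m, n, k]
      L[m, n] <- max(s, 0)
    }
    list(alpha = alpha, w = w, L = L)
  }
  set.seed(31)
  for (rep in 1:10) {
    A <- array(runif(4 * 4 * 3, 0, 2), c(4, 4, 3))
    g1 <- array(rnorm(48), c(4, 4, 3))
    g2 <- array(rnorm(48), c(4, 4, 3))
    g3 <- array(rnorm(48), c(4, 4, 3))
    stack <- feature_map_stack(A, g1, g2, g3)
    ref <- oracle(A, g1, g2, g3)
    al <- alpha_weights(stack)
    expect_equal(al, ref$alpha, tolerance = 1e-12)
    w <- channel_weights(stack, al)
    expect_equal(w, ref$w, tolerance = 1e-12)
    hm <- gradcam_heatmap(stack, w)
    expect_equal(hm$L, ref$L, tolerance = 1e-12)
    expect_true(all(hm$L >= 0))
    expect_true(all(hm$normalized >= 0 & hm$normalized <= 1))
  }
})

test_that("analytic derivatives agree with central finite differences", {
  # fixed tiny model: polynomial score head on K = 2 feature maps
  set.seed(37)
  M <- 3; N <- 3; K <- 2
  A <- array(runif(M * N * K, 0.2, 1.5), c(M, N, K))
  cf <- list(c1 = rnorm(K), c2 = rnorm(K), c3 = rnorm(K) / 3)
  score <- function(A) {
    s <- 0
    for (k in 1:K) {
      s <- s + sum(cf$c1[k] * A[, , k] + cf$c2[k] * A[, , k]^2 +
                     cf$c3[k] * A[, , k]^3)
    }
    s
  }
  # analytic elementwise derivatives of the polynomial
  g1 <- g2 <- g3 <- array(0, dim(A))
  for (k in 1:K) {
    g1[, , k] <- cf$c1[k] + 2 * cf$c2[k] * A[, , k] + 3 * cf$c3[k] * A[, , k]^2
    g2[, , k] <- 2 * cf$c2[k] + 6 * cf$c3[k] * A[, , k]
    g3[, , k] <- 6 * cf$c3[k]
  }
  # finite-difference derivatives, h = 1e-3
  h <- 1e-3
  f1 <- f2 <- f3 <- array(0, dim(A))
  for (i in seq_len(length(A))) {
    pert <- function(d) { B <- A; B[i] <- B[i] + d; score(B) }
    f1[i] <- (pert(h) - pert(-h)) / (2 * h)
    f2[i] <- (pert(h) - 2 * pert(0) + pert(-h)) / h^2
    f3[i] <- (pert(2 * h) - 2 * pert(h) + 2 * pert(-h) - pert(-2 * h)) /
      (2 * h^3)
  }
  expect_equal(f1, g1, tolerance = 1e-4)
  expect_equal(f2, g2, tolerance = 1e-3)
  expect_equal(f3, g3, tolerance = 1e-3)

  h_an <- gradcam_heatmap(feature_map_stack(A, g1, g2, g3))
  h_fd <- gradcam_heatmap(feature_map_stack(A, f1, f2, f3))
  expect_equal(h_fd$L, h_an$L, tolerance = 1e-3)
})

test_that("the staged pipeline equals a monolithic composition", {
  set.seed(41)
  A <- array(runif(5 * 6 * 4, 0, 1), c(5, 6, 4))
  g1 <- array(rnorm(120), dim(A)); g2 <- array(rnorm(120), dim(A))
  g3 <- array(rnorm(120), dim(A))
  stack <- feature_map_stack(A, g1, g2, g3)
  # monolithic: all three equations composed in one expression
  K <- 4
  L <- matrix(0, 5, 6)
  for (k in 1:K) {
    den <- 2 * g2[, , k] + sum(A[, , k] * g3[, , k])
    den[abs(den) < 1e-8] <- 1
    wk <- sum((g2[, , k] / den) * pmax(g1[, , k], 0))
    L <- L + wk * A[, , k]
  }
  L <- pmax(L, 0)
  expect_equal(gradcam_heatmap(stack)$L, L, tolerance = 1e-12)
})

test_that("heatmap normalization and upsampling behave at the edges", {
  stack <- feature_map_stack(A = array(2, c(3, 3, 1)),
                             grads1 = array(1, c(3, 3, 1)),
                             grads2 = array(1, c(3, 3, 1)),
                             grads3 = array(0, c(3, 3, 1)))
  hm <- gradcam_heatmap(stack, weights = 0)
  expect_true(all(hm$L == 0))
  expect_true(all(hm$normalized == 0))  # constant map normalises to zeros

  hm2 <- gradcam_heatmap(stack, weights = 1, upsample_to = c(9, 9))
  expect_equal(dim(hm2$upsampled), c(9, 9))
  expect_error(gradcam_heatmap(stack, weights = c(1, 2)), "one weight")
  expect_error(feature_map_stack(array(1, c(2, 2, 1)),
                                 array(1, c(2, 3, 1)),
                                 array(1, c(2, 2, 1)),
                                 array(1, c(2, 2, 1))), "share shape")
})
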