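#' Grad-CAM++ class activation heatmaps
#'
#' Given the last-convolution feature maps `A` and the first, second and
#' third derivatives of the target class score with respect to them, the
#' pixel-wise gradient weights are
#' `alpha = d2 / (2 d2 + sum_mn(A * d3))` (per map), the channel weights
#' `w_k = sum_mn alpha * relu(d1)`, and the heatmap
#' `L = relu(sum_k w_k A_k)`.
#'
#' @name gradcam
NULL

#' Bundle feature maps with score derivatives
#'
#' @param A Feature maps, array `M x N x K`.
#' @param grads1,grads2,grads3 First/second/third derivatives of the target
#'   class score with respect to `A`, same shape.
#' @param target_class Optional class index the derivatives refer to.
#' @return Object of class `lca_featuremap_stack`.
#' @export
feature_map_stack <- function(A, grads1, grads2, grads3,
                              target_class = NA_integer_) {
  dims <- dim(A)
  if (length(dims) == 2L) {
    dims <- c(dims, 1L)
    dim(A) <- dim(grads1) <- dim(grads2) <- dim(grads3) <- dims
  }
  for (g in list(grads1, grads2, grads3)) {
    if (!identical(dim(g), dims)) stop("A and gradient tensors must share shape")
  }
  structure(list(A = A, grads1 = grads1, grads2 = grads2, grads3 = grads3,
                 target_class = target_class),
            class = "lca_featuremap_stack")
}

relu <- function(x) pmax(x, 0)

#' Pixel-wise gradient weights (alpha)
#'
#' Where the denominator magnitude falls below `eps` it is replaced by 1,
#' so a linear score (vanishing higher derivatives) degrades gracefully to
#' zero alpha instead of NaN.
#'
#' @param stack `lca_featuremap_stack`.
#' @param eps Zero-denominator guard; default `1e-8`.
#' @return Array `M x N x K` of alpha weights.
#' @export
alpha_weights <- function(stack, eps = 1e-8) {
  stopifnot(inherits(stack, "lca_featuremap_stack"))
  K <- dim(stack$A)[3]
  global <- vapply(seq_len(K), function(k) {
    sum(stack$A[, , k] * stack$grads3[, , k])
  }, numeric(1))
  # denominator: 2*d2 + per-map global term, broadcast over (m, n)
  den <- 2 * stack$grads2
  for (k in seq_len(K)) den[, , k] <- den[, , k] + global[k]
  den[abs(den) < eps] <- 1
  stack$grads2 / den
}

#' Channel weights from alphas and positive gradients
#'
#' @param stack `lca_featuremap_stack`.
#' @param alphas Output of [alpha_weights()].
#' @return Numeric vector of length K.
#' @export
channel_weights <- function(stack, alphas = alpha_weights(stack)) {
  stopifnot(inherits(stack, "lca_featuremap_stack"))
  if (!identical(dim(alphas), dim(stack$A))) stop("alpha shape mismatch")
  K <- dim(stack$A)[3]
  vapply(seq_len(K), function(k) {
    sum(alphas[, , k] * relu(stack$grads1[, , k]))
  }, numeric(1))
}

#' Grad-CAM++ heatmap
#'
#' @param stack `lca_featuremap_stack`.
#' @param weights Channel weights; default computed via [alpha_weights()]
#'   and [channel_weights()].
#' @param upsample_to Optional `c(H, W)` for a bilinear upsample of the
#'   normalized map (for overlay at image resolution).
#' @return Object of class `lca_heatmap` with the raw nonnegative map `L`,
#'   a min-max `normalized` copy in `[0, 1]` (all zeros when `L` is
#'   constant), the `target_class`, and optionally `upsampled`.
#' @export
gradcam_heatmap <- function(stack, weights = NULL, upsample_to = NULL) {
  stopifnot(inherits(stack, "lca_featuremap_stack"))
  if (is.null(weights)) weights <- channel_weights(stack)
  K <- dim(stack$A)[3]
  if (length(weights) != K) stop("need one weight per feature map")
  L <- matrix(0, dim(stack$A)[1], dim(stack$A)[2])
  for (k in seq_len(K)) L <- L + weights[k] * stack$A[, , k]
  L <- relu(L)
  rng <- range(L)
  normalized <- if (rng[2] > rng[1]) (L - rng[1]) / (rng[2] - rng[1]) else L * 0
  out <- list(L = L, normalized = normalized,
              target_class = stack$target_class)
  if (!is.null(upsample_to)) {
    out$upsampled <- bilinear_resize(normalized, upsample_to[1], upsample_to[2])
  }
  structure(out, class = "lca_heatmap")
}

# Bilinear resize of a matrix to H x W (align corners).
bilinear_resize <- function(mat, H, W) {
  h0 <- nrow(mat); w0 <- ncol(mat)
  rows <- if (h0 == 1) rep(1, H) else seq(1, h0, length.out = H)
  cols <- if (w0 == 1) rep(1, W) else seq(1, w0, length.out = W)
  r0 <- pmax(pmin(floor(rows), h0 - 1L), 1)
  c0 <- pmax(pmin(floor(cols), w0 - 1L), 1)
  fr <- rows - r0; fc <- cols - c0
  if (h0 == 1) { r0 <- rep(1, H); fr <- rep(0, H) }
  if (w0 == 1) { c0 <- rep(1, W); fc <- rep(0, W) }
  r1 <- pmin(r0 + 1, h0); c1 <- pmin(c0 + 1, w0)
  m00 <- mat[r0, c0, drop = FALSE]; m10 <- mat[r1, c0, drop = FALSE]
  m01 <- mat[r0, c1, drop = FALSE]; m11 <- mat[r1, c1, drop = FALSE]
  wr <- matrix(fr, H, W); wc <- matrix(fc, H, W, byrow = TRUE)
  (1 - wr) * ((1 - wc) * m00 + wc * m01) + wr * ((1 - wc) * m10 + wc * m11)
}

#' Render a heatmap overlay on an image
#'
#' Blends a blue-to-red colormap of the normalized heatmap with the input
#' image and optionally writes the overlay (and the raw map as a 16-bit
#' grayscale PNG) to disk.
#'
#' @param heatmap `lca_heatmap`.
#' @param image `H x W x 3` array the map explains.
#' @param alpha Blend factor of the colormap; default 0.5.
#' @param overlay_png,raw_png Optional output paths.
#' @return The overlay image array, invisibly.
#' @export
heatmap_overlay <- function(heatmap, image, alpha = 0.5,
                            overlay_png = NULL, raw_png = NULL) {
  stopifnot(inherits(heatmap, "lca_heatmap"))
  stopifnot_image(image)
  H <- dim(image)[1]; W <- dim(image)[2]
  hm <- bilinear_resize(heatmap$normalized, H, W)
  ramp <- colorRamp(c("navy", "cyan", "yellow", "red"))
  cols <- ramp(as.vector(hm)) / 255
  cmap <- array(cols, dim = c(H, W, 3))
  overlay <- clip01((1 - alpha) * image + alpha * cmap)
  if (!is.null(overlay_png)) write_image_rgb(overlay, overlay_png)
  if (!is.null(raw_png)) {
    png::writePNG(clip01(hm), raw_png)  # 16-bit-capable grayscale raw map
  }
  invisible(overlay)
}
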