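#' Equidistant crop grid
#'
#' Top-left offsets are the rounded linear spacing from 0 to the maximal
#' offset along each axis, inclusive of both extremes, so the grid always
#' contains the upper-left and lower-right corner crops. With the defaults
#' (224 x 224 crops, 4 per axis) a 600 x 450 image yields the 16 regions of
#' interest used for multi-crop evaluation.
#'
#' @param image_size `c(H, W)` of the source image.
#' @param crop_size `c(h, w)` of each crop; default `c(224, 224)`.
#' @param n_per_axis Crops per axis; default 4 (16 crops).
#' @return Object of class `lca_crop_grid`: a data frame of 0-based offsets
#'   `x` (column) and `y` (row) plus attributes `crop_size`, `n_per_axis`.
#' @export
crop_grid <- function(image_size, crop_size = c(224, 224), n_per_axis = 4) {
  H <- image_size[1]; W <- image_size[2]
  ch <- crop_size[1]; cw <- crop_size[2]
  if (H < ch || W < cw) {
    stop(sprintf("image (%d x %d) smaller than crop (%d x %d)", H, W, ch, cw))
  }
  if (n_per_axis < 1) stop("n_per_axis must be >= 1")
  xs <- round(seq(0, W - cw, length.out = n_per_axis))
  ys <- round(seq(0, H - ch, length.out = n_per_axis))
  grid <- expand.grid(y = ys, x = xs)[, c("x", "y")]
  structure(grid, class = c("lca_crop_grid", "data.frame"),
            crop_size = c(ch, cw), n_per_axis = n_per_axis)
}

#' Cut the equidistant grid of crops from an image
#'
#' @param image `H x W x 3` array.
#' @inheritParams crop_grid
#' @return List of `n_per_axis^2` crop arrays, with the grid as attribute
#'   `grid`.
#' @export
grid_crops <- function(image, crop_size = c(224, 224), n_per_axis = 4) {
  stopifnot_image(image)
  g <- crop_grid(dim(image)[1:2], crop_size, n_per_axis)
  ch <- attr(g, "crop_size")[1]; cw <- attr(g, "crop_size")[2]
  crops <- lapply(seq_len(nrow(g)), function(i) {
    y0 <- g$y[i]; x0 <- g$x[i]
    image[(y0 + 1):(y0 + ch), (x0 + 1):(x0 + cw), , drop = FALSE]
  })
  attr(crops, "grid") <- g
  crops
}

#' Multi-crop prediction averaging
#'
#' Applies `model` to every crop of the equidistant grid and returns the
#' unweighted mean of the per-crop class-probability vectors; the average
#' of probability vectors is itself a probability vector.
#'
#' @param model Function mapping one crop array to a class-probability
#'   vector summing to 1.
#' @param image `H x W x 3` array.
#' @inheritParams crop_grid
#' @return Averaged class-probability vector.
#' @export
multicrop_predict <- function(model, image, crop_size = c(224, 224),
                              n_per_axis = 4) {
  crops <- grid_crops(image, crop_size, n_per_axis)
  preds <- lapply(crops, model)
  len <- unique(vapply(preds, length, integer(1)))
  if (length(len) != 1L) stop("model returned vectors of differing length")
  if (any(vapply(preds, function(p) abs(sum(p) - 1) > 1e-6, logical(1)))) {
    stop("model must return probability vectors summing to 1")
  }
  Reduce(`+`, preds) / length(preds)
}

#' Centre crop
#'
#' @param image `H x W x 3` array.
#' @param crop_size `c(h, w)`.
#' @return The central crop.
#' @export
center_crop <- function(image, crop_size) {
  H <- dim(image)[1]; W <- dim(image)[2]
  ch <- crop_size[1]; cw <- crop_size[2]
  if (H < ch || W < cw) stop("image smaller than crop")
  y0 <- floor((H - ch) / 2); x0 <- floor((W - cw) / 2)
  image[(y0 + 1):(y0 + ch), (x0 + 1):(x0 + cw), , drop = FALSE]
}

#' Random crop (uniform over valid offsets)
#'
#' @inheritParams center_crop
#' @return A crop drawn uniformly over all valid positions.
#' @export
random_crop <- function(image, crop_size) {
  H <- dim(image)[1]; W <- dim(image)[2]
  ch <- crop_size[1]; cw <- crop_size[2]
  if (H < ch || W < cw) stop("image smaller than crop")
  y0 <- sample.int(H - ch + 1L, 1L) - 1L
  x0 <- sample.int(W - cw + 1L, 1L) - 1L
  image[(y0 + 1):(y0 + ch), (x0 + 1):(x0 + cw), , drop = FALSE]
}
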