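#' Read an 8-bit RGB image
#'
#' Images are represented throughout the package as numeric arrays of
#' dimension `H x W x 3` with values in `[0, 1]` (row = image row, column =
#' image column). PNG files are read natively; JPEG files are supported when
#' the \pkg{EBImage} package is available.
#'
#' @param path Path to a PNG or JPEG file.
#' @return Numeric array `H x W x 3` in `[0, 1]`.
#' @export
read_image_rgb <- function(path) {
  if (!file.exists(path)) stop("image file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    img <- png::readPNG(path)
  } else if (ext %in% c("jpg", "jpeg")) {
    if (!requireNamespace("EBImage", quietly = TRUE)) {
      stop("reading JPEG requires the EBImage package")
    }
    eb <- EBImage::readImage(path)
    img <- aperm(EBImage::imageData(eb), c(2, 1, 3))
  } else {
    stop("unsupported image format: ", ext)
  }
  as_rgb_array(img)
}

#' Write an 8-bit RGB image as PNG
#'
#' @param image Numeric array `H x W x 3` in `[0, 1]`.
#' @param path Output path (`.png`).
#' @return `path`, invisibly.
#' @export
write_image_rgb <- function(image, path) {
  image <- as_rgb_array(image)
  png::writePNG(clip01(image), path)
  invisible(path)
}

# Coerce grayscale / RGBA inputs to the canonical H x W x 3 form.
as_rgb_array <- function(img) {
  if (is.matrix(img)) img <- array(rep(img, 3L), dim = c(dim(img), 3L))
  if (length(dim(img)) != 3L) stop("expected an image array with 2 or 3 dims")
  if (dim(img)[3] == 4L) img <- img[, , 1:3, drop = FALSE]
  if (dim(img)[3] != 3L) stop("expected 1, 3 or 4 channels")
  storage.mode(img) <- "double"
  img
}

clip01 <- function(x) {
  x[x < 0] <- 0
  x[x > 1] <- 1
  x
}

stopifnot_image <- function(image) {
  if (!is.array(image) || length(dim(image)) != 3L || dim(image)[3] != 3L) {
    stop("image must be an H x W x 3 numeric array")
  }
  if (anyNA(image)) stop("image contains NA values")
  invisible(image)
}

# Vectorised HSV -> RGB for H x W planes (h, s, v matrices in [0,1]).
hsv_to_rgb_planes <- function(h, s, v) {
  h6 <- (h %% 1) * 6
  i <- floor(h6) %% 6
  f <- h6 - floor(h6)
  p <- v * (1 - s)
  q <- v * (1 - f * s)
  t <- v * (1 - (1 - f) * s)
  pick <- function(a0, a1, a2, a3, a4, a5) {
    out <- a0
    out[i == 1] <- a1[i == 1]; out[i == 2] <- a2[i == 2]
    out[i == 3] <- a3[i == 3]; out[i == 4] <- a4[i == 4]
    out[i == 5] <- a5[i == 5]
    out
  }
  list(r = pick(v, q, p, p, t, v),
       g = pick(t, v, v, q, p, p),
       b = pick(p, p, t, v, v, q))
}

# RGB array -> list(h, s, v) matrices in [0,1].
rgb_to_hsv_planes <- function(image) {
  d <- dim(image)
  m <- rbind(as.vector(image[, , 1]), as.vector(image[, , 2]),
             as.vector(image[, , 3]))
  hsv <- grDevices::rgb2hsv(m, maxColorValue = 1)
  list(h = matrix(hsv[1, ], d[1], d[2]),
       s = matrix(hsv[2, ], d[1], d[2]),
       v = matrix(hsv[3, ], d[1], d[2]))
}

planes_to_rgb <- function(p) {
  array(c(p$r, p$g, p$b), dim = c(dim(p$r), 3L))
}
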