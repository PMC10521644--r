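#' Image transform operations
#'
#' Each augmentation primitive is a [transform_op()]: a named, categorised
#' (`color` or `geometric`) operation with a closed magnitude range in
#' op-specific units. Geometric warps keep the output frame equal to the
#' input frame, filling exposed pixels by edge reflection; every op clips
#' its output back to the valid intensity range `[0, 1]`.
#'
#' Magnitude units: degrees for `rotate`; fraction of the side length for
#' `translate`; shear coefficient for `shear`; multiplicative factor for
#' `scale`, `brightness`, `contrast`, `saturation`, `sharpness` and `gamma`
#' (1 = identity); hue offset in `[0, 1]` turns for `hue_shift`; channel
#' rebalance coefficient for `color_jitter`; pixel-intensity standard
#' deviation for `gaussian_noise`; bit depth for `posterize`; inversion
#' threshold for `solarize`; blend fraction for `equalize` and
#' `autocontrast`.
#'
#' @name transform-ops
NULL

# ---- geometric helpers -----------------------------------------------------

# Apply the inverse affine map [a b tx; c d ty] (output (col,row) -> source)
# about the image centre and resample with reflection (compiled kernel).
warp_affine <- function(image, mat) {
  warp_affine_cpp(image, mat)
}

luminance <- function(image) {
  0.299 * image[, , 1] + 0.587 * image[, , 2] + 0.114 * image[, , 3]
}

blur3 <- function(image) {
  # 3x3 box blur with reflective edges, per channel.
  H <- dim(image)[1]; W <- dim(image)[2]
  ri <- cbind(c(1, 1:(H - 1)), 1:H, c(2:H, H))
  ci <- cbind(c(1, 1:(W - 1)), 1:W, c(2:W, W))
  out <- image
  for (ch in 1:3) {
    p <- image[, , ch]
    rows <- (p[ri[, 1], ] + p[ri[, 2], ] + p[ri[, 3], ]) / 3
    out[, , ch] <- (rows[, ci[, 1]] + rows[, ci[, 2]] + rows[, ci[, 3]]) / 3
  }
  out
}

equalize_channel <- function(p) {
  # 256-bin histogram equalisation of one [0,1] plane.
  q <- as.integer(pmin(pmax(round(p * 255), 0), 255))
  h <- tabulate(q + 1L, nbins = 256L)
  cdf <- cumsum(h)
  cdf0 <- cdf[which(h > 0)[1]]
  if (cdf0 == length(q)) return(p)  # constant plane
  map <- (cdf - cdf0) / (length(q) - cdf0)
  matrix(map[q + 1L], nrow(p), ncol(p))
}

# ---- op implementations ----------------------------------------------------

op_fns <- list(
  brightness = function(image, m) image * m,
  contrast = function(image, m) {
    mu <- mean(luminance(image))
    (image - mu) * m + mu
  },
  saturation = function(image, m) {
    g <- luminance(image)
    gray <- array(rep(g, 3L), dim = dim(image))
    gray + (image - gray) * m
  },
  hue_shift = function(image, m) {
    p <- rgb_to_hsv_planes(image)
    planes_to_rgb(hsv_to_rgb_planes(p$h + m, p$s, p$v))
  },
  color_jitter = function(image, m) {
    # deterministic warm/cool white-balance shift
    image[, , 1] <- image[, , 1] * (1 + m)
    image[, , 3] <- image[, , 3] * (1 - m)
    image
  },
  gaussian_noise = function(image, m) {
    image + array(stats::rnorm(length(image), 0, m), dim = dim(image))
  },
  sharpness = function(image, m) {
    b <- blur3(image)
    b + (image - b) * m
  },
  posterize = function(image, m) {
    levels <- 2^as.integer(round(m)) - 1
    round(image * levels) / levels
  },
  solarize = function(image, m) {
    inv <- image > m
    image[inv] <- 1 - image[inv]
    image
  },
  equalize = function(image, m) {
    eq <- image
    for (ch in 1:3) eq[, , ch] <- equalize_channel(image[, , ch])
    image * (1 - m) + eq * m
  },
  autocontrast = function(image, m) {
    st <- image
    for (ch in 1:3) {
      p <- image[, , ch]
      lo <- min(p); hi <- max(p)
      if (hi > lo) st[, , ch] <- (p - lo) / (hi - lo)
    }
    image * (1 - m) + st * m
  },
  gamma = function(image, m) clip01(image)^m,
  hflip = function(image, m) image[, dim(image)[2]:1, , drop = FALSE],
  vflip = function(image, m) image[dim(image)[1]:1, , , drop = FALSE],
  rotate = function(image, m) {
    if (m == 0) return(image)
    th <- m * pi / 180
    # inverse rotation of the output grid
    warp_affine(image, matrix(c(cos(th), -sin(th), 0,
                                sin(th), cos(th), 0), 2, 3, byrow = TRUE))
  },
  scale = function(image, m) {
    if (m == 1) return(image)
    warp_affine(image, matrix(c(1 / m, 0, 0, 0, 1 / m, 0), 2, 3, byrow = TRUE))
  },
  translate = function(image, m) {
    dx <- m * dim(image)[2]
    dy <- m * dim(image)[1]
    warp_affine(image, matrix(c(1, 0, -dx, 0, 1, -dy), 2, 3, byrow = TRUE))
  },
  shear = function(image, m) {
    warp_affine(image, matrix(c(1, m, 0, 0, 1, 0), 2, 3, byrow = TRUE))
  }
)

default_op_table <- function() {
  data.frame(
    name = c("brightness", "contrast", "saturation", "hue_shift",
             "color_jitter", "gaussian_noise", "sharpness", "posterize",
             "solarize", "equalize", "autocontrast", "gamma",
             "hflip", "vflip", "rotate", "scale", "translate", "shear"),
    category = c(rep("color", 12), rep("geometric", 6)),
    lo = c(0.6, 0.6, 0.6, -0.1, -0.2, 0, 0.6, 4, 0.5, 0, 0, 0.6,
           0, 0, -30, 0.8, -0.2, -0.3),
    hi = c(1.4, 1.4, 1.4, 0.1, 0.2, 20 / 255, 1.4, 8, 1, 1, 1, 1.4,
           1, 1, 30, 1.2, 0.2, 0.3),
    stringsAsFactors = FALSE
  )
}

#' Construct a transform operation
#'
#' @param name Operation name. Must be one of the built-in ops listed by
#'   [list_transform_ops()].
#' @param magnitude_range Optional length-2 numeric `c(lo, hi)` overriding the
#'   default magnitude range.
#' @return An object of class `lca_transform_op` with fields `name`,
#'   `category`, `magnitude_range` and the pure apply function `fn`.
#' @export
transform_op <- function(name, magnitude_range = NULL) {
  tab <- default_op_table()
  row <- tab[tab$name == name, ]
  if (nrow(row) != 1L) {
    stop("unknown transform op: ", name, " (see list_transform_ops())")
  }
  rng <- if (is.null(magnitude_range)) c(row$lo, row$hi) else magnitude_range
  if (length(rng) != 2L || !is.numeric(rng) || rng[1] > rng[2]) {
    stop("magnitude_range must be numeric c(lo, hi) with lo <= hi")
  }
  structure(
    list(name = name, category = row$category,
         magnitude_range = as.numeric(rng), fn = op_fns[[name]]),
    class = "lca_transform_op"
  )
}

#' List the built-in transform operations
#'
#' @return Data frame with columns `name`, `category`, `lo`, `hi` (default
#'   magnitude range).
#' @export
list_transform_ops <- function() default_op_table()

#' @export
print.lca_transform_op <- function(x, ...) {
  cat(sprintf("<transform_op %s (%s), magnitude in [%g, %g]>\n",
              x$name, x$category, x$magnitude_range[1], x$magnitude_range[2]))
  invisible(x)
}

#' Apply one transform operation at a given magnitude
#'
#' Deterministic given `magnitude` for every op except `gaussian_noise`,
#' which draws from R's random number stream. Output is clipped to `[0, 1]`
#' and has the same dimensions as the input.
#'
#' @param image `H x W x 3` array in `[0, 1]`.
#' @param op An `lca_transform_op`.
#' @param magnitude Magnitude within `op$magnitude_range`.
#' @return Transformed image array.
#' @export
apply_op <- function(image, op, magnitude) {
  stopifnot_image(image)
  if (!inherits(op, "lca_transform_op")) stop("op must be an lca_transform_op")
  if (!is.numeric(magnitude) || length(magnitude) != 1L || is.na(magnitude)) {
    stop("magnitude must be a single number")
  }
  if (magnitude < op$magnitude_range[1] || magnitude > op$magnitude_range[2]) {
    stop(sprintf("magnitude %g outside range [%g, %g] for op %s",
                 magnitude, op$magnitude_range[1], op$magnitude_range[2],
                 op$name))
  }
  clip01(op$fn(image, magnitude))
}
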