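#' Synthetic dermoscopy-like datasets
#'
#' Renders class-imbalanced sets of skin-tone images with a centred
#' elliptical "lesion" whose color (hue/saturation/value), geometry
#' (eccentricity, size) and border (radial irregularity) statistics differ
#' by class. Images sharing a lesion group id share the underlying lesion
#' parameters up to small jitter, emulating repeated dermoscopy of the
#' same lesion; grouped cross-validation must keep them on one side of
#' every split. Identical spec and seed give bit-identical images.
#'
#' @name synthetic-data
NULL

#' Specification of a synthetic dataset
#'
#' @param class_counts Named integer vector of images per class. The
#'   default mirrors the 7-class imbalance of a well-known dermoscopy
#'   archive (counts spanning two orders of magnitude) scaled to 700
#'   images, so weighted-loss effects are visible at desk scale.
#' @param image_size `c(H, W)`, at least 64 x 64 (nominal sizes up to
#'   600 x 450 are supported).
#' @param color_signal Data frame with per-class `hue`, `sat`, `val`
#'   (lesion color in HSV); defaults spread hues across classes with
#'   lesion value kept below the skin luminance.
#' @param shape_signal Data frame with per-class `ecc` (ellipse
#'   eccentricity), `border_amp` (radial border irregularity amplitude),
#'   `border_freq` (lobes), `size` (lesion radius as a fraction of half
#'   the short side).
#' @param noise_sigma Additive Gaussian pixel noise sd; default 0.03.
#' @param groups_per_class Optional named/unnamed counts of lesion groups
#'   per class (each group then holds several images of "the same
#'   lesion"); `NULL` gives every image its own group.
#' @param seed Integer seed; the generator is fully deterministic given
#'   the spec.
#' @return Object of class `lca_synthetic_spec`.
#' @export
synthetic_spec <- function(class_counts = c(nv = 468, mel = 78, bkl = 77,
                                            bcc = 36, akiec = 23, vasc = 10,
                                            df = 8),
                           image_size = c(64, 64),
                           color_signal = NULL, shape_signal = NULL,
                           noise_sigma = 0.03, groups_per_class = NULL,
                           seed = 1) {
  if (any(class_counts < 0) || sum(class_counts) < 1) {
    stop("class_counts must be nonnegative with a positive total")
  }
  if (any(image_size < 64)) stop("image_size must be at least 64 x 64")
  C <- length(class_counts)
  if (is.null(names(class_counts))) {
    names(class_counts) <- paste0("class", seq_len(C))
  }
  if (is.null(color_signal)) {
    color_signal <- data.frame(hue = seq(0.02, 0.32, length.out = C),
                               sat = rep(0.65, C),
                               val = seq(0.35, 0.5, length.out = C))
  }
  if (is.null(shape_signal)) {
    shape_signal <- data.frame(ecc = seq(0.1, 0.85, length.out = C),
                               border_amp = seq(0.02, 0.2, length.out = C),
                               border_freq = round(seq(4, 8, length.out = C)),
                               size = rep(0.55, C))
  }
  stopifnot(nrow(color_signal) == C, nrow(shape_signal) == C)
  structure(list(class_counts = class_counts, image_size = image_size,
                 color_signal = color_signal, shape_signal = shape_signal,
                 noise_sigma = noise_sigma,
                 groups_per_class = groups_per_class, seed = seed),
            class = "lca_synthetic_spec")
}

# Render one lesion image from a full parameter record.
render_lesion_image <- function(H, W, p) {
  rr <- matrix(seq_len(H), H, W)
  cc <- matrix(seq_len(W), H, W, byrow = TRUE)
  # skin background with a gentle illumination field
  bg <- array(0, dim = c(H, W, 3))
  base <- c(0.86, 0.67, 0.58)
  field <- p$bg_amp * sin(2 * pi * (rr / H * p$bg_fy + p$bg_py)) *
    sin(2 * pi * (cc / W * p$bg_fx + p$bg_px))
  for (ch in 1:3) bg[, , ch] <- base[ch] * (1 + field)
  # lesion geometry
  u <- cc - (W + 1) / 2 - p$dx
  v <- rr - (H + 1) / 2 - p$dy
  ur <- cos(p$angle) * u + sin(p$angle) * v
  vr <- -sin(p$angle) * u + cos(p$angle) * v
  R <- p$size * min(H, W) / 2
  shrink <- sqrt(1 - p$ecc^2)
  a <- R / sqrt(shrink)
  b <- R * sqrt(shrink)
  rho <- sqrt((ur / a)^2 + (vr / b)^2)
  phi <- atan2(vr, ur)
  edge <- 1 + p$border_amp * sin(p$border_freq * phi + p$border_phase)
  mask <- 1 / (1 + exp((rho - edge) / 0.04))
  col <- hsv_to_rgb_planes(matrix(p$hue, 1, 1), matrix(p$sat, 1, 1),
                           matrix(p$val, 1, 1))
  lesion_rgb <- c(col$r, col$g, col$b)
  tex <- 1 + p$tex_amp * matrix(stats::rnorm(H * W), H, W)
  img <- bg
  for (ch in 1:3) {
    img[, , ch] <- bg[, , ch] * (1 - mask) + lesion_rgb[ch] * tex * mask
  }
  img <- img + array(stats::rnorm(H * W * 3, 0, p$noise_sigma),
                     dim = c(H, W, 3))
  clip01(img)
}

jitter_clamp <- function(x, sd, lo, hi) pmin(pmax(x + stats::rnorm(1, 0, sd), lo), hi)

#' Generate a synthetic dataset
#'
#' @param spec An [synthetic_spec()].
#' @param dir Optional output directory; when given, PNG images and
#'   `manifest.csv` are written there.
#' @return Dataset list: `images` (arrays), `manifest`
#'   (`image`, `label`, `group_id`), `levels`, and `params` (the true
#'   per-image generative parameters, useful for oracle checks).
#' @export
generate_dataset <- function(spec, dir = NULL) {
  stopifnot(inherits(spec, "lca_synthetic_spec"))
  set.seed(spec$seed)
  H <- spec$image_size[1]; W <- spec$image_size[2]
  classes <- names(spec$class_counts)
  images <- list(); rows <- list(); pars <- list()
  n_total <- 0L
  for (ci in seq_along(classes)) {
    n <- spec$class_counts[ci]
    if (n == 0) next
    g <- if (is.null(spec$groups_per_class)) n else
      min(n, spec$groups_per_class[min(ci, length(spec$groups_per_class))])
    group_of <- sort(rep_len(seq_len(g), n))
    cs <- spec$color_signal[ci, ]; ss <- spec$shape_signal[ci, ]
    group_base <- lapply(seq_len(g), function(gi) {
      list(hue = (cs$hue + stats::rnorm(1, 0, 0.02)) %% 1,
           sat = jitter_clamp(cs$sat, 0.05, 0.2, 1),
           val = jitter_clamp(cs$val, 0.03, 0.1, 0.6),
           ecc = jitter_clamp(ss$ecc, 0.03, 0, 0.95),
           border_amp = jitter_clamp(ss$border_amp, 0.01, 0, 0.35),
           border_freq = ss$border_freq,
           border_phase = stats::runif(1, 0, 2 * pi),
           size = jitter_clamp(ss$size, 0.03, 0.2, 0.85))
    })
    for (i in seq_len(n)) {
      gb <- group_base[[group_of[i]]]
      p <- list(
        hue = (gb$hue + stats::rnorm(1, 0, 0.005)) %% 1,
        sat = jitter_clamp(gb$sat, 0.01, 0.2, 1),
        val = jitter_clamp(gb$val, 0.01, 0.1, 0.6),
        ecc = jitter_clamp(gb$ecc, 0.01, 0, 0.95),
        border_amp = gb$border_amp,
        border_freq = gb$border_freq,
        border_phase = gb$border_phase + stats::rnorm(1, 0, 0.1),
        size = jitter_clamp(gb$size, 0.01, 0.2, 0.85),
        angle = stats::runif(1, 0, pi),
        dx = stats::rnorm(1, 0, W * 0.02), dy = stats::rnorm(1, 0, H * 0.02),
        tex_amp = 0.05,
        bg_amp = 0.03, bg_fx = stats::runif(1, 0.5, 1.5),
        bg_fy = stats::runif(1, 0.5, 1.5),
        bg_px = stats::runif(1), bg_py = stats::runif(1),
        noise_sigma = spec$noise_sigma
      )
      n_total <- n_total + 1L
      images[[n_total]] <- render_lesion_image(H, W, p)
      rows[[n_total]] <- data.frame(
        image = sprintf("%s_%04d.png", classes[ci], i),
        label = classes[ci],
        group_id = sprintf("%s_g%03d", classes[ci], group_of[i]))
      pars[[n_total]] <- data.frame(hue = p$hue, ecc = p$ecc,
                                    border_amp = p$border_amp,
                                    size = p$size, val = p$val)
    }
  }
  if (n_total == 0L) stop("spec generates zero images")
  dataset <- list(images = images, manifest = do.call(rbind, rows),
                  levels = classes, params = do.call(rbind, pars))
  if (!is.null(dir)) write_dataset(dataset, dir)
  dataset
}

#' Write a dataset to disk (PNG images + manifest.csv)
#'
#' @param dataset Dataset list.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(dataset$images)) {
    write_image_rgb(dataset$images[[i]],
                    file.path(dir, dataset$manifest$image[i]))
  }
  write.csv(dataset$manifest, file.path(dir, "manifest.csv"),
            row.names = FALSE)
  invisible(dir)
}

#' Load a dataset from a manifest
#'
#' @param manifest_csv Path to a CSV with columns `image`, `label`,
#'   `group_id`; image paths are resolved relative to the CSV directory.
#' @return Dataset list (`images`, `manifest`, `levels`).
#' @export
load_dataset <- function(manifest_csv) {
  manifest <- read.csv(manifest_csv, stringsAsFactors = FALSE)
  need <- c("image", "label", "group_id")
  if (!all(need %in% names(manifest))) {
    stop("manifest must have columns: ", paste(need, collapse = ", "))
  }
  base <- dirname(manifest_csv)
  images <- lapply(manifest$image, function(f) {
    read_image_rgb(if (file.exists(f)) f else file.path(base, f))
  })
  list(images = images, manifest = manifest,
       levels = sort(unique(manifest$label)))
}

#' Planted-invariance datasets for search validation
#'
#' `color-nuisance`: the class is carried purely by lesion shape
#' (eccentricity and border irregularity); hue is drawn uniformly per
#' lesion group, so color is a memorisable nuisance that color
#' augmentation should neutralise. `shape-nuisance`: the converse — class
#' is carried by hue and the geometry is randomised per group.
#'
#' @param kind `"color-nuisance"` or `"shape-nuisance"`.
#' @param n_per_class Images per class (each >= 40); either a single count
#'   shared by all classes or a vector of per-class counts. The default is
#'   the imbalanced profile `c(180, 100, 70, 50)` (400 images), since
#'   class-imbalanced sets are the regime the augmentation search targets.
#' @param n_classes Number of classes; default 4.
#' @param image_size `c(H, W)`; default 64 x 64.
#' @param images_per_group Images per lesion group; default 4.
#' @param seed Seed.
#' @return Dataset list as from [generate_dataset()].
#' @export
planted_invariance_dataset <- function(kind = c("color-nuisance",
                                                "shape-nuisance"),
                                       n_per_class = c(180, 100, 70, 50),
                                       n_classes = 4,
                                       image_size = c(64, 64),
                                       images_per_group = 4, seed = 1) {
  kind <- match.arg(kind)
  n_per_class <- rep_len(n_per_class, n_classes)
  if (any(n_per_class < 40)) stop("need at least 40 images per class")
  set.seed(seed)
  H <- image_size[1]; W <- image_size[2]
  classes <- paste0("class", seq_len(n_classes))
  ecc_sig <- seq(0.05, 0.88, length.out = n_classes)
  amp_sig <- seq(0.02, 0.22, length.out = n_classes)
  frq_sig <- round(seq(4, 7, length.out = n_classes))
  size_sig <- rep(0.55, n_classes)  # size carries no class information
  hue_sig <- (seq_len(n_classes) - 1) / n_classes
  images <- list(); rows <- list(); pars <- list()
  n_total <- 0L
  for (ci in seq_len(n_classes)) {
    n_i <- n_per_class[ci]
    groups_i <- max(1L, ceiling(n_i / images_per_group))
    group_of <- sort(rep_len(seq_len(groups_i), n_i))
    group_base <- lapply(seq_len(groups_i), function(gi) {
      base <- if (kind == "color-nuisance") {
        list(hue = stats::runif(1),                 # nuisance, per lesion
             sat = stats::runif(1, 0.5, 0.9),
             val = stats::runif(1, 0.3, 0.5),
             ecc = jitter_clamp(ecc_sig[ci], 0.03, 0, 0.95),
             border_amp = jitter_clamp(amp_sig[ci], 0.01, 0, 0.3),
             border_freq = frq_sig[ci],
             size = jitter_clamp(size_sig[ci], 0.02, 0.2, 0.85))
      } else {
        list(hue = (hue_sig[ci] + stats::rnorm(1, 0, 0.02)) %% 1,  # signal
             sat = stats::runif(1, 0.6, 0.9),
             val = stats::runif(1, 0.3, 0.5),
             ecc = stats::runif(1, 0, 0.9),          # nuisance, per lesion
             border_amp = stats::runif(1, 0, 0.25),
             border_freq = sample(4:8, 1),
             size = stats::runif(1, 0.4, 0.7))
      }
      # one lesion = one photographic framing, up to small jitter
      base$angle <- stats::runif(1, 0, pi)
      base$border_phase <- stats::runif(1, 0, 2 * pi)
      base$dx <- stats::rnorm(1, 0, W * 0.02)
      base$dy <- stats::rnorm(1, 0, H * 0.02)
      base
    })
    for (i in seq_len(n_i)) {
      gb <- group_base[[group_of[i]]]
      p <- list(hue = (gb$hue + stats::rnorm(1, 0, 0.005)) %% 1,
                sat = jitter_clamp(gb$sat, 0.01, 0.2, 1),
                val = jitter_clamp(gb$val, 0.01, 0.1, 0.6),
                ecc = jitter_clamp(gb$ecc, 0.01, 0, 0.95),
                border_amp = gb$border_amp,
                border_freq = gb$border_freq,
                border_phase = gb$border_phase + stats::rnorm(1, 0, 0.05),
                size = jitter_clamp(gb$size, 0.01, 0.2, 0.85),
                angle = gb$angle + stats::rnorm(1, 0, 0.05),
                dx = gb$dx + stats::rnorm(1, 0, 1),
                dy = gb$dy + stats::rnorm(1, 0, 1),
                tex_amp = 0.05, bg_amp = 0.03,
                bg_fx = stats::runif(1, 0.5, 1.5),
                bg_fy = stats::runif(1, 0.5, 1.5),
                bg_px = stats::runif(1), bg_py = stats::runif(1),
                noise_sigma = 0.04)
      n_total <- n_total + 1L
      images[[n_total]] <- render_lesion_image(H, W, p)
      rows[[n_total]] <- data.frame(
        image = sprintf("%s_%04d.png", classes[ci], i),
        label = classes[ci],
        group_id = sprintf("%s_g%03d", classes[ci], group_of[i]))
      pars[[n_total]] <- data.frame(hue = p$hue, ecc = p$ecc,
                                    border_amp = p$border_amp,
                                    size = p$size, val = p$val)
    }
  }
  list(images = images, manifest = do.call(rbind, rows), levels = classes,
       params = do.call(rbind, pars))
}

# ---- simple image readouts used as oracle classifiers ----------------------

segment_lesion <- function(image) {
  lum <- luminance(image)
  border <- c(lum[1:2, ], lum[(nrow(lum) - 1):nrow(lum), ],
              lum[, 1:2], lum[, (ncol(lum) - 1):ncol(lum)])
  lum < (stats::median(border) - 0.15)
}

#' Mean lesion hue of an image
#'
#' Segments the lesion as the pixels markedly darker than the image
#' border (skin) and returns the circular mean hue inside.
#'
#' @param image `H x W x 3` array.
#' @return Hue in `[0, 1)`, or `NA` if no lesion pixels are found.
#' @export
lesion_mean_hue <- function(image) {
  m <- segment_lesion(image)
  if (!any(m)) return(NA_real_)
  p <- rgb_to_hsv_planes(image)
  ang <- 2 * pi * p$h[m]
  (atan2(mean(sin(ang)), mean(cos(ang))) / (2 * pi)) %% 1
}

#' Lesion eccentricity estimate from second moments
#'
#' @param image `H x W x 3` array.
#' @return Eccentricity in `[0, 1)` of the segmented lesion, or `NA`.
#' @export
lesion_eccentricity <- function(image) {
  m <- segment_lesion(image)
  if (sum(m) < 16) return(NA_real_)
  idx <- which(m, arr.ind = TRUE)
  cc <- scale(idx, scale = FALSE)
  ev <- eigen(crossprod(cc) / nrow(cc), symmetric = TRUE)$values
  ev[ev < 0] <- 0
  if (ev[1] <= 0) return(NA_real_)
  sqrt(1 - ev[2] / ev[1])
}
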