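# Shared fixtures: small deterministic images and mock models.

random_rgb <- function(h = 16, w = 16, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  array(runif(h * w * 3), dim = c(h, w, 3))
}

constant_rgb <- function(h = 16, w = 16, value = 0.5) {
  array(value, dim = c(h, w, 3))
}

# A gradient image that every color/geometric op visibly alters.
gradient_rgb <- function(h = 16, w = 16) {
  r <- matrix(seq(0.2, 0.8, length.out = h), h, w)
  c <- matrix(seq(0.2, 0.8, length.out = w), h, w, byrow = TRUE)
  array(c(r, c, (r + c) / 2), dim = c(h, w, 3))
}

# A model returning a fixed probability vector regardless of the crop.
constant_model <- function(p) function(crop) p

# Tiny labelled dataset for trainer tests.
tiny_dataset <- function(n_per_class = 10, n_classes = 3, h = 24, seed = 1) {
  set.seed(seed)
  images <- list()
  labels <- character(0)
  for (ci in seq_len(n_classes)) {
    for (i in seq_len(n_per_class)) {
      img <- array(runif(h * h * 3, 0, 0.2), dim = c(h, h, 3))
      img[, , 1] <- img[, , 1] + (ci - 1) / n_classes  # class-coded red level
      images[[length(images) + 1]] <- pmin(img, 1)
      labels <- c(labels, paste0("c", ci))
    }
  }
  list(images = images,
       manifest = data.frame(image = paste0("img", seq_along(images), ".png"),
                             label = labels,
                             group_id = paste0("g", seq_along(images))),
       levels = paste0("c", seq_len(n_classes)))
}
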