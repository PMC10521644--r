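#' Subpolicies and the low-cost augmentation search space
#'
#' A subpolicy pairs one color operation with one geometric operation; the
#' search space is an unordered set of such subpolicies plus a ladder of
#' candidate execution probabilities. The only searched hyperparameter is
#' the execution probability shared by both ops of the selected subpolicy.
#'
#' @name augment-space
NULL

#' Construct a subpolicy
#'
#' @param color_op `lca_transform_op` with category `"color"`.
#' @param geometric_op `lca_transform_op` with category `"geometric"`.
#' @param id Integer identifier.
#' @return Object of class `lca_subpolicy`.
#' @export
subpolicy <- function(color_op, geometric_op, id = NA_integer_) {
  if (!inherits(color_op, "lca_transform_op") || color_op$category != "color") {
    stop("color_op must be a color transform op")
  }
  if (!inherits(geometric_op, "lca_transform_op") ||
      geometric_op$category != "geometric") {
    stop("geometric_op must be a geometric transform op")
  }
  structure(list(color_op = color_op, geometric_op = geometric_op,
                 id = as.integer(id)),
            class = "lca_subpolicy")
}

#' @export
print.lca_subpolicy <- function(x, ...) {
  cat(sprintf("<subpolicy %s: %s + %s>\n",
              ifelse(is.na(x$id), "?", x$id),
              x$color_op$name, x$geometric_op$name))
  invisible(x)
}

#' Construct a search space
#'
#' @param subpolicies List of [subpolicy()] objects.
#' @param ladder_probabilities Candidate execution probabilities in `(0, 1]`
#'   (a value of 0 is tolerated to allow explicit no-augmentation baselines).
#' @return Object of class `lca_search_space`.
#' @export
search_space <- function(subpolicies,
                         ladder_probabilities = c(0.1, 0.3, 0.5, 0.7, 0.9)) {
  if (length(subpolicies) < 1L) stop("need at least one subpolicy")
  ok <- vapply(subpolicies, inherits, logical(1), "lca_subpolicy")
  if (!all(ok)) stop("subpolicies must be lca_subpolicy objects")
  p <- as.numeric(ladder_probabilities)
  if (length(p) < 1L || any(is.na(p)) || any(p < 0) || any(p > 1)) {
    stop("ladder_probabilities must lie in [0, 1]")
  }
  for (i in seq_along(subpolicies)) {
    if (is.na(subpolicies[[i]]$id)) subpolicies[[i]]$id <- i
  }
  structure(list(subpolicies = subpolicies, ladder_probabilities = p),
            class = "lca_search_space")
}

#' @export
print.lca_search_space <- function(x, ...) {
  cat(sprintf("<search space: %d subpolicies x %d probabilities = %d combinations>\n",
              length(x$subpolicies), length(x$ladder_probabilities),
              length(x$subpolicies) * length(x$ladder_probabilities)))
  for (sp in x$subpolicies) print(sp)
  cat("ladder:", paste(x$ladder_probabilities, collapse = ", "), "\n")
  invisible(x)
}

#' An augmentation strategy: a space plus one execution probability
#'
#' @param space `lca_search_space`.
#' @param probability Execution probability in `[0, 1]` applied
#'   independently to each op of the randomly chosen subpolicy.
#' @return Object of class `lca_strategy`.
#' @export
augmentation_strategy <- function(space, probability) {
  if (!inherits(space, "lca_search_space")) stop("space must be a search space")
  if (!is.numeric(probability) || length(probability) != 1L ||
      is.na(probability) || probability < 0 || probability > 1) {
    stop("probability must be a single value in [0, 1]")
  }
  structure(list(space = space, probability = probability),
            class = "lca_strategy")
}

#' Build the default 60-candidate search space
#'
#' Twelve pairwise-distinct color operations are each paired with one of six
#' geometric operations such that every geometric operation appears in
#' exactly two subpolicies, and the probability ladder is
#' `{0.1, 0.3, 0.5, 0.7, 0.9}` — hence 12 x 5 = 60 candidate
#' (subpolicy, probability) combinations. The concrete pairing and the
#' magnitude ranges are package defaults in the spirit of widely used
#' auto-augmentation rosters; both are overridable via [space_from_yaml()].
#'
#' @return An `lca_search_space` with 12 subpolicies and a 5-step ladder.
#' @export
build_default_space <- function() {
  pairing <- c(brightness = "hflip", contrast = "rotate",
               saturation = "scale", hue_shift = "translate",
               color_jitter = "shear", gaussian_noise = "vflip",
               sharpness = "hflip", posterize = "rotate",
               solarize = "scale", equalize = "translate",
               autocontrast = "shear", gamma = "vflip")
  sps <- lapply(seq_along(pairing), function(i) {
    subpolicy(transform_op(names(pairing)[i]), transform_op(pairing[[i]]),
              id = i)
  })
  search_space(sps)
}

#' Enumerate the candidate strategies of a space
#'
#' The searched unit is the execution probability applied to the whole
#' space, so one strategy per ladder probability is returned; the full
#' combinatorial size `|subpolicies| * |ladder|` is attached as the
#' attribute `combinatorial_size` for logging.
#'
#' @param space `lca_search_space`.
#' @return List of [augmentation_strategy()] objects, one per ladder
#'   probability, with attribute `combinatorial_size`.
#' @export
enumerate_candidates <- function(space) {
  if (!inherits(space, "lca_search_space")) stop("space must be a search space")
  if (length(space$ladder_probabilities) == 0L) stop("empty probability ladder")
  out <- lapply(space$ladder_probabilities,
                function(p) augmentation_strategy(space, p))
  attr(out, "combinatorial_size") <-
    length(space$subpolicies) * length(space$ladder_probabilities)
  out
}

#' Draw one subpolicy uniformly at random
#'
#' Uses R's random number stream; seed with [set.seed()] for
#' reproducibility.
#'
#' @param space `lca_search_space`.
#' @return An `lca_subpolicy`.
#' @export
sample_subpolicy <- function(space) {
  if (!inherits(space, "lca_search_space") ||
      length(space$subpolicies) == 0L) {
    stop("space must be a non-empty search space")
  }
  space$subpolicies[[sample.int(length(space$subpolicies), 1L)]]
}

#' Stochastically augment one image
#'
#' Samples one subpolicy uniformly from the strategy's space; each of its
#' two ops then executes independently with the strategy's probability, the
#' color op first. An executing op draws its magnitude uniformly from its
#' range. With probability 0 the image is returned untouched and the random
#' stream is not consumed, so a zero-probability strategy is exactly
#' equivalent to no augmentation.
#'
#' @param image `H x W x 3` array in `[0, 1]`.
#' @param strategy `lca_strategy`.
#' @param return_info If `TRUE`, return a list with the augmented `image`
#'   and an `info` record (chosen subpolicy id, per-op executed flags and
#'   magnitudes) instead of the bare image.
#' @return Augmented image array, or a list when `return_info = TRUE`.
#' @export
apply_strategy <- function(image, strategy, return_info = FALSE) {
  stopifnot_image(image)
  if (!inherits(strategy, "lca_strategy")) {
    stop("strategy must be an lca_strategy")
  }
  p <- strategy$probability
  if (p == 0) {
    if (return_info) {
      return(list(image = image,
                  info = list(subpolicy_id = NA_integer_,
                              executed = c(color = FALSE, geometric = FALSE),
                              magnitudes = c(color = NA_real_,
                                             geometric = NA_real_))))
    }
    return(image)
  }
  sp <- sample_subpolicy(strategy$space)
  executed <- stats::runif(2) < p
  mags <- c(NA_real_, NA_real_)
  ops <- list(sp$color_op, sp$geometric_op)
  for (i in 1:2) {
    if (executed[i]) {
      rng <- ops[[i]]$magnitude_range
      mags[i] <- stats::runif(1, rng[1], rng[2])
      image <- apply_op(image, ops[[i]], mags[i])
    }
  }
  if (return_info) {
    list(image = image,
         info = list(subpolicy_id = sp$id,
                     executed = c(color = executed[1],
                                  geometric = executed[2]),
                     magnitudes = c(color = mags[1], geometric = mags[2])))
  } else {
    image
  }
}

#' Read a custom search space from YAML
#'
#' Schema: top-level keys `subpolicies` (a list of maps with keys
#' `color_op`, `geometric_op` and optional `color_range`,
#' `geometric_range`) and optional `ladder_probabilities`.
#'
#' @param path YAML file path.
#' @return An `lca_search_space`.
#' @export
space_from_yaml <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$subpolicies)) stop("YAML space must define 'subpolicies'")
  sps <- lapply(seq_along(cfg$subpolicies), function(i) {
    s <- cfg$subpolicies[[i]]
    if (is.null(s$color_op) || is.null(s$geometric_op)) {
      stop("subpolicy ", i, " must name color_op and geometric_op")
    }
    co <- transform_op(s$color_op, magnitude_range = unlist(s$color_range))
    go <- transform_op(s$geometric_op,
                       magnitude_range = unlist(s$geometric_range))
    if (co$category != "color") stop(s$color_op, " is not a color op")
    if (go$category != "geometric") stop(s$geometric_op,
                                         " is not a geometric op")
    subpolicy(co, go, id = i)
  })
  ladder <- cfg$ladder_probabilities %||% c(0.1, 0.3, 0.5, 0.7, 0.9)
  search_space(sps, ladder)
}

#' Write a search space to YAML
#'
#' @param space `lca_search_space`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
space_to_yaml <- function(space, path) {
  if (!inherits(space, "lca_search_space")) stop("space must be a search space")
  cfg <- list(
    subpolicies = lapply(space$subpolicies, function(sp) {
      list(color_op = sp$color_op$name,
           color_range = sp$color_op$magnitude_range,
           geometric_op = sp$geometric_op$name,
           geometric_range = sp$geometric_op$magnitude_range)
    }),
    ladder_probabilities = space$ladder_probabilities
  )
  yaml::write_yaml(cfg, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
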