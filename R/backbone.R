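#' Backbone contract and the reference CNN
#'
#' A backbone is a pluggable classifier: a list of class `lca_backbone`
#' with fields `name` and three functions: `init(input_shape, n_classes)`
#' returning a parameter list, `forward(params, x)` mapping a batch array
#' `h x w x 3 x B` to `list(logits, feats, cache)` where `feats` are the
#' last-convolution feature maps, and `backward(params, cache, dlogits)`
#' returning parameter gradients. A backbone may additionally provide
#' `gradcam(params, image, class_index)` returning a
#' [feature_map_stack()] for visual explanation.
#'
#' @name backbone
NULL

validate_backbone <- function(backbone) {
  ok <- inherits(backbone, "lca_backbone") &&
    is.function(backbone$init) && is.function(backbone$forward) &&
    is.function(backbone$backward)
  if (!ok) {
    stop("backbone contract violation: need an lca_backbone with init/forward/backward functions")
  }
  invisible(backbone)
}

#' Small reference convolutional network
#'
#' Two strided valid convolutions with ReLU, global average pooling and a
#' dense softmax head. Deliberately tiny (under a thousand parameters at
#' the defaults) so the search pipeline runs on a single CPU without
#' pretrained weights; real deployments substitute their own backbone
#' through the same contract. Grad-CAM++ derivatives are supplied
#' analytically through the exponentiated-score form, under which the
#' second and third derivatives of a linear head are nonvanishing.
#'
#' @param filters Integer vector of length 2: channels of the two
#'   convolution layers.
#' @param kernel Square kernel side; default 3.
#' @param stride Stride of both convolutions; default 2.
#' @param head `"flatten"` (default; dense layer on the flattened feature
#'   maps, enough capacity to overfit a few hundred images so augmentation
#'   has a regularising effect) or `"gap"` (global average pooling, an even
#'   smaller variant).
#' @param name Backbone identifier used in reports.
#' @return An `lca_backbone`.
#' @export
tiny_cnn_backbone <- function(filters = c(12, 12), kernel = 3, stride = 2,
                              head = c("flatten", "gap"),
                              name = "tiny_cnn") {
  f1 <- filters[1]; f2 <- filters[2]
  head <- match.arg(head)

  init <- function(input_shape, n_classes) {
    he <- function(fan_in, dims) {
      array(stats::rnorm(prod(dims), 0, sqrt(2 / fan_in)), dim = dims)
    }
    ho <- (input_shape[1] - kernel) %/% stride + 1
    ho <- (ho - kernel) %/% stride + 1
    wo <- (input_shape[2] - kernel) %/% stride + 1
    wo <- (wo - kernel) %/% stride + 1
    nfeat <- if (head == "gap") f2 else ho * wo * f2
    list(
      w1 = he(kernel * kernel * 3, c(kernel, kernel, 3, f1)),
      b1 = numeric(f1),
      w2 = he(kernel * kernel * f1, c(kernel, kernel, f1, f2)),
      b2 = numeric(f2),
      wd = matrix(stats::rnorm(nfeat * n_classes, 0, sqrt(1 / nfeat)),
                  nfeat, n_classes),
      bd = numeric(n_classes)
    )
  }

  forward <- function(params, x) {
    z1 <- conv2d_forward_cpp(x, params$w1, params$b1, stride)
    a1 <- pmax(z1, 0); dim(a1) <- dim(z1)
    z2 <- conv2d_forward_cpp(a1, params$w2, params$b2, stride)
    a2 <- pmax(z2, 0); dim(a2) <- dim(z2)
    d <- dim(a2)
    feat <- if (head == "gap") {
      t(matrix(colMeans(matrix(a2, d[1] * d[2], d[3] * d[4])),
               d[3], d[4]))                      # B x K
    } else {
      t(matrix(a2, d[1] * d[2] * d[3], d[4]))    # B x (M*N*K)
    }
    logits <- sweep(feat %*% params$wd, 2, params$bd, `+`)
    list(logits = logits, feats = a2,
         cache = list(x = x, z1 = z1, a1 = a1, z2 = z2, a2 = a2,
                      feat = feat))
  }

  backward <- function(params, cache, dlogits) {
    d <- dim(cache$a2)
    dwd <- t(cache$feat) %*% dlogits
    dbd <- colSums(dlogits)
    dfeat <- dlogits %*% t(params$wd)
    da2 <- if (head == "gap") {
      # spread each pooled gradient uniformly over its map
      array(rep(as.vector(t(dfeat) / (d[1] * d[2])), each = d[1] * d[2]),
            dim = d)
    } else {
      array(t(dfeat), dim = d)
    }
    dz2 <- da2 * (cache$z2 > 0)
    g2 <- conv2d_backward_cpp(cache$a1, params$w2, dz2, stride)
    dz1 <- g2$dx * (cache$z1 > 0)
    g1 <- conv2d_backward_cpp(cache$x, params$w1, dz1, stride)
    list(w1 = g1$dw, b1 = g1$db, w2 = g2$dw, b2 = g2$db,
         wd = dwd, bd = dbd)
  }

  gradcam <- function(params, image, class_index) {
    x <- array(image, dim = c(dim(image), 1L))
    fw <- forward(params, x)
    A <- fw$feats[, , , 1, drop = TRUE]
    if (length(dim(A)) == 2L) dim(A) <- c(dim(A), 1L)
    M <- dim(A)[1]; N <- dim(A)[2]; K <- dim(A)[3]
    z <- as.vector(fw$logits)
    s <- exp(z[class_index] - max(z))  # stable positive scale
    # dZ/dA is constant for the linear head: per-element weight coefficients
    cmat <- if (head == "gap") {
      array(rep(params$wd[, class_index] / (M * N), each = M * N),
            dim = c(M, N, K))
    } else {
      array(params$wd[, class_index], dim = c(M, N, K))
    }
    feature_map_stack(A, s * cmat, s * cmat^2, s * cmat^3,
                      target_class = class_index)
  }

  structure(list(name = name, init = init, forward = forward,
                 backward = backward, gradcam = gradcam,
                 config = list(filters = filters, kernel = kernel,
                               stride = stride)),
            class = "lca_backbone")
}

#' @export
print.lca_backbone <- function(x, ...) {
  cat(sprintf("<backbone %s>\n", x$name))
  invisible(x)
}
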