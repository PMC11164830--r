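# The multi-task network: a shared convolutional encoder (hard parameter
# sharing) with three task heads — target-gene regression, non-target-gene
# regression, and tumor classification.

#' Model configuration
#'
#' @param backbone `"tiny_cnn"` (two convolution blocks + global average
#'   pooling + a shared fully connected embedding; suitable for 32–64 px
#'   patches and CPU training) or `"resnet50"` (recognized for
#'   compatibility; requires externally supplied pretrained weights and is
#'   not available in this implementation).
#' @param pretrained load pretrained backbone weights (only meaningful for
#'   `resnet50`).
#' @param m number of target genes (set at training time if `NULL`).
#' @param n_nontarget number of non-target genes (set at training time if
#'   `NULL`).
#' @param embed_dim width of the shared embedding layer.
#' @param channels integer 2-vector: output channels of the two conv blocks.
#' @param kernels integer 2-vector: kernel sides of the two conv blocks.
#' @param strides integer 2-vector: strides of the two conv blocks.
#' @return list with class `model_config`.
#' @export
model_config <- function(backbone = c("tiny_cnn", "resnet50"),
                         pretrained = FALSE, m = NULL, n_nontarget = NULL,
                         embed_dim = 32L, channels = c(12L, 24L),
                         kernels = c(5L, 3L), strides = c(2L, 2L)) {
  backbone <- match.arg(backbone)
  if (backbone == "resnet50") {
    stop("backbone 'resnet50' needs externally supplied pretrained weights, ",
         "which this package does not ship; use backbone = 'tiny_cnn'")
  }
  if (!is.null(m) && m < 1L) stop("m must be >= 1")
  structure(list(backbone = backbone, pretrained = pretrained, m = m,
                 n_nontarget = n_nontarget, embed_dim = as.integer(embed_dim),
                 channels = as.integer(channels), kernels = as.integer(kernels),
                 strides = as.integer(strides)),
            class = "model_config")
}

#' Initialize a model
#'
#' Weights are He-initialized from the current RNG state (seed before
#' calling for reproducibility); biases start at zero. Regression-head
#' biases can be warm-started at the training-set gene means via
#' `target_bias` / `nontarget_bias`, which centres initial predictions.
#'
#' @param config a [model_config()] with `m` and `n_nontarget` set.
#' @param target_bias,nontarget_bias optional initial head biases.
#' @return list with class `sg_model` (config + parameter matrices).
#' @export
spotgene_model <- function(config, target_bias = NULL, nontarget_bias = NULL) {
  stopifnot(inherits(config, "model_config"))
  if (is.null(config$m) || is.null(config$n_nontarget)) {
    stop("config$m and config$n_nontarget must be set")
  }
  C <- config$channels; k <- config$kernels; E <- config$embed_dim
  params <- list(
    W1 = he_init(C[1], k[1]^2 * 3L, fan_in = k[1]^2 * 3L),
    b1 = numeric(C[1]),
    W2 = he_init(C[2], k[2]^2 * C[1], fan_in = k[2]^2 * C[1]),
    b2 = numeric(C[2]),
    Wf = he_init(E, C[2], fan_in = C[2]),
    bf = numeric(E),
    Wt = he_init(config$m, E, fan_in = E, gain = 1),
    bt = if (is.null(target_bias)) numeric(config$m) else as.numeric(target_bias),
    Wn = he_init(config$n_nontarget, E, fan_in = E, gain = 1),
    bn = if (is.null(nontarget_bias)) numeric(config$n_nontarget) else
      as.numeric(nontarget_bias),
    Wy = he_init(1L, E, fan_in = E, gain = 1),
    by = 0
  )
  structure(list(config = config, params = params, geom_cache = list()),
            class = "sg_model")
}

#' @export
print.sg_model <- function(x, ...) {
  n_par <- sum(vapply(x$params, length, integer(1)))
  cat(sprintf("<sg_model> %s: m=%d target, %d non-target genes, embed=%d (%d parameters)\n",
              x$config$backbone, x$config$m, x$config$n_nontarget,
              x$config$embed_dim, n_par))
  invisible(x)
}

# convert an N x S x S x 3 patch array into the flat (3*S*S) x N,
# channel-fastest batch matrix the engine uses
patches_to_batch <- function(patches) {
  a <- if (inherits(patches, "patch_set")) patches$patches else patches
  stopifnot(length(dim(a)) == 4L)
  matrix(aperm(a, c(4L, 2L, 3L, 1L)), ncol = dim(a)[1])
}

model_geom <- function(model, S) {
  key <- as.character(S)
  if (is.null(model$geom_cache[[key]])) {
    cfg <- model$config
    g1 <- conv_geom(3L, S, S, cfg$kernels[1], cfg$strides[1])
    g2 <- conv_geom(cfg$channels[1], g1$Hout, g1$Wout, cfg$kernels[2],
                    cfg$strides[2])
    model$geom_cache[[key]] <- list(g1 = g1, g2 = g2, S = S)
  }
  list(model = model, geom = model$geom_cache[[key]])
}

# full forward pass; returns predictions and (optionally) the cache needed
# for the backward pass
nn_forward <- function(model, X, S, keep_cache = FALSE) {
  mg <- model_geom(model, S)
  model <- mg$model; gg <- mg$geom
  p <- model$params
  B <- ncol(X)
  f1 <- conv_forward(X, p$W1, p$b1, gg$g1)
  a1 <- relu(f1$out)                               # C1 x (P1*B)
  X2 <- matrix(a1, ncol = B)                       # (C1*P1) x B
  f2 <- conv_forward(X2, p$W2, p$b2, gg$g2)
  a2 <- relu(f2$out)                               # C2 x (P2*B)
  gap <- gap_forward(a2, model$config$channels[2], gg$g2$P, B)
  h_pre <- p$Wf %*% gap + p$bf
  h <- relu(h_pre)
  t_out <- p$Wt %*% h + p$bt                       # m x B
  n_out <- p$Wn %*% h + p$bn
  score <- as.numeric(p$Wy %*% h + p$by)
  prob <- sigmoid(score)
  cache <- if (keep_cache) {
    list(X = X, f1 = f1, a1 = a1, X2 = X2, f2 = f2, a2 = a2, gap = gap,
         h_pre = h_pre, h = h, gg = gg, B = B)
  }
  list(model = model,
       g_hat_target = t(t_out), g_hat_nontarget = t(n_out), y_hat = prob,
       score = score, cache = cache)
}

# backward pass from head gradients (d_t: m x B, d_n: (M-m) x B, d_s: 1 x B)
nn_backward <- function(model, cache, d_t, d_n, d_s) {
  p <- model$params; gg <- cache$gg
  grads <- list()
  grads$Wt <- d_t %*% t(cache$h); grads$bt <- rowSums(d_t)
  grads$Wn <- d_n %*% t(cache$h); grads$bn <- rowSums(d_n)
  grads$Wy <- d_s %*% t(cache$h); grads$by <- sum(d_s)
  dh <- t(p$Wt) %*% d_t + t(p$Wn) %*% d_n + t(p$Wy) %*% d_s
  dh <- dh * (cache$h_pre > 0)
  grads$Wf <- dh %*% t(cache$gap); grads$bf <- rowSums(dh)
  dgap <- t(p$Wf) %*% dh
  da2 <- gap_backward(dgap, gg$g2$P)
  dz2 <- da2 * (cache$f2$out > 0)
  bw2 <- conv_backward(dz2, p$W2, cache$f2, gg$g2,
                       n_input = nrow(cache$X2), need_dx = TRUE)
  grads$W2 <- bw2$dW; grads$b2 <- bw2$db
  da1 <- matrix(bw2$dX, nrow = model$config$channels[1])  # C1 x (P1*B)
  dz1 <- da1 * (cache$f1$out > 0)
  bw1 <- conv_backward(dz1, p$W1, cache$f1, gg$g1,
                       n_input = nrow(cache$X), need_dx = FALSE)
  grads$W1 <- bw1$dW; grads$b1 <- bw1$db
  grads
}

#' Forward pass over a batch of patches
#'
#' Computes all three heads from one shared embedding. Deterministic for
#' fixed weights (the network has no stochastic layers).
#'
#' @param model an [spotgene_model()].
#' @param patches a normalized `patch_set` or an N x S x S x 3 array.
#' @return list with class `batch_prediction`: `g_hat_target` (N x m),
#'   `g_hat_nontarget` (N x (M - m)), `y_hat` (N probabilities in (0, 1)),
#'   and `spot_ids` when available.
#' @export
model_forward <- function(model, patches) {
  if (inherits(patches, "patch_set") && !isTRUE(patches$normalized)) {
    stop("patches must be normalized before the forward pass")
  }
  X <- patches_to_batch(patches)
  if (ncol(X) == 0L) stop("empty batch")
  S <- if (inherits(patches, "patch_set")) patches$out_size_px else
    dim(patches)[2]
  fw <- nn_forward(model, X, S, keep_cache = FALSE)
  structure(list(g_hat_target = fw$g_hat_target,
                 g_hat_nontarget = fw$g_hat_nontarget,
                 y_hat = fw$y_hat,
                 spot_ids = if (inherits(patches, "patch_set")) patches$spot_ids),
            class = "batch_prediction")
}
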