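# Multi-task loss terms and their analytic gradients.
#
# The model optimizes
#   L = L_primary + lambda * L_auxiliary + beta * L_tumor + gamma * L_spatial
# where the primary/auxiliary terms are mean squared errors over the target
# and non-target gene sets, the tumor term is binary cross-entropy, and the
# spatial term penalizes differing predicted target expression between
# grid-adjacent spots that carry the same pathological annotation.

check_finite <- function(x, what) {
  if (any(!is.finite(x))) stop("non-finite values in ", what)
}

#' Primary (target-gene) regression loss
#'
#' Mean squared error over all spots and target genes:
#' `(1 / (m * B)) * sum_ij (g_ij - ghat_ij)^2`.
#'
#' @param g_true,g_hat B x m matrices of true and predicted expression.
#' @return non-negative scalar.
#' @export
loss_primary <- function(g_true, g_hat) {
  g_true <- as.matrix(g_true); g_hat <- as.matrix(g_hat)
  stopifnot(identical(dim(g_true), dim(g_hat)))
  check_finite(g_true, "g_true"); check_finite(g_hat, "g_hat")
  mean((g_true - g_hat)^2)
}

#' Auxiliary (non-target-gene) regression loss
#'
#' Same functional form as [loss_primary()], averaged over the `M - m`
#' non-target genes.
#'
#' @param g_true,g_hat B x (M - m) matrices.
#' @return non-negative scalar.
#' @export
loss_auxiliary <- function(g_true, g_hat) loss_primary(g_true, g_hat)

#' Tumor-detection cross-entropy loss
#'
#' `-(1/B) * sum_i [y_i ln p_i + (1 - y_i) ln(1 - p_i)]` with probabilities
#' clamped to `[eps, 1 - eps]` for numerical stability.
#'
#' @param y_true B binary labels (0/1).
#' @param y_hat B predicted probabilities in (0, 1).
#' @param eps clamp width (default 1e-7).
#' @return non-negative scalar.
#' @export
loss_tumor <- function(y_true, y_hat, eps = 1e-7) {
  if (!all(y_true %in% c(0, 1))) stop("labels must be 0 or 1")
  stopifnot(length(y_true) == length(y_hat))
  p <- pmin(pmax(y_hat, eps), 1 - eps)
  -mean(y_true * log(p) + (1 - y_true) * log(1 - p))
}

# Enumerate directed same-annotation (central, neighbor) pairs among the
# batch rows. `spot_index` maps batch rows to node ids of `graph`.
spatial_pairs <- function(labels, graph, spot_index) {
  B <- length(spot_index)
  if (anyNA(labels)) {
    stop("spatial loss requires an annotation for every spot in the batch")
  }
  row_of <- integer(length(graph$neighbors))
  row_of[spot_index] <- seq_len(B)
  present <- logical(length(graph$neighbors))
  present[spot_index] <- TRUE
  ci <- integer(0); cj <- integer(0)
  for (b in seq_len(B)) {
    nb <- graph$neighbors[[spot_index[b]]]
    nb <- nb[present[nb]]
    if (length(nb) == 0L) next
    jb <- row_of[nb]
    same <- labels[jb] == labels[b]
    if (any(same)) {
      ci <- c(ci, rep.int(b, sum(same)))
      cj <- c(cj, jb[same])
    }
  }
  list(i = ci, j = cj, K = length(ci))
}

#' Spatial-aware constraint loss
#'
#' For every directed (central spot, neighbor) pair in the batch whose
#' pathological annotations agree (weight 1; pairs with differing
#' annotations get weight 0), accumulates the squared difference of the
#' predicted target expression — reduced over genes by `reduce` — and
#' divides by K, the number of same-annotation pairs. Returns 0 when K = 0.
#'
#' @param preds B x m matrix of predicted target expression for the spots in
#'   the batch.
#' @param labels B binary annotations (no NAs allowed).
#' @param graph a [build_neighbor_graph()] over the sample's spots.
#' @param spot_index integer length-B map from batch rows to graph node
#'   indices (default: rows 1..B are nodes 1..B).
#' @param reduce how to reduce the squared difference across the m genes:
#'   `"mean"` (default; keeps the scale comparable to [loss_primary()]) or
#'   `"sum"`.
#' @return non-negative scalar.
#' @export
loss_spatial <- function(preds, labels, graph, spot_index = seq_len(nrow(preds)),
                         reduce = c("mean", "sum")) {
  reduce <- match.arg(reduce)
  preds <- as.matrix(preds)
  stopifnot(nrow(preds) == length(labels), length(spot_index) == length(labels))
  pr <- spatial_pairs(labels, graph, spot_index)
  if (pr$K == 0L) return(0)
  d2 <- (preds[pr$i, , drop = FALSE] - preds[pr$j, , drop = FALSE])^2
  per_pair <- if (reduce == "mean") rowMeans(d2) else rowSums(d2)
  sum(per_pair) / pr$K
}

#' Combine the loss components
#'
#' `L = primary + lambda * auxiliary + beta * tumor + gamma * spatial`. With
#' all weights 0 this is exactly the primary loss.
#'
#' @param components list with numeric elements `primary`, `auxiliary`,
#'   `tumor`, `spatial` (missing components are treated as 0).
#' @param weights a [loss_weights()].
#' @return scalar total loss.
#' @export
loss_total <- function(components, weights = loss_weights()) {
  weights <- as_loss_weights(weights)
  cmp <- function(nm) {
    v <- components[[nm]] %||% 0
    if (!is.finite(v)) stop("component '", nm, "' is not finite")
    v
  }
  cmp("primary") + weights$lambda_aux * cmp("auxiliary") +
    weights$beta_tmr * cmp("tumor") + weights$gamma_spat * cmp("spatial")
}

#' Loss weights for the auxiliary, tumor, and spatial terms
#'
#' @param lambda_aux weight of the non-target (auxiliary) regression loss.
#' @param beta_tmr weight of the tumor cross-entropy loss.
#' @param gamma_spat weight of the spatial-aware constraint.
#' @return list with class `loss_weights`.
#' @export
loss_weights <- function(lambda_aux = 1, beta_tmr = 1, gamma_spat = 1) {
  w <- c(lambda_aux, beta_tmr, gamma_spat)
  if (any(!is.finite(w)) || any(w < 0)) {
    stop("loss weights must be finite and non-negative")
  }
  structure(list(lambda_aux = lambda_aux, beta_tmr = beta_tmr,
                 gamma_spat = gamma_spat), class = "loss_weights")
}

as_loss_weights <- function(w) {
  if (inherits(w, "loss_weights")) w else do.call(loss_weights, as.list(w))
}

# ---------------------------------------------------------------------------
# analytic gradients w.r.t. predictions (used by the training loop; each is
# checked against finite differences in the test suite)

grad_loss_mse <- function(g_true, g_hat) {
  2 * (g_hat - g_true) / length(g_true)
}

# gradient w.r.t. the pre-sigmoid score s where p = sigmoid(s)
grad_loss_tumor_score <- function(y_true, p) {
  (p - y_true) / length(y_true)
}

grad_loss_spatial <- function(preds, labels, graph,
                              spot_index = seq_len(nrow(preds)),
                              reduce = "mean") {
  g <- matrix(0, nrow(preds), ncol(preds))
  pr <- spatial_pairs(labels, graph, spot_index)
  if (pr$K == 0L) return(g)
  scale <- 2 / pr$K / (if (reduce == "mean") ncol(preds) else 1)
  diff <- preds[pr$i, , drop = FALSE] - preds[pr$j, , drop = FALSE]
  for (k in seq_len(pr$K)) {
    g[pr$i[k], ] <- g[pr$i[k], ] + scale * diff[k, ]
    g[pr$j[k], ] <- g[pr$j[k], ] - scale * diff[k, ]
  }
  g
}
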