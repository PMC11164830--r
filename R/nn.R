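# Minimal vectorized neural-network engine for the tiny_cnn backbone.
#
# Batches live in a flat matrix of shape (C*H*W) x B, channel-fastest
# ([c, i, j] -> c + (i-1)*C + (j-1)*C*H), so a convolution is one gather
# (im2col) plus one matrix multiply. Gradients are computed analytically;
# the test suite checks them against finite differences.

# im2col index template. Returns the gather index matrix (k*k*Cin) x P plus
# output geometry; `idx[r, p]` is the flat input index feeding kernel
# element r at output position p.
conv_geom <- function(Cin, H, W, k, stride) {
  Hout <- (H - k) %/% stride + 1L
  Wout <- (W - k) %/% stride + 1L
  if (Hout < 1L || Wout < 1L) stop("patch smaller than convolution kernel")
  r <- expand.grid(c = seq_len(Cin), di = seq_len(k), dj = seq_len(k))
  rowbase <- r$c + Cin * (r$di - 1L) + Cin * H * (r$dj - 1L)
  p <- expand.grid(oi = seq_len(Hout), oj = seq_len(Wout))
  colbase <- Cin * stride * (p$oi - 1L) + Cin * H * stride * (p$oj - 1L)
  list(idx = outer(rowbase, colbase, `+`), Hout = Hout, Wout = Wout,
       P = Hout * Wout, R = k * k * Cin)
}

# X: (Cin*H*W) x B -> list(out = Cout x (P*B), cols = R x (P*B))
conv_forward <- function(X, Wmat, b, geom) {
  B <- ncol(X)
  cols <- matrix(X[as.vector(geom$idx), , drop = FALSE], nrow = geom$R)
  out <- Wmat %*% cols + b
  list(out = out, cols = cols, B = B)
}

conv_backward <- function(d_out, Wmat, fwd, geom, n_input, need_dx = TRUE) {
  dW <- d_out %*% t(fwd$cols)
  db <- rowSums(d_out)
  dX <- NULL
  if (need_dx) {
    dcols <- t(Wmat) %*% d_out                       # R x (P*B)
    dcols <- matrix(dcols, nrow = geom$R * geom$P)   # (R*P) x B
    acc <- rowsum(dcols, group = as.vector(geom$idx))
    dX <- matrix(0, n_input, fwd$B)
    dX[as.integer(rownames(acc)), ] <- acc
  }
  list(dW = dW, db = db, dX = dX)
}

relu <- function(x) x * (x > 0)

sigmoid <- function(x) 1 / (1 + exp(-x))

# global average pool: z (C x (P*B)) -> C x B
gap_forward <- function(z, C, P, B) {
  arr <- array(z, c(C, P, B))
  out <- matrix(0, C, B)
  for (p in seq_len(P)) out <- out + arr[, p, , drop = FALSE][, 1, ]
  out / P
}

gap_backward <- function(dgap, P) {
  (dgap / P)[, rep(seq_len(ncol(dgap)), each = P), drop = FALSE]
}

he_init <- function(nrow, ncol, fan_in = ncol, gain = 2) {
  matrix(rnorm(nrow * ncol, sd = sqrt(gain / fan_in)), nrow, ncol)
}

adam_state <- function(params) {
  lapply(params, function(p) list(m = p * 0, v = p * 0))
}

adam_step <- function(params, grads, state, lr, t, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  for (nm in names(params)) {
    g <- grads[[nm]]
    st <- state[[nm]]
    st$m <- beta1 * st$m + (1 - beta1) * g
    st$v <- beta2 * st$v + (1 - beta2) * g^2
    mhat <- st$m / (1 - beta1^t)
    vhat <- st$v / (1 - beta2^t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
    state[[nm]] <- st
  }
  list(params = params, state = state)
}
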