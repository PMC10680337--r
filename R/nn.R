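# Minimal neural-network core: layer forward/backward passes and AdamW.
# All layers are written as paired *_fwd / *_bwd functions; forward passes
# return a cache holding exactly the quantities the backward pass needs.
# Tensors for the convolutional stack use channel-major layout
# (C, H, W, B) so per-channel normalization and activation statistics are
# plain vector-recycling operations.

xavier_mat <- function(nin, nout) {
  r <- sqrt(6 / (nin + nout))
  matrix(runif(nin * nout, -r, r), nin, nout)
}

# column-wise broadcast helpers for (N x D) matrices
scale_cols <- function(m, v) m * rep(v, each = nrow(m))
add_cols <- function(m, v) m + rep(v, each = nrow(m))

row_max <- function(m) {
  m[cbind(seq_len(nrow(m)), max.col(m, ties.method = "first"))]
}

# GELU, tanh approximation (cached for an exact gradient of the approximation)
gelu_fwd <- function(x) {
  inner <- 0.7978845608028654 * (x + 0.044715 * x^3)
  t <- tanh(inner)
  list(out = 0.5 * x * (1 + t), x = x, t = t)
}

gelu_bwd <- function(dout, cache) {
  x <- cache$x
  t <- cache$t
  dinner <- 0.7978845608028654 * (1 + 3 * 0.044715 * x^2)
  dout * (0.5 * (1 + t) + 0.5 * x * (1 - t^2) * dinner)
}

relu_fwd <- function(x) list(out = pmax(x, 0), pos = x > 0)
relu_bwd <- function(dout, cache) dout * cache$pos

# dense layer: X (N x Din) %*% W (Din x Dout) + b
linear_fwd <- function(x, W, b) {
  list(out = add_cols(x %*% W, b), x = x)
}

linear_bwd <- function(dout, cache, W) {
  list(dx = tcrossprod(dout, W),
       dW = crossprod(cache$x, dout),
       db = .colSums(dout, nrow(dout), ncol(dout)))
}

# layer normalization over the feature dimension (per row)
layernorm_fwd <- function(x, gamma, beta, eps = 1e-5) {
  nr <- nrow(x)
  nc <- ncol(x)
  mu <- .rowMeans(x, nr, nc)
  xc <- x - mu
  v <- .rowMeans(xc^2, nr, nc)
  inv <- 1 / sqrt(v + eps)
  xhat <- xc * inv
  list(out = add_cols(scale_cols(xhat, gamma), beta),
       xhat = xhat, inv = inv, gamma = gamma)
}

layernorm_bwd <- function(dout, cache) {
  xhat <- cache$xhat
  nr <- nrow(dout)
  nc <- ncol(dout)
  dxhat <- scale_cols(dout, cache$gamma)
  dx <- (dxhat - .rowMeans(dxhat, nr, nc) -
           xhat * .rowMeans(dxhat * xhat, nr, nc)) * cache$inv
  list(dx = dx,
       dgamma = .colSums(dout * xhat, nr, nc),
       dbeta = .colSums(dout, nr, nc))
}

softmax_rows <- function(s) {
  e <- exp(s - row_max(s))
  e / rowSums(e)
}

# inverted dropout; identity when p == 0 or train == FALSE
dropout_fwd <- function(x, p, train) {
  if (!train || p <= 0) return(list(out = x, mask = NULL))
  mask <- (runif(length(x)) >= p) / (1 - p)
  dim(mask) <- dim(x)
  list(out = x * mask, mask = mask)
}

dropout_bwd <- function(dout, cache) {
  if (is.null(cache$mask)) dout else dout * cache$mask
}

# --- 2-D convolution (3x3 default), layout (C, H, W, B) -------------------

conv2d_fwd <- function(x, W, b, stride = 1L, pad = 1L, kh = 3L, kw = 3L) {
  d <- dim(x)
  colsT <- im2col_chwb(as.numeric(x), d[1], d[2], d[3], d[4],
                       kh, kw, stride, pad)
  out <- crossprod(W, colsT) + b  # b recycles over the channel dimension
  ho <- (d[2] + 2 * pad - kh) %/% stride + 1
  wo <- (d[3] + 2 * pad - kw) %/% stride + 1
  dim(out) <- c(ncol(W), ho, wo, d[4])
  list(out = out, colsT = colsT, in_dim = d,
       stride = stride, pad = pad, kh = kh, kw = kw)
}

conv2d_bwd <- function(dout, cache, W) {
  d <- cache$in_dim
  doutM <- dout
  dim(doutM) <- c(dim(dout)[1], prod(dim(dout)[2:4]))
  dW <- tcrossprod(cache$colsT, doutM)
  db <- .rowSums(doutM, nrow(doutM), ncol(doutM))
  dcolsT <- W %*% doutM
  dx <- col2im_chwb(dcolsT, d[1], d[2], d[3], d[4],
                    cache$kh, cache$kw, cache$stride, cache$pad)
  dim(dx) <- d
  list(dx = dx, dW = dW, db = db)
}

# --- batch normalization over (H, W, B) per channel -----------------------

bn_fwd <- function(x, gamma, beta, state, train, momentum = 0.1, eps = 1e-5) {
  d <- dim(x)
  M <- x
  dim(M) <- c(d[1], prod(d[2:4]))
  nr <- d[1]
  nc <- prod(d[2:4])
  if (train) {
    mu <- .rowMeans(M, nr, nc)
    xc <- M - mu
    v <- .rowMeans(xc^2, nr, nc)
    state$mean <- (1 - momentum) * state$mean + momentum * mu
    state$var <- (1 - momentum) * state$var + momentum * v
  } else {
    mu <- state$mean
    v <- state$var
    xc <- M - mu
  }
  inv <- 1 / sqrt(v + eps)
  xhat <- xc * inv
  out <- xhat * gamma + beta
  dim(out) <- d
  list(out = out, xhat = xhat, inv = inv, gamma = gamma, dims = d,
       train = train, state = state)
}

bn_bwd <- function(dout, cache) {
  d <- cache$dims
  doutM <- dout
  dim(doutM) <- c(d[1], prod(d[2:4]))
  nr <- d[1]
  nc <- prod(d[2:4])
  xhat <- cache$xhat
  dgamma <- .rowSums(doutM * xhat, nr, nc)
  dbeta <- .rowSums(doutM, nr, nc)
  dxhat <- doutM * cache$gamma
  if (cache$train) {
    dx <- (dxhat - .rowMeans(dxhat, nr, nc) -
             xhat * .rowMeans(dxhat * xhat, nr, nc)) * cache$inv
  } else {
    dx <- dxhat * cache$inv
  }
  dim(dx) <- d
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

# --- AdamW ----------------------------------------------------------------

adamw_init <- function(params) {
  list(m = tree_zeros(params), v = tree_zeros(params), t = 0L)
}

# Decoupled weight decay is applied to weight matrices only; biases and
# normalization scale/shift parameters are exempt.
adamw_no_decay <- function(name) {
  grepl("^(b|bias|gamma|beta|ln)", name)
}

adamw_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                       eps = 1e-8, weight_decay = 0.01) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  walk <- function(p, g, m, v, name) {
    if (is.list(p)) {
      nm <- names(p)
      for (i in seq_along(p)) {
        res <- walk(p[[i]], g[[i]], m[[i]], v[[i]],
                    if (!is.null(nm)) nm[i] else "")
        p[[i]] <- res$p
        m[[i]] <- res$m
        v[[i]] <- res$v
      }
      return(list(p = p, m = m, v = v))
    }
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g^2
    upd <- (m / bc1) / (sqrt(v / bc2) + eps)
    if (!adamw_no_decay(name)) upd <- upd + weight_decay * p
    list(p = p - lr * upd, m = m, v = v)
  }
  res <- walk(params, grads, state$m, state$v, "")
  list(params = res$p, state = list(m = res$m, v = res$v, t = state$t))
}

# --- losses ---------------------------------------------------------------

# cross-entropy over rows of a logit matrix; targets are 0-based ids
cross_entropy_fwd <- function(logits, targets) {
  n <- nrow(logits)
  z <- logits - row_max(logits)
  lse <- log(rowSums(exp(z)))
  idx <- cbind(seq_len(n), targets + 1L)
  loss <- mean(lse - z[idx])
  p <- exp(z - lse)
  dlogits <- p
  dlogits[idx] <- dlogits[idx] - 1
  list(loss = loss, dlogits = dlogits / n)
}

# binary cross-entropy on a logit vector (numerically stable)
bce_fwd <- function(logits, y) {
  loss <- mean(pmax(logits, 0) - logits * y + log1p(exp(-abs(logits))))
  p <- plogis(logits)
  list(loss = loss, dlogits = (p - y) / length(logits), p = p)
}
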