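# Numerical checks of the layer primitives against naive oracles and
# finite differences.

naive_conv2d <- function(x, Wmat, b, stride = 1, pad = 1, k = 3) {
  # x: (C, H, W, B); Wmat: (k*k*C) x Cout with kh fastest, then kw, then c
  d <- dim(x)
  C <- d[1]; H <- d[2]; W <- d[3]; B <- d[4]
  Cout <- ncol(Wmat)
  Ho <- (H + 2 * pad - k) %/% stride + 1
  Wo <- (W + 2 * pad - k) %/% stride + 1
  out <- array(0, c(Cout, Ho, Wo, B))
  for (bb in 1:B) for (ho in 1:Ho) for (wo in 1:Wo) for (co in 1:Cout) {
    acc <- b[co]
    for (c_ in 1:C) for (kw_ in 1:k) for (kh_ in 1:k) {
      hi <- (ho - 1) * stride + kh_ - pad
      wi <- (wo - 1) * stride + kw_ - pad
      if (hi >= 1 && hi <= H && wi >= 1 && wi <= W) {
        kk <- (kh_ - 1) + k * ((kw_ - 1) + k * (c_ - 1)) + 1
        acc <- acc + x[c_, hi, wi, bb] * Wmat[kk, co]
      }
    }
    out[co, ho, wo, bb] <- acc
  }
  out
}

test_that("convolution forward matches a naive seven-loop oracle", {
  local_seed(5, {
    for (stride in c(1L, 2L)) {
      x <- array(rnorm(2 * 5 * 6 * 2), c(2, 5, 6, 2))
      Wm <- matrix(rnorm(9 * 2 * 3), 18, 3)
      b <- rnorm(3)
      got <- aptabind:::conv2d_fwd(x, Wm, b, stride = stride)$out
      want <- naive_conv2d(x, Wm, b, stride = stride)
      expect_equal(got, want, tolerance = 1e-12)
    }
  })
})

test_that("col2im is the exact adjoint of im2col", {
  local_seed(6, {
    for (stride in c(1L, 2L)) {
      dims <- c(3L, 6L, 7L, 2L)
      x <- rnorm(prod(dims))
      cols <- aptabind:::im2col_chwb(x, dims[1], dims[2], dims[3], dims[4],
                                     3L, 3L, stride, 1L)
      y <- matrix(rnorm(length(cols)), nrow(cols), ncol(cols))
      back <- aptabind:::col2im_chwb(y, dims[1], dims[2], dims[3], dims[4],
                                     3L, 3L, stride, 1L)
      expect_equal(sum(cols * y), sum(x * back), tolerance = 1e-10)
    }
  })
})

numgrad <- function(f, x, eps = 1e-6) {
  g <- numeric(length(x))
  for (i in seq_along(x)) {
    x1 <- x; x1[i] <- x1[i] + eps
    x2 <- x; x2[i] <- x2[i] - eps
    g[i] <- (f(x1) - f(x2)) / (2 * eps)
  }
  g
}

test_that("GELU, layer-norm and batch-norm backward match finite differences", {
  local_seed(7, {
    # GELU
    x <- rnorm(20)
    dy <- rnorm(20)
    ana <- aptabind:::gelu_bwd(dy, aptabind:::gelu_fwd(x))
    num <- numgrad(function(z) sum(aptabind:::gelu_fwd(z)$out * dy), x)
    expect_equal(ana, num, tolerance = 1e-5)

    # layer norm (gradient wrt input)
    X <- matrix(rnorm(4 * 6), 4, 6)
    gamma <- runif(6, 0.5, 1.5)
    beta <- rnorm(6)
    dY <- matrix(rnorm(4 * 6), 4, 6)
    fw <- aptabind:::layernorm_fwd(X, gamma, beta)
    ana <- aptabind:::layernorm_bwd(dY, fw)$dx
    num <- numgrad(function(z) {
      sum(aptabind:::layernorm_fwd(matrix(z, 4, 6), gamma, beta)$out * dY)
    }, as.numeric(X))
    expect_equal(as.numeric(ana), num, tolerance = 1e-5)

    # batch norm in training mode (gradient wrt input)
    xb <- array(rnorm(3 * 4 * 2 * 2), c(3, 4, 2, 2))
    st <- list(mean = numeric(3), var = rep(1, 3))
    g2 <- runif(3, 0.5, 1.5)
    b2 <- rnorm(3)
    dyb <- array(rnorm(length(xb)), dim(xb))
    fb <- aptabind:::bn_fwd(xb, g2, b2, st, train = TRUE)
    ana <- as.numeric(aptabind:::bn_bwd(dyb, fb)$dx)
    num <- numgrad(function(z) {
      z <- array(z, dim(xb))
      sum(aptabind:::bn_fwd(z, g2, b2, st, train = TRUE)$out * dyb)
    }, as.numeric(xb))
    expect_equal(ana, num, tolerance = 1e-4)
  })
})

test_that("end-to-end model gradients match finite differences", {
  model <- tiny_model(seed = 7)
  pairs <- random_pairs(2, seed = 8)
  toks <- lapply(pairs, function(p) aptabind:::tokenize_pair(model, p))
  y <- c(1, 0)
  loss_fn <- function(m) {
    fw <- aptabind:::api_forward_batch(m, toks, train = TRUE,
                                       bn_state = m$bn_state)
    aptabind:::bce_fwd(fw$logits, y)$loss
  }
  fw <- aptabind:::api_forward_batch(model, toks, train = TRUE,
                                     bn_state = model$bn_state)
  grads <- aptabind:::api_backward_batch(
    aptabind:::bce_fwd(fw$logits, y)$dlogits, fw, model)

  get_leaf <- function(tree, path) {
    for (k in path) tree <- tree[[k]]
    tree
  }
  set_leaf <- function(tree, path, val) {
    if (length(path) == 1) {
      tree[[path[[1]]]] <- val
      return(tree)
    }
    tree[[path[[1]]]] <- set_leaf(tree[[path[[1]]]], path[-1], val)
    tree
  }
  paths <- list(list("head", "W1"), list("head", "W2"),
                list("conv", "stages", 1L, "blocks", 1L, "W"),
                list("conv", "stages", 1L, "blocks", 3L, "gamma"),
                list("conv", "stages", 1L, "down", "W"),
                list("conv", "stages", 2L, "blocks", 2L, "W"),
                list("apta", "layers", 1L, "Wq"),
                list("apta", "layers", 1L, "W1"),
                list("apta", "layers", 1L, "ln2_gamma"),
                list("prot", "layers", 1L, "Wv"))
  local_seed(9, {
    for (path in paths) {
      g <- get_leaf(grads, path)
      p <- get_leaf(model$params, path)
      for (i in sample(length(p), 2)) {
        eps <- 1e-5
        q1 <- p; q1[i] <- q1[i] + eps
        q2 <- p; q2[i] <- q2[i] - eps
        m1 <- model; m1$params <- set_leaf(model$params, path, q1)
        m2 <- model; m2$params <- set_leaf(model$params, path, q2)
        num <- (loss_fn(m1) - loss_fn(m2)) / (2 * eps)
        rel <- abs(num - g[i]) / max(1e-6, abs(num) + abs(g[i]))
        expect_lt(rel, 1e-4)
      }
    }
  })
})

test_that("AdamW minimizes a quadratic and skips decay for norm parameters", {
  params <- list(W = matrix(c(2, -3), 1), gamma = c(5))
  grads_fn <- function(p) list(W = 2 * p$W, gamma = 0 * p$gamma)
  st <- aptabind:::adamw_init(params)
  for (i in 1:400) {
    upd <- aptabind:::adamw_step(params, grads_fn(params), st, lr = 0.05,
                                 weight_decay = 0.1)
    params <- upd$params
    st <- upd$state
  }
  expect_lt(sum(params$W^2), 1e-3)   # quadratic minimized
  expect_equal(params$gamma, 5)      # zero-gradient norm param untouched
})
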