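# Transformer encoder: embedding + sinusoidal positional encoding followed
# by post-norm multi-head self-attention / feed-forward layers, instantiated
# once for aptamers (k-mer tokens) and once for proteins (FCS tokens).

#' Encoder configuration
#'
#' Defaults follow the reference hyperparameter set: embedding size 128,
#' 8 attention heads, 6 layers, feed-forward hidden size 512, dropout 0.1.
#'
#' @param vocab_size token inventory size (specials included).
#' @param embed_dim embedding dimension (divisible by `n_heads`).
#' @param n_heads number of attention heads.
#' @param n_layers number of encoder layers.
#' @param ff_dim feed-forward hidden dimension.
#' @param dropout dropout rate in `[0, 1)` (training only).
#' @param max_len padding/truncation bound on token-stream length; longer
#'   streams are truncated from the right with a warning.
#' @return an object of class `encoder_config`.
#' @export
encoder_config <- function(vocab_size, embed_dim = 128L, n_heads = 8L,
                           n_layers = 6L, ff_dim = 512L, dropout = 0.1,
                           max_len = 512L) {
  embed_dim <- as.integer(embed_dim)
  n_heads <- as.integer(n_heads)
  if (embed_dim %% n_heads != 0) {
    stop("embed_dim must be divisible by n_heads", call. = FALSE)
  }
  if (dropout < 0 || dropout >= 1) {
    stop("dropout must be in [0, 1)", call. = FALSE)
  }
  structure(list(vocab_size = as.integer(vocab_size),
                 embed_dim = embed_dim, n_heads = n_heads,
                 n_layers = as.integer(n_layers),
                 ff_dim = as.integer(ff_dim),
                 dropout = dropout, max_len = as.integer(max_len)),
            class = "encoder_config")
}

#' Initialize encoder weights
#'
#' Xavier-uniform weight matrices, zero biases, unit layer-norm scales.
#'
#' @param cfg an [encoder_config()].
#' @param seed integer seed for the initial draw.
#' @return a nested list of parameter matrices/vectors.
#' @export
init_encoder <- function(cfg, seed = 1L) {
  D <- cfg$embed_dim
  local_seed(seed, {
    layers <- lapply(seq_len(cfg$n_layers), function(l) {
      list(Wq = xavier_mat(D, D), bq = numeric(D),
           Wk = xavier_mat(D, D), bk = numeric(D),
           Wv = xavier_mat(D, D), bv = numeric(D),
           Wo = xavier_mat(D, D), bo = numeric(D),
           ln1_gamma = rep(1, D), ln1_beta = numeric(D),
           W1 = xavier_mat(D, cfg$ff_dim), b1 = numeric(cfg$ff_dim),
           W2 = xavier_mat(cfg$ff_dim, D), b2 = numeric(D),
           ln2_gamma = rep(1, D), ln2_beta = numeric(D))
    })
    list(emb = xavier_mat(cfg$vocab_size, D), layers = layers)
  })
}

# fixed sinusoidal positional encoding, rows are 0-based positions
positional_encoding <- function(n_pos, d) {
  pos <- seq_len(n_pos) - 1
  i <- seq_len(d %/% 2) - 1
  angle <- outer(pos, 1 / 10000^(2 * i / d))
  pe <- matrix(0, n_pos, d)
  pe[, 2 * i + 1] <- sin(angle)
  pe[, 2 * i + 2] <- cos(angle)
  if (d %% 2 == 1) pe[, d] <- sin(pos / 10000)
  pe
}

# memoized view: the table depends only on (d) and grows as needed
.pe_cache <- new.env(parent = emptyenv())
get_positional_encoding <- function(n_pos, d) {
  key <- as.character(d)
  pe <- get0(key, envir = .pe_cache, ifnotfound = NULL)
  if (is.null(pe) || nrow(pe) < n_pos) {
    pe <- positional_encoding(max(n_pos, 128L), d)
    assign(key, pe, envir = .pe_cache)
  }
  pe[seq_len(n_pos), , drop = FALSE]
}

attn_fwd <- function(x, p, n_heads, mask, dropout, train) {
  T_ <- nrow(x)
  D <- ncol(x)
  dh <- D %/% n_heads
  q <- linear_fwd(x, p$Wq, p$bq)
  k <- linear_fwd(x, p$Wk, p$bk)
  v <- linear_fwd(x, p$Wv, p$bv)
  H <- matrix(0, T_, D)
  heads <- vector("list", n_heads)
  for (h in seq_len(n_heads)) {
    idx <- ((h - 1) * dh + 1):(h * dh)
    S <- tcrossprod(q$out[, idx, drop = FALSE],
                    k$out[, idx, drop = FALSE]) / sqrt(dh)
    if (!is.null(mask) && !all(mask)) S[, !mask] <- -1e30
    A <- softmax_rows(S)
    H[, idx] <- A %*% v$out[, idx, drop = FALSE]
    heads[[h]] <- list(A = A, idx = idx)
  }
  o <- linear_fwd(H, p$Wo, p$bo)
  drop <- dropout_fwd(o$out, dropout, train)
  list(out = drop$out,
       cache = list(q = q, k = k, v = v, H = H, heads = heads,
                    o = o, drop = drop, dh = dh, mask = mask))
}

attn_bwd <- function(dout, cache, p) {
  dout <- dropout_bwd(dout, cache$drop)
  o_b <- linear_bwd(dout, cache$o, p$Wo)
  dH <- o_b$dx
  q <- cache$q$out
  k <- cache$k$out
  v <- cache$v$out
  dq <- matrix(0, nrow(q), ncol(q))
  dk <- dq
  dv <- dq
  for (h in cache$heads) {
    idx <- h$idx
    A <- h$A
    dHh <- dH[, idx, drop = FALSE]
    dA <- tcrossprod(dHh, v[, idx, drop = FALSE])
    dv[, idx] <- crossprod(A, dHh)
    dS <- A * (dA - rowSums(dA * A))
    if (!is.null(cache$mask) && !all(cache$mask)) dS[, !cache$mask] <- 0
    dq[, idx] <- dS %*% k[, idx, drop = FALSE] / sqrt(cache$dh)
    dk[, idx] <- crossprod(dS, q[, idx, drop = FALSE]) / sqrt(cache$dh)
  }
  q_b <- linear_bwd(dq, cache$q, p$Wq)
  k_b <- linear_bwd(dk, cache$k, p$Wk)
  v_b <- linear_bwd(dv, cache$v, p$Wv)
  list(dx = q_b$dx + k_b$dx + v_b$dx,
       grads = list(Wq = q_b$dW, bq = q_b$db, Wk = k_b$dW, bk = k_b$db,
                    Wv = v_b$dW, bv = v_b$db, Wo = o_b$dW, bo = o_b$db))
}

encoder_layer_fwd <- function(x, p, cfg, mask, train) {
  att <- attn_fwd(x, p, cfg$n_heads, mask, cfg$dropout, train)
  r1 <- x + att$out
  n1 <- layernorm_fwd(r1, p$ln1_gamma, p$ln1_beta)
  f1 <- linear_fwd(n1$out, p$W1, p$b1)
  a1 <- relu_fwd(f1$out)
  f2 <- linear_fwd(a1$out, p$W2, p$b2)
  drop <- dropout_fwd(f2$out, cfg$dropout, train)
  r2 <- n1$out + drop$out
  n2 <- layernorm_fwd(r2, p$ln2_gamma, p$ln2_beta)
  list(out = n2$out,
       cache = list(att = att, n1 = n1, f1 = f1, a1 = a1, f2 = f2,
                    drop = drop, n2 = n2))
}

encoder_layer_bwd <- function(dout, cache, p) {
  n2_b <- layernorm_bwd(dout, cache$n2)
  dr2 <- n2_b$dx
  dff <- dropout_bwd(dr2, cache$drop)
  f2_b <- linear_bwd(dff, cache$f2, p$W2)
  da1 <- relu_bwd(f2_b$dx, cache$a1)
  f1_b <- linear_bwd(da1, cache$f1, p$W1)
  dn1 <- dr2 + f1_b$dx
  n1_b <- layernorm_bwd(dn1, cache$n1)
  dr1 <- n1_b$dx
  att_b <- attn_bwd(dr1, cache$att$cache, p)
  grads <- att_b$grads
  grads$ln1_gamma <- n1_b$dgamma
  grads$ln1_beta <- n1_b$dbeta
  grads$W1 <- f1_b$dW
  grads$b1 <- f1_b$db
  grads$W2 <- f2_b$dW
  grads$b2 <- f2_b$db
  grads$ln2_gamma <- n2_b$dgamma
  grads$ln2_beta <- n2_b$dbeta
  list(dx = dr1 + att_b$dx, grads = grads)
}

# Full forward pass over 0-based token ids. `mask` flags valid positions.
encoder_fwd <- function(ids, params, cfg, mask = NULL, train = FALSE) {
  T_ <- length(ids)
  if (T_ == 0) stop("empty token list", call. = FALSE)
  if (any(ids < 0 | ids >= cfg$vocab_size)) {
    stop("token id out of range for the encoder vocabulary", call. = FALSE)
  }
  D <- cfg$embed_dim
  x <- params$emb[ids + 1L, , drop = FALSE] * sqrt(D) +
    get_positional_encoding(T_, D)
  emb_drop <- dropout_fwd(x, cfg$dropout, train)
  x <- emb_drop$out
  layer_caches <- vector("list", cfg$n_layers)
  for (l in seq_len(cfg$n_layers)) {
    lf <- encoder_layer_fwd(x, params$layers[[l]], cfg, mask, train)
    x <- lf$out
    layer_caches[[l]] <- lf$cache
  }
  list(out = x, ids = ids, emb_drop = emb_drop, layer_caches = layer_caches)
}

# Backward pass; embedding gradient is returned sparsely as
# (unique ids, per-id summed rows).
encoder_bwd <- function(dout, fw, params, cfg) {
  grads_layers <- vector("list", cfg$n_layers)
  dx <- dout
  for (l in rev(seq_len(cfg$n_layers))) {
    lb <- encoder_layer_bwd(dx, fw$layer_caches[[l]], params$layers[[l]])
    dx <- lb$dx
    grads_layers[[l]] <- lb$grads
  }
  dx <- dropout_bwd(dx, fw$emb_drop)
  demb_rows <- dx * sqrt(cfg$embed_dim)
  agg <- rowsum(demb_rows, group = fw$ids)
  list(emb_ids = as.integer(rownames(agg)), emb_d = agg,
       layers = grads_layers)
}

#' Encode a tokenized sequence into contextual per-token embeddings
#'
#' Evaluation-mode forward pass (dropout disabled): embedding lookup plus
#' fixed sinusoidal positional encoding, followed by `n_layers` post-norm
#' blocks of multi-head self-attention and a position-wise feed-forward
#' network with residual connections and layer normalization. With
#' `n_layers = 0` the output is exactly embedding + positional encoding.
#'
#' Padding positions (when `pad_to` exceeds the stream length) carry the
#' `[PAD]` id, are excluded from attention via the validity mask, and are
#' flagged invalid in the result so downstream aggregation can skip them.
#'
#' @param ts a `tok_seq`.
#' @param weights encoder parameters from [init_encoder()] or
#'   [pretrain_encoder()].
#' @param cfg the matching [encoder_config()].
#' @param pad_to optional padded length.
#' @return an object of class `contextual_embeddings` with fields `matrix`
#'   (`n_tokens x embed_dim`) and `mask` (per-position validity).
#' @export
encode <- function(ts, weights, cfg, pad_to = NULL) {
  ids <- ts$token_ids
  if (length(ids) > cfg$max_len) {
    warning(sprintf("token stream of length %d truncated to max_len = %d",
                    length(ids), cfg$max_len))
    ids <- ids[seq_len(cfg$max_len)]
  }
  mask <- rep(TRUE, length(ids))
  if (!is.null(pad_to) && pad_to > length(ids)) {
    pad_n <- pad_to - length(ids)
    ids <- c(ids, rep(0L, pad_n))
    mask <- c(mask, rep(FALSE, pad_n))
  }
  fw <- encoder_fwd(ids, weights, cfg, mask = mask, train = FALSE)
  if (any(!is.finite(fw$out))) {
    stop("encoder produced non-finite values", call. = FALSE)
  }
  structure(list(matrix = fw$out, mask = mask),
            class = "contextual_embeddings")
}
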