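# API prediction model: dot-product interaction map between contextual
# embeddings, residual convolutional feature extraction, fully connected
# scoring head, fine-tuning with symmetric-aptamer augmentation, and the
# six evaluation metrics.

#' Convolutional stack configuration
#'
#' Three stages of five 3x3 convolution blocks (conv -> batch-norm -> GELU)
#' at 64/128/256 channels by default, with two residual skip connections per
#' stage (block 1 -> 3 and 3 -> 5) and one stride-2 downsizing block between
#' stages: 3 x 5 + 2 = 17 convolution layers at the defaults. The
#' interaction map is zero-padded (or truncated) to a fixed
#' `map_rows x map_cols` spatial size before convolution.
#'
#' @param stage_channels channel width per stage.
#' @param blocks_per_stage convolution blocks in each stage (odd blocks >= 3
#'   receive a skip from two blocks earlier).
#' @param map_rows,map_cols fixed spatial size of the padded interaction map
#'   (aptamer tokens x protein tokens).
#' @param head_hidden hidden width of the fully connected scoring head.
#' @param head_dropout dropout rate applied (during training) to the
#'   flattened feature vector before the fully connected head; the flatten
#'   head is position-specific, so feature dropout is the main guard
#'   against memorizing motif positions.
#' @return an object of class `conv_config`.
#' @export
conv_config <- function(stage_channels = c(64L, 128L, 256L),
                        blocks_per_stage = 5L,
                        map_rows = 64L, map_cols = 256L,
                        head_hidden = 128L, head_dropout = 0.1) {
  structure(list(stage_channels = as.integer(stage_channels),
                 blocks_per_stage = as.integer(blocks_per_stage),
                 map_rows = as.integer(map_rows),
                 map_cols = as.integer(map_cols),
                 head_hidden = as.integer(head_hidden),
                 head_dropout = head_dropout),
            class = "conv_config")
}

#' Total number of convolution layers in a stack
#' @param cfg a [conv_config()].
#' @export
n_conv_layers <- function(cfg) {
  length(cfg$stage_channels) * cfg$blocks_per_stage +
    (length(cfg$stage_channels) - 1L)
}

conv_block_params <- function(cin, cout) {
  list(W = xavier_mat(9L * cin, cout), b = numeric(cout),
       gamma = rep(1, cout), beta = numeric(cout))
}

conv_block_state <- function(cout) list(mean = numeric(cout),
                                        var = rep(1, cout))

init_conv_stack <- function(cfg, in_channels = 1L, seed = 1L) {
  local_seed(seed, {
    n_stage <- length(cfg$stage_channels)
    stages <- vector("list", n_stage)
    for (s in seq_len(n_stage)) {
      cs <- cfg$stage_channels[s]
      cin1 <- if (s == 1) in_channels else cs
      blocks <- vector("list", cfg$blocks_per_stage)
      blocks[[1]] <- conv_block_params(cin1, cs)
      for (i in seq_len(cfg$blocks_per_stage)[-1]) {
        blocks[[i]] <- conv_block_params(cs, cs)
      }
      st <- list(blocks = blocks)
      if (s < n_stage) {
        st$down <- conv_block_params(cs, cfg$stage_channels[s + 1])
      }
      stages[[s]] <- st
    }
    list(stages = stages)
  })
}

init_conv_state <- function(cfg) {
  n_stage <- length(cfg$stage_channels)
  stages <- vector("list", n_stage)
  for (s in seq_len(n_stage)) {
    cs <- cfg$stage_channels[s]
    st <- list(blocks = lapply(seq_len(cfg$blocks_per_stage),
                               function(i) conv_block_state(cs)))
    if (s < n_stage) st$down <- conv_block_state(cfg$stage_channels[s + 1])
    stages[[s]] <- st
  }
  list(stages = stages)
}

# spatial size of the stack output (stride-2 halvings between stages)
conv_out_shape <- function(cfg) {
  h <- cfg$map_rows
  w <- cfg$map_cols
  for (s in seq_len(length(cfg$stage_channels) - 1L)) {
    h <- (h + 2L - 3L) %/% 2L + 1L
    w <- (w + 2L - 3L) %/% 2L + 1L
  }
  c(h, w, cfg$stage_channels[length(cfg$stage_channels)])
}

conv_unit_fwd <- function(x, p, state, train, stride = 1L) {
  cv <- conv2d_fwd(x, p$W, p$b, stride = stride)
  bn <- bn_fwd(cv$out, p$gamma, p$beta, state, train)
  ge <- gelu_fwd(bn$out)
  list(out = ge$out, state = bn$state,
       cache = list(cv = cv, bn = bn, ge = ge))
}

conv_unit_bwd <- function(dout, cache, p) {
  dge <- gelu_bwd(dout, cache$ge)
  bnb <- bn_bwd(dge, cache$bn)
  cvb <- conv2d_bwd(bnb$dx, cache$cv, p$W)
  list(dx = cvb$dx,
       grads = list(W = cvb$dW, b = cvb$db,
                    gamma = bnb$dgamma, beta = bnb$dbeta))
}

conv_stack_fwd <- function(x, params, cfg, bn_state, train = FALSE) {
  n_stage <- length(cfg$stage_channels)
  nb <- cfg$blocks_per_stage
  stage_caches <- vector("list", n_stage)
  for (s in seq_len(n_stage)) {
    sp <- params$stages[[s]]
    sstate <- bn_state$stages[[s]]
    outs <- vector("list", nb)
    caches <- vector("list", nb)
    for (i in seq_len(nb)) {
      u <- conv_unit_fwd(x, sp$blocks[[i]], sstate$blocks[[i]], train)
      sstate$blocks[[i]] <- u$state
      y <- u$out
      if (i >= 3 && i %% 2 == 1) y <- y + outs[[i - 2]]
      outs[[i]] <- y
      caches[[i]] <- u$cache
      x <- y
    }
    down_cache <- NULL
    if (s < n_stage) {
      d <- conv_unit_fwd(x, sp$down, sstate$down, train, stride = 2L)
      sstate$down <- d$state
      x <- d$out
      down_cache <- d$cache
    }
    bn_state$stages[[s]] <- sstate
    stage_caches[[s]] <- list(blocks = caches, down = down_cache)
  }
  list(out = x, caches = stage_caches, bn_state = bn_state)
}

conv_stack_bwd <- function(dout, fw, params, cfg) {
  n_stage <- length(cfg$stage_channels)
  nb <- cfg$blocks_per_stage
  grads_stages <- vector("list", n_stage)
  dx <- dout
  for (s in rev(seq_len(n_stage))) {
    sp <- params$stages[[s]]
    sc <- fw$caches[[s]]
    gst <- list(blocks = vector("list", nb))
    if (!is.null(sc$down)) {
      db <- conv_unit_bwd(dx, sc$down, sp$down)
      gst$down <- db$grads
      dx <- db$dx
    }
    dys <- vector("list", nb)
    dys[[nb]] <- dx
    for (i in rev(seq_len(nb))) {
      dy <- dys[[i]]
      if (i >= 3 && i %% 2 == 1) {
        # skip connection: gradient flows straight to block i - 2's output
        dys[[i - 2]] <- if (is.null(dys[[i - 2]])) dy else dys[[i - 2]] + dy
      }
      ub <- conv_unit_bwd(dy, sc$blocks[[i]], sp$blocks[[i]])
      gst$blocks[[i]] <- ub$grads
      if (i > 1) {
        dys[[i - 1]] <- if (is.null(dys[[i - 1]])) ub$dx
                        else dys[[i - 1]] + ub$dx
      } else {
        dx <- ub$dx
      }
    }
    # reorder so grads match params element order (blocks first, then down)
    grads_stages[[s]] <- if (is.null(sc$down)) list(blocks = gst$blocks)
                         else list(blocks = gst$blocks, down = gst$down)
  }
  list(dx = dx, grads = list(stages = grads_stages))
}

# --- interaction map ------------------------------------------------------

#' Dot-product interaction map
#'
#' The plain (unscaled) matrix of pairwise dot products between aptamer and
#' protein contextual token embeddings; entry (i, j) is the interaction
#' value between aptamer token i and protein token j. Rows/columns arising
#' from padding positions are flagged invalid.
#'
#' @param ea,ep `contextual_embeddings` for the aptamer and the protein
#'   (equal embedding dimension).
#' @return an object of class `interaction_map` with fields `values`,
#'   `row_mask`, `col_mask`.
#' @export
interaction_map <- function(ea, ep) {
  if (ncol(ea$matrix) != ncol(ep$matrix)) {
    stop("embedding dimensions differ between aptamer and protein",
         call. = FALSE)
  }
  structure(list(values = tcrossprod(ea$matrix, ep$matrix),
                 row_mask = ea$mask, col_mask = ep$mask),
            class = "interaction_map")
}

#' @export
print.interaction_map <- function(x, ...) {
  cat(sprintf("<interaction_map> %d x %d (valid %d x %d)\n",
              nrow(x$values), ncol(x$values),
              sum(x$row_mask), sum(x$col_mask)))
  invisible(x)
}

pad_map <- function(values, rows, cols) {
  out <- matrix(0, rows, cols)
  r <- min(nrow(values), rows)
  c_ <- min(ncol(values), cols)
  out[seq_len(r), seq_len(c_)] <- values[seq_len(r), seq_len(c_)]
  out
}

#' Extract the convolutional feature vector of an interaction map
#'
#' Evaluation-mode pass through the residual convolution stack: the map is
#' zero-padded/truncated to the configured fixed spatial size, convolved,
#' and the final activation tensor flattened.
#'
#' @param im an [interaction_map()] (or plain matrix).
#' @param cfg a [conv_config()].
#' @param weights conv-stack parameters (e.g. `model$params$conv`).
#' @param bn_state batch-norm running statistics; fresh (zero-mean,
#'   unit-variance) statistics when `NULL`.
#' @return numeric feature vector of fixed length for a fixed config.
#' @export
conv_feature_extract <- function(im, cfg, weights, bn_state = NULL) {
  values <- if (inherits(im, "interaction_map")) im$values else im
  bn_state <- bn_state %||% init_conv_state(cfg)
  x <- array(0, c(1L, cfg$map_rows, cfg$map_cols, 1L))
  x[1L, , , 1L] <- pad_map(values, cfg$map_rows, cfg$map_cols)
  fw <- conv_stack_fwd(x, weights, cfg, bn_state, train = FALSE)
  as.numeric(fw$out)
}

# --- full model -----------------------------------------------------------

#' Assemble an untrained API prediction model
#'
#' Wires two encoders, the convolution stack and the fully connected head
#' into one container carrying both vocabularies, all weights and the
#' batch-norm running statistics.
#'
#' @param apta_vocab,prot_vocab token vocabularies.
#' @param apta_cfg,prot_cfg [encoder_config()]s (vocab sizes must match).
#' @param conv_cfg a [conv_config()].
#' @param seed integer seed for weight initialization.
#' @param k k-mer order for aptamer tokenization.
#' @return an object of class `api_model`.
#' @export
build_api_model <- function(apta_vocab, prot_vocab, apta_cfg, prot_cfg,
                            conv_cfg = conv_config(), seed = 1L, k = 3L) {
  stopifnot(apta_cfg$vocab_size == vocab_size(apta_vocab),
            prot_cfg$vocab_size == vocab_size(prot_vocab),
            apta_cfg$embed_dim == prot_cfg$embed_dim)
  shape <- conv_out_shape(conv_cfg)
  n_feat <- prod(shape)
  head <- local_seed(derive_seed(seed, "head"), {
    list(W1 = xavier_mat(n_feat, conv_cfg$head_hidden),
         b1 = numeric(conv_cfg$head_hidden),
         W2 = xavier_mat(conv_cfg$head_hidden, 1L),
         b2 = numeric(1))
  })
  structure(list(
    apta_vocab = apta_vocab, prot_vocab = prot_vocab,
    apta_cfg = apta_cfg, prot_cfg = prot_cfg, conv_cfg = conv_cfg,
    k = as.integer(k),
    params = list(
      apta = init_encoder(apta_cfg, derive_seed(seed, "apta-encoder")),
      prot = init_encoder(prot_cfg, derive_seed(seed, "prot-encoder")),
      conv = init_conv_stack(conv_cfg, seed = derive_seed(seed, "conv")),
      head = head),
    bn_state = init_conv_state(conv_cfg)),
    class = "api_model")
}

#' @export
print.api_model <- function(x, ...) {
  cat(sprintf(paste0(
    "<api_model> embed_dim %d, %d+%d encoder layers, ",
    "%d conv layers, map %d x %d\n"),
    x$apta_cfg$embed_dim, x$apta_cfg$n_layers, x$prot_cfg$n_layers,
    n_conv_layers(x$conv_cfg), x$conv_cfg$map_rows, x$conv_cfg$map_cols))
  invisible(x)
}

tokenize_pair <- function(model, pair) {
  list(a = kmer_tokenize(pair$aptamer, k = model$k,
                         vocab = model$apta_vocab),
       p = fcs_tokenize(pair$protein, model$prot_vocab))
}

# Forward pass over a list of tokenized pairs. Returns logits plus all
# caches needed for the backward pass; updates bn running stats in train
# mode. With `jitter = TRUE` (training only) each interaction map is
# placed at a random offset on the fixed padded canvas instead of the
# top-left corner: the planted map content is unchanged, but the
# position-specific flatten head then sees every map region during
# training, which teaches it translation invariance instead of letting it
# memorize absolute motif positions. Evaluation always uses the
# deterministic top-left placement.
api_forward_batch <- function(model, toks, train = FALSE,
                              bn_state = model$bn_state, jitter = FALSE) {
  cfg <- model$conv_cfg
  B <- length(toks)
  x4 <- array(0, c(1L, cfg$map_rows, cfg$map_cols, B))
  enc <- vector("list", B)
  for (b in seq_len(B)) {
    ia <- toks[[b]]$a$token_ids
    ip <- toks[[b]]$p$token_ids
    if (length(ia) > model$apta_cfg$max_len) {
      ia <- ia[seq_len(model$apta_cfg$max_len)]
    }
    if (length(ip) > model$prot_cfg$max_len) {
      ip <- ip[seq_len(model$prot_cfg$max_len)]
    }
    fa <- encoder_fwd(ia, model$params$apta, model$apta_cfg, train = train)
    fp <- encoder_fwd(ip, model$params$prot, model$prot_cfg, train = train)
    im <- tcrossprod(fa$out, fp$out)
    ru <- min(nrow(im), cfg$map_rows)
    cu <- min(ncol(im), cfg$map_cols)
    off_r <- 0L
    off_c <- 0L
    if (jitter && train) {
      off_r <- sample.int(cfg$map_rows - ru + 1L, 1) - 1L
      off_c <- sample.int(cfg$map_cols - cu + 1L, 1) - 1L
    }
    x4[1L, off_r + seq_len(ru), off_c + seq_len(cu), b] <-
      im[seq_len(ru), seq_len(cu)]
    enc[[b]] <- list(fa = fa, fp = fp, ru = ru, cu = cu,
                     off_r = off_r, off_c = off_c)
  }
  cv <- conv_stack_fwd(x4, model$params$conv, cfg, bn_state, train = train)
  top <- cv$out
  td <- dim(top)
  feat <- t(`dim<-`(top, c(td[1] * td[2] * td[3], td[4])))
  fdrop <- dropout_fwd(feat, cfg$head_dropout %||% 0, train)
  h1 <- linear_fwd(fdrop$out, model$params$head$W1, model$params$head$b1)
  g1 <- gelu_fwd(h1$out)
  h2 <- linear_fwd(g1$out, model$params$head$W2, model$params$head$b2)
  list(logits = as.numeric(h2$out), bn_state = cv$bn_state,
       cache = list(enc = enc, cv = cv, top_dim = td, fdrop = fdrop,
                    h1 = h1, g1 = g1, h2 = h2))
}

# Backward pass; returns gradients shaped exactly like model$params.
api_backward_batch <- function(dlogits, fwc, model) {
  cache <- fwc$cache
  td <- cache$top_dim
  h2b <- linear_bwd(matrix(dlogits, ncol = 1), cache$h2,
                    model$params$head$W2)
  dg1 <- gelu_bwd(h2b$dx, cache$g1)
  h1b <- linear_bwd(dg1, cache$h1, model$params$head$W1)
  dfeat <- dropout_bwd(h1b$dx, cache$fdrop)
  dtop <- `dim<-`(t(dfeat), td)
  cvb <- conv_stack_bwd(dtop, cache$cv, model$params$conv, model$conv_cfg)
  dx4 <- cvb$dx
  g_apta_emb <- matrix(0, model$apta_cfg$vocab_size,
                       model$apta_cfg$embed_dim)
  g_prot_emb <- matrix(0, model$prot_cfg$vocab_size,
                       model$prot_cfg$embed_dim)
  g_apta_layers <- NULL
  g_prot_layers <- NULL
  for (b in seq_along(cache$enc)) {
    e <- cache$enc[[b]]
    dim_u <- dx4[1L, e$off_r + seq_len(e$ru), e$off_c + seq_len(e$cu), b,
                 drop = FALSE]
    dim_u <- matrix(dim_u, e$ru, e$cu)
    ea <- e$fa$out
    ep <- e$fp$out
    dea <- matrix(0, nrow(ea), ncol(ea))
    dep <- matrix(0, nrow(ep), ncol(ep))
    dea[seq_len(e$ru), ] <- dim_u %*% ep[seq_len(e$cu), , drop = FALSE]
    dep[seq_len(e$cu), ] <- crossprod(dim_u, ea[seq_len(e$ru), , drop = FALSE])
    ab <- encoder_bwd(dea, e$fa, model$params$apta, model$apta_cfg)
    pb <- encoder_bwd(dep, e$fp, model$params$prot, model$prot_cfg)
    g_apta_emb[ab$emb_ids + 1L, ] <- g_apta_emb[ab$emb_ids + 1L, ] + ab$emb_d
    g_prot_emb[pb$emb_ids + 1L, ] <- g_prot_emb[pb$emb_ids + 1L, ] + pb$emb_d
    g_apta_layers <- if (is.null(g_apta_layers)) ab$layers
                     else tree_add(g_apta_layers, ab$layers)
    g_prot_layers <- if (is.null(g_prot_layers)) pb$layers
                     else tree_add(g_prot_layers, pb$layers)
  }
  list(apta = list(emb = g_apta_emb, layers = g_apta_layers),
       prot = list(emb = g_prot_emb, layers = g_prot_layers),
       conv = cvb$grads,
       head = list(W1 = h1b$dW, b1 = h1b$db, W2 = h2b$dW, b2 = h2b$db))
}

#' Symmetric-aptamer data augmentation
#'
#' Oligonucleotide aptamers have no distinct head or tail, so the
#' residue-reversed sequence denotes the same molecule: for every pair a
#' reversed-aptamer copy with the same protein and label is appended,
#' exactly doubling the dataset and preserving the class balance.
#'
#' @param pairs list of [api_pair()].
#' @return list of length `2 * length(pairs)`.
#' @examples
#' p <- api_pair("ACGAC", bio_seq("SVFSERT", alphabet = "PROTEIN"), 1)
#' augment_pairs(list(p))[[2]]$aptamer$residues # "CAGCA"
#' @export
augment_pairs <- function(pairs) {
  rev_str <- function(x) paste(rev(strsplit(x, "", fixed = TRUE)[[1]]),
                               collapse = "")
  c(pairs, lapply(pairs, function(p) {
    api_pair(bio_seq(rev_str(p$aptamer$residues),
                     id = paste0(p$aptamer$id, "_rev"), alphabet = "RNA"),
             p$protein, p$label)
  }))
}

#' Train (fine-tune) the API prediction model
#'
#' Applies [augment_pairs()] to the training pairs, tokenizes once, and
#' minimizes binary cross-entropy on the sigmoid binding score with AdamW.
#' Encoders are initialized from pretrained checkpoints when given (weights
#' reproduced bit-exactly at epoch 0) and randomly otherwise.
#'
#' @param train_pairs list of [api_pair()]; both classes must be present.
#' @param prot_vocab protein FCS vocabulary; mined from the training
#'   proteins when `NULL`.
#' @param apta_cfg,prot_cfg [encoder_config()]s; `NULL` uses the reference
#'   defaults for the corresponding vocabulary.
#' @param conv_cfg a [conv_config()].
#' @param epochs,batch_size optimization schedule.
#' @param lr AdamW learning rate (reference default `1e-5`; desk-scale
#'   configs typically use a larger rate, see [tiny_api_config()]).
#' @param weight_decay AdamW decoupled weight decay.
#' @param seed global seed; per-stage seeds are derived from it.
#' @param apta_pretrained,prot_pretrained optional `pretrained_encoder`
#'   objects (vocabulary hashes are checked).
#' @param map_jitter place each interaction map at a random offset on the
#'   padded canvas during training (evaluation is always deterministic,
#'   top-left). Regularizes the position-specific flatten head towards
#'   translation invariance; recommended whenever the map canvas is much
#'   larger than typical maps or training sets are small.
#' @param token_dropout probability of replacing an input token with
#'   `[MASK]` during training (fresh draw every epoch). A word-dropout
#'   augmentation that suppresses memorization of individual training
#'   pairs and matches the masked-token pretraining distribution;
#'   evaluation always sees the unmasked stream.
#' @param lr_schedule `"constant"`, or `"cosine"` decay to 5% of `lr`
#'   over the run.
#' @param warmup_steps linear learning-rate warm-up over this many
#'   optimizer steps (stabilizes early post-norm transformer training).
#' @param clip_grad_norm global gradient-norm clipping threshold
#'   (`Inf` disables).
#' @param swa_start average the weights of epochs `swa_start..epochs`
#'   (stochastic weight averaging) and refresh the batch-norm statistics
#'   with one pass over the training data; `0` disables. Smooths the
#'   epoch-to-epoch oscillation of small-sample training.
#' @param k k-mer order.
#' @param verbose print per-epoch losses.
#' @return an object of class `api_fit`: `model` plus a per-epoch `trace`
#'   data frame of the mean training loss.
#' @export
train_api_model <- function(train_pairs, prot_vocab = NULL,
                            apta_cfg = NULL, prot_cfg = NULL,
                            conv_cfg = conv_config(),
                            epochs = 50L, batch_size = 32L, lr = 1e-5,
                            weight_decay = 0.01, seed = 1L,
                            apta_pretrained = NULL, prot_pretrained = NULL,
                            map_jitter = TRUE, token_dropout = 0,
                            lr_schedule = c("constant", "cosine"),
                            warmup_steps = 0L, clip_grad_norm = Inf,
                            swa_start = 0L, k = 3L, verbose = FALSE) {
  lr_schedule <- match.arg(lr_schedule)
  labels <- vapply(train_pairs, function(p) p$label, integer(1))
  if (length(unique(labels)) < 2) {
    stop("training set contains a single class; need both labels",
         call. = FALSE)
  }
  apta_vocab <- kmer_vocab(k)
  prot_vocab <- prot_vocab %||%
    mine_fcs_vocab(lapply(train_pairs, function(p) p$protein))
  apta_cfg <- apta_cfg %||% encoder_config(vocab_size(apta_vocab))
  prot_cfg <- prot_cfg %||% encoder_config(vocab_size(prot_vocab))
  model <- build_api_model(apta_vocab, prot_vocab, apta_cfg, prot_cfg,
                           conv_cfg, seed = derive_seed(seed, "init"), k = k)
  if (!is.null(apta_pretrained)) {
    model$params$apta <- load_pretrained_into(apta_pretrained, apta_cfg,
                                              apta_vocab, "aptamer")
  }
  if (!is.null(prot_pretrained)) {
    model$params$prot <- load_pretrained_into(prot_pretrained, prot_cfg,
                                              prot_vocab, "protein")
  }
  aug <- augment_pairs(train_pairs)
  y <- vapply(aug, function(p) p$label, numeric(1))
  toks <- lapply(aug, function(p) tokenize_pair(model, p))
  trace <- data.frame(epoch = integer(0), loss = numeric(0))
  if (epochs > 0) {
    opt <- adamw_init(model$params)
    n <- length(aug)
    steps_per_epoch <- length(seq(1, n, by = batch_size))
    total_steps <- steps_per_epoch * epochs
    step_no <- 0
    swa_sum <- NULL
    swa_n <- 0
    for (epoch in seq_len(epochs)) {
      set.seed(derive_seed(seed, paste0("epoch", epoch)))
      ord <- sample.int(n)
      loss_sum <- 0
      n_batch <- 0
      for (start in seq(1, n, by = batch_size)) {
        idx <- ord[start:min(start + batch_size - 1, n)]
        batch_toks <- toks[idx]
        if (token_dropout > 0) {
          batch_toks <- lapply(batch_toks, drop_tokens, token_dropout)
        }
        fw <- api_forward_batch(model, batch_toks, train = TRUE,
                                jitter = map_jitter)
        model$bn_state <- fw$bn_state
        bce <- bce_fwd(fw$logits, y[idx])
        grads <- api_backward_batch(bce$dlogits, fw, model)
        if (is.finite(clip_grad_norm)) {
          grads <- clip_global_norm(grads, clip_grad_norm)
        }
        step_no <- step_no + 1
        lr_t <- scheduled_lr(lr, step_no, total_steps, lr_schedule,
                             warmup_steps)
        step <- adamw_step(model$params, grads, opt, lr = lr_t,
                           weight_decay = weight_decay)
        model$params <- step$params
        opt <- step$state
        loss_sum <- loss_sum + bce$loss
        n_batch <- n_batch + 1
      }
      epoch_loss <- loss_sum / n_batch
      if (!is.finite(epoch_loss)) {
        stop("non-finite training loss at epoch ", epoch, call. = FALSE)
      }
      if (verbose) log_msg("epoch %d: loss %.4f", epoch, epoch_loss)
      trace <- rbind(trace, data.frame(epoch = epoch, loss = epoch_loss))
      if (swa_start > 0 && epoch >= swa_start) {
        swa_sum <- if (is.null(swa_sum)) model$params
                   else tree_add(swa_sum, model$params)
        swa_n <- swa_n + 1
      }
    }
    if (swa_n > 0) {
      model$params <- tree_scale(swa_sum, 1 / swa_n)
      model <- refresh_bn_state(model, toks, batch_size, seed)
    }
  }
  structure(list(model = model, trace = trace), class = "api_fit")
}

# Recompute batch-norm running statistics for the (averaged) weights with
# forward passes over the training token streams; no parameter updates.
refresh_bn_state <- function(model, toks, batch_size, seed) {
  model$bn_state <- init_conv_state(model$conv_cfg)
  set.seed(derive_seed(seed, "bn-refresh"))
  n <- length(toks)
  for (start in seq(1, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1, n)
    fw <- api_forward_batch(model, toks[idx], train = TRUE)
    model$bn_state <- fw$bn_state
  }
  model
}

# replace each token id with [MASK] independently at rate p
drop_tokens <- function(tk, p) {
  for (side in c("a", "p")) {
    ids <- tk[[side]]$token_ids
    hit <- runif(length(ids)) < p
    if (any(hit)) {
      ids[hit] <- 1L
      tk[[side]]$token_ids <- ids
    }
  }
  tk
}

clip_global_norm <- function(grads, max_norm) {
  sq <- 0
  walk <- function(g) {
    if (is.list(g)) {
      for (el in g) walk(el)
    } else {
      sq <<- sq + sum(g * g)
    }
    invisible(NULL)
  }
  walk(grads)
  nrm <- sqrt(sq)
  if (nrm <= max_norm) grads else tree_scale(grads, max_norm / nrm)
}

scheduled_lr <- function(lr, step, total, schedule, warmup) {
  fac <- if (warmup > 0 && step <= warmup) step / warmup else 1
  if (schedule == "cosine") {
    prog <- max(0, (step - warmup) / max(1, total - warmup))
    fac <- fac * (0.05 + 0.95 * (1 + cos(pi * prog)) / 2)
  }
  lr * fac
}

load_pretrained_into <- function(pre, cfg, vocab, what) {
  if (!inherits(pre, "pretrained_encoder")) {
    stop("expected a pretrained_encoder for the ", what, " side",
         call. = FALSE)
  }
  if (!identical(pre$vocab_hash, string_hash(vocab$tokens))) {
    stop("pretrained ", what,
         " encoder was built with a different vocabulary", call. = FALSE)
  }
  if (!identical(unclass(pre$encoder_cfg)[c("vocab_size", "embed_dim",
                                            "n_heads", "n_layers", "ff_dim")],
                 unclass(cfg)[c("vocab_size", "embed_dim", "n_heads",
                                "n_layers", "ff_dim")])) {
    stop("pretrained ", what, " encoder config differs from the model's",
         call. = FALSE)
  }
  pre$params
}

#' Predict the binding score of one aptamer-protein pair
#'
#' Tokenizes both sequences, encodes them, forms the interaction map, runs
#' the convolutional stack in evaluation mode and returns the sigmoid of
#' the head's logit.
#'
#' @param model a trained [build_api_model()] / [train_api_model()] model
#'   (an `api_fit` is accepted).
#' @param aptamer RNA sequence (string or [bio_seq()]; DNA is normalized).
#' @param protein protein sequence (string or [bio_seq()]).
#' @param return_im also return the interaction map.
#' @return an object of class `binding_prediction` with fields `score` (in
#'   `[0, 1]`), `logit`, and optionally `im`.
#' @export
predict_binding <- function(model, aptamer, protein, return_im = FALSE) {
  if (inherits(model, "api_fit")) model <- model$model
  if (!inherits(aptamer, "bio_seq")) aptamer <- dna_to_rna(aptamer)
  protein <- as_bio_seq(protein, "PROTEIN")
  pair <- list(aptamer = aptamer, protein = protein)
  toks <- tokenize_pair(model, pair)
  fw <- api_forward_batch(model, list(toks), train = FALSE)
  out <- list(score = plogis(fw$logits[1]), logit = fw$logits[1])
  if (return_im) {
    e <- fw$cache$enc[[1]]
    out$im <- structure(list(values = tcrossprod(e$fa$out, e$fp$out),
                             row_mask = rep(TRUE, nrow(e$fa$out)),
                             col_mask = rep(TRUE, nrow(e$fp$out))),
                        class = "interaction_map")
    rownames(out$im$values) <- toks$a$tokens[seq_len(nrow(out$im$values))]
    colnames(out$im$values) <- toks$p$tokens[seq_len(ncol(out$im$values))]
  }
  structure(out, class = "binding_prediction")
}

#' @export
print.binding_prediction <- function(x, ...) {
  cat(sprintf("<binding_prediction> score %.4f (logit %.3f)\n",
              x$score, x$logit))
  invisible(x)
}

#' Predict binding scores for a list of pairs
#' @param model an `api_model` or `api_fit`.
#' @param pairs list of [api_pair()].
#' @param batch_size forward-pass batch size.
#' @return numeric vector of scores in `[0, 1]`.
#' @export
predict_pairs <- function(model, pairs, batch_size = 32L) {
  if (inherits(model, "api_fit")) model <- model$model
  toks <- lapply(pairs, function(p) tokenize_pair(model, p))
  out <- numeric(length(pairs))
  for (start in seq(1, length(pairs), by = batch_size)) {
    idx <- start:min(start + batch_size - 1, length(pairs))
    fw <- api_forward_batch(model, toks[idx], train = FALSE)
    out[idx] <- plogis(fw$logits)
  }
  out
}

#' Evaluate a model on labelled pairs
#' @inheritParams predict_pairs
#' @param threshold classification threshold for the confusion counts.
#' @return a `metrics_report`, see [compute_metrics()].
#' @export
evaluate_pairs <- function(model, pairs, threshold = 0.5) {
  scores <- predict_pairs(model, pairs)
  labels <- vapply(pairs, function(p) p$label, integer(1))
  compute_metrics(scores, labels, threshold = threshold)
}

# --- metrics --------------------------------------------------------------

#' Binary classification metrics for API prediction
#'
#' Computes ROC-AUC (rank statistic with midranks for ties, equivalent to
#' integrating the ROC curve over all thresholds), and the five
#' threshold-based metrics from the confusion counts at `threshold`:
#' accuracy, sensitivity `TP / (TP + FN)`, specificity `TN / (TN + FP)`,
#' Matthews correlation coefficient in its standard square-root-denominator
#' form, and F1 `2 TP / (2 TP + FP + FN)`. MCC and F1 are defined as 0 when
#' their denominators vanish.
#'
#' @param scores predicted probabilities in `[0, 1]`.
#' @param labels binary labels (0/1); both classes must be present.
#' @param threshold scores `>= threshold` are called positive.
#' @return an object of class `metrics_report` with fields `roc_auc`,
#'   `acc`, `mcc`, `sn`, `sp`, `f1`, `threshold` and `counts`
#'   (TP/TN/FP/FN).
#' @examples
#' compute_metrics(c(1, 1, 0, 0), c(1, 1, 0, 0))$roc_auc # 1
#' @export
compute_metrics <- function(scores, labels, threshold = 0.5) {
  stopifnot(length(scores) == length(labels))
  labels <- as.integer(labels)
  if (!all(labels %in% c(0L, 1L))) {
    stop("labels must be 0/1", call. = FALSE)
  }
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) {
    stop("roc_auc undefined: labels contain a single class", call. = FALSE)
  }
  r <- rank(scores)
  roc_auc <- (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  pred <- as.integer(scores >= threshold)
  tp <- sum(pred == 1 & labels == 1)
  tn <- sum(pred == 0 & labels == 0)
  fp <- sum(pred == 1 & labels == 0)
  fn <- sum(pred == 0 & labels == 1)
  acc <- (tp + tn) / (tp + tn + fp + fn)
  sn <- if (tp + fn > 0) tp / (tp + fn) else 0
  sp <- if (tn + fp > 0) tn / (tn + fp) else 0
  f1 <- if (2 * tp + fp + fn > 0) 2 * tp / (2 * tp + fp + fn) else 0
  denom <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  mcc <- if (denom > 0) (tp * tn - fp * fn) / denom else 0
  structure(list(roc_auc = roc_auc, acc = acc, mcc = mcc, sn = sn, sp = sp,
                 f1 = f1, threshold = threshold,
                 counts = list(TP = tp, TN = tn, FP = fp, FN = fn)),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf(paste0("<metrics_report> ROC-AUC %.3f ACC %.3f MCC %.3f ",
                     "Sn %.3f Sp %.3f F1 %.3f (threshold %.2f)\n"),
              x$roc_auc, x$acc, x$mcc, x$sn, x$sp, x$f1, x$threshold))
  invisible(x)
}

# --- checkpoints ----------------------------------------------------------

#' Save a model or pretrained encoder with a JSON sidecar
#'
#' Writes the object itself (bit-exact reload) plus a human-readable JSON
#' sidecar (`<path>.json`) recording configs and vocabulary hashes.
#'
#' @param object an `api_model`, `api_fit` or `pretrained_encoder`.
#' @param path output file.
#' @export
save_checkpoint <- function(object, path) {
  saveRDS(object, path)
  meta <- list(class = class(object)[1], saved = format(Sys.time()))
  obj <- if (inherits(object, "api_fit")) object$model else object
  if (inherits(obj, "api_model")) {
    meta$apta_cfg <- unclass(obj$apta_cfg)
    meta$prot_cfg <- unclass(obj$prot_cfg)
    meta$conv_cfg <- unclass(obj$conv_cfg)
    meta$apta_vocab_hash <- string_hash(obj$apta_vocab$tokens)
    meta$prot_vocab_hash <- string_hash(obj$prot_vocab$tokens)
  } else if (inherits(obj, "pretrained_encoder")) {
    meta$encoder_cfg <- unclass(obj$encoder_cfg)
    meta$vocab_hash <- obj$vocab_hash
  }
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

#' Load a checkpoint written by [save_checkpoint()]
#' @param path checkpoint file.
#' @export
load_checkpoint <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  readRDS(path)
}

#' Desk-scale model and training configuration
#'
#' The package's recipe for laptop-scale experiments and the synthetic
#' planted-rule studies: 2-layer encoders with embedding size 32 (4 heads,
#' feed-forward width 64, dropout 0.1), a single 8-channel stage of 3
#' convolution blocks on a 28 x 40 interaction map with a width-16 head
#' (feature dropout 0.3), and AdamW at `1e-3` — a rate appropriate for
#' training this size of model from scratch — with cosine decay, 100
#' warm-up steps, gradient-norm clipping at 4 and weight decay 0.02.
#' Warm-up and clipping are part of the recipe because desk-scale
#' post-norm training can otherwise collapse to the constant class-prior
#' prediction on some seeds; map-placement jitter and head feature
#' dropout counter position memorization by the flatten head.
#'
#' @param apta_vocab,prot_vocab the vocabularies the model will use.
#' @return list with `apta_cfg`, `prot_cfg`, `conv_cfg` and the training
#'   settings `lr`, `batch_size`, `weight_decay`, `warmup_steps`,
#'   `clip_grad_norm`, `lr_schedule`, `map_jitter`.
#' @export
tiny_api_config <- function(apta_vocab, prot_vocab) {
  list(
    apta_cfg = encoder_config(vocab_size(apta_vocab), embed_dim = 32L,
                              n_heads = 4L, n_layers = 2L, ff_dim = 64L,
                              dropout = 0.1, max_len = 64L),
    prot_cfg = encoder_config(vocab_size(prot_vocab), embed_dim = 32L,
                              n_heads = 4L, n_layers = 2L, ff_dim = 64L,
                              dropout = 0.1, max_len = 64L),
    conv_cfg = conv_config(stage_channels = 8L, blocks_per_stage = 3L,
                           map_rows = 28L, map_cols = 40L,
                           head_hidden = 16L, head_dropout = 0.3),
    lr = 1e-3, batch_size = 32L, weight_decay = 0.02,
    warmup_steps = 100L, clip_grad_norm = 4, lr_schedule = "cosine",
    map_jitter = TRUE)
}
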