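# Self-supervised encoder pretraining: masked-token prediction (MTP) with
# overlap-aware masking for k-mer streams, and secondary-structure
# prediction (SSP) over span-aligned structure tokens. The two tasks share
# the encoder and are trained jointly with equal loss weights through two
# linear heads.

#' Pretraining configuration
#'
#' @param mask_rate fraction of candidate tokens selected for masking
#'   (ceiling rule guarantees at least one masked position).
#' @param neighbor_radius for k-mer streams, how many neighbours on each
#'   side of a selected centre are masked along with it; radius 1 hides
#'   every token sharing at least two residues with a 3-mer centre.
#' @param epochs,batch_size,lr,weight_decay optimization settings (AdamW).
#' @param seed integer seed.
#' @return an object of class `pretrain_config`.
#' @export
pretrain_config <- function(mask_rate = 0.15, neighbor_radius = 1L,
                            epochs = 5L, batch_size = 16L, lr = 1e-3,
                            weight_decay = 0.01, seed = 1L) {
  if (mask_rate <= 0 || mask_rate >= 1) {
    stop("mask_rate must be in (0, 1)", call. = FALSE)
  }
  structure(list(mask_rate = mask_rate,
                 neighbor_radius = as.integer(neighbor_radius),
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 lr = lr, weight_decay = weight_decay,
                 seed = as.integer(seed)),
            class = "pretrain_config")
}

new_masked_batch <- function(input_ids, target_ids, mask_positions) {
  structure(list(input_ids = as.integer(input_ids),
                 target_ids = target_ids,
                 mask_positions = as.integer(mask_positions)),
            class = "masked_batch")
}

#' Mask tokens of an FCS (protein) stream
#'
#' Selects `ceiling(mask_rate * n)` positions uniformly without replacement
#' and replaces each with the `[MASK]` id. Targets are the original ids at
#' the masked positions (`NA` elsewhere). Positions are 1-based.
#'
#' @param ts a `tok_seq`.
#' @param cfg a [pretrain_config()].
#' @param seed optional seed; `NULL` uses the current RNG stream.
#' @param positions optional explicit 1-based positions to mask (overrides
#'   the random draw).
#' @return a `masked_batch` with fields `input_ids`, `target_ids`
#'   (full-length, `NA` outside the mask) and `mask_positions`.
#' @export
mask_protein_tokens <- function(ts, cfg = pretrain_config(), seed = NULL,
                                positions = NULL) {
  n <- length(ts$token_ids)
  stopifnot(n >= 1)
  if (is.null(positions)) {
    draw <- function() sort(sample.int(n, ceiling(cfg$mask_rate * n)))
    positions <- if (is.null(seed)) draw() else local_seed(seed, draw())
  }
  apply_mask(ts$token_ids, positions)
}

#' Mask tokens of a k-mer stream together with their neighbours
#'
#' Overlapping k-mer tokens leak their neighbours' residues, so for every
#' selected centre `i` the positions `i - r .. i + r` (clipped to the
#' stream) are all replaced with `[MASK]`; each masked position is a
#' prediction target exactly once, even when windows overlap.
#'
#' @inheritParams mask_protein_tokens
#' @param centers optional explicit 1-based centre positions (overrides the
#'   random draw).
#' @return a `masked_batch`.
#' @export
mask_kmer_tokens <- function(ts, cfg = pretrain_config(), seed = NULL,
                             centers = NULL) {
  if (!identical(ts$mode, "kmer")) {
    stop("mask_kmer_tokens expects a k-mer tok_seq", call. = FALSE)
  }
  n <- length(ts$token_ids)
  stopifnot(n >= 1)
  r <- cfg$neighbor_radius
  if (is.null(centers)) {
    draw <- function() sort(sample.int(n, ceiling(cfg$mask_rate * n)))
    centers <- if (is.null(seed)) draw() else local_seed(seed, draw())
  }
  pos <- sort(unique(unlist(lapply(centers, function(i) {
    max(1L, i - r):min(n, i + r)
  }))))
  apply_mask(ts$token_ids, pos)
}

apply_mask <- function(ids, pos, mask_id = 1L) {
  input <- ids
  input[pos] <- mask_id
  targets <- rep(NA_integer_, length(ids))
  targets[pos] <- ids[pos]
  new_masked_batch(input, targets, pos)
}

#' Span-aligned secondary-structure targets
#'
#' Co-tokenizes the structure string along the sequence tokens and maps
#' every structure token to its id in the structure vocabulary; tokens not
#' in the vocabulary map to `[UNK]`.
#'
#' @param ts a `tok_seq`.
#' @param ann a [structure_annotation()].
#' @param svocab structure vocabulary from [build_structure_vocab()].
#' @return integer vector of 0-based target ids, one per sequence token.
#' @export
make_ssp_targets <- function(ts, ann, svocab) {
  stoks <- cotokenize_structure(ts, ann)
  vapply(stoks, function(t) {
    id <- token_id(svocab, t)
    if (is.na(id)) svocab$specials[["unk"]] else id
  }, integer(1), USE.NAMES = FALSE)
}

#' Pretrain an encoder with masked-token and structure prediction
#'
#' Jointly minimizes (a) cross-entropy of original-token prediction at
#' masked positions and (b) cross-entropy of structure-token prediction at
#' all positions, with equal weights, via two linear heads on the shared
#' encoder. RNA corpora are tokenized as k-mers and masked with
#' [mask_kmer_tokens()]; protein corpora use the FCS vocabulary and
#' [mask_protein_tokens()]. With `structure_corpus = NULL` only the
#' masked-token task is trained.
#'
#' @param corpus list of [bio_seq()] (all RNA or all protein).
#' @param structure_corpus list of [structure_annotation()] aligned with
#'   `corpus` (or `NULL`).
#' @param vocab sequence vocabulary ([kmer_vocab()] or [mine_fcs_vocab()]).
#' @param encoder_cfg an [encoder_config()]; its `vocab_size` must equal
#'   `vocab_size(vocab)`.
#' @param cfg a [pretrain_config()].
#' @param svocab optional structure vocabulary; mined from the corpus when
#'   `NULL`.
#' @param k k-mer order for RNA corpora.
#' @return an object of class `pretrained_encoder`: encoder `params`, the
#'   two head parameter sets, `trace` (per-epoch mean losses), the configs
#'   and vocabulary hashes.
#' @export
pretrain_encoder <- function(corpus, structure_corpus, vocab, encoder_cfg,
                             cfg = pretrain_config(), svocab = NULL, k = 3L) {
  if (length(corpus) == 0) stop("empty corpus", call. = FALSE)
  if (encoder_cfg$vocab_size != vocab_size(vocab)) {
    stop("encoder_cfg$vocab_size != vocab_size(vocab)", call. = FALSE)
  }
  alphabet <- corpus[[1]]$alphabet
  tss <- lapply(corpus, function(s) {
    ts <- if (alphabet == "RNA") kmer_tokenize(s, k = k, vocab = vocab)
          else fcs_tokenize(s, vocab)
    if (length(ts$token_ids) > encoder_cfg$max_len) {
      stop("corpus sequence exceeds encoder max_len; increase max_len",
           call. = FALSE)
    }
    ts
  })
  use_ssp <- !is.null(structure_corpus)
  ssp_targets <- NULL
  if (use_ssp) {
    stopifnot(length(structure_corpus) == length(corpus))
    stok_lists <- Map(cotokenize_structure, tss, structure_corpus)
    svocab <- svocab %||% build_structure_vocab(stok_lists)
    ssp_targets <- Map(make_ssp_targets, tss, structure_corpus,
                       MoreArgs = list(svocab = svocab))
  }
  D <- encoder_cfg$embed_dim
  params <- local_seed(derive_seed(cfg$seed, "pretrain-init"), {
    p <- init_encoder(encoder_cfg, seed = derive_seed(cfg$seed, "encoder"))
    p$mtp_head <- list(W = xavier_mat(D, vocab_size(vocab)),
                       b = numeric(vocab_size(vocab)))
    if (use_ssp) {
      p$ssp_head <- list(W = xavier_mat(D, vocab_size(svocab)),
                         b = numeric(vocab_size(svocab)))
    }
    p
  })
  trace <- data.frame(epoch = integer(0), mtp_loss = numeric(0),
                      ssp_loss = numeric(0))
  if (cfg$epochs > 0) {
    opt <- adamw_init(params)
    n <- length(tss)
    for (epoch in seq_len(cfg$epochs)) {
      ord <- local_seed(derive_seed(cfg$seed, paste0("pretrain-epoch", epoch)),
                        sample.int(n))
      mtp_sum <- 0
      ssp_sum <- 0
      set.seed(derive_seed(cfg$seed, paste0("pretrain-mask", epoch)))
      for (start in seq(1, n, by = cfg$batch_size)) {
        batch <- ord[start:min(start + cfg$batch_size - 1, n)]
        acc <- NULL
        for (i in batch) {
          ex <- pretrain_example_grad(
            tss[[i]], if (use_ssp) ssp_targets[[i]] else NULL,
            params, encoder_cfg, cfg, alphabet)
          mtp_sum <- mtp_sum + ex$mtp_loss
          ssp_sum <- ssp_sum + ex$ssp_loss
          acc <- if (is.null(acc)) ex$grads else tree_add(acc, ex$grads)
        }
        acc <- tree_scale(acc, 1 / length(batch))
        step <- adamw_step(params, acc, opt, lr = cfg$lr,
                           weight_decay = cfg$weight_decay)
        params <- step$params
        opt <- step$state
      }
      trace <- rbind(trace, data.frame(epoch = epoch, mtp_loss = mtp_sum / n,
                                       ssp_loss = ssp_sum / n))
      if (any(!is.finite(c(mtp_sum, ssp_sum)))) {
        stop("non-finite pretraining loss", call. = FALSE)
      }
    }
  }
  structure(list(params = params[c("emb", "layers")],
                 mtp_head = params$mtp_head,
                 ssp_head = params$ssp_head,
                 encoder_cfg = encoder_cfg, pretrain_cfg = cfg,
                 svocab = if (use_ssp) svocab else NULL,
                 vocab_hash = string_hash(vocab$tokens),
                 trace = trace),
            class = "pretrained_encoder")
}

# loss and gradients for one pretraining example (dense grads except emb)
pretrain_example_grad <- function(ts, ssp_t, params, ecfg, cfg, alphabet) {
  mb <- if (alphabet == "RNA") mask_kmer_tokens(ts, cfg)
        else mask_protein_tokens(ts, cfg)
  fw <- encoder_fwd(mb$input_ids, params, ecfg, train = TRUE)
  out <- fw$out
  pos <- mb$mask_positions
  mtp_logits <- sweep(out[pos, , drop = FALSE] %*% params$mtp_head$W,
                      2, params$mtp_head$b, `+`)
  ce_m <- cross_entropy_fwd(mtp_logits, mb$target_ids[pos])
  dout <- matrix(0, nrow(out), ncol(out))
  dout[pos, ] <- tcrossprod(ce_m$dlogits, params$mtp_head$W)
  g_mtp <- list(W = crossprod(out[pos, , drop = FALSE], ce_m$dlogits),
                b = colSums(ce_m$dlogits))
  ssp_loss <- 0
  g_ssp <- NULL
  if (!is.null(ssp_t)) {
    ssp_logits <- sweep(out %*% params$ssp_head$W, 2, params$ssp_head$b, `+`)
    ce_s <- cross_entropy_fwd(ssp_logits, ssp_t)
    ssp_loss <- ce_s$loss
    dout <- dout + tcrossprod(ce_s$dlogits, params$ssp_head$W)
    g_ssp <- list(W = crossprod(out, ce_s$dlogits),
                  b = colSums(ce_s$dlogits))
  }
  enc_b <- encoder_bwd(dout, fw, params, ecfg)
  demb <- matrix(0, ecfg$vocab_size, ecfg$embed_dim)
  demb[enc_b$emb_ids + 1L, ] <- enc_b$emb_d
  grads <- list(emb = demb, layers = enc_b$layers, mtp_head = g_mtp)
  if (!is.null(g_ssp)) grads$ssp_head <- g_ssp
  list(grads = grads, mtp_loss = ce_m$loss, ssp_loss = ssp_loss)
}
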