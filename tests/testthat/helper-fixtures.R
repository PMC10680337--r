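# Shared fixtures and independent oracles used across the suite.

rand_rna <- function(n) {
  paste(sample(c("A", "C", "G", "U"), n, replace = TRUE), collapse = "")
}

rand_protein <- function(n) {
  paste(sample(aptabind:::PROTEIN_LETTERS, n, replace = TRUE), collapse = "")
}

rand_protein_seqs <- function(k, len_range = c(10, 40)) {
  lapply(seq_len(k), function(i) {
    bio_seq(rand_protein(sample(len_range[1]:len_range[2], 1)),
            id = paste0("p", i), alphabet = "PROTEIN")
  })
}

# brute-force substring counting oracle for FCS vocabulary mining
oracle_substring_counts <- function(strings, max_len = 3) {
  subs <- character(0)
  for (s in strings) {
    n <- nchar(s)
    for (L in seq_len(max_len)) {
      if (n < L) next
      for (i in seq_len(n - L + 1)) subs <- c(subs, substr(s, i, i + L - 1))
    }
  }
  table(subs)
}

# position-by-position greedy tokenizer, independent of the implementation
oracle_greedy_tokenize <- function(s, token_set, max_len = 3) {
  out <- character(0)
  pos <- 1
  n <- nchar(s)
  while (pos <= n) {
    hit <- NULL
    for (len in seq(min(max_len, n - pos + 1), 1)) {
      cand <- substr(s, pos, pos + len - 1)
      if (cand %in% token_set) {
        hit <- cand
        break
      }
    }
    if (is.null(hit)) stop("oracle: no match at ", pos)
    out <- c(out, hit)
    pos <- pos + nchar(hit)
  }
  out
}

# confusion-matrix enumeration oracle
oracle_confusion <- function(scores, labels, threshold = 0.5) {
  tp <- tn <- fp <- fn <- 0L
  for (i in seq_along(scores)) {
    pred <- if (scores[i] >= threshold) 1 else 0
    if (pred == 1 && labels[i] == 1) tp <- tp + 1L
    if (pred == 0 && labels[i] == 0) tn <- tn + 1L
    if (pred == 1 && labels[i] == 0) fp <- fp + 1L
    if (pred == 0 && labels[i] == 1) fn <- fn + 1L
  }
  list(TP = tp, TN = tn, FP = fp, FN = fn)
}

# threshold-sweep trapezoidal ROC integration oracle
oracle_auc_sweep <- function(scores, labels) {
  ths <- sort(unique(scores))
  tpr <- c(1)
  fpr <- c(1)
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  for (t in ths) {
    tpr <- c(tpr, sum(scores >= t & labels == 1) / n1)
    fpr <- c(fpr, sum(scores >= t & labels == 0) / n0)
  }
  tpr <- c(tpr, 0)
  fpr <- c(fpr, 0)
  # trapezoid over the (fpr, tpr) staircase, descending
  auc <- 0
  for (i in seq_len(length(tpr) - 1)) {
    auc <- auc + (fpr[i] - fpr[i + 1]) * (tpr[i] + tpr[i + 1]) / 2
  }
  auc
}

# tiny encoder fixture
tiny_encoder <- function(vocab, n_layers = 1L, embed_dim = 16L,
                         seed = 1L, dropout = 0) {
  cfg <- encoder_config(vocab_size(vocab), embed_dim = embed_dim,
                        n_heads = 2L, n_layers = n_layers, ff_dim = 24L,
                        dropout = dropout, max_len = 64L)
  list(cfg = cfg, weights = init_encoder(cfg, seed = seed))
}

# tiny end-to-end model fixture over random vocabularies
tiny_model <- function(seed = 7L, prot_corpus_n = 15L) {
  av <- kmer_vocab(3)
  pv <- local_seed(seed, mine_fcs_vocab(rand_protein_seqs(prot_corpus_n)))
  acfg <- encoder_config(vocab_size(av), embed_dim = 16L, n_heads = 2L,
                         n_layers = 1L, ff_dim = 24L, dropout = 0,
                         max_len = 32L)
  pcfg <- encoder_config(vocab_size(pv), embed_dim = 16L, n_heads = 2L,
                         n_layers = 1L, ff_dim = 24L, dropout = 0,
                         max_len = 32L)
  ccfg <- conv_config(stage_channels = c(3L, 4L), blocks_per_stage = 3L,
                      map_rows = 8L, map_cols = 10L, head_hidden = 5L,
                      head_dropout = 0)
  build_api_model(av, pv, acfg, pcfg, ccfg, seed = seed)
}

local_seed <- aptabind:::local_seed

random_pairs <- function(n, seed = 1) {
  local_seed(seed, {
    lapply(seq_len(n), function(i) {
      api_pair(bio_seq(rand_rna(sample(10:16, 1)), alphabet = "RNA"),
               bio_seq(rand_protein(sample(12:25, 1)), alphabet = "PROTEIN"),
               label = i %% 2)
    })
  })
}
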