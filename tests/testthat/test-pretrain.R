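make_protein_ts <- function(seq, extra_tokens) {
  v <- new_vocab(c(extra_tokens, aptabind:::PROTEIN_LETTERS))
  fcs_tokenize(bio_seq(seq, alphabet = "PROTEIN"), v)
}

test_that("protein masking replaces selected tokens and keeps the rest", {
  ts <- make_protein_ts("MSRLDKSK", c("MSR", "LDK", "SK"))
  expect_identical(ts$tokens, c("MSR", "LDK", "SK"))
  mb <- mask_protein_tokens(ts, positions = 2L)
  expect_identical(mb$input_ids,
                   c(ts$token_ids[1], 1L, ts$token_ids[3]))
  expect_identical(mb$target_ids[2], ts$token_ids[2]) # LDK recovered
  expect_true(all(is.na(mb$target_ids[-2])))
  expect_identical(mb$mask_positions, 2L)
})

test_that("the ceiling rule guarantees at least one masked position", {
  v <- new_vocab(aptabind:::PROTEIN_LETTERS)
  cfg <- pretrain_config(mask_rate = 0.15)
  for (n in c(1, 2, 5, 13, 20)) {
    ts <- fcs_tokenize(bio_seq(local_seed(n, rand_protein(n)),
                               alphabet = "PROTEIN"), v)
    mb <- mask_protein_tokens(ts, cfg, seed = 1)
    expect_equal(length(mb$mask_positions), ceiling(0.15 * n))
    expect_gte(length(mb$mask_positions), 1)
  }
})

test_that("k-mer masking hides the centre and its neighbours", {
  # 7-nt sequence -> 5 overlapping 3-mers; masking the centre token hides
  # the three middle tokens, leaving only the flanks visible
  ts <- kmer_tokenize(dna_to_rna("ACCGTAC"))
  expect_identical(ts$tokens, c("ACC", "CCG", "CGU", "GUA", "UAC"))
  mb <- mask_kmer_tokens(ts, centers = 3L)
  expect_identical(aptabind:::id_to_token(kmer_vocab(3), mb$input_ids),
                   c("ACC", "[MASK]", "[MASK]", "[MASK]", "UAC"))
  expect_identical(mb$mask_positions, 2:4)
  expect_identical(mb$target_ids[2:4], ts$token_ids[2:4])

  # boundary clipping at the left edge
  mb0 <- mask_kmer_tokens(ts, centers = 1L)
  expect_identical(mb0$mask_positions, 1:2)

  # overlapping windows mask the union, each position targeted once
  mb2 <- mask_kmer_tokens(ts, centers = c(2L, 3L))
  expect_identical(mb2$mask_positions, 1:4)
  expect_identical(sum(!is.na(mb2$target_ids)), 4L)
})

test_that("masking is reproducible from a seed and never alters the rest", {
  v <- kmer_vocab(3)
  cfg <- pretrain_config(mask_rate = 0.2)
  local_seed(77, {
    for (rep in 1:1000) {
      ts <- kmer_tokenize(bio_seq(rand_rna(sample(3:40, 1)),
                                  alphabet = "RNA"), vocab = v)
      mb <- mask_kmer_tokens(ts, cfg)
      out <- setdiff(seq_along(ts$token_ids), mb$mask_positions)
      expect_identical(mb$input_ids[out], ts$token_ids[out])
      expect_true(all(mb$input_ids[mb$mask_positions] == 1L))
    }
  })
  ts <- kmer_tokenize(bio_seq(local_seed(1, rand_rna(30)),
                              alphabet = "RNA"), vocab = v)
  m1 <- mask_kmer_tokens(ts, cfg, seed = 5)
  m2 <- mask_kmer_tokens(ts, cfg, seed = 5)
  expect_identical(m1$mask_positions, m2$mask_positions)
})

test_that("SSP targets align one-to-one with sequence tokens", {
  v <- new_vocab(c("MSR", "LD", aptabind:::PROTEIN_LETTERS))
  ts <- fcs_tokenize("MSRLD", v)
  sv <- build_structure_vocab(list(c("SSS", "HH")))
  ids <- make_ssp_targets(ts, structure_annotation("SSSHH", "PROTEIN_SS"),
                          sv)
  expect_identical(aptabind:::id_to_token(sv, ids), c("SSS", "HH"))
  # all-coil annotation collapses to one repeated target id
  sv2 <- build_structure_vocab(list(c("CCC", "CC")))
  ids2 <- make_ssp_targets(ts, structure_annotation("CCCCC", "PROTEIN_SS"),
                           sv2)
  expect_equal(length(unique(ids2)), 2) # CCC and CC spans
  # length law on random fixtures
  local_seed(55, {
    corpus <- rand_protein_seqs(5)
    v3 <- mine_fcs_vocab(corpus)
    for (rep in 1:20) {
      n <- sample(6:30, 1)
      ts3 <- fcs_tokenize(bio_seq(rand_protein(n), alphabet = "PROTEIN"), v3)
      st <- paste(sample(aptabind:::PROTEIN_SS_LETTERS, n, TRUE),
                  collapse = "")
      ids3 <- make_ssp_targets(
        ts3, structure_annotation(st, "PROTEIN_SS"),
        build_structure_vocab(list(cotokenize_structure(
          ts3, structure_annotation(st, "PROTEIN_SS")))))
      expect_length(ids3, length(ts3$token_ids))
    }
  })
})

test_that("zero-epoch pretraining returns the initial weights unchanged", {
  corpus <- make_structure_corpus(6, length_range = c(15, 25), seed = 3)
  seqs <- lapply(corpus, `[[`, "seq")
  anns <- lapply(corpus, `[[`, "ann")
  v <- mine_fcs_vocab(seqs)
  ecfg <- encoder_config(vocab_size(v), embed_dim = 16, n_heads = 2,
                         n_layers = 1, ff_dim = 24, dropout = 0.1,
                         max_len = 64)
  pre <- pretrain_encoder(seqs, anns, v, ecfg,
                          cfg = pretrain_config(epochs = 0, seed = 9))
  ref <- init_encoder(ecfg, seed = derive_seed(9L, "encoder"))
  expect_identical(pre$params$emb, ref$emb)
  expect_identical(pre$params$layers, ref$layers)
  expect_equal(nrow(pre$trace), 0)
})

test_that("one-epoch pretraining is deterministic and records finite losses", {
  corpus <- make_structure_corpus(8, length_range = c(15, 25), seed = 4)
  seqs <- lapply(corpus, `[[`, "seq")
  anns <- lapply(corpus, `[[`, "ann")
  v <- mine_fcs_vocab(seqs)
  ecfg <- encoder_config(vocab_size(v), embed_dim = 16, n_heads = 2,
                         n_layers = 1, ff_dim = 24, dropout = 0.1,
                         max_len = 64)
  cfg <- pretrain_config(epochs = 2, batch_size = 4, seed = 10)
  p1 <- pretrain_encoder(seqs, anns, v, ecfg, cfg = cfg)
  p2 <- pretrain_encoder(seqs, anns, v, ecfg, cfg = cfg)
  expect_identical(p1$trace, p2$trace)
  expect_identical(p1$params$emb, p2$params$emb)
  expect_equal(nrow(p1$trace), 2)
  expect_true(all(is.finite(p1$trace$mtp_loss)))
  expect_true(all(is.finite(p1$trace$ssp_loss)))
})

test_that("masked-token pretraining beats the unigram baseline on a
           deterministic motif grammar", {
  # every sequence is a repetition of one of three 6-residue motifs, so
  # context fully determines a masked token; a unigram predictor cannot
  # exploit it
  motifs <- c("MSRLDK", "WAGHTE", "KVYPQN")
  local_seed(123, {
    corpus <- lapply(1:45, function(i) {
      m <- motifs[(i %% 3) + 1]
      bio_seq(paste(rep(m, 5), collapse = ""), id = paste0("g", i),
              alphabet = "PROTEIN")
    })
    heldout <- corpus[1:6]
    trained <- corpus[7:45]
    v <- mine_fcs_vocab(trained)
    ecfg <- encoder_config(vocab_size(v), embed_dim = 16, n_heads = 2,
                           n_layers = 1, ff_dim = 32, dropout = 0,
                           max_len = 64)
    pre <- pretrain_encoder(trained, structure_corpus = NULL, v, ecfg,
                            cfg = pretrain_config(epochs = 8,
                                                  batch_size = 8,
                                                  seed = 2))
    # unigram baseline: always predict the single most frequent token
    all_ids <- unlist(lapply(trained,
                             function(s) fcs_tokenize(s, v)$token_ids))
    majority <- as.integer(names(which.max(table(all_ids))))
    correct <- 0
    base_correct <- 0
    total <- 0
    for (i in seq_along(heldout)) {
      ts <- fcs_tokenize(heldout[[i]], v)
      mb <- mask_protein_tokens(ts, pretrain_config(mask_rate = 0.2),
                                seed = i)
      fw <- aptabind:::encoder_fwd(mb$input_ids, pre$params, ecfg)
      logits <- fw$out[mb$mask_positions, , drop = FALSE] %*%
        pre$mtp_head$W
      pred <- max.col(logits) - 1L
      truth <- mb$target_ids[mb$mask_positions]
      correct <- correct + sum(pred == truth)
      base_correct <- base_correct + sum(majority == truth)
      total <- total + length(truth)
    }
    expect_gt(correct / total, base_correct / total)
  })
})
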