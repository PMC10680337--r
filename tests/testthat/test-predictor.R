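make_ce <- function(m) {
  structure(list(matrix = m, mask = rep(TRUE, nrow(m))),
            class = "contextual_embeddings")
}

test_that("interaction map is the matrix of pairwise dot products", {
  # orthonormal rows give an identity-patterned map
  ea <- make_ce(diag(4))
  ep <- make_ce(diag(4))
  expect_equal(interaction_map(ea, ep)$values, diag(4))

  # shape contract
  local_seed(3, {
    im <- interaction_map(make_ce(matrix(rnorm(7 * 6), 7, 6)),
                          make_ce(matrix(rnorm(5 * 6), 5, 6)))
    expect_equal(dim(im$values), c(7L, 5L))
  })

  expect_error(interaction_map(make_ce(matrix(0, 2, 4)),
                               make_ce(matrix(0, 2, 5))),
               "dimensions differ")

  # brute-force double-loop oracle
  local_seed(4, {
    for (rep in 1:100) {
      na <- sample(2:8, 1)
      np <- sample(2:8, 1)
      d <- sample(2:6, 1)
      A <- matrix(rnorm(na * d), na, d)
      P <- matrix(rnorm(np * d), np, d)
      im <- interaction_map(make_ce(A), make_ce(P))$values
      for (i in seq_len(na)) for (j in seq_len(np)) {
        expect_equal(im[i, j], sum(A[i, ] * P[j, ]), tolerance = 1e-5)
      }
    }
  })
})

test_that("conv feature extraction has fixed geometry and is deterministic", {
  model <- tiny_model(seed = 11)
  cfg <- model$conv_cfg
  local_seed(12, {
    f1 <- conv_feature_extract(matrix(rnorm(6 * 7), 6, 7), cfg,
                               model$params$conv, model$bn_state)
    f2 <- conv_feature_extract(matrix(rnorm(8 * 10), 8, 10), cfg,
                               model$params$conv, model$bn_state)
  })
  expect_length(f1, prod(aptabind:::conv_out_shape(cfg)))
  expect_length(f2, length(f1))
  f3 <- conv_feature_extract(matrix(0, 8, 10), cfg, model$params$conv,
                             model$bn_state)
  expect_true(all(is.finite(f3))) # zero map through eval batch-norm
  f4 <- conv_feature_extract(matrix(0, 8, 10), cfg, model$params$conv,
                             model$bn_state)
  expect_identical(f3, f4)
})

test_that("symmetric-aptamer augmentation appends reversed copies", {
  p <- api_pair("ACGAC", bio_seq("SVFSERT", alphabet = "PROTEIN"), 1)
  aug <- augment_pairs(list(p))
  expect_length(aug, 2)
  expect_equal(aug[[2]]$aptamer$residues, "CAGCA")
  expect_equal(aug[[2]]$protein$residues, "SVFSERT")
  expect_equal(aug[[2]]$label, 1L)

  # palindromic aptamer still appended unconditionally
  pal <- api_pair("ACGCA", bio_seq("MKV", alphabet = "PROTEIN"), 0)
  expect_length(augment_pairs(list(pal)), 2)

  # exact doubling and class-balance preservation on random datasets
  local_seed(5, {
    for (rep in 1:10) {
      pairs <- random_pairs(sample(3:20, 1), seed = rep)
      aug <- augment_pairs(pairs)
      expect_length(aug, 2 * length(pairs))
      ratio <- function(x) mean(vapply(x, function(p) p$label, integer(1)))
      expect_equal(ratio(aug), ratio(pairs))
    }
  })
})

test_that("metrics match hand-computable cases", {
  perfect <- compute_metrics(c(1, 1, 1, 0, 0), c(1, 1, 1, 0, 0))
  expect_equal(perfect$roc_auc, 1)
  expect_equal(perfect$acc, 1)
  expect_equal(perfect$mcc, 1)
  expect_equal(perfect$sn, 1)
  expect_equal(perfect$sp, 1)
  expect_equal(perfect$f1, 1)

  sym <- compute_metrics(c(0.9, 0.1, 0.9, 0.1), c(1, 1, 0, 0))
  expect_equal(sym$counts, list(TP = 1L, TN = 1L, FP = 1L, FN = 1L))
  expect_equal(sym$acc, 0.5)
  expect_equal(sym$sn, 0.5)
  expect_equal(sym$sp, 0.5)
  expect_equal(sym$mcc, 0)

  expect_error(compute_metrics(c(0.2, 0.8), c(1, 1)), "single class")
})

test_that("metrics match independent confusion and ROC oracles", {
  local_seed(6, {
    for (rep in 1:300) {
      n <- sample(6:40, 1)
      labels <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
      scores <- round(runif(n), 2) # rounding forces score ties
      got <- compute_metrics(scores, labels)
      cm <- oracle_confusion(scores, labels)
      expect_identical(got$counts, cm)
      expect_equal(got$acc, (cm$TP + cm$TN) / n)
      expect_equal(got$roc_auc, oracle_auc_sweep(scores, labels),
                   tolerance = 1e-10)
    }
  })
  # cross-check the rank AUC against pROC on a few draws
  skip_if_not_installed("pROC")
  local_seed(7, {
    for (rep in 1:10) {
      labels <- c(0, 1, sample(0:1, 28, replace = TRUE))
      scores <- runif(30)
      expect_equal(compute_metrics(scores, labels)$roc_auc,
                   as.numeric(pROC::auc(pROC::roc(
                     labels, scores, quiet = TRUE,
                     levels = c(0, 1), direction = "<"))),
                   tolerance = 1e-10)
    }
  })
})

test_that("binding prediction returns a deterministic probability", {
  model <- tiny_model(seed = 21)
  p1 <- predict_binding(model, "ACGUACGUACGU", "MKVWAGHTE")
  expect_s3_class(p1, "binding_prediction")
  expect_gte(p1$score, 0)
  expect_lte(p1$score, 1)
  expect_equal(p1$score, plogis(p1$logit))
  p2 <- predict_binding(model, "ACGUACGUACGU", "MKVWAGHTE")
  expect_identical(p1$score, p2$score)
  # DNA input is normalized before scoring
  p3 <- predict_binding(model, "ACGTACGTACGT", "MKVWAGHTE")
  expect_identical(p1$score, p3$score)
  # interaction map exposure
  p4 <- predict_binding(model, "ACGUACGUACGU", "MKVWAGHTE",
                        return_im = TRUE)
  expect_s3_class(p4$im, "interaction_map")
  expect_equal(nrow(p4$im$values), 10) # 12 nt -> 10 3-mers
})

test_that("training requires both classes and supports zero epochs", {
  pairs <- random_pairs(8, seed = 31)
  pos_only <- Filter(function(p) p$label == 1, pairs)
  expect_error(train_api_model(pos_only, epochs = 1), "single class")

  fx <- tiny_model(seed = 5)
  fit0 <- train_api_model(pairs, prot_vocab = fx$prot_vocab,
                          apta_cfg = fx$apta_cfg, prot_cfg = fx$prot_cfg,
                          conv_cfg = fx$conv_cfg, epochs = 0, seed = 5)
  expect_s3_class(fit0, "api_fit")
  expect_equal(nrow(fit0$trace), 0)
  # zero-epoch weights equal a fresh initialization with the same seed
  ref <- build_api_model(fit0$model$apta_vocab, fit0$model$prot_vocab,
                         fx$apta_cfg, fx$prot_cfg, fx$conv_cfg,
                         seed = derive_seed(5L, "init"))
  expect_identical(fit0$model$params$head, ref$params$head)
})

test_that("a few optimization steps decrease the training loss", {
  ds <- make_api_dataset(8, 8, apta_length = c(10, 14),
                         prot_length = c(12, 18), seed = 41)
  fx <- tiny_model(seed = 6)
  fit <- train_api_model(ds$train, prot_vocab = fx$prot_vocab,
                         apta_cfg = fx$apta_cfg, prot_cfg = fx$prot_cfg,
                         conv_cfg = fx$conv_cfg, epochs = 4,
                         batch_size = 8, lr = 1e-3, seed = 6)
  expect_equal(nrow(fit$trace), 4)
  expect_true(all(is.finite(fit$trace$loss)))
  expect_lt(fit$trace$loss[4], fit$trace$loss[1])
})

test_that("pretrained encoder weights are reproduced bit-exactly at epoch 0", {
  corpus <- make_structure_corpus(6, length_range = c(12, 20), seed = 8)
  seqs <- lapply(corpus, `[[`, "seq")
  v <- mine_fcs_vocab(seqs)
  ecfg <- encoder_config(vocab_size(v), embed_dim = 16, n_heads = 2,
                         n_layers = 1, ff_dim = 24, dropout = 0,
                         max_len = 64)
  pre <- pretrain_encoder(seqs, lapply(corpus, `[[`, "ann"), v, ecfg,
                          cfg = pretrain_config(epochs = 1, seed = 3))
  pairs <- random_pairs(6, seed = 51)
  acfg <- encoder_config(vocab_size(kmer_vocab(3)), embed_dim = 16,
                         n_heads = 2, n_layers = 1, ff_dim = 24,
                         dropout = 0, max_len = 32)
  ccfg <- conv_config(stage_channels = 4L, blocks_per_stage = 3L,
                      map_rows = 8L, map_cols = 10L, head_hidden = 4L)
  fit <- train_api_model(pairs, prot_vocab = v, apta_cfg = acfg,
                         prot_cfg = ecfg, conv_cfg = ccfg, epochs = 0,
                         seed = 9, prot_pretrained = pre)
  expect_identical(fit$model$params$prot$emb, pre$params$emb)
  expect_identical(fit$model$params$prot$layers, pre$params$layers)
  # mismatched vocabulary is rejected
  v2 <- mine_fcs_vocab(rand_protein_seqs(5))
  expect_error(train_api_model(pairs, prot_vocab = v2, apta_cfg = acfg,
                               prot_cfg = encoder_config(
                                 vocab_size(v2), embed_dim = 16,
                                 n_heads = 2, n_layers = 1, ff_dim = 24,
                                 dropout = 0, max_len = 64),
                               conv_cfg = ccfg, epochs = 0, seed = 9,
                               prot_pretrained = pre),
               "different vocabulary")
})

test_that("checkpoints reload bit-exactly with a JSON sidecar", {
  model <- tiny_model(seed = 61)
  f <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(model, f)
  back <- load_checkpoint(f)
  expect_identical(back$params, model$params)
  expect_true(file.exists(paste0(f, ".json")))
  meta <- jsonlite::read_json(paste0(f, ".json"))
  expect_equal(meta$conv_cfg$map_rows, model$conv_cfg$map_rows)
})

test_that("evaluate_pairs wires predictions into the metrics report", {
  model <- tiny_model(seed = 71)
  pairs <- random_pairs(10, seed = 72)
  rep <- evaluate_pairs(model, pairs)
  scores <- predict_pairs(model, pairs)
  labels <- vapply(pairs, function(p) p$label, integer(1))
  expect_equal(rep$roc_auc, compute_metrics(scores, labels)$roc_auc)
  expect_equal(rep$counts$TP + rep$counts$TN + rep$counts$FP + rep$counts$FN,
               length(pairs))
})
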