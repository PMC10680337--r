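# Deterministic desk-scale generators: structure-annotated pretraining
# corpora with realistic marginal state frequencies, and labelled
# aptamer-protein pair datasets with a planted, recoverable binding rule.

sample_range <- function(r) r[1] + sample.int(r[2] - r[1] + 1L, 1) - 1L

#' Reference marginal frequencies of protein secondary-structure states
#'
#' Marginal proportions of the 8 DSSP-style states typical of a large
#' protein structure corpus (alpha-helix H 32.74%, beta-sheet E 21.11%,
#' turn T 11.06%, beta-bridge B 1.22%, 3-10 helix G 3.63%, bend S 9.15%,
#' coil C 20.45%, pi-helix I 0.64%).
#' @return named numeric vector summing to 1.
#' @export
protein_ss_proportions <- function() {
  c(H = 0.3274, E = 0.2111, T = 0.1106, B = 0.0122,
    G = 0.0363, S = 0.0915, C = 0.2045, I = 0.0064)
}

#' Reference marginal frequencies of RNA secondary-structure types
#'
#' Marginal proportions of bpRNA-style structure types typical of a large
#' RNA structure corpus (stem S 48.50%, hairpin loop H 22.51%, multiloop M
#' 4.86%, internal loop I 7.51%, bulge B 1.95%, external loop X 11.34%,
#' pseudoknot K 3.33%).
#' @return named numeric vector summing to 1.
#' @export
rna_ss_proportions <- function() {
  c(S = 0.4850, H = 0.2251, M = 0.0486, I = 0.0751,
    B = 0.0195, X = 0.1134, K = 0.0333)
}

#' Generate a structure-annotated pretraining corpus
#'
#' Residues are uniform over the alphabet; structure states are emitted in
#' runs (run state drawn from `state_proportions`, run length geometric
#' with the given mean) so that the empirical marginal state frequencies
#' approximate the requested proportions while keeping the run structure
#' of real annotations.
#'
#' @param n number of sequences.
#' @param length_range inclusive residue-length range.
#' @param alphabet `"PROTEIN"` or `"RNA"`.
#' @param state_proportions named marginal state frequencies (must sum to 1
#'   within 1e-6); defaults to [protein_ss_proportions()] or
#'   [rna_ss_proportions()].
#' @param mean_run_length mean structure run length in residues.
#' @param seed integer seed (same seed, same corpus).
#' @return list of `list(seq = bio_seq, ann = structure_annotation)`.
#' @export
make_structure_corpus <- function(n, length_range = c(60L, 120L),
                                  alphabet = c("PROTEIN", "RNA"),
                                  state_proportions = NULL,
                                  mean_run_length = 5, seed = 1L) {
  alphabet <- match.arg(alphabet)
  letters_seq <- if (alphabet == "PROTEIN") PROTEIN_LETTERS else RNA_LETTERS
  props <- state_proportions %||%
    if (alphabet == "PROTEIN") protein_ss_proportions() else
      rna_ss_proportions()
  if (abs(sum(props) - 1) > 1e-6) {
    stop("state proportions must sum to 1", call. = FALSE)
  }
  ss_alpha <- if (alphabet == "PROTEIN") "PROTEIN_SS" else "RNA_SS"
  ok_states <- if (alphabet == "PROTEIN") PROTEIN_SS_LETTERS else
    RNA_SS_LETTERS
  if (!all(names(props) %in% ok_states)) {
    stop("unknown state letters in proportions", call. = FALSE)
  }
  local_seed(derive_seed(seed, "structure-corpus"), {
    lapply(seq_len(n), function(i) {
      len <- sample_range(length_range)
      res <- paste(sample(letters_seq, len, replace = TRUE), collapse = "")
      states <- character(0)
      while (length(states) < len) {
        st <- sample(names(props), 1, prob = props)
        run <- 1L + stats::rgeom(1, 1 / mean_run_length)
        states <- c(states, rep(st, run))
      }
      list(seq = bio_seq(res, id = sprintf("seq%04d", i),
                         alphabet = alphabet),
           ann = structure_annotation(
             paste(states[seq_len(len)], collapse = ""), ss_alpha))
    })
  })
}

#' Planted binding rule for synthetic API data
#'
#' A pair is a true binder exactly when the protein contains
#' `protein_key_motif` and the aptamer contains `aptamer_response_motif`;
#' labels are flipped with probability `noise_rate`.
#'
#' @param protein_key_motif short amino-acid motif.
#' @param aptamer_response_motif short RNA motif.
#' @param noise_rate label-flip fraction in `[0, 0.5)`.
#' @return an object of class `planted_rule`.
#' @export
planted_rule <- function(protein_key_motif = "KWHE",
                         aptamer_response_motif = "GCAGC",
                         noise_rate = 0) {
  if (nchar(protein_key_motif) == 0 || nchar(aptamer_response_motif) == 0) {
    stop("motifs must be non-empty", call. = FALSE)
  }
  if (noise_rate < 0 || noise_rate >= 0.5) {
    stop("noise_rate must be in [0, 0.5)", call. = FALSE)
  }
  check_alphabet(protein_key_motif, PROTEIN_LETTERS, "PROTEIN")
  check_alphabet(aptamer_response_motif, RNA_LETTERS, "RNA")
  structure(list(protein_key_motif = protein_key_motif,
                 aptamer_response_motif = aptamer_response_motif,
                 noise_rate = noise_rate),
            class = "planted_rule")
}

random_seq_with_motif <- function(letters_pool, len, motif, present,
                                  max_tries = 100L) {
  m <- nchar(motif)
  for (try in seq_len(max_tries)) {
    res <- paste(sample(letters_pool, len, replace = TRUE), collapse = "")
    if (present) {
      off <- sample.int(len - m + 1L, 1)
      res <- paste0(substr(res, 1, off - 1), motif,
                    substr(res, off + m, len))
      return(res)
    }
    if (!grepl(motif, res, fixed = TRUE)) return(res)
  }
  stop("could not generate a motif-free sequence", call. = FALSE)
}

#' Generate a labelled API pair dataset with a planted rule
#'
#' Positives carry both motifs; negatives carry exactly one (protein-only
#' or aptamer-only, in equal numbers) or neither, so a motif-matching
#' oracle classifier separates the noise-free data perfectly. The dataset
#' is split 80/20 into train/test, stratified by label, with a fixed
#' permutation derived from `seed`.
#'
#' @param n_pos,n_neg numbers of positive and negative pairs (the
#'   reference benchmark ratio is 1:3).
#' @param rule a [planted_rule()].
#' @param apta_length,prot_length inclusive length ranges.
#' @param train_frac training fraction of the stratified split.
#' @param seed integer seed (same seed, byte-identical dataset).
#' @return list with elements `train` and `test`, each a list of
#'   [api_pair()].
#' @export
make_api_dataset <- function(n_pos, n_neg, rule = planted_rule(),
                             apta_length = c(20L, 30L),
                             prot_length = c(30L, 50L),
                             train_frac = 0.8, seed = 1L) {
  stopifnot(n_pos >= 1, n_neg >= 1)
  if (nchar(rule$protein_key_motif) > prot_length[1] ||
      nchar(rule$aptamer_response_motif) > apta_length[1]) {
    stop("motif longer than the minimum sequence length", call. = FALSE)
  }
  local_seed(derive_seed(seed, "api-dataset"), {
    gen_pair <- function(i, apta_has, prot_has, label) {
      alen <- sample_range(apta_length)
      plen <- sample_range(prot_length)
      apt <- random_seq_with_motif(RNA_LETTERS, alen,
                                   rule$aptamer_response_motif, apta_has)
      prt <- random_seq_with_motif(PROTEIN_LETTERS, plen,
                                   rule$protein_key_motif, prot_has)
      api_pair(bio_seq(apt, id = sprintf("apt%04d", i), alphabet = "RNA"),
               bio_seq(prt, id = sprintf("prot%04d", i),
                       alphabet = "PROTEIN"),
               label)
    }
    pairs <- vector("list", n_pos + n_neg)
    for (i in seq_len(n_pos)) pairs[[i]] <- gen_pair(i, TRUE, TRUE, 1L)
    # negatives: equal thirds protein-only / aptamer-only / neither
    neg_kind <- rep_len(1:3, n_neg)
    for (j in seq_len(n_neg)) {
      i <- n_pos + j
      pairs[[i]] <- switch(neg_kind[j],
                           gen_pair(i, FALSE, TRUE, 0L),
                           gen_pair(i, TRUE, FALSE, 0L),
                           gen_pair(i, FALSE, FALSE, 0L))
    }
    if (rule$noise_rate > 0) {
      flip <- runif(length(pairs)) < rule$noise_rate
      for (i in which(flip)) pairs[[i]]$label <- 1L - pairs[[i]]$label
    }
    labels <- vapply(pairs, function(p) p$label, integer(1))
    train_idx <- integer(0)
    for (lab in c(1L, 0L)) {
      idx <- which(labels == lab)
      idx <- idx[sample.int(length(idx))]
      train_idx <- c(train_idx, idx[seq_len(round(train_frac * length(idx)))])
    }
    test_idx <- setdiff(seq_along(pairs), train_idx)
    list(train = pairs[train_idx[sample.int(length(train_idx))]],
         test = pairs[test_idx[sample.int(length(test_idx))]])
  })
}
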