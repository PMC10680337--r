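# Tokenization: k-mer windows for RNA, mined FCS subword vocabulary with
# greedy longest-match tokenization for proteins, and span-aligned
# co-tokenization of secondary-structure strings.

#' Token vocabulary
#'
#' An ordered token inventory with contiguous integer ids starting at 0.
#' The first three ids are reserved for the specials `[PAD]`, `[MASK]`,
#' `[UNK]`; content tokens follow.
#'
#' @param content character vector of content tokens (no duplicates).
#' @param max_token_len maximum content-token length used by the greedy
#'   tokenizer (defaults to the longest content token).
#' @return an object of class `apta_vocab` with fields `tokens` (all tokens,
#'   specials first), `index` (hashed token -> id environment), `specials`
#'   (named ids for `pad`, `mask`, `unk`) and `max_token_len`.
#' @export
new_vocab <- function(content, max_token_len = NULL) {
  stopifnot(is.character(content))
  if (anyDuplicated(content) > 0) {
    stop("vocabulary contains duplicate tokens", call. = FALSE)
  }
  specials <- c("[PAD]", "[MASK]", "[UNK]")
  if (any(content %in% specials)) {
    stop("content tokens may not collide with specials", call. = FALSE)
  }
  tokens <- c(specials, content)
  index <- new.env(parent = emptyenv())
  for (i in seq_along(tokens)) assign(tokens[i], i - 1L, envir = index)
  structure(list(
    tokens = tokens,
    index = index,
    specials = c(pad = 0L, mask = 1L, unk = 2L),
    max_token_len = as.integer(max_token_len %||%
                                 max(nchar(content), 1L))),
    class = "apta_vocab")
}

#' @export
print.apta_vocab <- function(x, ...) {
  cat(sprintf("<apta_vocab> %d tokens (3 specials), max token length %d\n",
              length(x$tokens), x$max_token_len))
  invisible(x)
}

#' Vocabulary size (specials included)
#' @param vocab an `apta_vocab`.
#' @export
vocab_size <- function(vocab) length(vocab$tokens)

token_id <- function(vocab, token) {
  get0(token, envir = vocab$index, ifnotfound = NA_integer_)
}

#' Token strings for a vector of ids
#' @param vocab an `apta_vocab`.
#' @param ids 0-based integer ids.
#' @export
id_to_token <- function(vocab, ids) vocab$tokens[ids + 1L]

#' Write a vocabulary to a plain-text file (one token per line)
#'
#' Line number minus one is the token id; the first three lines are the
#' specials `[PAD]`, `[MASK]`, `[UNK]`.
#'
#' @param vocab an `apta_vocab`.
#' @param path output file.
#' @export
write_vocab <- function(vocab, path) {
  writeLines(vocab$tokens, path)
  invisible(path)
}

#' Read a vocabulary written by [write_vocab()]
#' @param path vocabulary file.
#' @export
read_vocab <- function(path) {
  tokens <- readLines(path)
  if (length(tokens) < 3 ||
      !identical(tokens[1:3], c("[PAD]", "[MASK]", "[UNK]"))) {
    stop("vocabulary file must start with [PAD], [MASK], [UNK]",
         call. = FALSE)
  }
  new_vocab(tokens[-(1:3)])
}

#' Complete k-mer vocabulary over the RNA alphabet
#'
#' All `4^k` nucleotide k-mers in lexicographic order (A < C < G < U),
#' preceded by the specials.
#'
#' @param k word length (default 3).
#' @export
kmer_vocab <- function(k = 3L) {
  k <- as.integer(k)
  stopifnot(k >= 1)
  grid <- do.call(expand.grid,
                  c(rep(list(RNA_LETTERS), k),
                    list(KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)))
  # expand.grid varies the first factor fastest; reverse for lexicographic
  toks <- sort(apply(grid, 1, paste, collapse = ""))
  new_vocab(toks, max_token_len = k)
}

new_tok_seq <- function(token_ids, tokens, spans, source_length, mode, k = NA) {
  structure(list(token_ids = as.integer(token_ids),
                 tokens = tokens,
                 spans = spans,
                 source_length = as.integer(source_length),
                 mode = mode, k = k),
            class = "tok_seq")
}

#' @export
print.tok_seq <- function(x, ...) {
  cat(sprintf("<tok_seq %s> %d tokens over %d residues: %s%s\n",
              x$mode, length(x$token_ids), x$source_length,
              paste(utils::head(x$tokens, 8), collapse = " "),
              if (length(x$tokens) > 8) " ..." else ""))
  invisible(x)
}

#' Sliding-window k-mer tokenization
#'
#' Divides a sequence into all its length-`k` windows at stride 1, left to
#' right, so a sequence of length `L` yields `L - k + 1` tokens whose spans
#' overlap by `k - 1` residues.
#'
#' @param seq an RNA [bio_seq()] (or string).
#' @param k word length (default 3).
#' @param vocab vocabulary used to assign ids; defaults to the complete
#'   [kmer_vocab()] of order `k`.
#' @return a `tok_seq` with 0-based half-open residue `spans`.
#' @examples
#' kmer_tokenize(bio_seq("GGCGGAGAA", alphabet = "RNA"))$tokens
#' @export
kmer_tokenize <- function(seq, k = 3L, vocab = NULL) {
  seq <- as_bio_seq(seq, "RNA")
  k <- as.integer(k)
  n <- nchar(seq$residues)
  if (n < k) {
    stop(sprintf("sequence length %d is shorter than k = %d", n, k),
         call. = FALSE)
  }
  vocab <- vocab %||% kmer_vocab(k)
  starts <- seq_len(n - k + 1L)
  tokens <- substring(seq$residues, starts, starts + k - 1L)
  ids <- vapply(tokens, function(t) {
    id <- token_id(vocab, t)
    if (is.na(id)) vocab$specials[["unk"]] else id
  }, integer(1), USE.NAMES = FALSE)
  spans <- cbind(start = starts - 1L, end = starts - 1L + k)
  new_tok_seq(ids, tokens, spans, n, mode = "kmer", k = k)
}

#' Mine a frequent-consecutive-subsequence (FCS) vocabulary
#'
#' Counts every substring of length 1..`max_len` over a protein corpus,
#' pools the counts across lengths, and drops candidates whose count is
#' strictly below the mean count. All 20 single amino-acid letters are
#' always retained (even when below average, or unobserved) so that every
#' protein sequence stays tokenizable. Content tokens are ordered by
#' decreasing count, ties broken lexicographically.
#'
#' @param corpus list of protein [bio_seq()] (or character vector).
#' @param max_len maximum substring length (default 3).
#' @return an `apta_vocab`.
#' @examples
#' v <- mine_fcs_vocab(list(bio_seq("AAA", alphabet = "PROTEIN")))
#' setdiff(v$tokens[-(1:3)], PROTEIN_LETTERS) # "AA"
#' @export
mine_fcs_vocab <- function(corpus, max_len = 3L) {
  if (is.character(corpus)) {
    corpus <- lapply(corpus, bio_seq, alphabet = "PROTEIN")
  }
  if (length(corpus) == 0) stop("empty corpus", call. = FALSE)
  max_len <- as.integer(max_len)
  subs <- unlist(lapply(corpus, function(s) {
    res <- if (inherits(s, "bio_seq")) s$residues else s
    n <- nchar(res)
    unlist(lapply(seq_len(max_len), function(L) {
      if (n < L) return(character(0))
      starts <- seq_len(n - L + 1L)
      substring(res, starts, starts + L - 1L)
    }))
  }))
  counts <- table(subs)
  keep <- names(counts)[as.numeric(counts) >= mean(as.numeric(counts))]
  keep <- union(keep, PROTEIN_LETTERS)
  cnt <- as.numeric(counts[keep])
  cnt[is.na(cnt)] <- 0
  ord <- order(-cnt, keep)
  new_vocab(keep[ord], max_token_len = max_len)
}

#' Hierarchical (greedy longest-match) FCS tokenization
#'
#' Tokenizes a protein sequence against a mined vocabulary by taking, at
#' each position, the longest matching vocabulary token of length at most
#' `max_token_len`. The resulting spans are a disjoint, ordered, exact cover
#' of the sequence, so the token strings concatenate back to the input.
#'
#' @param seq a protein [bio_seq()] (or string).
#' @param vocab an `apta_vocab` covering all 20 single letters.
#' @return a `tok_seq` with 0-based half-open `spans`.
#' @export
fcs_tokenize <- function(seq, vocab) {
  seq <- as_bio_seq(seq, "PROTEIN")
  res <- seq$residues
  n <- nchar(res)
  ids <- integer(0)
  tokens <- character(0)
  starts <- integer(0)
  ends <- integer(0)
  pos <- 1L
  while (pos <= n) {
    hit_len <- 0L
    hit_id <- NA_integer_
    for (len in seq(min(vocab$max_token_len, n - pos + 1L), 1L)) {
      tok <- substr(res, pos, pos + len - 1L)
      id <- token_id(vocab, tok)
      if (!is.na(id)) {
        hit_len <- len
        hit_id <- id
        break
      }
    }
    if (hit_len == 0L) {
      stop(sprintf("residue '%s' at position %d is absent from the vocabulary",
                   substr(res, pos, pos), pos), call. = FALSE)
    }
    ids <- c(ids, hit_id)
    tokens <- c(tokens, substr(res, pos, pos + hit_len - 1L))
    starts <- c(starts, pos - 1L)
    ends <- c(ends, pos - 1L + hit_len)
    pos <- pos + hit_len
  }
  new_tok_seq(ids, tokens, cbind(start = starts, end = ends), n, mode = "fcs")
}

#' Co-tokenize a structure string along a tokenized sequence
#'
#' Cuts a per-residue structure-state string into tokens whose lengths match
#' the residue spans of an already-tokenized sequence: overlapping windows in
#' k-mer mode, an exact cover in FCS mode. Structure token i therefore has
#' the same length as sequence token i.
#'
#' @param ts a `tok_seq`.
#' @param ann a [structure_annotation()] of the same underlying length.
#' @return character vector of structure tokens, one per sequence token.
#' @export
cotokenize_structure <- function(ts, ann) {
  states <- if (inherits(ann, "structure_annotation")) ann$states else ann
  if (nchar(states) != ts$source_length) {
    stop(sprintf("structure length %d != sequence length %d",
                 nchar(states), ts$source_length), call. = FALSE)
  }
  substring(states, ts$spans[, "start"] + 1L, ts$spans[, "end"])
}

#' Build a structure-token vocabulary
#'
#' One id per distinct structure token observed in a corpus of
#' co-tokenized structure-token lists; unseen tokens map to `[UNK]` at
#' prediction time.
#'
#' @param token_lists list of character vectors (output of
#'   [cotokenize_structure()]).
#' @return an `apta_vocab`.
#' @export
build_structure_vocab <- function(token_lists) {
  if (length(token_lists) == 0) stop("empty structure corpus", call. = FALSE)
  toks <- sort(unique(unlist(token_lists)))
  new_vocab(toks)
}
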