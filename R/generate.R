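# Monte Carlo tree search over nucleotide space: grows a candidate aptamer
# left to right, committing one position at a time after a batch of UCB1
# simulations with uniform random rollouts, using the API predictor (or any
# scorer mapping a pair to [0, 1]) as the reward.

#' MCTS configuration for candidate-aptamer generation
#'
#' @param target_length length of the generated aptamers (nt).
#' @param iterations MCTS simulations per committed position.
#' @param c_explore UCB1 exploration constant (default `sqrt(2)`; 0 gives
#'   the purely greedy exploitation limit).
#' @param top_k number of candidates to return.
#' @param seed integer seed (rollouts and tie-free determinism).
#' @return an object of class `mcts_config`.
#' @export
mcts_config <- function(target_length, iterations = 200L,
                        c_explore = sqrt(2), top_k = 10L, seed = 1L) {
  target_length <- as.integer(target_length)
  top_k <- as.integer(top_k)
  if (target_length < 1) stop("target_length must be >= 1", call. = FALSE)
  if (top_k < 1) stop("top_k must be >= 1", call. = FALSE)
  if (c_explore < 0) stop("c_explore must be >= 0", call. = FALSE)
  structure(list(target_length = target_length,
                 iterations = as.integer(iterations),
                 c_explore = c_explore, top_k = top_k,
                 seed = as.integer(seed)),
            class = "mcts_config")
}

new_mcts_node <- function() {
  node <- new.env(parent = emptyenv())
  node$N <- integer(4)     # visit counts per child A, C, G, U
  node$W <- numeric(4)     # summed rewards per child
  node$kids <- vector("list", 4)
  node
}

#' Generate candidate aptamers for a target protein
#'
#' Builds the sequence left to right. At each position it runs
#' `cfg$iterations` MCTS simulations from the current prefix -- UCB1
#' selection over the children `A`, `C`, `G`, `U` (unvisited children are
#' expanded first, in lexicographic order), uniform random rollout to
#' `target_length`, reward equal to the scorer output, mean-value
#' backpropagation -- then commits the child with the highest mean reward.
#' Every complete sequence ever scored enters a deduplicated pool; the
#' `top_k` pool members are returned sorted by score (descending), ties
#' broken lexicographically.
#'
#' @param protein target protein ([bio_seq()] or string).
#' @param scorer function `(aptamer bio_seq, protein bio_seq) -> [0, 1]`,
#'   e.g. [score_with_model()]; values outside `[0, 1]` raise a contract
#'   error.
#' @param cfg an [mcts_config()].
#' @return list of `candidate_aptamer` objects (fields `sequence`, `score`)
#'   with attribute `best_trace`, the running best score after each
#'   committed position.
#' @export
generate_candidates <- function(protein, scorer, cfg) {
  protein <- as_bio_seq(protein, "PROTEIN")
  stopifnot(inherits(cfg, "mcts_config"), is.function(scorer))
  L <- cfg$target_length
  pool <- new.env(parent = emptyenv())
  score_seq <- function(seq_str) {
    cached <- get0(seq_str, envir = pool, ifnotfound = NULL)
    if (!is.null(cached)) return(cached)
    s <- scorer(bio_seq(seq_str, alphabet = "RNA"), protein)
    if (!is.numeric(s) || length(s) != 1 || is.na(s) || s < 0 || s > 1) {
      stop("scorer contract violated: expected a single value in [0, 1]",
           call. = FALSE)
    }
    assign(seq_str, s, envir = pool)
    s
  }
  local_seed(derive_seed(cfg$seed, "mcts"), {
    prefix <- ""
    best_trace <- numeric(L)
    for (pos in seq_len(L)) {
      root <- new_mcts_node()
      for (it in seq_len(cfg$iterations)) {
        mcts_simulate(root, prefix, L, cfg$c_explore, score_seq)
      }
      visited <- which(root$N > 0)
      means <- root$W[visited] / root$N[visited]
      # ties broken lexicographically: RNA_LETTERS is in A < C < G < U order
      commit <- visited[which.max(means)]
      prefix <- paste0(prefix, RNA_LETTERS[commit])
      best_trace[pos] <- max(vapply(ls(pool), function(k) get(k, pool),
                                    numeric(1)))
    }
    score_seq(prefix)
    keys <- ls(pool)
    scores <- vapply(keys, function(k) get(k, envir = pool), numeric(1))
    ord <- order(-scores, keys)
    take <- utils::head(ord, cfg$top_k)
    out <- lapply(take, function(i) {
      structure(list(sequence = bio_seq(keys[i], alphabet = "RNA"),
                     score = unname(scores[i])),
                class = "candidate_aptamer")
    })
    attr(out, "best_trace") <- best_trace
    out
  })
}

# one simulation: selection down the tree, expansion, rollout, backup
mcts_simulate <- function(node, prefix, L, c_explore, score_seq) {
  path_nodes <- list()
  path_children <- integer(0)
  depth_prefix <- prefix
  repeat {
    if (nchar(depth_prefix) == L) break
    unvisited <- which(node$N == 0L)
    if (length(unvisited) > 0) {
      # expansion: first unvisited child in lexicographic order
      child <- unvisited[1]
      path_nodes <- c(path_nodes, node)
      path_children <- c(path_children, child)
      depth_prefix <- paste0(depth_prefix, RNA_LETTERS[child])
      # rollout: uniform random completion
      rem <- L - nchar(depth_prefix)
      rollout <- if (rem > 0) {
        paste(sample(RNA_LETTERS, rem, replace = TRUE), collapse = "")
      } else ""
      reward <- score_seq(paste0(depth_prefix, rollout))
      backup(path_nodes, path_children, reward)
      return(invisible(reward))
    }
    total <- sum(node$N)
    ucb <- node$W / node$N + c_explore * sqrt(log(total) / node$N)
    child <- which.max(ucb)  # ties -> lexicographically first
    path_nodes <- c(path_nodes, node)
    path_children <- c(path_children, child)
    depth_prefix <- paste0(depth_prefix, RNA_LETTERS[child])
    if (is.null(node$kids[[child]])) node$kids[[child]] <- new_mcts_node()
    node <- node$kids[[child]]
  }
  # reached a complete sequence through the tree
  reward <- score_seq(depth_prefix)
  backup(path_nodes, path_children, reward)
  invisible(reward)
}

backup <- function(path_nodes, path_children, reward) {
  for (i in seq_along(path_nodes)) {
    nd <- path_nodes[[i]]
    ch <- path_children[i]
    nd$N[ch] <- nd$N[ch] + 1L
    nd$W[ch] <- nd$W[ch] + reward
  }
}

#' @export
print.candidate_aptamer <- function(x, ...) {
  cat(sprintf("<candidate_aptamer> %s score %.4f\n",
              x$sequence$residues, x$score))
  invisible(x)
}

#' Wrap a trained model as an MCTS scoring function
#'
#' Adapter exposing [predict_binding()] as the MCTS reward:
#' `scorer(a, p) == predict_binding(model, a, p)$score`.
#'
#' @param model an `api_model` or `api_fit`.
#' @return function `(aptamer, protein) -> score in [0, 1]`.
#' @export
score_with_model <- function(model) {
  if (inherits(model, "api_fit")) model <- model$model
  function(aptamer, protein) predict_binding(model, aptamer, protein)$score
}
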