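# Internal helpers: alphabets, seeding, small tree utilities.

RNA_LETTERS <- c("A", "C", "G", "U")
PROTEIN_LETTERS <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                     "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
# 8-state DSSP-style protein secondary structure letters
PROTEIN_SS_LETTERS <- c("H", "E", "T", "B", "G", "S", "C", "I")
# bpRNA-style RNA structure-type letters:
# S stem, H hairpin loop, M multiloop, I internal loop, B bulge,
# X external loop, K pseudoknot
RNA_SS_LETTERS <- c("S", "H", "M", "I", "B", "X", "K")

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a stage-specific seed from a global seed
#'
#' Mixes a global integer seed with a stage label so that independent
#' stochastic stages (data generation, initialisation, epoch shuffling, ...)
#' consume independent streams while remaining reproducible from one seed.
#'
#' @param seed integer global seed.
#' @param label character stage label.
#' @return an integer seed in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.character(label))
  m <- 2147483647
  h <- 17
  for (ch in utf8ToInt(label)) h <- (h * 31 + ch) %% m
  s <- (h * 69069 + abs(as.numeric(seed)) + 1) %% (m - 1)
  as.integer(s + 1)
}

# Evaluate `code` under `set.seed(seed)`, restoring the caller's RNG state.
local_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# --- nested-list (parameter tree) utilities -------------------------------

tree_map <- function(f, a) {
  if (is.list(a)) lapply(a, function(x) tree_map(f, x)) else f(a)
}

tree_map2 <- function(f, a, b) {
  if (is.list(a)) {
    out <- vector("list", length(a))
    names(out) <- names(a)
    for (i in seq_along(a)) out[[i]] <- tree_map2(f, a[[i]], b[[i]])
    out
  } else {
    f(a, b)
  }
}

tree_zeros <- function(a) tree_map(function(x) x * 0, a)
tree_add <- function(a, b) tree_map2(`+`, a, b)
tree_scale <- function(a, s) tree_map(function(x) x * s, a)

# Deterministic content hash for vocabulary provenance in sidecar metadata.
string_hash <- function(x) {
  m <- 2147483647
  h <- 7
  for (s in x) {
    for (ch in utf8ToInt(s)) h <- (h * 131 + ch) %% m
    h <- (h * 131 + 10) %% m
  }
  sprintf("%08x", h)
}

log_msg <- function(...) {
  message(format(Sys.time(), "[%Y-%m-%d %H:%M:%S] "), sprintf(...))
}
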