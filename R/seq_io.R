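# Sequence containers and file I/O: FASTA, labelled pair TSV, structure TSV.

#' Validated biological sequence
#'
#' A residue string over a fixed alphabet: RNA (`A`, `C`, `G`, `U`) or
#' protein (the 20 standard amino-acid letters). Input is uppercased before
#' validation; ambiguity codes (`N`, `X`, ...) are rejected rather than
#' dropped because the tokenizers define no behaviour for them.
#'
#' @param residues character scalar, the sequence.
#' @param id free-text identifier.
#' @param alphabet `"RNA"` or `"PROTEIN"`.
#' @return an object of class `bio_seq` with fields `id`, `residues`,
#'   `alphabet`.
#' @examples
#' bio_seq("ACGU", id = "apt1", alphabet = "RNA")
#' @export
bio_seq <- function(residues, id = "", alphabet = c("RNA", "PROTEIN")) {
  alphabet <- match.arg(alphabet)
  stopifnot(is.character(residues), length(residues) == 1)
  residues <- toupper(residues)
  if (nchar(residues) == 0) {
    stop("bio_seq: residues must be non-empty (id: '", id, "')", call. = FALSE)
  }
  letters_ok <- if (alphabet == "RNA") RNA_LETTERS else PROTEIN_LETTERS
  check_alphabet(residues, letters_ok, alphabet, id)
  structure(list(id = id, residues = residues, alphabet = alphabet),
            class = "bio_seq")
}

check_alphabet <- function(residues, letters_ok, alphabet, id = "") {
  chars <- strsplit(residues, "", fixed = TRUE)[[1]]
  bad <- which(!(chars %in% letters_ok))
  if (length(bad) > 0) {
    stop(sprintf(
      "invalid %s alphabet: character '%s' at position %d%s",
      alphabet, chars[bad[1]], bad[1],
      if (nzchar(id)) paste0(" (id: '", id, "')") else ""), call. = FALSE)
  }
  invisible(TRUE)
}

#' @export
print.bio_seq <- function(x, ...) {
  res <- x$residues
  if (nchar(res) > 60) res <- paste0(substr(res, 1, 57), "...")
  cat(sprintf("<bio_seq %s> %s [%d nt/aa] %s\n",
              x$alphabet, if (nzchar(x$id)) x$id else "<unnamed>",
              nchar(x$residues), res))
  invisible(x)
}

as_bio_seq <- function(x, alphabet, id = "") {
  if (inherits(x, "bio_seq")) {
    if (x$alphabet != alphabet) {
      stop("expected a ", alphabet, " sequence, got ", x$alphabet,
           call. = FALSE)
    }
    return(x)
  }
  bio_seq(x, id = id, alphabet = alphabet)
}

#' Normalize a DNA/RNA string to RNA
#'
#' Uppercases, substitutes thymine (T) with uracil (U) and validates the
#' result, so DNA aptamer sequences and already-normalized RNA sequences are
#' both accepted. Idempotent.
#'
#' @param x character scalar or `bio_seq`; may contain `A`, `C`, `G`, `T`,
#'   `U` in any case.
#' @param id identifier for the returned sequence (taken from `x` when `x`
#'   is a `bio_seq`).
#' @return a `bio_seq` with `alphabet = "RNA"`.
#' @examples
#' dna_to_rna("ACGT")$residues # "ACGU"
#' @export
dna_to_rna <- function(x, id = "") {
  if (inherits(x, "bio_seq")) {
    id <- x$id
    x <- x$residues
  }
  stopifnot(is.character(x), length(x) == 1)
  up <- toupper(x)
  check_alphabet(up, c("A", "C", "G", "T", "U"), "RNA", id)
  bio_seq(gsub("T", "U", up, fixed = TRUE), id = id, alphabet = "RNA")
}

#' Read sequences from a FASTA file
#'
#' The description line up to the first whitespace becomes the id; sequence
#' lines are concatenated. RNA records are passed through [dna_to_rna()] so
#' DNA input is normalized on the way in.
#'
#' @param path FASTA file.
#' @param alphabet `"RNA"` or `"PROTEIN"`.
#' @return list of [bio_seq()] objects (empty list for an empty file).
#' @export
read_fasta <- function(path, alphabet = c("RNA", "PROTEIN")) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (file.size(path) == 0) return(list())
  set <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  out <- vector("list", length(set))
  for (i in seq_along(set)) {
    res <- as.character(set[[i]])
    if (nchar(res) == 0) {
      stop("FASTA record '", ids[i], "' has an empty sequence", call. = FALSE)
    }
    out[[i]] <- if (alphabet == "RNA") {
      dna_to_rna(res, id = ids[i])
    } else {
      bio_seq(res, id = ids[i], alphabet = "PROTEIN")
    }
  }
  out
}

#' Write sequences to a FASTA file
#'
#' @param seqs list of [bio_seq()]; an optional `desc` attribute on an
#'   element is appended to its header line.
#' @param path output file.
#' @export
write_fasta <- function(seqs, path) {
  if (inherits(seqs, "bio_seq")) seqs <- list(seqs)
  res <- vapply(seqs, function(s) s$residues, character(1))
  nms <- vapply(seqs, function(s) {
    d <- attr(s, "desc")
    if (is.null(d)) s$id else paste(s$id, d)
  }, character(1))
  set <- Biostrings::BStringSet(res)
  names(set) <- nms
  Biostrings::writeXStringSet(set, filepath = path)
  invisible(path)
}

#' Labelled aptamer-protein pair
#'
#' @param aptamer RNA [bio_seq()] (or string, normalized via [dna_to_rna()]).
#' @param protein protein [bio_seq()] (or string).
#' @param label binary interaction label, 1 = binding, 0 = non-binding.
#' @return an object of class `api_pair`.
#' @export
api_pair <- function(aptamer, protein, label) {
  if (!inherits(aptamer, "bio_seq")) aptamer <- dna_to_rna(aptamer)
  protein <- as_bio_seq(protein, "PROTEIN")
  if (aptamer$alphabet != "RNA") stop("aptamer must be RNA", call. = FALSE)
  label <- as.integer(label)
  if (length(label) != 1 || is.na(label) || !(label %in% c(0L, 1L))) {
    stop("label must be 0 or 1", call. = FALSE)
  }
  structure(list(aptamer = aptamer, protein = protein, label = label),
            class = "api_pair")
}

#' Read a labelled pair dataset (TSV)
#'
#' Expects a UTF-8 TSV with header columns `aptamer`, `protein`, `label`.
#' Aptamer sequences are normalized with [dna_to_rna()]; labels must be 0/1.
#'
#' @param path TSV file.
#' @return list of [api_pair()] objects.
#' @export
read_pairs <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          colClasses = "character", check.names = FALSE)
  need <- c("aptamer", "protein", "label")
  missing_cols <- setdiff(need, colnames(df))
  if (length(missing_cols) > 0) {
    stop("pair file schema error: missing column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  lapply(seq_len(nrow(df)), function(i) {
    lab <- df$label[i]
    if (!(lab %in% c("0", "1"))) {
      stop(sprintf("row %d: label '%s' is not binary (0/1)", i, lab),
           call. = FALSE)
    }
    api_pair(dna_to_rna(df$aptamer[i], id = sprintf("apt%04d", i)),
             bio_seq(df$protein[i], id = sprintf("prot%04d", i),
                     alphabet = "PROTEIN"),
             as.integer(lab))
  })
}

#' Write a labelled pair dataset (TSV)
#'
#' @param pairs list of [api_pair()].
#' @param path output file.
#' @export
write_pairs <- function(pairs, path) {
  df <- data.frame(
    aptamer = vapply(pairs, function(p) p$aptamer$residues, character(1)),
    protein = vapply(pairs, function(p) p$protein$residues, character(1)),
    label = vapply(pairs, function(p) p$label, integer(1)),
    stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     eol = "\n")
  invisible(path)
}

#' Per-residue secondary-structure annotation
#'
#' One structure state letter per residue: 8 DSSP-style states for proteins
#' (`H E T B G S C I`) or bpRNA-style structure types for RNA
#' (`S H M I B X K`).
#'
#' @param states character scalar of state letters.
#' @param alphabet `"PROTEIN_SS"` or `"RNA_SS"`.
#' @return an object of class `structure_annotation`.
#' @export
structure_annotation <- function(states, alphabet = c("PROTEIN_SS", "RNA_SS")) {
  alphabet <- match.arg(alphabet)
  stopifnot(is.character(states), length(states) == 1)
  states <- toupper(states)
  if (nchar(states) == 0) stop("states must be non-empty", call. = FALSE)
  ok <- if (alphabet == "PROTEIN_SS") PROTEIN_SS_LETTERS else RNA_SS_LETTERS
  check_alphabet(states, ok, alphabet)
  structure(list(states = states, alphabet = alphabet),
            class = "structure_annotation")
}

#' Read a structure-annotated corpus (TSV)
#'
#' Expects header columns `id`, `residues`, `states` with one record per
#' sequence; `states` must have the same length as `residues`.
#'
#' @param path TSV file.
#' @param alphabet sequence alphabet, `"PROTEIN"` or `"RNA"`.
#' @return list of `list(seq = bio_seq, ann = structure_annotation)`.
#' @export
read_structure_corpus <- function(path, alphabet = c("PROTEIN", "RNA")) {
  alphabet <- match.arg(alphabet)
  ss_alpha <- if (alphabet == "PROTEIN") "PROTEIN_SS" else "RNA_SS"
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          colClasses = "character", check.names = FALSE)
  need <- c("id", "residues", "states")
  if (length(setdiff(need, colnames(df))) > 0) {
    stop("structure corpus schema error: need columns id, residues, states",
         call. = FALSE)
  }
  lapply(seq_len(nrow(df)), function(i) {
    seq <- if (alphabet == "RNA") {
      dna_to_rna(df$residues[i], id = df$id[i])
    } else {
      bio_seq(df$residues[i], id = df$id[i], alphabet = "PROTEIN")
    }
    ann <- structure_annotation(df$states[i], alphabet = ss_alpha)
    if (nchar(ann$states) != nchar(seq$residues)) {
      stop(sprintf("record '%s': states length %d != residues length %d",
                   df$id[i], nchar(ann$states), nchar(seq$residues)),
           call. = FALSE)
    }
    list(seq = seq, ann = ann)
  })
}

#' Write a structure-annotated corpus (TSV)
#'
#' @param corpus list of `list(seq, ann)` as returned by
#'   [make_structure_corpus()] or [read_structure_corpus()].
#' @param path output file.
#' @export
write_structure_corpus <- function(corpus, path) {
  df <- data.frame(
    id = vapply(corpus, function(r) r$seq$id, character(1)),
    residues = vapply(corpus, function(r) r$seq$residues, character(1)),
    states = vapply(corpus, function(r) r$ann$states, character(1)),
    stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     eol = "\n")
  invisible(path)
}
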