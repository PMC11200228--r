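# SMILES vocabulary and tokenizer.

.TOKEN_REGEX <- "\\[[^]]+\\]|%[0-9]{2}|Cl|Br|."

#' Split a SMILES string into lexical tokens
#'
#' Multi-character units -- bracket atoms (`[nH]`), two-letter halogens
#' (`Cl`, `Br`) and `%NN` ring closures -- are single tokens; everything else
#' is one character per token.
#'
#' @param smiles a single SMILES string.
#' @return character vector of tokens.
#' @export
smiles_tokens <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) == 1L, !is.na(smiles))
  if (!nzchar(smiles)) return(character(0))
  regmatches(smiles, gregexpr(.TOKEN_REGEX, smiles))[[1L]]
}

#' Build a SMILES vocabulary from a corpus
#'
#' Collects every lexical token occurring in the corpus and adds the three
#' special tokens: start (`^`), end (`$`) and pad. The ring-closure digits
#' `1`-`9` are always included: randomized writings of a molecule can need
#' closure digits its canonical form never uses, and they must stay
#' encodable. Token/index mapping is bijective; strings containing tokens
#' outside the vocabulary are an encoding error, never silently skipped.
#'
#' @param corpus character vector of SMILES strings.
#' @return object of class `"smiles_vocab"`.
#' @export
build_vocabulary <- function(corpus) {
  stopifnot(is.character(corpus), length(corpus) > 0L)
  toks <- sort(unique(c(as.character(1:9),
                        unlist(lapply(corpus, smiles_tokens)))))
  tokens <- c("<pad>", "^", "$", toks)
  structure(
    list(tokens = tokens,
         index = stats::setNames(seq_along(tokens), tokens),
         pad = 1L, start = 2L, end = 3L),
    class = "smiles_vocab"
  )
}

#' @export
print.smiles_vocab <- function(x, ...) {
  cat("SMILES vocabulary:", length(x$tokens), "tokens",
      "(incl. start/end/pad)\n")
  invisible(x)
}

#' Encode a SMILES string as token indices
#'
#' @param smiles a single SMILES string.
#' @param vocab a [build_vocabulary()] object.
#' @return integer vector of token indices, terminated by the end token.
#' @export
encode_smiles <- function(smiles, vocab) {
  toks <- smiles_tokens(smiles)
  idx <- vocab$index[toks]
  if (anyNA(idx)) {
    bad <- unique(toks[is.na(idx)])
    stop("unknown token(s) not in vocabulary: ",
         paste(sQuote(bad), collapse = ", "))
  }
  c(unname(idx), vocab$end)
}

#' Decode token indices back to a SMILES string
#'
#' Inverse of [encode_smiles()]: stops at the end token and drops padding.
#'
#' @param ids integer vector of token indices.
#' @param vocab a [build_vocabulary()] object.
#' @return a single SMILES string.
#' @export
decode_smiles <- function(ids, vocab) {
  stop_at <- which(ids == vocab$end)
  if (length(stop_at) > 0L) ids <- ids[seq_len(stop_at[1L] - 1L)]
  ids <- ids[ids != vocab$pad & ids != vocab$start]
  paste0(vocab$tokens[ids], collapse = "")
}
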