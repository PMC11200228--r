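# Public chemistry interface: canonical SMILES, randomized (augmented)
# SMILES, Bemis-Murcko scaffolds, Morgan fingerprints, Tanimoto similarity,
# and .smi/CSV corpus I/O.

# process-wide canonical-SMILES memo (OpenBabel calls are the slow step)
.can_cache <- new.env(parent = emptyenv())
# parsed-graph memo: replay-buffer molecules are re-randomized every epoch,
# so their graphs are parsed once and reused
.graph_cache <- new.env(parent = emptyenv())

.parse_cached <- function(smiles) {
  g <- .graph_cache[[smiles]]
  if (is.null(g)) {
    g <- smi_parse(smiles)
    # bounded: drop the memo rather than grow without limit
    if (length(.graph_cache) > 4096L) {
      rm(list = ls(.graph_cache), envir = .graph_cache)
    }
    .graph_cache[[smiles]] <- g
  }
  g
}

.ob_canonical <- function(smiles) {
  # batch call to OpenBabel; returns character vector aligned to input,
  # NA where OpenBabel could not produce a canonical SMILES
  n <- length(smiles)
  out <- rep(NA_character_, n)
  idx <- seq_len(n)
  inp <- paste0(smiles, "\t", idx, collapse = "\n")
  res <- tryCatch(
    ChemmineOB::convertFormat("SMILES", "CAN", inp),
    error = function(e) ""
  )
  if (!nzchar(res)) return(out)
  lines <- strsplit(res, "\n", fixed = TRUE)[[1L]]
  for (ln in lines) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
    if (length(parts) == 2L) {
      i <- suppressWarnings(as.integer(parts[2L]))
      if (!is.na(i) && i >= 1L && i <= n && nzchar(parts[1L])) {
        out[i] <- parts[1L]
      }
    }
  }
  out
}

#' Canonicalize SMILES strings
#'
#' Validates each string with the package's strict SMILES parser (syntax,
#' ring/branch closure, element support, valence on organic-subset atoms) and
#' returns the OpenBabel canonical SMILES. Unparseable input yields `NA`
#' rather than an error, so a sampled batch containing invalid strings can be
#' processed wholesale.
#'
#' Canonicalization is idempotent: `canonicalize(canonicalize(s))` equals
#' `canonicalize(s)` for valid `s`. Results are memoized for the session.
#'
#' @param smiles character vector of SMILES strings.
#' @return character vector of canonical SMILES, `NA` for invalid input.
#' @examples
#' canonicalize(c("c1ccccc1", "C1=CC=CC=C1", "C("))
#' @export
canonicalize <- function(smiles) {
  stopifnot(is.character(smiles))
  out <- rep(NA_character_, length(smiles))
  todo <- integer(0)
  for (i in seq_along(smiles)) {
    s <- smiles[i]
    if (is.na(s) || !nzchar(s)) next
    hit <- .can_cache[[s]]
    if (!is.null(hit)) {
      out[i] <- hit
    } else {
      todo <- c(todo, i)
    }
  }
  if (length(todo) > 0L) {
    ok <- vapply(smiles[todo], function(s) smi_parse(s)$ok, TRUE,
                 USE.NAMES = FALSE)
    fresh <- rep(NA_character_, length(todo))
    if (any(ok)) fresh[ok] <- .ob_canonical(smiles[todo][ok])
    # a hard OpenBabel failure on one batch member must not poison the rest:
    # retry missing parse-ok entries one at a time before declaring them
    # invalid
    retry <- which(ok & is.na(fresh))
    for (j in retry) fresh[j] <- .ob_canonical(smiles[todo[j]])
    for (j in seq_along(todo)) {
      val <- fresh[j]
      .can_cache[[smiles[todo[j]]]] <- if (is.na(val)) NA_character_ else val
      out[todo[j]] <- val
    }
  }
  out
}

#' Test whether SMILES strings are valid
#'
#' @param smiles character vector.
#' @return logical vector.
#' @export
is_valid_smiles <- function(smiles) {
  !is.na(canonicalize(smiles))
}

#' Randomize a SMILES string (augmentation)
#'
#' Writes the same molecular graph as a different SMILES string by uniformly
#' shuffling the atom numbering and re-running the depth-first traversal from
#' the new first atom. The result always denotes the same molecule:
#' `canonicalize(randomize_smiles(s))` equals `canonicalize(s)`.
#'
#' Draws from R's RNG stream, so results are reproducible under `set.seed()`.
#' Stereo-annotated input is returned in canonical form unchanged (atom
#' renumbering does not rewrite stereo parities). In the rare event that a
#' rewritten string fails to round-trip, the canonical SMILES is returned.
#'
#' @param smiles a single SMILES string; must parse.
#' @return a single SMILES string of the same molecule.
#' @examples
#' set.seed(1)
#' randomize_smiles("CCO")
#' @export
randomize_smiles <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) == 1L)
  g <- .parse_cached(smiles)
  if (!g$ok) stop("invalid SMILES '", smiles, "': ", g$error)
  can <- canonicalize(smiles)
  if (is.na(can)) stop("invalid SMILES '", smiles, "'")
  if (.has_stereo(g)) return(can)
  perm <- sample.int(length(g$symbol))
  s2 <- smi_write(g, order = perm)
  # guard: the rewritten string must re-parse (graph identity holds by
  # construction of the writer and is property-tested against the canonical
  # form); otherwise fall back to the canonical SMILES for this round
  if (is.na(s2) || !smi_parse(s2)$ok) return(can)
  s2
}

#' Bemis-Murcko scaffold of a molecule
#'
#' Strips side chains down to the ring systems plus their linkers on the
#' heavy-atom graph (terminal atoms held by a double or triple bond are kept),
#' and returns the scaffold as a canonical SMILES. For acyclic molecules the
#' framework is empty; by convention the molecule's own canonical SMILES is
#' returned instead, so every valid molecule has a non-empty scaffold key and
#' acyclic molecules are not pooled into one shared bucket.
#'
#' @param smiles a single SMILES string; must parse.
#' @return a single canonical SMILES string (the scaffold key).
#' @examples
#' scaffold("Cc1ccccc1")  # toluene -> benzene
#' @export
scaffold <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) == 1L)
  g <- smi_parse(smiles)
  if (!g$ok) stop("invalid SMILES '", smiles, "': ", g$error)
  can <- canonicalize(smiles)
  if (is.na(can)) stop("invalid SMILES '", smiles, "'")
  core <- .murcko_atoms(g)
  if (length(core) == 0L) return(can)
  h <- .smi_subgraph(g, core)
  if (!h$ok) return(can)
  s <- smi_write(h)
  out <- canonicalize(s)
  if (is.na(out)) can else out
}

#' Morgan (extended-connectivity) fingerprint
#'
#' Circular substructure fingerprint: atom environments of radius 0..`radius`
#' are hashed onto a fixed-length bit vector (radius 2, 2048 bits by default,
#' the usual similarity-search configuration). Returned as the sorted integer
#' positions of the set bits.
#'
#' @param smiles a single SMILES string; must parse.
#' @param radius maximum environment radius (bonds).
#' @param nbits length of the bit vector.
#' @return integer vector of set-bit positions (0-based) with attribute
#'   `nbits`; class `"morgan_fp"`.
#' @export
morgan_fp <- function(smiles, radius = 2L, nbits = 2048L) {
  stopifnot(is.character(smiles), length(smiles) == 1L)
  g <- smi_parse(smiles)
  if (!g$ok) stop("invalid SMILES '", smiles, "': ", g$error)
  bits <- smi_morgan_bits(g, radius = radius, nbits = as.integer(nbits))
  structure(bits, nbits = as.integer(nbits), class = "morgan_fp")
}

#' Tanimoto similarity between two fingerprints
#'
#' `|a AND b| / |a OR b|` on the set bits; defined as 0 when both
#' fingerprints are empty.
#'
#' @param a,b fingerprints from [morgan_fp()] (or plain integer vectors of
#'   set-bit positions with matching `nbits`).
#' @return similarity in `[0, 1]`.
#' @export
tanimoto <- function(a, b) {
  na <- attr(a, "nbits"); nb <- attr(b, "nbits")
  if (!is.null(na) && !is.null(nb) && na != nb) {
    stop("fingerprint length mismatch: ", na, " vs ", nb)
  }
  u <- length(union(a, b))
  if (u == 0L) return(0)
  length(intersect(a, b)) / u
}

#' Read a SMILES corpus
#'
#' Accepts `.smi` (one SMILES per line, optional tab-separated name) or CSV
#' with a `smiles` column.
#'
#' @param path file path.
#' @return character vector of SMILES strings.
#' @export
read_smiles <- function(path) {
  stopifnot(file.exists(path))
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    if (!("smiles" %in% names(df))) stop("CSV has no 'smiles' column")
    return(as.character(df$smiles))
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  vapply(strsplit(lines, "[\t ]+"), `[[`, "", 1L)
}

#' Write a SMILES corpus to a `.smi` file
#'
#' @param smiles character vector.
#' @param path output path.
#' @param names optional molecule names (tab-separated second column).
#' @export
write_smiles <- function(smiles, path, names = NULL) {
  lines <- if (is.null(names)) smiles else paste(smiles, names, sep = "\t")
  writeLines(lines, path)
  invisible(path)
}
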