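# Experience replay buffer, scaffold diversity filter and Selective Memory
# Purge.
#
# The buffer keeps the highest-rewarding molecules sampled so far (100 by
# default), unique by canonical SMILES, reward-sorted with stable ties.
# The diversity filter counts how often each Bemis-Murcko scaffold has been
# sampled in buckets of fixed size (25 by default); a full bucket zeroes the
# reward of further members. Selective Memory Purge removes penalized
# scaffolds from the buffer each epoch, so augmented replay never reinforces
# scaffolds that no longer earn reward.

#' Create an experience-replay buffer
#'
#' @param capacity maximum number of stored molecules.
#' @return object of class `"replay_buffer"` (reference semantics).
#' @export
replay_buffer <- function(capacity = 100L) {
  stopifnot(capacity >= 1L)
  e <- new.env(parent = emptyenv())
  e$capacity <- as.integer(capacity)
  e$entries <- data.frame(canonical_smiles = character(0),
                          reward = numeric(0), scaffold = character(0),
                          inserted = integer(0), stringsAsFactors = FALSE)
  e$counter <- 0L
  class(e) <- "replay_buffer"
  e
}

#' @export
print.replay_buffer <- function(x, ...) {
  cat("replay buffer:", nrow(x$entries), "/", x$capacity, "molecules\n")
  invisible(x)
}

#' Number of molecules currently in a buffer
#' @param buffer a [replay_buffer()].
#' @return integer.
#' @export
buffer_size <- function(buffer) nrow(buffer$entries)

#' Buffer contents
#' @param buffer a [replay_buffer()].
#' @return data.frame (`canonical_smiles`, `reward`, `scaffold`), reward
#'   descending.
#' @export
buffer_entries <- function(buffer) {
  buffer$entries[, c("canonical_smiles", "reward", "scaffold")]
}

#' Merge scored molecules into the buffer
#'
#' Deduplicates by canonical SMILES (keeping the higher reward), sorts by
#' reward descending with earlier-inserted entries first on ties, and
#' truncates to capacity. Invalid and zero-reward molecules are never
#' inserted.
#'
#' @param buffer a [replay_buffer()]; mutated in place.
#' @param batch data.frame from [score_batch()] (needs `canonical_smiles`,
#'   `reward`, `scaffold`, `valid`).
#' @return the buffer, invisibly.
#' @export
buffer_update <- function(buffer, batch) {
  stopifnot(inherits(buffer, "replay_buffer"))
  keep <- batch$valid & batch$reward > 0
  batch <- batch[keep, c("canonical_smiles", "reward", "scaffold"),
                 drop = FALSE]
  if (nrow(batch) > 0L) {
    # within-batch dedupe keeping max reward, preserving first occurrence
    agg <- tapply(batch$reward, batch$canonical_smiles, max)
    batch <- batch[!duplicated(batch$canonical_smiles), , drop = FALSE]
    batch$reward <- as.numeric(agg[batch$canonical_smiles])
    ent <- buffer$entries
    for (i in seq_len(nrow(batch))) {
      j <- match(batch$canonical_smiles[i], ent$canonical_smiles)
      if (is.na(j)) {
        buffer$counter <- buffer$counter + 1L
        ent <- rbind(ent, data.frame(
          canonical_smiles = batch$canonical_smiles[i],
          reward = batch$reward[i], scaffold = batch$scaffold[i],
          inserted = buffer$counter, stringsAsFactors = FALSE))
      } else if (batch$reward[i] > ent$reward[j]) {
        ent$reward[j] <- batch$reward[i]
      }
    }
    ent <- ent[order(-ent$reward, ent$inserted), , drop = FALSE]
    if (nrow(ent) > buffer$capacity) {
      ent <- ent[seq_len(buffer$capacity), , drop = FALSE]
    }
    rownames(ent) <- NULL
    buffer$entries <- ent
  }
  invisible(buffer)
}

#' Sample molecules from the buffer without replacement
#'
#' @param buffer a [replay_buffer()].
#' @param n requested sample size; the whole buffer is returned when
#'   `n >= buffer_size(buffer)`.
#' @return data.frame subset of [buffer_entries()].
#' @export
buffer_sample <- function(buffer, n) {
  stopifnot(n >= 0L)
  sz <- buffer_size(buffer)
  k <- min(n, sz)
  if (k == 0L) return(buffer_entries(buffer)[0L, , drop = FALSE])
  idx <- sample.int(sz, k)
  out <- buffer_entries(buffer)[idx, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Augment the whole buffer
#'
#' One freshly randomized SMILES per stored molecule, paired with the stored
#' reward. No oracle is consulted: the score obtained when the molecule was
#' first sampled is reused for the new string representation.
#'
#' @param buffer a [replay_buffer()].
#' @return data.frame with `smiles` (randomized), `canonical_smiles`,
#'   `reward`, `scaffold`.
#' @export
buffer_augment <- function(buffer) {
  ent <- buffer_entries(buffer)
  if (nrow(ent) == 0L) {
    return(data.frame(smiles = character(0),
                      canonical_smiles = character(0),
                      reward = numeric(0), scaffold = character(0),
                      stringsAsFactors = FALSE))
  }
  data.frame(
    smiles = vapply(ent$canonical_smiles, randomize_smiles, "",
                    USE.NAMES = FALSE),
    canonical_smiles = ent$canonical_smiles,
    reward = ent$reward, scaffold = ent$scaffold,
    stringsAsFactors = FALSE
  )
}

#' Create a scaffold diversity filter
#'
#' @param bucket_size number of times a scaffold may be sampled before
#'   further members are zero-rewarded.
#' @return object of class `"diversity_filter"` (reference semantics).
#' @export
diversity_filter <- function(bucket_size = 25L) {
  stopifnot(bucket_size >= 0L)
  e <- new.env(parent = emptyenv())
  e$bucket_size <- as.integer(bucket_size)
  e$counts <- new.env(parent = emptyenv())
  class(e) <- "diversity_filter"
  e
}

#' @export
print.diversity_filter <- function(x, ...) {
  cat("diversity filter:", length(ls(x$counts)), "scaffolds, bucket size",
      x$bucket_size, "\n")
  invisible(x)
}

#' Scaffold bucket counts
#' @param df a [diversity_filter()].
#' @return named integer vector (scaffold -> count).
#' @export
df_counts <- function(df) {
  nms <- ls(df$counts)
  stats::setNames(vapply(nms, function(s) df$counts[[s]], 1L), nms)
}

#' Scaffolds currently penalized by the filter
#' @param df a [diversity_filter()].
#' @return character vector of scaffold keys whose bucket is full.
#' @export
df_penalized <- function(df) {
  cnt <- df_counts(df)
  names(cnt)[cnt >= df$bucket_size]
}

#' Apply the diversity filter to a scored batch
#'
#' In batch order: a molecule whose scaffold bucket is already full has its
#' reward set to 0; afterwards the bucket count is incremented. Only valid
#' molecules touch buckets. With `bucket_size = 0` every valid molecule is
#' zeroed.
#'
#' @param df a [diversity_filter()]; mutated in place.
#' @param batch data.frame from [score_batch()].
#' @return the batch with filtered rewards (column `reward_oracle` keeps the
#'   pre-filter value).
#' @export
df_apply <- function(df, batch) {
  stopifnot(inherits(df, "diversity_filter"))
  batch$reward_oracle <- batch$reward
  for (i in seq_len(nrow(batch))) {
    if (!batch$valid[i]) next
    sc <- batch$scaffold[i]
    cur <- df$counts[[sc]]
    if (is.null(cur)) cur <- 0L
    if (cur >= df$bucket_size) batch$reward[i] <- 0
    df$counts[[sc]] <- cur + 1L
  }
  batch
}

#' Selective Memory Purge
#'
#' Removes every buffer entry whose scaffold the diversity filter penalizes,
#' preserving the order of survivors. After the purge, augmented replay only
#' reinforces scaffolds that can still earn reward.
#'
#' @param buffer a [replay_buffer()]; mutated in place.
#' @param df a [diversity_filter()].
#' @return the buffer, invisibly.
#' @export
selective_memory_purge <- function(buffer, df) {
  stopifnot(inherits(buffer, "replay_buffer"),
            inherits(df, "diversity_filter"))
  pen <- df_penalized(df)
  if (length(pen) > 0L && buffer_size(buffer) > 0L) {
    keep <- !(buffer$entries$scaffold %in% pen)
    buffer$entries <- buffer$entries[keep, , drop = FALSE]
    rownames(buffer$entries) <- NULL
  }
  invisible(buffer)
}
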