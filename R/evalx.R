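# Evaluation under an oracle budget: AUC Top-10, internal diversity,
# filter-based triage, and across-seed comparison.

#' Area under the Top-k curve over an oracle budget
#'
#' After every oracle call, the running mean of the k best rewards seen so
#' far is recorded; the resulting step function is integrated over
#' `[0, budget]` calls and normalized by the budget. A run that ends before
#' the budget is carried forward at its final value; while fewer than `k`
#' molecules have been scored, the mean over those available is used.
#'
#' @param history data.frame from [ledger_history()] (or any frame with a
#'   `reward` column in scoring order).
#' @param k size of the top set.
#' @param budget oracle-call budget.
#' @return value in `[0, 1]`.
#' @export
auc_topk <- function(history, k = 10L, budget = 10000L) {
  stopifnot(nrow(history) > 0L, k >= 1L, budget >= 1L)
  rewards <- history$reward
  n <- min(length(rewards), budget)
  top <- numeric(0)
  total <- 0
  running <- 0
  for (i in seq_len(n)) {
    r <- rewards[i]
    if (length(top) < k) {
      top <- c(top, r)
    } else if (r > top[1L]) {
      top[1L] <- r
    }
    top <- sort(top)          # ascending; top[1] is the current k-th best
    running <- mean(top)
    total <- total + running
  }
  if (n < budget) total <- total + (budget - n) * running
  total / budget
}

#' Internal diversity (IntDiv1) of a molecule set
#'
#' `1 - mean pairwise Tanimoto similarity` over all ordered pairs including
#' self-pairs, on Morgan fingerprints. Repeating one molecule n times gives
#' 0; two structurally disjoint molecules give 0.5 (the self-pairs bound the
#' metric below 1).
#'
#' @param smiles character vector; invalid entries are dropped.
#' @return value in `[0, 1)`.
#' @export
intdiv1 <- function(smiles) {
  cans <- canonicalize(smiles)
  cans <- cans[!is.na(cans)]
  if (length(cans) == 0L) stop("no valid molecules")
  fps <- lapply(cans, morgan_fp)
  n <- length(fps)
  s <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      s <- s + tanimoto(fps[[i]], fps[[j]])
    }
  }
  1 - s / n^2
}

#' Filter molecules by component-score rules
#'
#' Case-study style triage: each rule is
#' `list(component, comparator, threshold)` with comparator one of
#' `"<", "<=", ">", ">="`; a molecule passes when it satisfies all rules.
#'
#' @param scored data.frame with one column per rule component (as produced
#'   by [score_batch()] -- either bare component names or `score_` prefixed).
#' @param rules list of rules; the empty list passes everything.
#' @return list with `count` and `survivors` (the passing rows).
#' @export
filter_pass <- function(scored, rules = list()) {
  keep <- rep(TRUE, nrow(scored))
  for (rule in rules) {
    stopifnot(length(rule) == 3L)
    comp <- rule[[1L]]; cmp <- rule[[2L]]; thr <- rule[[3L]]
    col <- if (comp %in% names(scored)) comp else paste0("score_", comp)
    if (!(col %in% names(scored))) {
      stop("component '", comp, "' not present in scores")
    }
    v <- scored[[col]]
    keep <- keep & switch(cmp,
                          "<" = v < thr, "<=" = v <= thr,
                          ">" = v > thr, ">=" = v >= thr,
                          stop("unknown comparator '", cmp, "'"))
  }
  keep[is.na(keep)] <- FALSE
  list(count = sum(keep), survivors = scored[keep, , drop = FALSE])
}

#' Compare a metric between two algorithms across seeds
#'
#' Welch's two-sample t-test at 95% confidence, the conventional check that
#' a sample-efficiency difference across replicate runs is not noise.
#'
#' @param x,y per-seed metric values for the two algorithms.
#' @return list with `p_value`, `significant` (at 0.05), `mean_x`, `mean_y`.
#' @export
compare_runs <- function(x, y) {
  ht <- stats::t.test(x, y)
  list(p_value = ht$p.value, significant = ht$p.value < 0.05,
       mean_x = mean(x), mean_y = mean(y))
}
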