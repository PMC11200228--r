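# Scoring components, multi-parameter-objective aggregation and oracle-call
# accounting.
#
# A reward S(A) in [0,1] is the weighted geometric mean of component
# desirabilities. The ledger charges one oracle call per distinct canonical
# SMILES ever scored: duplicates, and in particular augmented SMILES of
# already-scored molecules, are free. That accounting rule is what makes
# augmentation rounds oracle-free.

#' Define a scoring component
#'
#' @param name component name (used in logs and filter rules).
#' @param raw_fn function of one canonical SMILES returning the raw value.
#' @param transform monotone map from raw value to `[0, 1]`.
#' @param weight nonnegative aggregation weight.
#' @return object of class `"scoring_component"`.
#' @export
scoring_component <- function(name, raw_fn, transform = identity,
                              weight = 1) {
  stopifnot(is.character(name), is.function(raw_fn), is.function(transform),
            weight >= 0)
  structure(list(name = name, raw_fn = raw_fn, transform = transform,
                 weight = weight),
            class = "scoring_component")
}

#' Combine scoring components into an objective function
#'
#' Aggregation is the weighted geometric mean, so any zero component zeroes
#' the reward; invalid molecules always score 0.
#'
#' @param ... [scoring_component()] objects.
#' @return object of class `"objective_fn"`.
#' @export
objective_function <- function(...) {
  comps <- list(...)
  if (length(comps) == 1L && is.list(comps[[1L]]) &&
      !inherits(comps[[1L]], "scoring_component")) {
    comps <- comps[[1L]]
  }
  stopifnot(length(comps) > 0L,
            all(vapply(comps, inherits, TRUE, "scoring_component")))
  nms <- vapply(comps, `[[`, "", "name")
  if (anyDuplicated(nms)) stop("duplicate component names")
  structure(list(components = comps, names = nms), class = "objective_fn")
}

#' Oracle-call ledger
#'
#' Mutable cache + counter with reference semantics. `call_count` equals the
#' number of distinct canonical SMILES ever scored; the scoring history
#' (call index, canonical SMILES, reward) drives budgeted-run metrics.
#'
#' @return object of class `"oracle_ledger"`.
#' @export
oracle_ledger <- function() {
  e <- new.env(parent = emptyenv())
  e$cache <- new.env(parent = emptyenv())
  e$call_count <- 0L
  e$history_smiles <- character(0)
  e$history_reward <- numeric(0)
  e$history_scaffold <- character(0)
  class(e) <- "oracle_ledger"
  e
}

#' @export
print.oracle_ledger <- function(x, ...) {
  cat("oracle ledger:", x$call_count, "calls charged\n")
  invisible(x)
}

#' Number of oracle calls charged so far
#' @param ledger an [oracle_ledger()].
#' @return integer.
#' @export
ledger_calls <- function(ledger) ledger$call_count

#' Scoring history of a ledger
#' @param ledger an [oracle_ledger()].
#' @return data.frame with `call`, `canonical_smiles`, `reward`, `scaffold`,
#'   one row per distinct molecule in scoring order.
#' @export
ledger_history <- function(ledger) {
  data.frame(call = seq_along(ledger$history_smiles),
             canonical_smiles = ledger$history_smiles,
             reward = ledger$history_reward,
             scaffold = ledger$history_scaffold,
             stringsAsFactors = FALSE)
}

.aggregate_components <- function(values, weights) {
  if (any(values <= 0)) return(0)
  w <- weights / sum(weights)
  exp(sum(w * log(values)))
}

#' Score a batch of SMILES against an objective
#'
#' Invalid SMILES get reward 0 and are never charged; cache hits are free;
#' each new distinct valid molecule is charged exactly one oracle call. A
#' failing component raw function zeroes that molecule's reward (with a
#' warning) rather than aborting the batch.
#'
#' @param objective an [objective_function()].
#' @param smiles character vector (raw, possibly invalid, SMILES).
#' @param ledger an [oracle_ledger()]; mutated in place.
#' @return data.frame with one row per input: `smiles`, `canonical_smiles`,
#'   `valid`, `reward`, `scaffold`, and one `score_<name>` column per
#'   component.
#' @export
score_batch <- function(objective, smiles, ledger) {
  stopifnot(inherits(objective, "objective_fn"),
            inherits(ledger, "oracle_ledger"))
  n <- length(smiles)
  cans <- canonicalize(smiles)
  nc <- length(objective$components)
  comp_scores <- matrix(NA_real_, n, nc,
                        dimnames = list(NULL, objective$names))
  reward <- numeric(n)
  scaff <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    can <- cans[i]
    if (is.na(can)) next
    hit <- ledger$cache[[can]]
    if (is.null(hit)) {
      vals <- numeric(nc)
      failed <- FALSE
      for (j in seq_len(nc)) {
        comp <- objective$components[[j]]
        v <- tryCatch(comp$transform(comp$raw_fn(can)),
                      error = function(e) {
                        warning("component '", comp$name, "' failed on ",
                                can, ": ", conditionMessage(e), call. = FALSE)
                        NA_real_
                      })
        if (is.na(v) || !is.finite(v)) { failed <- TRUE; v <- 0 }
        vals[j] <- min(max(v, 0), 1)
      }
      r <- if (failed) 0 else {
        .aggregate_components(vals, vapply(objective$components, `[[`, 1,
                                           "weight"))
      }
      sc <- scaffold(can)
      hit <- list(reward = r, components = vals, scaffold = sc)
      ledger$cache[[can]] <- hit
      ledger$call_count <- ledger$call_count + 1L
      ledger$history_smiles <- c(ledger$history_smiles, can)
      ledger$history_reward <- c(ledger$history_reward, r)
      ledger$history_scaffold <- c(ledger$history_scaffold, sc)
    }
    reward[i] <- hit$reward
    comp_scores[i, ] <- hit$components
    scaff[i] <- hit$scaffold
  }
  out <- data.frame(smiles = smiles, canonical_smiles = cans,
                    valid = !is.na(cans), reward = reward,
                    scaffold = scaff, stringsAsFactors = FALSE)
  colnames(comp_scores) <- paste0("score_", colnames(comp_scores))
  cbind(out, comp_scores)
}

# ---- component library -----------------------------------------------------

#' Tanimoto-similarity scoring component
#'
#' Similarity of the Morgan fingerprint to a fixed reference molecule;
#' identity transform (the raw similarity is already in `[0, 1]`). The
#' rediscovery task scores 1 exactly on the reference itself.
#'
#' @param reference reference SMILES; must parse.
#' @param weight aggregation weight.
#' @return a [scoring_component()].
#' @export
tanimoto_similarity_component <- function(reference, weight = 1) {
  can <- canonicalize(reference)
  if (is.na(can)) stop("unparseable reference SMILES")
  ref_fp <- morgan_fp(can)
  scoring_component(
    name = "similarity",
    raw_fn = function(s) tanimoto(morgan_fp(s), ref_fp),
    transform = identity, weight = weight
  )
}

#' QED drug-likeness scoring component
#'
#' @param weight aggregation weight.
#' @return a [scoring_component()].
#' @export
qed_component <- function(weight = 1) {
  scoring_component(name = "qed", raw_fn = qed, transform = identity,
                    weight = weight)
}

#' Molecular-weight threshold component
#'
#' Hard step: 1 when MW is strictly below `limit` (500 Da by default), else
#' 0, so overweight molecules zero the aggregate reward.
#'
#' @param limit mass threshold in Dalton.
#' @param weight aggregation weight.
#' @return a [scoring_component()].
#' @export
mw_threshold_component <- function(limit = 500, weight = 1) {
  stopifnot(limit > 0)
  scoring_component(
    name = "mw",
    raw_fn = molecular_weight,
    transform = function(x) as.numeric(x < limit),
    weight = weight
  )
}

#' Reverse-sigmoid transform for minimized external quantities
#'
#' Maps a raw score (e.g. a docking score, where lower is better) onto
#' `(0, 1)`: 0.5 at `midpoint`, approaching 1 as the raw value decreases.
#'
#' @param midpoint raw value mapped to 0.5.
#' @param slope positive steepness (per raw unit).
#' @return transform function.
#' @export
reverse_sigmoid <- function(midpoint, slope = 1) {
  stopifnot(slope > 0)
  function(x) 1 / (1 + exp(slope * (x - midpoint)))
}

#' Synthetic-accessibility transform
#'
#' Maps the SA score range `[1, 10]` reversed onto `[0, 1]` (1 = easiest).
#'
#' @return transform function.
#' @export
sa_transform <- function() {
  function(x) min(max((10 - x) / 9, 0), 1)
}

#' Wrap an external oracle as a scoring component
#'
#' Adapter for property predictors that run outside the package (docking,
#' semiempirical IP estimates, SA scoring): the caller supplies the raw
#' function (typically a subprocess adapter, in tests a deterministic stub)
#' and a monotone transform onto `[0, 1]`. External failures zero the
#' component (and thus the reward) for that molecule.
#'
#' @param kind label, e.g. `"docking"`, `"xtb_ip"`, `"sa_score"`.
#' @param raw_fn function of one canonical SMILES returning the external raw
#'   value; may error on failure.
#' @param transform monotone transform, e.g. [reverse_sigmoid()] or
#'   [sa_transform()].
#' @param weight aggregation weight.
#' @return a [scoring_component()].
#' @export
external_oracle_component <- function(kind, raw_fn, transform,
                                      weight = 1) {
  scoring_component(name = kind, raw_fn = raw_fn, transform = transform,
                    weight = weight)
}
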