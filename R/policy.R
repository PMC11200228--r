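# Autoregressive LSTM policy over the SMILES vocabulary.
#
# The same network type serves as the frozen Prior and the trainable Agent.
# Forward, sampling, exact sequence log-likelihoods and backpropagation
# through time are implemented directly with base matrix operations; the
# batch dimension is vectorized, the time dimension is an explicit loop.
# Gate layout in the fused weight matrices is (input, forget, cell, output).



#' Create an LSTM policy network
#'
#' Embedding layer, one or more LSTM layers, and a softmax projection onto
#' the vocabulary. At every step the output is a normalized distribution over
#' tokens. Parameters are initialized uniformly in `[-scale, scale]`; the
#' forget-gate bias starts at 1 (standard trainability device).
#'
#' @param vocab a [build_vocabulary()] object; stored inside the model.
#' @param emb_size embedding dimension.
#' @param hidden_sizes integer vector, one entry per LSTM layer.
#' @param init_scale half-width of the uniform initializer.
#' @return object of class `"policy_net"`.
#' @export
policy_net <- function(vocab, emb_size = 128L, hidden_sizes = c(512L, 512L),
                       init_scale = 0.1) {
  stopifnot(inherits(vocab, "smiles_vocab"), emb_size >= 1L,
            all(hidden_sizes >= 1L))
  V <- length(vocab$tokens)
  rmat <- function(nr, nc) {
    matrix(stats::runif(nr * nc, -init_scale, init_scale), nr, nc)
  }
  layers <- list()
  input_dim <- emb_size
  for (h in hidden_sizes) {
    b <- rep(0, 4L * h)
    b[(h + 1L):(2L * h)] <- 1  # forget gate bias
    layers[[length(layers) + 1L]] <-
      list(Wx = rmat(4L * h, input_dim), Wh = rmat(4L * h, h), b = b)
    input_dim <- h
  }
  structure(
    list(vocab = vocab, emb_size = as.integer(emb_size),
         hidden_sizes = as.integer(hidden_sizes),
         params = list(emb = rmat(V, emb_size), layers = layers,
                       Wo = rmat(V, input_dim), bo = rep(0, V))),
    class = "policy_net"
  )
}

#' @export
print.policy_net <- function(x, ...) {
  cat("LSTM policy: |V| =", length(x$vocab$tokens),
      " emb =", x$emb_size,
      " hidden =", paste(x$hidden_sizes, collapse = "/"), "\n")
  invisible(x)
}

# pad a list of index sequences into B x T matrix (pad id fills the tail)
.pad_batch <- function(seqs, pad) {
  Tm <- max(lengths(seqs))
  B <- length(seqs)
  m <- matrix(pad, B, Tm)
  for (b in seq_len(B)) m[b, seq_along(seqs[[b]])] <- seqs[[b]]
  m
}

# Teacher-forced forward over a padded batch (compiled core). The start and
# pad tokens are clamped out of every per-step distribution, which keeps
# sampling and likelihood evaluation exactly consistent. Returns per-sequence
# log-likelihoods plus, on request, the per-step probability matrices and
# per-token NLLs.
.policy_forward <- function(model, seqs, keep_cache = FALSE,
                            per_token = FALSE) {
  vocab <- model$vocab
  B <- length(seqs)
  lens <- lengths(seqs)
  tgt <- .pad_batch(seqs, vocab$pad)
  Tm <- ncol(tgt)
  inp <- cbind(rep(vocab$start, B), tgt[, -Tm, drop = FALSE])
  res <- .cpp_policy_fb(model$params, inp, tgt, as.integer(lens),
                        numeric(0), numeric(0), vocab$pad, vocab$start,
                        keep_cache || per_token)
  ll <- as.numeric(res$loglik)
  ptok <- NULL
  if (per_token) {
    ptok <- lapply(seq_len(B), function(b) {
      vapply(seq_len(lens[b]), function(t)
        -log(pmax(res$probs[[t]][b, tgt[b, t]], 1e-30)), 1)
    })
  }
  list(loglik = ll, nll = -ll, per_token_nll = ptok,
       inp = inp, tgt = tgt, lens = lens,
       probs = if (keep_cache) res$probs else NULL)
}

# gradient of J = sum_b weights[b] * loglik_b with respect to all parameters
# (compiled BPTT). Returns a list shaped like model$params.
.policy_grad <- function(model, seqs, weights) {
  vocab <- model$vocab
  B <- length(seqs)
  lens <- lengths(seqs)
  tgt <- .pad_batch(seqs, vocab$pad)
  Tm <- ncol(tgt)
  inp <- cbind(rep(vocab$start, B), tgt[, -Tm, drop = FALSE])
  res <- .cpp_policy_fb(model$params, inp, tgt, as.integer(lens),
                        as.numeric(weights), numeric(0),
                        vocab$pad, vocab$start, FALSE)
  res$grads
}

# forward + squared-difference backward in one compiled pass: the loss
# mean_b (targets_b - loglik_b)^2 and its parameter gradients
.policy_dap_grad <- function(model, seqs, targets) {
  vocab <- model$vocab
  B <- length(seqs)
  lens <- lengths(seqs)
  tgt <- .pad_batch(seqs, vocab$pad)
  Tm <- ncol(tgt)
  inp <- cbind(rep(vocab$start, B), tgt[, -Tm, drop = FALSE])
  .cpp_policy_fb(model$params, inp, tgt, as.integer(lens),
                 numeric(0), as.numeric(targets),
                 vocab$pad, vocab$start, FALSE)
}

# encode without the condition-handling overhead of encode_smiles(); returns
# NULL when any lexical unit is outside the vocabulary
.encode_quiet <- function(smiles, vocab) {
  toks <- smiles_tokens(smiles)
  idx <- vocab$index[toks]
  if (anyNA(idx)) return(NULL)
  c(unname(idx), vocab$end)
}

# ---- Adam optimizer --------------------------------------------------------

.adam_init <- function(params) {
  zero_like <- function(x) {
    if (is.list(x)) lapply(x, zero_like)
    else if (is.matrix(x)) matrix(0, nrow(x), ncol(x))
    else rep(0, length(x))
  }
  list(m = zero_like(params), v = zero_like(params), t = 0L)
}

# applies theta <- theta - lr * mhat / (sqrt(vhat) + eps) where grads are the
# gradients of the LOSS (so callers pass dLoss/dtheta)
.adam_update <- function(params, grads, state, lr, beta1 = 0.9,
                         beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  tt <- state$t
  walk <- function(p, g, m, v) {
    if (is.list(p)) {
      out <- list(p = p, m = m, v = v)
      for (nm in seq_along(p)) {
        r <- walk(p[[nm]], g[[nm]], m[[nm]], v[[nm]])
        out$p[[nm]] <- r$p; out$m[[nm]] <- r$m; out$v[[nm]] <- r$v
      }
      out
    } else {
      m2 <- beta1 * m + (1 - beta1) * g
      v2 <- beta2 * v + (1 - beta2) * g * g
      mhat <- m2 / (1 - beta1^tt)
      vhat <- v2 / (1 - beta2^tt)
      list(p = p - lr * mhat / (sqrt(vhat) + eps), m = m2, v = v2)
    }
  }
  r <- walk(params, grads, state$m, state$v)
  list(params = r$p, state = list(m = r$m, v = r$v, t = tt))
}

# ---- public operations -----------------------------------------------------

#' Exact sequence negative log-likelihood
#'
#' `-sum_t log P(a_t | s_t)` under the model, summed through the end token.
#' This is the sequence-level quantity entering the augmented-likelihood
#' target and the squared-difference loss.
#'
#' @param model a [policy_net()].
#' @param smiles character vector of SMILES strings (must be encodable).
#' @return numeric vector of NLL values (nonnegative).
#' @export
sequence_nll <- function(model, smiles) {
  stopifnot(inherits(model, "policy_net"))
  seqs <- lapply(smiles, encode_smiles, vocab = model$vocab)
  .policy_forward(model, seqs)$nll
}

#' Sample a batch of SMILES from the policy
#'
#' Multinomial sampling token-by-token from the per-step softmax; each
#' sequence terminates at the end token or at `max_length`. Deterministic
#' under `set.seed()`.
#'
#' @param model a [policy_net()].
#' @param batch_size number of sequences.
#' @param max_length maximum number of tokens before forced termination.
#' @return list with `smiles` (character), `nll` (numeric), and `tokens`
#'   (list of index vectors including the end token where reached).
#' @export
sample_batch <- function(model, batch_size = 64L, max_length = 256L) {
  stopifnot(inherits(model, "policy_net"), batch_size >= 1L)
  vocab <- model$vocab
  res <- .cpp_policy_sample(model$params, as.integer(batch_size),
                            as.integer(max_length), vocab$pad, vocab$start,
                            vocab$end)
  toks <- res$tokens
  smiles <- vapply(toks, decode_smiles, "", vocab = vocab)
  list(smiles = smiles, nll = as.numeric(res$nll), tokens = toks)
}

#' Train a prior policy by maximum likelihood
#'
#' Teacher-forced cross-entropy training on a SMILES corpus with Adam.
#' Deterministic under `set.seed()`.
#'
#' @param corpus character vector of SMILES (all must be valid).
#' @param epochs passes over the corpus.
#' @param lr initial Adam learning rate.
#' @param lr_decay multiplicative learning-rate decay per epoch (1 = none);
#'   annealing the step size lets the fit settle instead of oscillating
#'   around the corpus entropy floor.
#' @param batch_size minibatch size.
#' @param emb_size,hidden_sizes network architecture, see [policy_net()].
#' @param augment randomized-SMILES data augmentation during training:
#'   `FALSE` (train on the fixed canonical forms), `TRUE` (a fresh random
#'   writing of every molecule each epoch), or a fraction in (0, 1) — each
#'   epoch that share of molecules is randomized and the rest stay
#'   canonical. Mixed schedules keep the canonical syntax sharp while
#'   exposing the model to alternative writings of the same graphs, which a
#'   policy must understand before augmented replay can reuse scores across
#'   representations.
#' @param augment_after first epoch (1-based) at which augmentation is
#'   applied; earlier epochs train on canonical forms only. A
#'   canonical-first curriculum lets the model master the grammar before
#'   the representation variety is introduced.
#' @param verbose print the mean corpus NLL per epoch.
#' @return a trained [policy_net()] with attribute `nll_history` (mean corpus
#'   NLL at initialization and after each epoch; evaluated on the canonical
#'   forms).
#' @export
train_prior <- function(corpus, epochs = 10L, lr = 5e-3, lr_decay = 0.95,
                        batch_size = 64L,
                        emb_size = 128L, hidden_sizes = c(512L, 512L),
                        augment = FALSE, augment_after = 1L,
                        verbose = FALSE) {
  stopifnot(length(corpus) > 0L)
  aug_frac <- if (isTRUE(augment)) 1 else if (isFALSE(augment)) 0
              else as.numeric(augment)
  stopifnot(aug_frac >= 0, aug_frac <= 1)
  vocab_corpus <- corpus
  if (aug_frac > 0) {
    # randomized writings can need lexical units the canonical forms never
    # use (chiefly additional ring-closure digits); build the vocabulary
    # over the corpus plus a sample of its augmentations
    vocab_corpus <- c(corpus, unlist(lapply(corpus, function(s)
      replicate(3L, randomize_smiles(s)))))
  }
  vocab <- build_vocabulary(vocab_corpus)
  model <- policy_net(vocab, emb_size, hidden_sizes)
  opt <- .adam_init(model$params)
  seqs_all <- lapply(corpus, encode_smiles, vocab = vocab)
  mean_nll <- function() mean(.policy_forward(model, seqs_all)$nll)
  hist <- mean_nll()
  lr_ep <- lr
  for (ep in seq_len(epochs)) {
    seqs_ep <- if (aug_frac > 0 && ep >= augment_after) {
      pick <- stats::runif(length(corpus)) < aug_frac
      lapply(seq_along(corpus), function(i) {
        if (!pick[i]) return(seqs_all[[i]])
        r <- randomize_smiles(corpus[i])
        # fall back to the canonical form if a randomized writing uses a
        # token absent from the corpus-derived vocabulary
        tryCatch(encode_smiles(r, vocab),
                 error = function(e) seqs_all[[i]])
      })
    } else seqs_all
    ord <- sample.int(length(seqs_ep))
    for (start in seq(1L, length(ord), by = batch_size)) {
      idx <- ord[start:min(start + batch_size - 1L, length(ord))]
      seqs <- seqs_ep[idx]
      # loss = mean NLL = -(1/B) sum loglik  ->  dLoss = grad with w = -1/B
      gr <- .policy_grad(model, seqs, rep(-1 / length(seqs), length(seqs)))
      upd <- .adam_update(model$params, gr, opt, lr_ep)
      model$params <- upd$params; opt <- upd$state
    }
    lr_ep <- lr_ep * lr_decay
    hist <- c(hist, mean_nll())
    if (verbose) message(sprintf("epoch %d: mean NLL %.3f", ep, hist[ep + 1L]))
  }
  attr(model, "nll_history") <- hist
  model
}

#' Save / load a policy checkpoint
#'
#' The checkpoint is a versioned container holding the architecture, the
#' embedded vocabulary and all parameters.
#'
#' @param model a [policy_net()].
#' @param path file path (`.rds`).
#' @return `load_policy()` returns the restored [policy_net()].
#' @export
save_policy <- function(model, path) {
  stopifnot(inherits(model, "policy_net"))
  saveRDS(list(format = "augmem-policy", version = 1L,
               emb_size = model$emb_size, hidden_sizes = model$hidden_sizes,
               vocab = unclass(model$vocab), params = model$params), path)
  invisible(path)
}

#' @rdname save_policy
#' @export
load_policy <- function(path) {
  x <- readRDS(path)
  if (!identical(x$format, "augmem-policy")) stop("not a policy checkpoint")
  structure(
    list(vocab = structure(x$vocab, class = "smiles_vocab"),
         emb_size = x$emb_size, hidden_sizes = x$hidden_sizes,
         params = x$params),
    class = "policy_net"
  )
}
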