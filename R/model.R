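# The shared bi-LSTM encoder and its two heads: a pooled drug-name classifier
# (unsupervised phase) and a per-token tag classifier (supervised phase).
#
# Parameter orientation: batches are row-major (one example per row), so gate
# pre-activations are  a = X %*% I + H_prev %*% W + b  with projection
# matrices I (embed_dim x hidden_dim) and recurrent matrices W
# (hidden_dim x hidden_dim).
#
# The published update equations for the memory cell contain two apparent
# misprints (the forget term drops m_{t-1}; the output uses m_{t-1} inside a
# misplaced tanh), under which the memory cell never propagates. This package
# implements the standard LSTM cell:
#   m_t = g^f * m_{t-1} + g^u * g^c ;  h_t = g^o * tanh(m_t)

#' Model configuration
#'
#' Dimensions of the encoder and heads. Defaults match the published setting
#' (400-dimensional word vectors, 500 hidden units per direction); the
#' synthetic benchmark uses a smaller configuration.
#'
#' @param token_vocab_size Number of tokens in the vocabulary (incl. specials).
#' @param drug_vocab_size Number of distinct target drug names (phase 1).
#' @param embed_dim Word-embedding dimension (default 400).
#' @param hidden_dim Hidden units per LSTM direction (default 500).
#' @param tag_count Number of IO tags; always 4.
#' @param pool Pooling over hidden states for the drug head: `"mean"`
#'   (average over non-padding steps, the default) or `"sum"` (the literal
#'   printed formula; kept for fidelity experiments).
#' @param train_embeddings Update the embedding matrix during training?
#' @return An object of class `adr_model_config`.
#' @export
model_config <- function(token_vocab_size, drug_vocab_size = 2L,
                         embed_dim = 400L, hidden_dim = 500L,
                         tag_count = 4L, pool = c("mean", "sum"),
                         train_embeddings = TRUE) {
  pool <- match.arg(pool)
  stopifnot(token_vocab_size >= 1L, drug_vocab_size >= 1L,
            embed_dim >= 1L, hidden_dim >= 1L, tag_count == 4L)
  structure(list(token_vocab_size = as.integer(token_vocab_size),
                 drug_vocab_size = as.integer(drug_vocab_size),
                 embed_dim = as.integer(embed_dim),
                 hidden_dim = as.integer(hidden_dim),
                 tag_count = 4L,
                 pool = pool,
                 train_embeddings = isTRUE(train_embeddings)),
            class = "adr_model_config")
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# Numerically stable row-wise softmax.
softmax_rows <- function(z) {
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

glorot <- function(nr, nc) {
  lim <- sqrt(6 / (nr + nc))
  matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
}

.init_dir <- function(d, h) {
  list(Iu = glorot(d, h), If = glorot(d, h), Io = glorot(d, h), Ic = glorot(d, h),
       Wu = glorot(h, h), Wf = glorot(h, h), Wo = glorot(h, h), Wc = glorot(h, h),
       bu = rep(0, h), bf = rep(1, h),  # forget-gate bias 1: remember by default
       bo = rep(0, h), bc = rep(0, h))
}

#' Initialize an encoder state
#'
#' Creates the shared bi-LSTM encoder: embedding matrix plus, per direction,
#' the four projection matrices I, recurrent matrices W and biases. Weights
#' are Glorot-uniform draws from the current RNG state (seed before calling
#' for reproducibility); the forget-gate bias starts at 1.
#'
#' @param cfg An [model_config()].
#' @param embeddings Optional pre-built embedding matrix
#'   (`token_vocab_size` x `embed_dim`), e.g. from [init_embeddings()];
#'   drawn uniformly from (-0.05, 0.05) with a zero `<PAD>` row if omitted.
#' @return An object of class `adr_encoder`.
#' @export
init_encoder <- function(cfg, embeddings = NULL) {
  stopifnot(inherits(cfg, "adr_model_config"))
  V <- cfg$token_vocab_size; d <- cfg$embed_dim; h <- cfg$hidden_dim
  if (is.null(embeddings)) {
    embeddings <- matrix(stats::runif(V * d, -0.05, 0.05), V, d)
    embeddings[1L, ] <- 0  # <PAD> row
  }
  stopifnot(nrow(embeddings) == V, ncol(embeddings) == d)
  structure(list(config = cfg, E = embeddings,
                 fwd = .init_dir(d, h), bwd = .init_dir(d, h)),
            class = "adr_encoder")
}

#' Initialize the drug-prediction head
#' @param cfg An [model_config()].
#' @return List with weight matrix `W` (2*hidden_dim x drug_vocab_size) and
#'   bias `b`.
#' @export
init_drug_head <- function(cfg) {
  list(W = glorot(2L * cfg$hidden_dim, cfg$drug_vocab_size),
       b = rep(0, cfg$drug_vocab_size))
}

#' Initialize the per-token tag head
#' @param cfg An [model_config()].
#' @return List with weight matrix `W` (2*hidden_dim x 4) and bias `b`.
#' @export
init_tag_head <- function(cfg) {
  list(W = glorot(2L * cfg$hidden_dim, cfg$tag_count),
       b = rep(0, cfg$tag_count))
}

.add_bias <- function(M, b) M + rep(b, each = nrow(M))

# One LSTM cell update on a batch: X (B x d), Hprev/Mprev (B x h).
.lstm_cell <- function(X, Hprev, Mprev, p) {
  gu <- sigmoid(.add_bias(X %*% p$Iu + Hprev %*% p$Wu, p$bu))
  gf <- sigmoid(.add_bias(X %*% p$If + Hprev %*% p$Wf, p$bf))
  go <- sigmoid(.add_bias(X %*% p$Io + Hprev %*% p$Wo, p$bo))
  gc <- tanh(.add_bias(X %*% p$Ic + Hprev %*% p$Wc, p$bc))
  M <- gf * Mprev + gu * gc
  tM <- tanh(M)
  list(H = go * tM, M = M, tM = tM, gu = gu, gf = gf, go = go, gc = gc,
       Hprev = Hprev, Mprev = Mprev, X = X)
}

#' Single LSTM step
#'
#' One update of the standard LSTM recurrence: update, forget and output
#' gates from the logistic sigmoid of `W h_{t-1} + I x_t + b`, a tanh
#' candidate cell, `m_t = g^f * m_{t-1} + g^u * g^c` and
#' `h_t = g^o * tanh(m_t)`.
#'
#' @param x_t Input vector (length `embed_dim`).
#' @param h_prev,m_prev Previous hidden and memory-cell vectors (length
#'   `hidden_dim`).
#' @param params One direction's parameter list (e.g. `enc$fwd`).
#' @return List with the new `h` and `m` vectors.
#' @export
lstm_step <- function(x_t, h_prev, m_prev, params) {
  d <- nrow(params$Iu); h <- nrow(params$Wu)
  if (length(x_t) != d) stop("x_t has length ", length(x_t), ", expected ", d)
  if (length(h_prev) != h || length(m_prev) != h) {
    stop("state vectors must have length ", h)
  }
  cell <- .lstm_cell(matrix(x_t, 1L), matrix(h_prev, 1L), matrix(m_prev, 1L),
                     params)
  list(h = drop(cell$H), m = drop(cell$M))
}

# Run one direction over a batch. Xs: list over time of (B x d) matrices in
# *processing* order. Returns caches (one per step, processing order).
.run_dir <- function(Xs, p) {
  B <- nrow(Xs[[1L]]); h <- nrow(p$Wu)
  H <- matrix(0, B, h); M <- matrix(0, B, h)
  caches <- vector("list", length(Xs))
  for (s in seq_along(Xs)) {
    cell <- .lstm_cell(Xs[[s]], H, M, p)
    H <- cell$H; M <- cell$M
    caches[[s]] <- cell
  }
  caches
}

# Full batched forward pass of the encoder.
# idx: T x B integer matrix of 0-based token indices (0 = <PAD>).
# Returns H (list over time of B x 2h), per-direction caches, the input
# matrices, and the non-PAD mask (B x T).
.forward_batch <- function(idx, enc) {
  Tn <- nrow(idx); B <- ncol(idx)
  Xs <- lapply(seq_len(Tn), function(t) {
    enc$E[idx[t, ] + 1L, , drop = FALSE]
  })
  fwd <- .run_dir(Xs, enc$fwd)                       # step s = time s
  bwd <- .run_dir(Xs[rev(seq_len(Tn))], enc$bwd)     # step s = time T-s+1
  H <- lapply(seq_len(Tn), function(t) {
    cbind(fwd[[t]]$H, bwd[[Tn - t + 1L]]$H)
  })
  mask <- t(idx > 0L)  # B x T
  storage.mode(mask) <- "double"
  list(H = H, fwd = fwd, bwd = bwd, Xs = Xs, mask = mask, Tn = Tn, B = B)
}

#' Encode a token-index sequence with the bi-LSTM
#'
#' Runs the recurrence in both directions over the full (padded) sequence
#' and concatenates forward and backward hidden states per time-step.
#'
#' @param indices Integer vector of 0-based token indices (non-empty).
#' @param enc An `adr_encoder`.
#' @return Matrix of shape `length(indices)` x `2*hidden_dim`.
#' @export
bilstm_encode <- function(indices, enc) {
  if (length(indices) == 0L) stop("cannot encode an empty sequence")
  fb <- .forward_batch(matrix(as.integer(indices), ncol = 1L), enc)
  do.call(rbind, lapply(fb$H, function(Ht) Ht[1L, ]))
}

#' Pool hidden states into one sequence representation
#'
#' Average (default) or sum of the per-step hidden vectors over non-padding
#' positions.
#'
#' @param hidden_states Matrix (T x 2*hidden_dim) of per-step hidden states.
#' @param mask Optional logical/numeric vector of length T; TRUE/1 marks
#'   non-padding steps. All steps are used if omitted.
#' @param pool `"mean"` or `"sum"`.
#' @return Pooled vector of length 2*hidden_dim.
#' @export
pool <- function(hidden_states, mask = NULL, pool = c("mean", "sum")) {
  pool <- match.arg(pool)
  if (is.null(mask)) mask <- rep(1, nrow(hidden_states))
  mask <- as.numeric(mask)
  n <- sum(mask)
  if (n == 0) stop("cannot pool an all-padding sequence")
  s <- colSums(hidden_states * mask)
  if (pool == "mean") s / n else s
}

#' Predict a drug-name distribution from a masked sequence
#'
#' Encodes the sequence, pools the hidden states over non-padding steps and
#' applies a softmax over all drug names.
#'
#' @param indices Integer vector of 0-based token indices (the masked tweet,
#'   containing the `<DRUG>` token).
#' @param enc An `adr_encoder`.
#' @param head A drug head from [init_drug_head()].
#' @return Numeric probability vector of length `drug_vocab_size` (sums
#'   to 1).
#' @export
drug_forward <- function(indices, enc, head) {
  H <- bilstm_encode(indices, enc)
  p <- pool(H, mask = indices > 0L, pool = enc$config$pool)
  drop(softmax_rows(matrix(p, 1L) %*% head$W + rep(head$b, each = 1L)))
}

#' Predict per-token tag distributions
#'
#' Applies the tag softmax `y_t = softmax(W h_t + b)` at every time-step of
#' the encoded sequence.
#'
#' @param indices Integer vector of 0-based token indices.
#' @param enc An `adr_encoder`.
#' @param head A tag head from [init_tag_head()].
#' @return Matrix (T x 4) of per-step tag probabilities, columns in
#'   [tag_set()] order; every row sums to 1.
#' @export
tag_forward <- function(indices, enc, head) {
  H <- bilstm_encode(indices, enc)
  probs <- softmax_rows(.add_bias(H %*% head$W, head$b))
  colnames(probs) <- tag_set()
  probs
}

#' Summed cross-entropy loss of a tag sequence
#'
#' `L = -sum_t sum_i yhat_{t,i} log y_{t,i}` with one-hot gold labels;
#' padding positions are excluded from the sum.
#'
#' @param y Matrix (T x 4) of predicted tag probabilities.
#' @param gold Character vector of length T over [tag_set()].
#' @return Non-negative scalar; 0 iff predictions are exactly one-hot on the
#'   gold tags.
#' @export
sequence_loss <- function(y, gold) {
  if (nrow(y) != length(gold)) {
    stop("prediction has ", nrow(y), " steps but gold has ", length(gold))
  }
  keep <- gold != PAD_TOK
  if (!any(keep)) return(0)
  cls <- match(gold[keep], tag_set())
  if (anyNA(cls)) stop("gold tags outside the tag set")
  -sum(log(y[cbind(which(keep), cls)]))
}

#' Transfer a pretrained encoder to the tagging phase
#'
#' Returns a value-identical copy of the pretrained encoder (embeddings and
#' all recurrent/projection weights) for supervised fine-tuning; the tag
#' head is initialized fresh by the caller. Nothing is frozen: fine-tuning
#' may update all transferred weights.
#'
#' @param pretrained An `adr_encoder` from phase-1 training.
#' @param cfg Optional [model_config()] for phase 2; must agree with the
#'   pretrained encoder in embedding dimension, hidden dimension and token
#'   vocabulary size.
#' @return An `adr_encoder` for phase 2.
#' @export
transfer_encoder <- function(pretrained, cfg = NULL) {
  stopifnot(inherits(pretrained, "adr_encoder"))
  if (!is.null(cfg)) {
    same <- cfg$embed_dim == pretrained$config$embed_dim &&
      cfg$hidden_dim == pretrained$config$hidden_dim &&
      cfg$token_vocab_size == pretrained$config$token_vocab_size
    if (!same) stop("phase-2 config does not match the pretrained encoder ",
                    "(embed_dim/hidden_dim/token_vocab_size must agree)")
    pretrained$config <- cfg
  }
  pretrained
}

# ---- backward pass -------------------------------------------------------

.zero_like_dir <- function(p) lapply(p, function(w) w * 0)

# BPTT through one direction. caches: processing-order caches from .run_dir;
# dHs: list (processing order) of external gradients w.r.t. that direction's
# hidden output (B x h). Returns parameter gradients and per-step input
# gradients dXs (processing order).
.bptt_dir <- function(caches, dHs, p) {
  g <- .zero_like_dir(p)
  n <- length(caches)
  B <- nrow(caches[[1L]]$H); h <- ncol(caches[[1L]]$H)
  dHrec <- matrix(0, B, h); dMrec <- matrix(0, B, h)
  dXs <- vector("list", n)
  for (s in seq(n, 1L)) {
    cc <- caches[[s]]
    dH <- dHs[[s]] + dHrec
    dgo <- dH * cc$tM
    dM <- dH * cc$go * (1 - cc$tM^2) + dMrec
    dgf <- dM * cc$Mprev
    dgu <- dM * cc$gc
    dgc <- dM * cc$gu
    dMrec <- dM * cc$gf
    dau <- dgu * cc$gu * (1 - cc$gu)
    daf <- dgf * cc$gf * (1 - cc$gf)
    dao <- dgo * cc$go * (1 - cc$go)
    dac <- dgc * (1 - cc$gc^2)
    g$Iu <- g$Iu + crossprod(cc$X, dau)
    g$If <- g$If + crossprod(cc$X, daf)
    g$Io <- g$Io + crossprod(cc$X, dao)
    g$Ic <- g$Ic + crossprod(cc$X, dac)
    g$Wu <- g$Wu + crossprod(cc$Hprev, dau)
    g$Wf <- g$Wf + crossprod(cc$Hprev, daf)
    g$Wo <- g$Wo + crossprod(cc$Hprev, dao)
    g$Wc <- g$Wc + crossprod(cc$Hprev, dac)
    g$bu <- g$bu + colSums(dau)
    g$bf <- g$bf + colSums(daf)
    g$bo <- g$bo + colSums(dao)
    g$bc <- g$bc + colSums(dac)
    dHrec <- dau %*% t(p$Wu) + daf %*% t(p$Wf) +
      dao %*% t(p$Wo) + dac %*% t(p$Wc)
    dXs[[s]] <- dau %*% t(p$Iu) + daf %*% t(p$If) +
      dao %*% t(p$Io) + dac %*% t(p$Ic)
  }
  list(grads = g, dXs = dXs)
}

# Backprop from per-time-step gradients on the concatenated hidden states
# (dH: list over time of B x 2h) through both directions into an encoder
# gradient (same shape as the encoder). idx: T x B 0-based indices.
.backward_batch <- function(fb, dH, idx, enc) {
  h <- enc$config$hidden_dim
  Tn <- fb$Tn
  dH_fwd <- lapply(dH, function(g) g[, seq_len(h), drop = FALSE])
  dH_bwd <- lapply(rev(seq_len(Tn)), function(t) {
    dH[[t]][, h + seq_len(h), drop = FALSE]
  })
  bf <- .bptt_dir(fb$fwd, dH_fwd, enc$fwd)
  bb <- .bptt_dir(fb$bwd, dH_bwd, enc$bwd)
  dE <- NULL
  if (enc$config$train_embeddings) {
    # total input gradient per (t, example), summed over directions
    rows <- matrix(0, Tn * fb$B, enc$config$embed_dim)
    for (t in seq_len(Tn)) {
      block <- (t - 1L) * fb$B + seq_len(fb$B)
      rows[block, ] <- bf$dXs[[t]] + bb$dXs[[Tn - t + 1L]]
    }
    # rows are stacked time-major (all examples of t=1, then t=2, ...), so
    # the token id of row (t-1)*B + b is idx[t, b]
    ids <- as.vector(t(idx))
    dE <- matrix(0, enc$config$token_vocab_size, enc$config$embed_dim)
    agg <- rowsum(rows, group = ids, reorder = FALSE)
    dE[as.integer(rownames(agg)) + 1L, ] <- agg
    dE[1L, ] <- 0  # <PAD> embedding stays fixed at zero
  }
  list(E = dE, fwd = bf$grads, bwd = bb$grads)
}
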