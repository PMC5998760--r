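# Two-phase training: unsupervised drug-name-prediction pretraining on masked
# tweets (mini-batch adam, batch 128) and supervised IO-tag fine-tuning
# (per-example adam, batch 1). Both phases update the shared encoder.

#' Training configuration
#'
#' Defaults follow the published setting: adam for both phases, batch size
#' 128 and 30 epochs for the unsupervised phase, batch size 1 and 5 epochs
#' for the supervised phase. The learning rate is the adam default 0.001
#' (not stated in the original setting). Gradients are clipped to global
#' norm 5 to stabilize the batch-size-1 updates.
#'
#' @param phase1,phase2 Lists with elements `batch_size`, `epochs`, `lr`.
#' @param seed Integer seed controlling initialization and shuffling.
#' @param embedding_init `"random"`, or the path of a word2vec text/binary
#'   file used to initialize the embedding rows (see [init_embeddings()]).
#' @param clip_norm Global gradient-norm clip; `Inf` disables clipping.
#' @return An object of class `adr_train_config`.
#' @export
train_config <- function(phase1 = list(batch_size = 128L, epochs = 30L, lr = 1e-3),
                         phase2 = list(batch_size = 1L, epochs = 5L, lr = 1e-3),
                         seed = 1L, embedding_init = "random",
                         clip_norm = 5) {
  defaults1 <- list(batch_size = 128L, epochs = 30L, lr = 1e-3)
  defaults2 <- list(batch_size = 1L, epochs = 5L, lr = 1e-3)
  phase1 <- utils::modifyList(defaults1, phase1)
  phase2 <- utils::modifyList(defaults2, phase2)
  stopifnot(phase1$batch_size >= 1L, phase2$batch_size >= 1L,
            phase1$epochs >= 0L, phase2$epochs >= 0L)
  structure(list(phase1 = phase1, phase2 = phase2, seed = as.integer(seed),
                 embedding_init = embedding_init, clip_norm = clip_norm),
            class = "adr_train_config")
}

#' Read a training configuration from YAML
#'
#' The file mirrors [train_config()]: top-level keys `phase1`, `phase2`
#' (each with `batch_size`, `epochs`, `lr`), `seed`, `embedding_init`,
#' `clip_norm`; all optional, missing values fall back to the defaults.
#'
#' @param path YAML file path.
#' @return An `adr_train_config`.
#' @export
read_train_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("reading YAML training configs requires the 'yaml' package")
  }
  vals <- yaml::read_yaml(path)
  known <- c("phase1", "phase2", "seed", "embedding_init", "clip_norm")
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0L) {
    stop("unknown training-config field(s): ", paste(unknown, collapse = ", "))
  }
  do.call(train_config, vals)
}

# ---- parameter-tree utilities -------------------------------------------

.tree_map <- function(f, a) {
  if (is.list(a)) lapply(a, function(el) .tree_map(f, el)) else f(a)
}

.tree_map2 <- function(f, a, b) {
  if (is.list(a)) {
    out <- vector("list", length(a))
    names(out) <- names(a)
    for (i in seq_along(a)) out[[i]] <- .tree_map2(f, a[[i]], b[[i]])
    out
  } else f(a, b)
}

.tree_sumsq <- function(a) {
  if (is.list(a)) sum(vapply(a, .tree_sumsq, numeric(1L))) else sum(a^2)
}

.clip_grads <- function(grads, clip_norm) {
  if (!is.finite(clip_norm)) return(grads)
  nrm <- sqrt(.tree_sumsq(grads))
  if (nrm > clip_norm) grads <- .tree_map(function(g) g * (clip_norm / nrm), grads)
  grads
}

adam_init <- function(params) {
  list(m = .tree_map(function(p) p * 0, params),
       v = .tree_map(function(p) p * 0, params),
       t = 0L)
}

adam_step <- function(opt, params, grads, lr = 1e-3,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  opt$t <- opt$t + 1L
  opt$m <- .tree_map2(function(m, g) beta1 * m + (1 - beta1) * g, opt$m, grads)
  opt$v <- .tree_map2(function(v, g) beta2 * v + (1 - beta2) * g^2, opt$v, grads)
  c1 <- 1 - beta1^opt$t
  c2 <- 1 - beta2^opt$t
  mv <- .tree_map2(function(m, v) (m / c1) / (sqrt(v / c2) + eps), opt$m, opt$v)
  params <- .tree_map2(function(p, u) p - lr * u, params, mv)
  list(opt = opt, params = params)
}

# Bundle/unbundle the trainable parameters of (encoder, head). The <PAD>
# embedding row carries zero gradient, so it stays zero under adam too.
.bundle <- function(enc, head) {
  b <- list(fwd = enc$fwd, bwd = enc$bwd, head = head)
  if (enc$config$train_embeddings) b$E <- enc$E
  b
}

.unbundle <- function(bundle, enc) {
  enc$fwd <- bundle$fwd
  enc$bwd <- bundle$bwd
  if (enc$config$train_embeddings) enc$E <- bundle$E
  list(enc = enc, head = bundle$head)
}

.grad_bundle <- function(enc_grads, head_grads, enc) {
  b <- list(fwd = enc_grads$fwd, bwd = enc_grads$bwd, head = head_grads)
  if (enc$config$train_embeddings) b$E <- enc_grads$E
  b
}

# ---- phase-specific loss + gradient --------------------------------------

# Drug-prediction loss on one mini-batch. idx: T x B, targets: 1-based drug
# class per example. Mean cross-entropy over the batch.
.phase1_batch <- function(idx, targets, enc, head) {
  fb <- .forward_batch(idx, enc)
  B <- fb$B
  lens <- rowSums(fb$mask)
  if (any(lens == 0)) stop("all-padding sequence in pretraining batch")
  pooled <- matrix(0, B, 2L * enc$config$hidden_dim)
  for (t in seq_len(fb$Tn)) pooled <- pooled + fb$H[[t]] * fb$mask[, t]
  if (enc$config$pool == "mean") pooled <- pooled / lens
  logits <- .add_bias(pooled %*% head$W, head$b)
  P <- softmax_rows(logits)
  picked <- P[cbind(seq_len(B), targets)]
  loss <- -mean(log(picked))
  acc <- mean(max.col(P, ties.method = "first") == targets)
  dlogits <- P
  dlogits[cbind(seq_len(B), targets)] <- dlogits[cbind(seq_len(B), targets)] - 1
  dlogits <- dlogits / B
  head_g <- list(W = crossprod(pooled, dlogits), b = colSums(dlogits))
  dpool <- dlogits %*% t(head$W)
  if (enc$config$pool == "mean") dpool <- dpool / lens
  dH <- lapply(seq_len(fb$Tn), function(t) dpool * fb$mask[, t])
  enc_g <- .backward_batch(fb, dH, idx, enc)
  list(loss = loss, acc = acc, grads = .grad_bundle(enc_g, head_g, enc))
}

# Tagging loss on one example. idx: length-T index vector; gold: length-T
# tag vector over tag_set(). Summed cross-entropy over non-PAD steps.
.phase2_example <- function(idx, gold, enc, head) {
  idxm <- matrix(as.integer(idx), ncol = 1L)
  fb <- .forward_batch(idxm, enc)
  H <- do.call(rbind, lapply(fb$H, function(Ht) Ht[1L, , drop = FALSE]))
  logits <- .add_bias(H %*% head$W, head$b)
  P <- softmax_rows(logits)
  keep <- gold != PAD_TOK
  cls <- match(gold, tag_set())
  loss <- if (any(keep)) -sum(log(P[cbind(which(keep), cls[keep])])) else 0
  dlogits <- P
  dlogits[cbind(seq_along(gold), cls)] <- dlogits[cbind(seq_along(gold), cls)] - 1
  dlogits[!keep, ] <- 0
  head_g <- list(W = crossprod(H, dlogits), b = colSums(dlogits))
  dHmat <- dlogits %*% t(head$W)
  dH <- lapply(seq_len(fb$Tn), function(t) dHmat[t, , drop = FALSE])
  enc_g <- .backward_batch(fb, dH, idxm, enc)
  list(loss = loss, grads = .grad_bundle(enc_g, head_g, enc))
}

# ---- embedding initialization --------------------------------------------

#' Initialize the embedding matrix
#'
#' Either random uniform(-0.05, 0.05) rows, or rows copied from a word2vec
#' file for the vocabulary tokens found there (missing tokens fall back to
#' the random draw). The `<PAD>` row is always zero. Draws come from the
#' current RNG state; seed before calling for reproducibility.
#'
#' @param vocab An `adr_vocabulary`.
#' @param scheme `"random"` or the path of a word2vec text/binary file.
#' @param embed_dim Embedding dimension; for a word2vec file it must equal
#'   the file's vector dimension.
#' @return Matrix `vocab_size x embed_dim` with attribute `coverage`: the
#'   fraction of vocabulary tokens found in the file (1 for random).
#' @export
init_embeddings <- function(vocab, scheme = "random", embed_dim) {
  V <- vocab_size(vocab)
  E <- matrix(stats::runif(V * embed_dim, -0.05, 0.05), V, embed_dim)
  coverage <- 1
  if (!identical(scheme, "random")) {
    w2v <- read_word2vec(scheme)
    if (ncol(w2v$vectors) != embed_dim) {
      stop("word2vec file has dimension ", ncol(w2v$vectors),
           " but embed_dim is ", embed_dim)
    }
    hit <- match(vocab$tokens, w2v$words)
    found <- which(!is.na(hit))
    E[found, ] <- w2v$vectors[hit[found], , drop = FALSE]
    coverage <- length(found) / V
  }
  E[vocab$index[[PAD_TOK]] + 1L, ] <- 0
  attr(E, "coverage") <- coverage
  E
}

#' Read word vectors in word2vec format
#'
#' Supports the text format (`"V D"` header line then one
#' `token v1 ... vD` line per word) and the binary format (same header,
#' then per word the token bytes, a space, and D little-endian float32
#' values).
#'
#' @param path File path.
#' @param binary `TRUE`, `FALSE`, or `"auto"` (sniff the bytes after the
#'   header).
#' @return List with `words` (character) and `vectors` (numeric matrix,
#'   one row per word).
#' @export
read_word2vec <- function(path, binary = "auto") {
  if (identical(binary, "auto")) {
    raw <- readBin(path, "raw", n = 4096L)
    binary <- any(raw == as.raw(0L)) ||
      mean(raw > as.raw(126L)) > 0.05
  }
  if (binary) .read_word2vec_binary(path) else .read_word2vec_text(path)
}

.read_word2vec_text <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  if (length(lines) == 0L) stop("word2vec file '", path, "' is empty")
  hdr <- strsplit(trimws(lines[1L]), "\\s+")[[1L]]
  if (length(hdr) != 2L || anyNA(suppressWarnings(as.integer(hdr)))) {
    stop("word2vec file '", path, "': line 1 is not a 'count dim' header")
  }
  n <- as.integer(hdr[1L]); d <- as.integer(hdr[2L])
  if (length(lines) - 1L < n) {
    stop("word2vec file '", path, "': header promises ", n,
         " vectors but only ", length(lines) - 1L, " lines follow")
  }
  words <- character(n)
  vectors <- matrix(NA_real_, n, d)
  for (i in seq_len(n)) {
    parts <- strsplit(lines[i + 1L], "\\s+")[[1L]]
    parts <- parts[nzchar(parts)]
    vals <- suppressWarnings(as.numeric(parts[-1L]))
    if (length(parts) != d + 1L || anyNA(vals)) {
      stop("word2vec file '", path, "': malformed vector on line ", i + 1L)
    }
    words[i] <- parts[1L]
    vectors[i, ] <- vals
  }
  list(words = words, vectors = vectors)
}

.read_word2vec_binary <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  read_until <- function(stop_chars) {
    out <- raw(0L)
    repeat {
      b <- readBin(con, "raw", n = 1L)
      if (length(b) == 0L) break
      if (rawToChar(b) %in% stop_chars) break
      out <- c(out, b)
    }
    rawToChar(out)
  }
  hdr <- strsplit(trimws(read_until("\n")), "\\s+")[[1L]]
  if (length(hdr) != 2L || anyNA(suppressWarnings(as.integer(hdr)))) {
    stop("word2vec binary file '", path, "': malformed header")
  }
  n <- as.integer(hdr[1L]); d <- as.integer(hdr[2L])
  words <- character(n)
  vectors <- matrix(NA_real_, n, d)
  for (i in seq_len(n)) {
    words[i] <- sub("^\n", "", read_until(" "))
    vec <- readBin(con, "numeric", n = d, size = 4L, endian = "little")
    if (length(vec) != d) {
      stop("word2vec binary file '", path, "': truncated vector for word ", i)
    }
    vectors[i, ] <- vec
  }
  list(words = words, vectors = vectors)
}

# ---- phase 1: unsupervised pretraining -----------------------------------

#' Pretrain the encoder on masked drug-name prediction
#'
#' Trains the bi-LSTM encoder plus a pooled softmax head to predict which
#' drug was masked out of each tweet, by mini-batch adam over shuffled
#' epochs. Fully reproducible given the seed in `train`.
#'
#' @param examples List of `adr_masked_example`s (see [mask_corpus()]);
#'   needs at least two distinct target drugs.
#' @param vocab An `adr_vocabulary`.
#' @param cfg An [model_config()]; its `token_vocab_size` and
#'   `drug_vocab_size` are set from `vocab` and the examples.
#' @param train An [train_config()].
#' @param max_len Maximum sequence length; default [choose_max_len()] of the
#'   examples.
#' @return An `adr_pretrained` object: the trained `encoder`, the
#'   `drug_head`, the sorted `drugs` factor levels, `max_len`, and a
#'   per-epoch `log` (mean loss and training accuracy).
#' @export
pretrain <- function(examples, vocab, cfg, train = train_config(),
                     max_len = NULL) {
  stopifnot(length(examples) >= 1L)
  drugs <- sort(unique(vapply(examples, `[[`, character(1L), "target_drug")))
  if (length(drugs) < 2L) {
    stop("pretraining needs at least two distinct target drugs; got ",
         length(drugs))
  }
  if (is.null(max_len)) max_len <- choose_max_len(examples)
  set.seed(train$seed)
  cfg$token_vocab_size <- vocab_size(vocab)
  cfg$drug_vocab_size <- length(drugs)
  E <- init_embeddings(vocab, train$embedding_init, cfg$embed_dim)
  enc <- init_encoder(cfg, embeddings = E)
  head <- init_drug_head(cfg)

  N <- length(examples)
  idx_all <- vapply(examples, function(ex) {
    encode_tokens(ex$masked_tokens, vocab, max_len)
  }, integer(max_len))
  idx_all <- matrix(idx_all, nrow = max_len)  # T x N
  targets <- match(vapply(examples, `[[`, character(1L), "target_drug"), drugs)

  params <- .bundle(enc, head)
  opt <- adam_init(params)
  log <- data.frame(epoch = integer(), loss = numeric(), accuracy = numeric())
  n_batches <- ceiling(N / train$phase1$batch_size)
  for (epoch in seq_len(train$phase1$epochs)) {
    perm <- sample.int(N)
    losses <- numeric(n_batches); accs <- numeric(n_batches)
    for (b in seq_len(n_batches)) {
      take <- perm[(((b - 1L) * train$phase1$batch_size) + 1L):
                     min(b * train$phase1$batch_size, N)]
      st <- .unbundle(params, enc)
      res <- .phase1_batch(idx_all[, take, drop = FALSE], targets[take],
                           st$enc, st$head)
      step <- adam_step(opt, params, .clip_grads(res$grads, train$clip_norm),
                        lr = train$phase1$lr)
      opt <- step$opt; params <- step$params
      losses[b] <- res$loss; accs[b] <- res$acc
    }
    log <- rbind(log, data.frame(epoch = epoch, loss = mean(losses),
                                 accuracy = mean(accs)))
  }
  st <- .unbundle(params, enc)
  structure(list(encoder = st$enc, drug_head = st$head, drugs = drugs,
                 vocab = vocab, max_len = max_len, log = log,
                 train = train),
            class = "adr_pretrained")
}

#' Drug-prediction accuracy of a pretrained model
#'
#' Fraction of masked examples whose target drug gets the highest predicted
#' probability under the final weights.
#'
#' @param pretrained An `adr_pretrained`.
#' @param examples List of `adr_masked_example`s.
#' @return Accuracy in `[0, 1]`.
#' @export
drug_accuracy <- function(pretrained, examples) {
  hits <- vapply(examples, function(ex) {
    idx <- encode_tokens(ex$masked_tokens, pretrained$vocab, pretrained$max_len)
    p <- drug_forward(idx, pretrained$encoder, pretrained$drug_head)
    pretrained$drugs[which.max(p)] == ex$target_drug
  }, logical(1L))
  mean(hits)
}

#' @export
print.adr_pretrained <- function(x, ...) {
  cat("<adr_pretrained> ", length(x$drugs), " drugs, max_len ", x$max_len,
      ", ", nrow(x$log), " epochs", sep = "")
  if (nrow(x$log) > 0L) {
    cat(sprintf(", final loss %.4f (train acc %.3f)",
                x$log$loss[nrow(x$log)], x$log$accuracy[nrow(x$log)]))
  }
  cat("\n")
  invisible(x)
}

# ---- phase 2: supervised fine-tuning -------------------------------------

#' Encode a labeled document for the tagger
#'
#' Produces the index/tag record consumed by [finetune()] and
#' [evaluate_tagger()].
#'
#' @param doc An `adr_document`.
#' @param spans Entity spans for the document (see
#'   [align_char_spans_to_tokens()]).
#' @param vocab An `adr_vocabulary`.
#' @param max_len Encoded sequence length.
#' @return List with `doc_id`, `indices` (length `max_len`), `tags`
#'   (length `max_len`, `<PAD>`-padded) and `n_tokens`.
#' @export
encode_labeled <- function(doc, spans, vocab, max_len) {
  tags <- spans_to_tags(spans, length(doc$tokens))
  list(doc_id = doc$doc_id,
       indices = encode_tokens(doc$tokens, vocab, max_len),
       tags = encode_tags(tags, max_len),
       n_tokens = min(length(doc$tokens), max_len))
}

#' Fine-tune a tagger on labeled documents
#'
#' Trains the per-token IO tag classifier by per-example (batch size 1) adam
#' updates of the summed cross-entropy loss. When `encoder` is supplied the
#' shared encoder weights are transferred from phase 1 and all of them keep
#' training; when it is `NULL` the model trains from scratch (the comparison
#' baseline).
#'
#' @param records List of encoded labeled records from [encode_labeled()].
#' @param vocab An `adr_vocabulary`.
#' @param cfg An [model_config()].
#' @param train An [train_config()].
#' @param encoder Optional pretrained `adr_encoder` (or an `adr_pretrained`,
#'   whose encoder is taken); `NULL` trains from scratch.
#' @return An `adr_tagger`: `encoder`, `tag_head`, `max_len` and a
#'   per-epoch `log` of mean loss.
#' @export
finetune <- function(records, vocab, cfg, train = train_config(),
                     encoder = NULL) {
  stopifnot(length(records) >= 1L)
  max_len <- length(records[[1L]]$indices)
  if (inherits(encoder, "adr_pretrained")) encoder <- encoder$encoder
  set.seed(train$seed)
  cfg$token_vocab_size <- vocab_size(vocab)
  if (is.null(encoder)) {
    E <- init_embeddings(vocab, train$embedding_init, cfg$embed_dim)
    enc <- init_encoder(cfg, embeddings = E)
  } else {
    enc <- transfer_encoder(encoder, cfg)
  }
  head <- init_tag_head(enc$config)
  if (!any(vapply(records, function(r) any(r$tags %in% names(.tag_to_label)),
                  logical(1L)))) {
    warning("labeled corpus contains no entity tags; span metrics on it ",
            "will be undefined")
  }
  N <- length(records)
  params <- .bundle(enc, head)
  opt <- adam_init(params)
  log <- data.frame(epoch = integer(), loss = numeric())
  for (epoch in seq_len(train$phase2$epochs)) {
    perm <- sample.int(N)
    losses <- numeric(N)
    for (k in seq_len(N)) {
      r <- records[[perm[k]]]
      st <- .unbundle(params, enc)
      res <- .phase2_example(r$indices, r$tags, st$enc, st$head)
      step <- adam_step(opt, params, .clip_grads(res$grads, train$clip_norm),
                        lr = train$phase2$lr)
      opt <- step$opt; params <- step$params
      losses[k] <- res$loss
    }
    log <- rbind(log, data.frame(epoch = epoch, loss = mean(losses)))
  }
  st <- .unbundle(params, enc)
  structure(list(encoder = st$enc, tag_head = st$head, max_len = max_len,
                 log = log, train = train),
            class = "adr_tagger")
}

#' @export
print.adr_tagger <- function(x, ...) {
  cat("<adr_tagger> max_len ", x$max_len, ", ", nrow(x$log), " epochs",
      sep = "")
  if (nrow(x$log) > 0L) {
    cat(sprintf(", final mean loss %.4f", x$log$loss[nrow(x$log)]))
  }
  cat("\n")
  invisible(x)
}

#' Predict IO tags for an encoded sequence
#'
#' Argmax decoding of [tag_forward()]. Padding positions get the `<PAD>`
#' tag; real tokens are decoded over the three content tags (the padding
#' category describes padding tokens only).
#'
#' @param tagger An `adr_tagger`.
#' @param indices Integer vector of 0-based token indices.
#' @return Character tag vector of the same length.
#' @export
predict_tags <- function(tagger, indices) {
  probs <- tag_forward(indices, tagger$encoder, tagger$tag_head)
  content <- probs[, 1:3, drop = FALSE]
  tags <- tag_set()[max.col(content, ties.method = "first")]
  tags[indices == 0L] <- PAD_TOK
  tags
}
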