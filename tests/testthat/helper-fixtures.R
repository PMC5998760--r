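# Shared fixtures: tiny model configurations and hand-built corpora.

tiny_model <- function(vocab_n = 12L, drugs = 3L, embed = 3L, hidden = 2L) {
  model_config(token_vocab_size = vocab_n, drug_vocab_size = drugs,
               embed_dim = embed, hidden_dim = hidden)
}

# A deterministic toy vocabulary: tokens t01..t20 at indices 5..24.
toy_vocab <- function(n = 20L) {
  docs <- lapply(seq_len(n), function(i) sprintf("t%02d", seq_len(i)))
  # token t01 occurs n times, t02 n-1 times, ... frequency-ranked as built
  build_vocabulary(docs, max_size = n)
}

# Entity-span data frame helper.
spans_df <- function(doc_id, label, starts, ends) {
  data.frame(doc_id = doc_id, label = label, token_start = starts,
             token_end = ends, stringsAsFactors = FALSE)
}

# Brute-force approximate matcher used as an independent oracle: all-pairs
# token-set intersection per document.
oracle_match <- function(pred, gold, label = "ADR",
                         precision_numerator = "per_prediction") {
  pred <- pred[pred$label == label, , drop = FALSE]
  gold <- gold[gold$label == label, , drop = FALSE]
  toks <- function(s, e) seq(s, e - 1L)
  p_hit <- logical(nrow(pred))
  g_hit <- logical(nrow(gold))
  pair_hits <- matrix(FALSE, nrow(pred), nrow(gold))
  for (i in seq_len(nrow(pred))) for (j in seq_len(nrow(gold))) {
    if (pred$doc_id[i] == gold$doc_id[j] &&
        length(intersect(toks(pred$token_start[i], pred$token_end[i]),
                         toks(gold$token_start[j], gold$token_end[j]))) > 0) {
      p_hit[i] <- TRUE; g_hit[j] <- TRUE; pair_hits[i, j] <- TRUE
    }
  }
  n_pred_matched <- if (precision_numerator == "per_prediction") sum(p_hit)
    else sum(g_hit)
  P <- if (nrow(pred) > 0) n_pred_matched / nrow(pred) else 0
  R <- if (nrow(gold) > 0) sum(g_hit) / nrow(gold) else 0
  F1 <- if (P + R > 0) 2 * P * R / (P + R) else 0
  list(precision = P, recall = R, f1 = F1,
       n_pred_matched = n_pred_matched, n_true_matched = sum(g_hit))
}

# Random span tables over n_docs documents for oracle comparisons.
random_spans <- function(n_docs, max_spans = 3L, max_tok = 12L,
                         labels = c("ADR", "Indication")) {
  out <- list()
  for (d in seq_len(n_docs)) {
    k <- sample(0:max_spans, 1L)
    if (k == 0L) next
    for (i in seq_len(k)) {
      s <- sample(0:(max_tok - 1L), 1L)
      e <- s + sample(1:3, 1L)
      out[[length(out) + 1L]] <- spans_df(sprintf("d%03d", d),
                                          sample(labels, 1L), s, e)
    }
  }
  if (length(out) == 0L) return(spans_df(character(), character(),
                                         integer(), integer()))
  do.call(rbind, out)
}

# Interval-union reference for the IO round trip.
merge_ref <- function(spans, n_tokens) {
  covered <- list(ADR = rep(FALSE, n_tokens),
                  Indication = rep(FALSE, n_tokens))
  for (i in seq_len(nrow(spans))) {
    lab <- spans$label[i]
    covered[[lab]][(spans$token_start[i] + 1L):spans$token_end[i]] <- TRUE
  }
  covered$Indication <- covered$Indication & !covered$ADR  # ADR wins
  out <- list()
  for (lab in c("ADR", "Indication")) {
    r <- rle(covered[[lab]])
    ends <- cumsum(r$lengths); starts <- ends - r$lengths
    for (k in which(r$values)) {
      out[[length(out) + 1L]] <- data.frame(label = lab,
                                            token_start = starts[k],
                                            token_end = ends[k],
                                            stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L) {
    return(data.frame(label = character(), token_start = integer(),
                      token_end = integer(), stringsAsFactors = FALSE))
  }
  df <- do.call(rbind, out)
  df <- df[order(df$token_start, df$token_end, df$label), , drop = FALSE]
  rownames(df) <- NULL
  df
}

sort_spans <- function(df) {
  df <- df[order(df$token_start, df$token_end, df$label), , drop = FALSE]
  rownames(df) <- NULL
  df
}
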