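# Approximate span-match evaluation: a predicted span counts as correct if
# it overlaps at least one gold span of the same label. Precision and recall
# use different numerators (predicted-side vs gold-side overlap counts); the
# symmetric reading would not be bounded by its denominator. Counts are
# micro-aggregated over documents.

#' Do two entity spans overlap?
#'
#' Half-open token intervals overlap iff `max(starts) < min(ends)`; labels
#' must agree. Adjacent spans (one ending where the other starts) do not
#' overlap.
#'
#' @param a,b Lists or one-row data frames with `token_start`, `token_end`
#'   and `label`.
#' @return Logical.
#' @export
overlaps <- function(a, b) {
  a$label == b$label &&
    max(a$token_start, b$token_start) < min(a$token_end, b$token_end)
}

.span_df <- function(x) {
  need <- c("doc_id", "label", "token_start", "token_end")
  if (is.null(x) || nrow(x) == 0L) {
    return(data.frame(doc_id = character(), label = character(),
                      token_start = integer(), token_end = integer(),
                      stringsAsFactors = FALSE))
  }
  missing <- setdiff(need, names(x))
  if (length(missing) > 0L) {
    stop("span table lacks column(s): ", paste(missing, collapse = ", "))
  }
  x[need]
}

#' Approximate span matching over a corpus
#'
#' Scores predicted against gold entity spans with approximate (overlap)
#' matching for one label. The precision numerator counts predicted spans
#' that overlap at least one gold span; the recall numerator counts gold
#' spans overlapped by at least one predicted span; both are summed over
#' documents before dividing (micro-aggregation). With
#' `precision_numerator = "unique_gold"` the precision numerator instead
#' counts distinct gold spans hit, so several predictions on one gold span
#' are credited once.
#'
#' @param pred,gold Data frames of spans with columns `doc_id`, `label`,
#'   `token_start`, `token_end` (0-based half-open token intervals).
#' @param label The label to score (default `"ADR"`).
#' @param precision_numerator `"per_prediction"` (default) or
#'   `"unique_gold"`.
#' @return An `adr_match_result`: counts `n_pred`, `n_true`,
#'   `n_pred_matched`, `n_true_matched` and `precision`, `recall`, `f1`.
#'   Zero predicted spans give precision 0 with a warning; zero gold spans
#'   give recall 0 with a warning; F1 is 0 when P + R = 0.
#' @export
approximate_match <- function(pred, gold, label = "ADR",
                              precision_numerator = c("per_prediction",
                                                      "unique_gold")) {
  precision_numerator <- match.arg(precision_numerator)
  pred <- .span_df(pred); gold <- .span_df(gold)
  pred <- pred[pred$label == label, , drop = FALSE]
  gold <- gold[gold$label == label, , drop = FALSE]
  n_pred <- nrow(pred); n_true <- nrow(gold)
  n_pred_matched <- 0L; n_true_matched <- 0L
  for (id in unique(c(pred$doc_id, gold$doc_id))) {
    p <- pred[pred$doc_id == id, , drop = FALSE]
    g <- gold[gold$doc_id == id, , drop = FALSE]
    if (nrow(p) == 0L || nrow(g) == 0L) next
    hit <- outer(seq_len(nrow(p)), seq_len(nrow(g)),
                 Vectorize(function(i, j) {
                   max(p$token_start[i], g$token_start[j]) <
                     min(p$token_end[i], g$token_end[j])
                 }))
    g_hit <- colSums(hit) > 0L
    n_true_matched <- n_true_matched + sum(g_hit)
    n_pred_matched <- n_pred_matched +
      if (precision_numerator == "per_prediction") sum(rowSums(hit) > 0L)
      else sum(g_hit)
  }
  if (n_pred == 0L) {
    warning("no predicted '", label, "' spans; precision set to 0")
    precision <- 0
  } else precision <- n_pred_matched / n_pred
  if (n_true == 0L) {
    warning("no gold '", label, "' spans; recall set to 0")
    recall <- 0
  } else recall <- n_true_matched / n_true
  f1 <- if (precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else 0
  structure(list(label = label, n_pred = n_pred, n_true = n_true,
                 n_pred_matched = as.integer(n_pred_matched),
                 n_true_matched = as.integer(n_true_matched),
                 precision = precision, recall = recall, f1 = f1,
                 precision_numerator = precision_numerator),
            class = "adr_match_result")
}

#' @export
print.adr_match_result <- function(x, ...) {
  cat(sprintf(paste0("<adr_match_result> %s: P %.3f (%d/%d)  R %.3f (%d/%d)",
                     "  F1 %.3f\n"),
              x$label, x$precision, x$n_pred_matched, x$n_pred,
              x$recall, x$n_true_matched, x$n_true, x$f1))
  invisible(x)
}

#' Score exact span matches (reference scorer)
#'
#' Strict counterpart of [approximate_match()]: a predicted span is correct
#' only if it equals a gold span exactly. Provided as a reference; exact
#' scores can never exceed approximate scores on the same input.
#'
#' @inheritParams approximate_match
#' @return An `adr_match_result`.
#' @export
exact_match <- function(pred, gold, label = "ADR") {
  pred <- .span_df(pred); gold <- .span_df(gold)
  pred <- pred[pred$label == label, , drop = FALSE]
  gold <- gold[gold$label == label, , drop = FALSE]
  key <- function(d) paste(d$doc_id, d$token_start, d$token_end)
  n_pred <- nrow(pred); n_true <- nrow(gold)
  n_pred_matched <- sum(key(pred) %in% key(gold))
  n_true_matched <- sum(key(gold) %in% key(pred))
  precision <- if (n_pred > 0L) n_pred_matched / n_pred else 0
  recall <- if (n_true > 0L) n_true_matched / n_true else 0
  f1 <- if (precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else 0
  structure(list(label = label, n_pred = n_pred, n_true = n_true,
                 n_pred_matched = as.integer(n_pred_matched),
                 n_true_matched = as.integer(n_true_matched),
                 precision = precision, recall = recall, f1 = f1,
                 precision_numerator = "exact"),
            class = "adr_match_result")
}

#' Decode and score a tagger on an encoded corpus
#'
#' Argmax-decodes tags for every record, reconstructs entity spans and
#' scores them with approximate matching. The headline metric is the ADR
#' label; Indication is scored separately and reported alongside.
#'
#' @param tagger An `adr_tagger` from [finetune()].
#' @param records Encoded labeled records (see [encode_labeled()]).
#' @param ... Passed to [approximate_match()] (e.g.
#'   `precision_numerator`).
#' @return An `adr_evaluation`: `adr` and `indication` match results plus
#'   per-document predicted and gold span tables.
#' @export
evaluate_tagger <- function(tagger, records, ...) {
  pred_all <- list(); gold_all <- list()
  for (r in records) {
    pred_tags <- predict_tags(tagger, r$indices)
    ps <- tags_to_spans(pred_tags)
    gs <- tags_to_spans(r$tags)
    if (nrow(ps) > 0L) ps <- cbind(doc_id = r$doc_id, ps)
    if (nrow(gs) > 0L) gs <- cbind(doc_id = r$doc_id, gs)
    pred_all[[length(pred_all) + 1L]] <- ps
    gold_all[[length(gold_all) + 1L]] <- gs
  }
  pred <- do.call(rbind, pred_all[vapply(pred_all, nrow, integer(1L)) > 0L])
  gold <- do.call(rbind, gold_all[vapply(gold_all, nrow, integer(1L)) > 0L])
  adr <- suppressWarnings(approximate_match(pred, gold, label = "ADR", ...))
  ind <- suppressWarnings(approximate_match(pred, gold, label = "Indication",
                                            ...))
  structure(list(adr = adr, indication = ind, pred = .span_df(pred),
                 gold = .span_df(gold)),
            class = "adr_evaluation")
}

#' @export
print.adr_evaluation <- function(x, ...) {
  cat("ADR (headline):       "); print(x$adr)
  cat("Indication (aside):   "); print(x$indication)
  invisible(x)
}

#' Paired t-test over per-seed F1 scores
#'
#' Utility mirroring the significance protocol used to compare methods over
#' repeated trials: a standard paired t-test over per-seed metric pairs.
#' Degenerate cases are handled explicitly: identical vectors give t = 0,
#' p = 1; a constant non-zero difference has zero variance, reported as
#' t = +/-Inf, p = 0.
#'
#' @param f1s_a,f1s_b Equal-length numeric vectors (length >= 2), paired by
#'   seed.
#' @return List with `t`, `p_value`, `mean_diff` (a minus b) and `n`.
#' @export
paired_seed_comparison <- function(f1s_a, f1s_b) {
  if (length(f1s_a) != length(f1s_b)) {
    stop("paired comparison requires equal-length vectors")
  }
  if (length(f1s_a) < 2L) stop("need at least two pairs")
  d <- f1s_a - f1s_b
  if (stats::sd(d) == 0) {
    if (mean(d) == 0) return(list(t = 0, p_value = 1, mean_diff = 0,
                                  n = length(d)))
    return(list(t = sign(mean(d)) * Inf, p_value = 0, mean_diff = mean(d),
                n = length(d)))
  }
  tt <- stats::t.test(f1s_a, f1s_b, paired = TRUE)
  list(t = unname(tt$statistic), p_value = tt$p.value,
       mean_diff = unname(tt$estimate), n = length(d))
}
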