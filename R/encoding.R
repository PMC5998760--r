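# IO tag encoding: character-offset annotations <-> per-token tag sequences
# <-> entity spans. The tag set is exactly {I-ADR, I-Indication, O, <PAD>}.

#' IO tag set
#'
#' The four per-token categories of the IO scheme: inside an ADR mention,
#' inside an Indication mention, outside any mention, or padding. Because IO
#' has no Begin tag, adjacent mentions with the same label merge into one
#' span by construction.
#'
#' @return Character vector of the four tags, in model output order.
#' @export
tag_set <- function() c("I-ADR", "I-Indication", "O", PAD_TOK)

.label_to_tag <- c(ADR = "I-ADR", Indication = "I-Indication")
.tag_to_label <- c("I-ADR" = "ADR", "I-Indication" = "Indication")

.empty_spans <- function() {
  data.frame(label = character(), token_start = integer(),
             token_end = integer(), stringsAsFactors = FALSE)
}

#' Align character-offset annotations to tokens
#'
#' A token belongs to an annotation iff its character interval overlaps the
#' annotation interval; runs of adjacent same-label tokens merge into one
#' entity span. Annotations that overlap no token are dropped with a warning.
#'
#' @param doc An `adr_document`.
#' @param char_spans Data frame with columns `start`, `end`, `label`
#'   (`ADR` or `Indication`), offsets 0-based half-open. By default they
#'   refer to the document's normalized text; set `offsets = "raw"` if they
#'   refer to the raw text the document was built from.
#' @param offsets Which text the offsets index: `"normalized"` or `"raw"`.
#' @return Data frame of entity spans: `label`, `token_start`, `token_end`
#'   (0-based half-open token indices).
#' @export
align_char_spans_to_tokens <- function(doc, char_spans,
                                       offsets = c("normalized", "raw")) {
  offsets <- match.arg(offsets)
  tok_iv <- if (offsets == "raw") doc$raw_spans else doc$char_spans
  n_tok <- length(doc$tokens)
  out <- .empty_spans()
  if (is.null(char_spans) || nrow(char_spans) == 0L) return(out)
  for (k in seq_len(nrow(char_spans))) {
    a <- char_spans$start[k]; b <- char_spans$end[k]
    hit <- which(pmax(tok_iv[, 1L], a) < pmin(tok_iv[, 2L], b))
    if (length(hit) == 0L) {
      warning("annotation [", a, ",", b, ") '", char_spans$label[k],
              "' in document ", doc$doc_id, " overlaps no token; dropped")
      next
    }
    out <- rbind(out, data.frame(label = as.character(char_spans$label[k]),
                                 token_start = min(hit) - 1L,
                                 token_end = max(hit),
                                 stringsAsFactors = FALSE))
  }
  merge_entity_spans(out, n_tok)
}

# Interval-union merge of same-label spans that touch or overlap; the
# reference semantics for the IO round trip.
merge_entity_spans <- function(spans, n_tokens = NULL) {
  if (nrow(spans) == 0L) return(.empty_spans())
  out <- .empty_spans()
  for (lab in unique(spans$label)) {
    s <- spans[spans$label == lab, , drop = FALSE]
    s <- s[order(s$token_start, s$token_end), , drop = FALSE]
    cs <- s$token_start[1L]; ce <- s$token_end[1L]
    for (i in seq_len(nrow(s))[-1L]) {
      if (s$token_start[i] <= ce) ce <- max(ce, s$token_end[i])
      else {
        out <- rbind(out, data.frame(label = lab, token_start = cs,
                                     token_end = ce, stringsAsFactors = FALSE))
        cs <- s$token_start[i]; ce <- s$token_end[i]
      }
    }
    out <- rbind(out, data.frame(label = lab, token_start = cs,
                                 token_end = ce, stringsAsFactors = FALSE))
  }
  out <- out[order(out$token_start, out$token_end, out$label), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Convert entity spans to an IO tag sequence
#'
#' Tokens inside an ADR span get `I-ADR`, inside an Indication span
#' `I-Indication`, all others `O`. When spans of both labels cover the same
#' token, ADR wins (ADR is the evaluated class).
#'
#' @param spans Data frame with `label`, `token_start`, `token_end`
#'   (0-based half-open token indices within `[0, n_tokens)`).
#' @param n_tokens Number of tokens in the sequence.
#' @return Character vector of length `n_tokens` over [tag_set()] (no
#'   padding tags; padding is added by [encode_tags()]).
#' @export
spans_to_tags <- function(spans, n_tokens) {
  tags <- rep("O", n_tokens)
  if (nrow(spans) == 0L) return(tags)
  if (any(spans$token_start < 0L) || any(spans$token_end > n_tokens) ||
      any(spans$token_start >= spans$token_end)) {
    stop("entity span out of range for a sequence of ", n_tokens, " tokens")
  }
  for (lab in c("Indication", "ADR")) {  # ADR last so it overrides
    s <- spans[spans$label == lab, , drop = FALSE]
    for (i in seq_len(nrow(s))) {
      tags[(s$token_start[i] + 1L):s$token_end[i]] <- .label_to_tag[[lab]]
    }
  }
  tags
}

#' Recover entity spans from an IO tag sequence
#'
#' Maximal runs of identical `I-*` tags become one span each; `O` and
#' padding tags separate runs. Under IO encoding adjacent same-label
#' mentions are indistinguishable from one long mention, by design.
#'
#' @param tags Character vector over [tag_set()].
#' @return Data frame of entity spans (`label`, `token_start`, `token_end`).
#' @export
tags_to_spans <- function(tags) {
  if (length(tags) == 0L) return(.empty_spans())
  r <- rle(tags)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- r$values %in% names(.tag_to_label)
  data.frame(label = unname(.tag_to_label[r$values[keep]]),
             token_start = starts[keep],
             token_end = ends[keep],
             stringsAsFactors = FALSE)
}

#' Pad or truncate a tag sequence to the encoded length
#'
#' Companion to [encode_tokens()]: pads with the `<PAD>` tag to `max_len`
#' and truncates longer sequences.
#'
#' @param tags Character tag vector.
#' @param max_len Target length.
#' @return Character vector of length `max_len`; `<PAD>` never precedes a
#'   non-`<PAD>` tag.
#' @export
encode_tags <- function(tags, max_len) {
  if (length(tags) > max_len) tags <- tags[seq_len(max_len)]
  c(tags, rep(PAD_TOK, max_len - length(tags)))
}
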