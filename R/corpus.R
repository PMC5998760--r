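# Text normalization, tokenization, vocabulary and drug-lexicon handling for
# tweet-style input. All character offsets in this package are 0-based,
# half-open [start, end).

#' Special tokens
#'
#' Reserved tokens used throughout the package: `PAD_TOK` (sequence padding,
#' always vocabulary index 0), `UNK_TOK` (out-of-vocabulary), `DRUG_TOK`
#' (dummy token substituted for a masked drug mention), `LINK_TOK`
#' (normalized URL) and `USER_TOK` (normalized user handle).
#'
#' @format Length-one character constants.
#' @name special-tokens
#' @aliases PAD_TOK UNK_TOK DRUG_TOK LINK_TOK USER_TOK
NULL

#' @export
PAD_TOK <- "<PAD>"
#' @export
UNK_TOK <- "<UNK>"
#' @export
DRUG_TOK <- "<DRUG>"
#' @export
LINK_TOK <- "<LINK>"
#' @export
USER_TOK <- "<USER>"

special_tokens <- function() c(PAD_TOK, UNK_TOK, DRUG_TOK, LINK_TOK, USER_TOK)

.re_url <- "https?://|www\\."

# Classify and clean one whitespace-delimited raw chunk. Returns the emitted
# token ("" if the chunk vanishes) plus the 0-based half-open interval of the
# raw characters it came from.
.clean_chunk <- function(chunk, chunk_start) {
  n <- nchar(chunk)
  if (chunk %in% c(DRUG_TOK, LINK_TOK, USER_TOK, PAD_TOK, UNK_TOK)) {
    return(list(token = chunk, start = chunk_start, end = chunk_start + n))
  }
  if (grepl(.re_url, chunk, ignore.case = TRUE)) {
    return(list(token = LINK_TOK, start = chunk_start, end = chunk_start + n))
  }
  if (startsWith(chunk, "@") && n > 1L) {
    return(list(token = USER_TOK, start = chunk_start, end = chunk_start + n))
  }
  # keep ASCII letters and digits only: strips punctuation, '#', and all
  # non-ASCII characters (emoticons); lower-case the survivors
  chars <- strsplit(chunk, "", fixed = TRUE)[[1L]]
  keep <- grepl("[A-Za-z0-9]", chars)
  if (!any(keep)) {
    return(list(token = "", start = chunk_start, end = chunk_start))
  }
  idx <- which(keep)
  token <- tolower(paste0(chars[idx], collapse = ""))
  list(token = token,
       start = chunk_start + idx[1L] - 1L,
       end = chunk_start + idx[length(idx)])
}

# Scan a raw string into normalized tokens, keeping for every token the raw
# character interval it derives from (needed to carry raw-offset annotations
# through normalization).
.scan_raw <- function(raw) {
  m <- gregexpr("\\S+", raw)[[1L]]
  if (m[1L] == -1L) {
    return(list(tokens = character(), raw_spans = matrix(integer(), 0L, 2L)))
  }
  chunks <- regmatches(raw, gregexpr("\\S+", raw))[[1L]]
  starts <- as.integer(m) - 1L  # 0-based
  tokens <- character(0L)
  spans <- matrix(integer(), 0L, 2L)
  for (i in seq_along(chunks)) {
    cl <- .clean_chunk(chunks[i], starts[i])
    if (nzchar(cl$token)) {
      tokens <- c(tokens, cl$token)
      spans <- rbind(spans, c(cl$start, cl$end))
    }
  }
  list(tokens = tokens, raw_spans = spans)
}

#' Normalize tweet-style text
#'
#' Applies the preprocessing used for both the unlabeled and the annotated
#' corpus: URLs are replaced by [LINK_TOK], user handles (`@name`) by
#' [USER_TOK], punctuation and `#` are removed, non-ASCII characters
#' (emoticons) are dropped, the text is lower-cased and whitespace is
#' collapsed to single spaces. Existing special tokens are preserved, so the
#' function is idempotent.
#'
#' @param raw A character vector of raw documents.
#' @return A character vector of normalized text (possibly empty strings).
#' @examples
#' normalize_text("Check http://t.co/abc @JonDoe #fun!")
#' @export
normalize_text <- function(raw) {
  vapply(raw, function(x) paste(.scan_raw(x)$tokens, collapse = " "),
         character(1L), USE.NAMES = FALSE)
}

#' Tokenize normalized text
#'
#' Whitespace tokenization of already-normalized text. Special tokens such as
#' `<DRUG>` are kept intact. Character spans index into the normalized string,
#' 0-based and half-open.
#'
#' @param text A single normalized string (see [normalize_text()]).
#' @return A list with `tokens` (character vector) and `char_spans`
#'   (integer matrix with columns `start`, `end`).
#' @export
tokenize <- function(text) {
  stopifnot(length(text) == 1L)
  m <- gregexpr("\\S+", text)[[1L]]
  if (m[1L] == -1L) {
    return(list(tokens = character(),
                char_spans = matrix(integer(), 0L, 2L,
                                    dimnames = list(NULL, c("start", "end")))))
  }
  tokens <- regmatches(text, gregexpr("\\S+", text))[[1L]]
  starts <- as.integer(m) - 1L
  ends <- starts + attr(m, "match.length")
  list(tokens = tokens,
       char_spans = cbind(start = starts, end = ends))
}

#' Build a tokenized document from raw text
#'
#' Normalizes and tokenizes a raw document while tracking, for every token,
#' the interval of raw characters it came from. The raw spans make it
#' possible to align annotations whose offsets refer to the raw text.
#'
#' @param doc_id Document identifier (unique within a corpus).
#' @param raw Raw UTF-8 text.
#' @return An object of class `adr_document`: a list with `doc_id`, `text`
#'   (normalized), `tokens`, `char_spans` (offsets into the normalized text)
#'   and `raw_spans` (offsets into the raw text), all 0-based half-open.
#' @export
as_document <- function(doc_id, raw) {
  sc <- .scan_raw(raw)
  text <- paste(sc$tokens, collapse = " ")
  tk <- tokenize(text)
  structure(list(doc_id = as.character(doc_id),
                 text = text,
                 tokens = tk$tokens,
                 char_spans = tk$char_spans,
                 raw_spans = sc$raw_spans),
            class = "adr_document")
}

#' @export
print.adr_document <- function(x, ...) {
  cat("<adr_document> ", x$doc_id, ": ", x$text, "\n", sep = "")
  invisible(x)
}

#' Read a drug-name lexicon
#'
#' Reads a plain-text lexicon, one drug name per line; `#` starts a comment.
#' Names are normalized and tokenized exactly like documents, so multi-token
#' names (e.g. "zoledronic acid") are supported.
#'
#' @param path Path to the lexicon file.
#' @return An `adr_lexicon` object.
#' @export
read_lexicon <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  as_lexicon(lines[nzchar(lines)])
}

#' Create a drug lexicon from a character vector
#'
#' @param names Character vector of drug names (may be multi-word).
#' @return An `adr_lexicon`: normalized token sequences supporting
#'   left-to-right longest-match lookup via [find_drug_mentions()].
#' @export
as_lexicon <- function(names) {
  toks <- lapply(names, function(x) .scan_raw(x)$tokens)
  keep <- lengths(toks) > 0L
  toks <- toks[keep]
  keys <- vapply(toks, paste, character(1L), collapse = " ")
  dup <- duplicated(keys)
  toks <- toks[!dup]
  keys <- keys[!dup]
  if (length(keys) == 0L) stop("lexicon contains no usable entries")
  structure(list(entries = toks,
                 keys = keys,
                 key_set = as.list(stats::setNames(seq_along(keys), keys)),
                 max_len = max(lengths(toks))),
            class = "adr_lexicon")
}

#' @export
print.adr_lexicon <- function(x, ...) {
  cat("<adr_lexicon> ", length(x$keys), " entries, longest ",
      x$max_len, " token(s)\n", sep = "")
  invisible(x)
}

#' Find drug mentions in a tokenized document
#'
#' Scans the token sequence left to right and matches lexicon entries
#' case-insensitively and exactly, preferring the longest match at each
#' position; matched spans never overlap.
#'
#' @param doc An `adr_document` (or any list with a `tokens` element).
#' @param lex An `adr_lexicon`.
#' @return A data frame with 0-based half-open token intervals
#'   (`token_start`, `token_end`) and the canonical lexicon entry (`drug`).
#' @export
find_drug_mentions <- function(doc, lex) {
  stopifnot(inherits(lex, "adr_lexicon"))
  tokens <- tolower(doc$tokens)
  n <- length(tokens)
  starts <- integer(0L); ends <- integer(0L); drugs <- character(0L)
  i <- 1L
  while (i <= n) {
    hit <- 0L
    for (len in seq(min(lex$max_len, n - i + 1L), 1L)) {
      key <- paste(tokens[i:(i + len - 1L)], collapse = " ")
      if (!is.null(lex$key_set[[key]])) { hit <- len; break }
    }
    if (hit > 0L) {
      starts <- c(starts, i - 1L)
      ends <- c(ends, i - 1L + hit)
      drugs <- c(drugs, paste(tokens[i:(i + hit - 1L)], collapse = " "))
      i <- i + hit
    } else {
      i <- i + 1L
    }
  }
  data.frame(token_start = starts, token_end = ends, drug = drugs,
             stringsAsFactors = FALSE)
}

#' Keep only documents mentioning exactly one drug
#'
#' Retains documents whose [find_drug_mentions()] result contains exactly one
#' span. A document mentioning the same drug twice has two mentions and is
#' dropped.
#'
#' @param corpus A list of `adr_document`s.
#' @param lex An `adr_lexicon`.
#' @return The filtered list.
#' @export
filter_single_drug <- function(corpus, lex) {
  keep <- vapply(corpus, function(d) nrow(find_drug_mentions(d, lex)) == 1L,
                 logical(1L))
  corpus[keep]
}

#' Mask the single drug mention of a document
#'
#' Replaces the tokens of the (single) matched drug span by one [DRUG_TOK]
#' and records the canonical drug name as the prediction target. Multi-token
#' drug names collapse to a single dummy token, so the sequence may shrink.
#'
#' @param doc An `adr_document`.
#' @param spans The result of [find_drug_mentions()] for `doc`; must contain
#'   exactly one row (filter with [filter_single_drug()] first).
#' @param lex The lexicon used for matching.
#' @return An `adr_masked_example`: list with `doc_id`, `masked_tokens`
#'   (containing exactly one `<DRUG>`) and `target_drug`.
#' @export
mask_drugs <- function(doc, spans, lex) {
  if (!is.data.frame(spans) || nrow(spans) != 1L) {
    stop("mask_drugs() requires exactly one drug span; got ",
         if (is.data.frame(spans)) nrow(spans) else "invalid input",
         " (apply filter_single_drug() first)")
  }
  s <- spans$token_start[1L] + 1L   # to 1-based
  e <- spans$token_end[1L]          # inclusive 1-based end
  tokens <- doc$tokens
  masked <- c(if (s > 1L) tokens[seq_len(s - 1L)], DRUG_TOK,
              if (e < length(tokens)) tokens[(e + 1L):length(tokens)])
  structure(list(doc_id = doc$doc_id,
                 masked_tokens = masked,
                 target_drug = spans$drug[1L]),
            class = "adr_masked_example")
}

#' Build the masked pretraining corpus
#'
#' Convenience pipeline: keep single-drug documents and mask their drug
#' mention, producing the training examples for the unsupervised
#' drug-name-prediction phase.
#'
#' @param corpus A list of `adr_document`s.
#' @param lex An `adr_lexicon`.
#' @return A list of `adr_masked_example`s.
#' @export
mask_corpus <- function(corpus, lex) {
  out <- list()
  for (doc in corpus) {
    spans <- find_drug_mentions(doc, lex)
    if (nrow(spans) == 1L) out[[length(out) + 1L]] <- mask_drugs(doc, spans, lex)
  }
  out
}

#' Build a frequency-capped vocabulary
#'
#' Counts token frequencies across one or more corpora (labeled and unlabeled
#' are pooled, matching the combined-dictionary setting), removes stopwords,
#' and keeps the `max_size` most frequent tokens. Ties are broken
#' lexicographically. The special tokens are always present; `<PAD>` is
#' always index 0. Stopword removal affects only vocabulary membership, not
#' the token sequences themselves.
#'
#' @param corpora A list of documents, or a list of such lists. Elements may
#'   be `adr_document`s, `adr_masked_example`s, or plain token vectors.
#' @param max_size Maximum number of non-special tokens kept (default 15000).
#' @param stopwords Character vector of tokens excluded from the vocabulary;
#'   see [default_stopwords()].
#' @return An `adr_vocabulary`: token-to-index map with 0-based dense
#'   indices, `<PAD>` at 0.
#' @export
build_vocabulary <- function(corpora, max_size = 15000L,
                             stopwords = character()) {
  stopifnot(max_size >= 1L)
  counts <- new.env(hash = TRUE, parent = emptyenv())
  add_tokens <- function(tokens) {
    for (tok in tokens) {
      prev <- counts[[tok]]
      counts[[tok]] <- if (is.null(prev)) 1L else prev + 1L
    }
  }
  walk <- function(x) {
    if (is.character(x)) add_tokens(x)
    else if (inherits(x, "adr_document")) add_tokens(x$tokens)
    else if (inherits(x, "adr_masked_example")) add_tokens(x$masked_tokens)
    else if (is.list(x)) for (el in x) walk(el)
    else stop("unsupported corpus element of class ", class(x)[1L])
  }
  walk(corpora)
  toks <- ls(counts)
  toks <- setdiff(toks, c(special_tokens(), stopwords))
  if (length(toks) > 0L) {
    freq <- vapply(toks, function(t) counts[[t]], integer(1L))
    ord <- order(-freq, toks, method = "radix")
    toks <- toks[ord][seq_len(min(max_size, length(toks)))]
  }
  all_tokens <- c(special_tokens(), toks)
  structure(list(tokens = all_tokens,
                 index = stats::setNames(seq_along(all_tokens) - 1L,
                                         all_tokens),
                 max_size = as.integer(max_size)),
            class = "adr_vocabulary")
}

#' @export
print.adr_vocabulary <- function(x, ...) {
  cat("<adr_vocabulary> ", length(x$tokens), " tokens (cap ",
      x$max_size, " + specials)\n", sep = "")
  invisible(x)
}

#' Number of tokens in a vocabulary
#' @param vocab An `adr_vocabulary`.
#' @export
vocab_size <- function(vocab) length(vocab$tokens)

#' Default English stopword list
#'
#' The stopword list shipped with the package (a standard short English
#' function-word list). Used only for vocabulary construction, never to
#' delete tokens from sequences.
#'
#' @return A character vector of stopwords.
#' @export
default_stopwords <- function() {
  path <- system.file("extdata", "stopwords_en.txt", package = "adrtag",
                      mustWork = TRUE)
  lines <- trimws(readLines(path, warn = FALSE))
  lines[nzchar(lines) & !startsWith(lines, "#")]
}

#' Encode tokens as padded index sequences
#'
#' Maps tokens to 0-based vocabulary indices. Out-of-vocabulary tokens map to
#' `<UNK>`; sequences are right-padded with the `<PAD>` index (0) to
#' `max_len` and truncated beyond it (with a warning, since annotations past
#' the cut are lost).
#'
#' @param tokens Character vector of tokens.
#' @param vocab An `adr_vocabulary`.
#' @param max_len Target sequence length (>= 1).
#' @return Integer vector of length `max_len` of 0-based indices.
#' @export
encode_tokens <- function(tokens, vocab, max_len) {
  stopifnot(max_len >= 1L)
  if (length(tokens) > max_len) {
    warning("sequence of length ", length(tokens), " truncated to ", max_len,
            "; content beyond the cut is dropped")
    tokens <- tokens[seq_len(max_len)]
  }
  idx <- unname(vocab$index[tokens])
  idx[is.na(idx)] <- vocab$index[[UNK_TOK]]
  c(idx, rep(vocab$index[[PAD_TOK]], max_len - length(idx)))
}

#' Decode an index sequence back to tokens
#'
#' Inverse of [encode_tokens()] up to `<UNK>` replacement and truncation;
#' trailing padding is removed.
#'
#' @param indices Integer vector of 0-based indices.
#' @param vocab An `adr_vocabulary`.
#' @export
decode_tokens <- function(indices, vocab) {
  toks <- vocab$tokens[indices + 1L]
  n <- length(toks)
  while (n > 0L && toks[n] == PAD_TOK) n <- n - 1L
  toks[seq_len(n)]
}

#' Choose a maximum sequence length from a corpus
#'
#' Default policy: the 95th percentile of token-sequence lengths (rounded
#' up), so extreme outliers do not inflate padding.
#'
#' @param corpora List of documents or masked examples (nested lists allowed).
#' @param quantile Percentile in (0, 1]; default 0.95.
#' @return Integer length >= 1.
#' @export
choose_max_len <- function(corpora, quantile = 0.95) {
  lens <- integer(0L)
  walk <- function(x) {
    if (inherits(x, "adr_document")) lens[[length(lens) + 1L]] <<- length(x$tokens)
    else if (inherits(x, "adr_masked_example")) lens[[length(lens) + 1L]] <<- length(x$masked_tokens)
    else if (is.character(x)) lens[[length(lens) + 1L]] <<- length(x)
    else if (is.list(x)) for (el in x) walk(el)
  }
  walk(corpora)
  if (length(lens) == 0L) return(1L)
  max(1L, as.integer(ceiling(stats::quantile(lens, quantile, names = FALSE))))
}
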