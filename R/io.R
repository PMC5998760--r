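# Readers and writers for the package's plain-text interchange formats:
# one-document-per-line corpora, TSV span annotations, JSON-lines encodings
# and model checkpoints.

#' Read a corpus file
#'
#' One document per line, UTF-8. Lines may carry an explicit id as
#' `id<TAB>text`; otherwise ids `d00001`, `d00002`, ... are assigned. Blank
#' lines are skipped.
#'
#' @param path Corpus file path.
#' @return A list of `adr_document`s (normalized and tokenized).
#' @export
read_corpus <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  has_id <- grepl("\t", lines, fixed = TRUE)
  docs <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    if (has_id[i]) {
      parts <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
      docs[[i]] <- as_document(parts[1L],
                               paste(parts[-1L], collapse = "\t"))
    } else {
      docs[[i]] <- as_document(sprintf("d%05d", i), lines[i])
    }
  }
  ids <- vapply(docs, `[[`, character(1L), "doc_id")
  if (anyDuplicated(ids)) stop("duplicate doc_id in ", path)
  docs
}

#' Convert raw-document lists to tokenized documents
#'
#' @param raw_docs List of `list(doc_id, text)` records, e.g. from
#'   [generate_unlabeled()].
#' @return A list of `adr_document`s.
#' @export
docs_from_raw <- function(raw_docs) {
  lapply(raw_docs, function(d) as_document(d$doc_id, d$text))
}

#' Read a span-annotation file
#'
#' Tab-separated with header columns `doc_id`, `start`, `end`, `label`,
#' `text`; offsets are 0-based half-open character positions in the raw
#' text of the corpus the file accompanies; labels are `ADR` or
#' `Indication`.
#'
#' @param path Annotation TSV path.
#' @return A data frame with those columns.
#' @export
read_annotations <- function(path) {
  ann <- utils::read.delim(path, stringsAsFactors = FALSE, quote = "")
  need <- c("doc_id", "start", "end", "label")
  missing <- setdiff(need, names(ann))
  if (length(missing) > 0L) {
    stop("annotation file ", path, " lacks column(s): ",
         paste(missing, collapse = ", "))
  }
  bad <- !(ann$label %in% c("ADR", "Indication"))
  if (any(bad)) {
    stop("annotation file ", path, " has unknown label(s): ",
         paste(unique(ann$label[bad]), collapse = ", "))
  }
  ann
}

#' Encode raw labeled documents into tagger records
#'
#' Full labeled-side pipeline: normalize and tokenize each raw document,
#' carry its raw-offset annotations through normalization, convert them to
#' IO tags and encode tokens and tags to fixed length.
#'
#' @param raw_docs List of `list(doc_id, text)` records.
#' @param annotations Annotation data frame (see [read_annotations()]).
#' @param vocab An `adr_vocabulary`.
#' @param max_len Encoded sequence length.
#' @return A list of records as produced by [encode_labeled()].
#' @export
prepare_labeled_records <- function(raw_docs, annotations, vocab, max_len) {
  lapply(raw_docs, function(d) {
    doc <- as_document(d$doc_id, d$text)
    ann <- annotations[annotations$doc_id == d$doc_id, , drop = FALSE]
    spans <- align_char_spans_to_tokens(doc, ann, offsets = "raw")
    encode_labeled(doc, spans, vocab, max_len)
  })
}

#' Write documents as JSON lines
#'
#' One JSON object per line with `doc_id`, `tokens` and `char_spans`
#' (for documents) or `doc_id`, `masked_tokens` and `target_drug` (for
#' masked examples), or `doc_id`, `tokens`, `tags` (for encoded labeled
#' records given with a vocabulary).
#'
#' @param x List of `adr_document`s, `adr_masked_example`s, or encoded
#'   labeled records.
#' @param path Output file.
#' @param vocab Required to decode token indices when `x` holds encoded
#'   records.
#' @return `path`, invisibly.
#' @export
write_jsonl <- function(x, path, vocab = NULL) {
  lines <- vapply(x, function(el) {
    rec <- if (inherits(el, "adr_document")) {
      list(doc_id = el$doc_id, tokens = el$tokens,
           char_spans = unname(apply(el$char_spans, 1L, as.list,
                                     simplify = FALSE)))
    } else if (inherits(el, "adr_masked_example")) {
      list(doc_id = el$doc_id, masked_tokens = el$masked_tokens,
           target_drug = el$target_drug)
    } else if (!is.null(el$indices) && !is.null(el$tags)) {
      if (is.null(vocab)) stop("vocab is required to write encoded records")
      list(doc_id = el$doc_id,
           tokens = decode_tokens(el$indices, vocab),
           tags = el$tags[seq_len(el$n_tokens)])
    } else stop("unsupported record type for write_jsonl()")
    jsonlite::toJSON(rec, auto_unbox = TRUE)
  }, character(1L))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Save a model checkpoint
#'
#' Serializes a pretrained model or tagger (configuration plus named weight
#' arrays) to a single file. Weight names are stable across the two phases,
#' so a phase-1 checkpoint can seed phase-2 fine-tuning.
#'
#' @param x An `adr_pretrained`, `adr_tagger` or `adr_encoder`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
save_checkpoint <- function(x, path) {
  stopifnot(inherits(x, c("adr_pretrained", "adr_tagger", "adr_encoder")))
  saveRDS(x, path)
  invisible(path)
}

#' Load a model checkpoint
#' @param path Checkpoint file from [save_checkpoint()].
#' @return The saved object.
#' @export
load_checkpoint <- function(path) {
  x <- readRDS(path)
  if (!inherits(x, c("adr_pretrained", "adr_tagger", "adr_encoder"))) {
    stop(path, " is not an adrtag checkpoint")
  }
  x
}
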