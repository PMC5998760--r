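test_that("normalization replaces URLs/handles, strips noise and lower-cases", {
  expect_identical(normalize_text("Check http://t.co/abc @JonDoe #fun!"),
                   "check <LINK> <USER> fun")
  expect_identical(normalize_text(""), "")
  expect_identical(normalize_text("Cymbalta \U0001F642\U0001F642"), "cymbalta")
  expect_identical(normalize_text("don't-stop   NOW!!"), "dontstop now")
  expect_identical(normalize_text("see www.example.com ok"), "see <LINK> ok")
})

test_that("normalization is idempotent and preserves special tokens", {
  set.seed(1)
  samples <- c("Check http://t.co/abc @JonDoe #fun!",
               "<DRUG> causing rash :(",
               "A   b\tC?? \U0001F60A @x http://a.b/c",
               "plain words only")
  for (s in samples) {
    once <- normalize_text(s)
    expect_identical(normalize_text(once), once)
  }
  expect_identical(normalize_text("<DRUG> causing rash"), "<DRUG> causing rash")
})

test_that("character-filter oracle agrees with normalization of plain words", {
  # per-character reference: keep ASCII alphanumerics, lower-cased
  set.seed(42)
  alphabet <- c(letters, LETTERS, 0:9, "!", "#", ",", ".", "\U0001F642", "?")
  for (i in 1:50) {
    word <- paste0(sample(alphabet, sample(2:10, 1), replace = TRUE),
                   collapse = "")
    if (startsWith(word, "@")) next
    chars <- strsplit(word, "")[[1]]
    ref <- tolower(paste0(chars[grepl("[A-Za-z0-9]", chars)], collapse = ""))
    expect_identical(normalize_text(word), ref)
  }
})

test_that("tokenize splits on whitespace with 0-based half-open char spans", {
  tk <- tokenize("lamictal and trileptal")
  expect_identical(tk$tokens, c("lamictal", "and", "trileptal"))
  expect_equal(unname(tk$char_spans),
               matrix(c(0L, 8L, 9L, 12L, 13L, 22L), ncol = 2, byrow = TRUE),
               ignore_attr = TRUE)
  expect_identical(tokenize("<DRUG> causing rash")$tokens,
                   c("<DRUG>", "causing", "rash"))
  expect_identical(tokenize("")$tokens, character())
})

test_that("detokenized join of tokens reproduces the normalized text", {
  set.seed(7)
  for (i in 1:25) {
    raw <- paste(sample(c("Ab!", "cd", "@user", "http://x.y/z", "#tag",
                          "\U0001F642", "e9"),
                        sample(1:8, 1), replace = TRUE), collapse = " ")
    text <- normalize_text(raw)
    expect_identical(paste(tokenize(text)$tokens, collapse = " "), text)
  }
})

test_that("document raw spans point back at the source characters", {
  raw <- "Bad rash!! from Cymbalta \U0001F642 http://t.co/q"
  doc <- as_document("d1", raw)
  expect_identical(doc$tokens, c("bad", "rash", "from", "cymbalta", "<LINK>"))
  for (i in seq_along(doc$tokens)[-5]) {
    src <- substr(raw, doc$raw_spans[i, 1] + 1, doc$raw_spans[i, 2])
    expect_identical(tolower(src), doc$tokens[i])
  }
})

test_that("vocabulary ranks by frequency with lexicographic ties, caps size", {
  corpus <- list(c(rep("a", 5), rep("b", 3), "c"))
  v <- build_vocabulary(corpus, max_size = 2)
  expect_setequal(setdiff(v$tokens, c(PAD_TOK, UNK_TOK, DRUG_TOK,
                                      LINK_TOK, USER_TOK)), c("a", "b"))
  v2 <- build_vocabulary(corpus, max_size = 2, stopwords = "a")
  expect_setequal(setdiff(v2$tokens, c(PAD_TOK, UNK_TOK, DRUG_TOK,
                                       LINK_TOK, USER_TOK)), c("b", "c"))
  expect_identical(unname(v$index[PAD_TOK]), 0L)
  # non-binding cap keeps everything
  set.seed(3)
  toks <- replicate(1000, paste0(sample(letters, 6, TRUE), collapse = ""))
  v3 <- build_vocabulary(list(toks), max_size = 15000)
  expect_identical(vocab_size(v3), length(unique(toks)) + 5L)
})

test_that("vocabulary frequencies agree with a brute-force counter", {
  set.seed(11)
  toks <- sample(sprintf("w%02d", 1:40), 5000, replace = TRUE,
                 prob = seq(40, 1))
  v <- build_vocabulary(list(toks), max_size = 10)
  tab <- sort(table(toks), decreasing = TRUE)
  kept <- setdiff(v$tokens, c(PAD_TOK, UNK_TOK, DRUG_TOK, LINK_TOK, USER_TOK))
  expect_setequal(kept, names(tab)[1:10])
  expect_lte(vocab_size(v), 10L + 5L)
})

test_that("lexicon matching is exact, case-insensitive, longest-first", {
  lex <- as_lexicon(c("lamotrigine", "zoledronic acid", "acid"))
  doc <- as_document("t", "since last week lamotrigine causing rash")
  expect_equal(find_drug_mentions(doc, lex)$token_start, 3L)
  expect_equal(find_drug_mentions(doc, lex)$token_end, 4L)
  none <- as_document("t2", "no drugs here at all")
  expect_identical(nrow(find_drug_mentions(none, lex)), 0L)
  multi <- as_document("t3", "took Zoledronic Acid yesterday")
  m <- find_drug_mentions(multi, lex)
  expect_identical(nrow(m), 1L)
  expect_identical(m$drug, "zoledronic acid")
  expect_identical(m$token_end - m$token_start, 2L)
})

test_that("greedy longest match equals exhaustive maximal matching", {
  # oracle: enumerate all non-overlapping matchings, prefer ones that are
  # left-to-right maximal (no earlier or longer match available)
  lex_words <- c("aa", "bb", "aa bb", "cc")
  lex <- as_lexicon(lex_words)
  entries <- strsplit(lex_words, " ")
  oracle <- function(tokens) {
    res <- list(); i <- 1
    while (i <= length(tokens)) {
      best <- 0
      for (e in entries) {
        len <- length(e)
        if (len > best && i + len - 1 <= length(tokens) &&
            all(tokens[i:(i + len - 1)] == e)) best <- len
      }
      if (best > 0) { res[[length(res) + 1]] <- c(i - 1, i - 1 + best)
                      i <- i + best } else i <- i + 1
    }
    res
  }
  set.seed(5)
  for (rep in 1:40) {
    tokens <- sample(c("aa", "bb", "cc", "xx", "yy"), 8, replace = TRUE)
    doc <- list(tokens = tokens)
    got <- find_drug_mentions(doc, lex)
    want <- oracle(tokens)
    expect_identical(nrow(got), length(want))
    for (k in seq_along(want)) {
      expect_identical(c(got$token_start[k], got$token_end[k]),
                       as.integer(want[[k]]))
    }
  }
})

test_that("single-drug filter equals a brute-force mention recount", {
  gen <- generator_config(n_drugs = 5L, n_unlabeled = 100L, seed = 21L)
  world <- generate_world(gen)
  docs <- docs_from_raw(generate_unlabeled(gen, world))
  # corrupt some documents to carry 0 or 2 mentions
  docs[[1]]$tokens <- c("plain", "words")
  docs[[2]]$tokens <- c(docs[[2]]$tokens, strsplit(world$drug_keys[1], " ")[[1]],
                        strsplit(world$drug_keys[2], " ")[[1]])
  kept <- filter_single_drug(docs, world$lex)
  want <- Filter(function(d) nrow(find_drug_mentions(d, world$lex)) == 1L, docs)
  expect_identical(length(kept), length(want))
  expect_identical(vapply(kept, `[[`, character(1), "doc_id"),
                   vapply(want, `[[`, character(1), "doc_id"))
  expect_false(docs[[1]]$doc_id %in% vapply(kept, `[[`, character(1), "doc_id"))
})

test_that("masking replaces the drug span with one dummy token", {
  lex <- as_lexicon(c("lamotrigine", "zoledronic acid"))
  doc <- as_document("t", "since last week lamotrigine causing steven johnson syndrome")
  m <- mask_drugs(doc, find_drug_mentions(doc, lex), lex)
  expect_identical(paste(m$masked_tokens, collapse = " "),
                   "since last week <DRUG> causing steven johnson syndrome")
  expect_identical(m$target_drug, "lamotrigine")
  multi <- as_document("t2", "zoledronic acid hurts my jaw")
  m2 <- mask_drugs(multi, find_drug_mentions(multi, lex), lex)
  expect_identical(sum(m2$masked_tokens == DRUG_TOK), 1L)
  expect_identical(length(m2$masked_tokens), length(multi$tokens) - 2L + 1L)
  none <- as_document("t3", "nothing to see")
  expect_error(mask_drugs(none, find_drug_mentions(none, lex), lex),
               "exactly one")
})

test_that("masked corpora carry one <DRUG> and no residual lexicon match", {
  gen <- generator_config(n_drugs = 6L, n_unlabeled = 80L, seed = 9L)
  world <- generate_world(gen)
  docs <- docs_from_raw(generate_unlabeled(gen, world))
  masked <- mask_corpus(docs, world$lex)
  expect_gt(length(masked), 0L)
  for (m in masked) {
    expect_identical(sum(m$masked_tokens == DRUG_TOK), 1L)
    expect_identical(nrow(find_drug_mentions(list(tokens = m$masked_tokens),
                                             world$lex)), 0L)
    expect_true(m$target_drug %in% world$lex$keys)
  }
})

test_that("token encoding pads, truncates and maps OOV to <UNK>", {
  v <- build_vocabulary(list(c("rash", "bad")), max_size = 10)
  idx_rash <- unname(v$index["rash"])
  expect_identical(encode_tokens("rash", v, 3L), c(idx_rash, 0L, 0L))
  expect_identical(encode_tokens("unseen", v, 2L)[1],
                   unname(v$index[UNK_TOK]))
  expect_warning(encode_tokens(c("rash", "bad", "rash"), v, 2L), "truncated")
  # round trip up to UNK/truncation
  set.seed(13)
  v2 <- toy_vocab()
  for (i in 1:20) {
    toks <- sample(sprintf("t%02d", 1:25), sample(1:12, 1), replace = TRUE)
    enc <- suppressWarnings(encode_tokens(toks, v2, 8L))
    dec <- decode_tokens(enc, v2)
    want <- toks[seq_len(min(length(toks), 8L))]
    want[!(want %in% v2$tokens)] <- UNK_TOK
    # trailing in-vocab PADs cannot occur; decode strips padding only
    expect_identical(dec, want)
  }
})

test_that("max_len heuristic takes the 95th percentile of lengths", {
  docs <- lapply(c(rep(4, 19), 40), function(n) sprintf("w%d", seq_len(n)))
  expect_identical(choose_max_len(list(docs)),
                   as.integer(ceiling(quantile(c(rep(4, 19), 40), 0.95))))
  expect_identical(choose_max_len(list()), 1L)
})

test_that("lexicon and corpus files round-trip through the readers", {
  lex_path <- tempfile(fileext = ".txt")
  writeLines(c("# comment", "Humira", "zoledronic acid", ""), lex_path)
  lex <- read_lexicon(lex_path)
  expect_setequal(lex$keys, c("humira", "zoledronic acid"))
  corp_path <- tempfile(fileext = ".txt")
  writeLines(c("a1\tFirst doc here", "plain second doc"), corp_path)
  docs <- read_corpus(corp_path)
  expect_identical(docs[[1]]$doc_id, "a1")
  expect_identical(docs[[1]]$tokens, c("first", "doc", "here"))
  expect_identical(docs[[2]]$doc_id, "d00002")
})
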