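# Seeded generator of tweet-like corpora with planted drug mentions, ADR and
# Indication spans, and a controllable statistical association between each
# drug and its context words. The association is what makes encoder
# pretraining transferable: ADR phrases are composed from the same
# drug-conditioned word pools that generate unlabeled context, rather than
# from a fixed phrase list, so a tagger cannot simply memorize phrases.

#' Synthetic-corpus generator configuration
#'
#' Desk-scale defaults (10 drugs, 2000 unlabeled documents, 150 labeled
#' documents) are sized so that the full semi-supervised pipeline runs in
#' minutes on one CPU while preserving the structure of the real task:
#' short noisy texts, exactly one drug mention per document, and ADR spans
#' statistically tied to the drug in context.
#'
#' @param n_drugs Number of pseudo-drug names (>= 2).
#' @param n_unlabeled Unlabeled documents to generate.
#' @param n_labeled Labeled documents to generate.
#' @param context_signal Probability in `[0, 1]` that a context (or phrase)
#'   word is drawn from the drug's private pool rather than the shared pool.
#' @param adr_rate Fraction of documents carrying an ADR phrase (annotated
#'   in the labeled corpus, plain text in the unlabeled one).
#' @param indication_rate Fraction of documents carrying an Indication
#'   phrase.
#' @param off_drug_rate Probability that a non-private context slot holds an
#'   ADR word of a *different* drug (tagged O): symptom vocabulary is only
#'   an adverse reaction when attributable to the mentioned drug, which ties
#'   correct tagging to the drug-symptom pairing.
#' @param url_rate,mention_rate,emoticon_rate,typo_rate,punct_rate Noise
#'   rates: probability of inserting a URL / user-mention / emoticon unit,
#'   of perturbing a context word, and of attaching punctuation to a word.
#' @param shared_vocab_size Size of the shared context-word pool.
#' @param doc_len_mean Mean number of context words per document.
#' @param seed Integer seed; every generated artifact is a deterministic
#'   function of the configuration.
#' @return An object of class `adr_generator_config`.
#' @export
generator_config <- function(n_drugs = 10L, n_unlabeled = 2000L,
                             n_labeled = 150L, context_signal = 0.8,
                             adr_rate = 0.6, indication_rate = 0.15,
                             off_drug_rate = 0.5,
                             url_rate = 0.1, mention_rate = 0.1,
                             emoticon_rate = 0.1, typo_rate = 0.05,
                             punct_rate = 0.15, shared_vocab_size = 150L,
                             doc_len_mean = 9, seed = 1L) {
  rates <- c(context_signal, adr_rate, indication_rate, off_drug_rate,
             url_rate, mention_rate, emoticon_rate, typo_rate, punct_rate)
  stopifnot(n_drugs >= 2L, all(rates >= 0 & rates <= 1),
            shared_vocab_size >= 10L, doc_len_mean >= 3)
  structure(list(n_drugs = as.integer(n_drugs),
                 n_unlabeled = as.integer(n_unlabeled),
                 n_labeled = as.integer(n_labeled),
                 context_signal = context_signal,
                 adr_rate = adr_rate, indication_rate = indication_rate,
                 off_drug_rate = off_drug_rate,
                 url_rate = url_rate, mention_rate = mention_rate,
                 emoticon_rate = emoticon_rate, typo_rate = typo_rate,
                 punct_rate = punct_rate,
                 shared_vocab_size = as.integer(shared_vocab_size),
                 doc_len_mean = doc_len_mean,
                 seed = as.integer(seed)),
            class = "adr_generator_config")
}

.consonants <- c("b", "c", "d", "f", "g", "k", "l", "m", "n", "p", "r", "s",
                 "t", "v", "z")
.vowels <- c("a", "e", "i", "o", "u")
.drug_suffixes <- c("ine", "ol", "ax", "il", "one", "epta")
.emoticons <- c("\U0001F642", "\U0001F622", "\U0001F621", "\U0001F60A")

.syllable_word <- function(n_syl) {
  paste0(paste0(sample(.consonants, n_syl, replace = TRUE),
                sample(.vowels, n_syl, replace = TRUE)), collapse = "")
}

# Draw words until `n` fresh ones are found (deterministic given RNG state).
.fresh_words <- function(n, used, maker) {
  out <- character(0L)
  while (length(out) < n) {
    w <- maker()
    if (!(w %in% used) && !(w %in% out)) out <- c(out, w)
  }
  out
}

#' Generate a pseudo-drug lexicon
#'
#' Pronounceable consonant-vowel syllable names with drug-like suffixes;
#' one in ten entries is multi-token (`"<name> acid"`). Deterministic per
#' seed, with all names unique.
#'
#' @param cfg An [generator_config()].
#' @return An `adr_lexicon` of `n_drugs` entries.
#' @export
generate_lexicon <- function(cfg) {
  stopifnot(inherits(cfg, "adr_generator_config"))
  set.seed(cfg$seed)
  maker <- function() paste0(.syllable_word(sample(2:3, 1L)),
                             sample(.drug_suffixes, 1L))
  stems <- .fresh_words(cfg$n_drugs, c("acid"), maker)
  n_multi <- cfg$n_drugs %/% 10L
  if (n_multi > 0L) {
    stems[seq_len(n_multi)] <- paste(stems[seq_len(n_multi)], "acid")
  }
  as_lexicon(stems)
}

#' Generate the full synthetic world
#'
#' Builds the lexicon plus the word pools that define the drug-context
#' association: a shared context pool, a per-drug private pool split into
#' plain context words, ADR-phrase words and Indication-phrase words, and
#' small shared ADR/Indication pools. All pools are mutually disjoint and
#' disjoint from the drug names, so tag identity is decidable from word
#' identity while the drug identity is carried by which private pool a word
#' came from.
#'
#' @param cfg An [generator_config()].
#' @return An `adr_world` list with `cfg`, `lex`, `drug_keys`, `shared`,
#'   `shared_adr`, `shared_ind` and per-drug `pools`
#'   (`context`/`adr`/`indication` character vectors).
#' @export
generate_world <- function(cfg) {
  lex <- generate_lexicon(cfg)
  set.seed(cfg$seed + 1L)
  used <- c(unlist(lapply(lex$entries, identity)), "acid")
  maker <- function() .syllable_word(sample(2:3, 1L))
  shared <- .fresh_words(cfg$shared_vocab_size, used, maker)
  used <- c(used, shared)
  shared_adr <- .fresh_words(40L, used, maker)
  used <- c(used, shared_adr)
  shared_ind <- .fresh_words(8L, used, maker)
  used <- c(used, shared_ind)
  pools <- vector("list", cfg$n_drugs)
  for (k in seq_len(cfg$n_drugs)) {
    context <- .fresh_words(5L, used, maker); used <- c(used, context)
    adr <- .fresh_words(25L, used, maker); used <- c(used, adr)
    ind <- .fresh_words(3L, used, maker); used <- c(used, ind)
    pools[[k]] <- list(context = context, adr = adr, indication = ind)
  }
  names(pools) <- lex$keys
  structure(list(cfg = cfg, lex = lex, drug_keys = lex$keys, shared = shared,
                 shared_adr = shared_adr, shared_ind = shared_ind,
                 pools = pools),
            class = "adr_world")
}

# One word unit of a synthetic document: the clean words plus surface noise.
# `skip` leading words are excluded from any annotation (trigger words).
.unit <- function(words, kind, skip = 0L) {
  list(words = words, kind = kind, skip = skip)
}

# Sample the units of one document. Labeled and unlabeled documents follow
# the *same* distribution -- unlabeled text simply never gets annotations --
# which is what makes phase-1 pretraining transferable: the encoder sees ADR
# phrases and drug contexts from the distribution the tagger is later scored
# on. Whether a symptom word is an ADR mention depends on the drug present:
# a drug's own ADR words occur (only) inside its annotated phrases, while
# *other* drugs' ADR words can occur scattered as plain context (tagged O),
# the way a symptom term is only an adverse reaction when it is attributable
# to the mentioned drug. Correct tagging of unseen words therefore requires
# the drug-symptom pairing that phase 1 learns from unlabeled text.
.sample_units <- function(world, drug_key) {
  cfg <- world$cfg
  pool <- world$pools[[drug_key]]
  others <- setdiff(world$drug_keys, drug_key)
  n_ctx <- max(2L, stats::rpois(1L, cfg$doc_len_mean - 1))
  ctx <- vapply(seq_len(n_ctx), function(i) {
    if (stats::runif(1L) < cfg$context_signal) {
      sample(pool$context, 1L)
    } else if (stats::runif(1L) < cfg$off_drug_rate) {
      sample(world$pools[[sample(others, 1L)]]$adr, 1L)
    } else {
      sample(world$shared, 1L)
    }
  }, character(1L))
  units <- lapply(ctx, .unit, kind = "context")
  units[[length(units) + 1L]] <- .unit(strsplit(drug_key, " ")[[1L]], "drug")
  if (stats::runif(1L) < cfg$adr_rate) {
    len <- sample(1:4, 1L)
    phrase <- vapply(seq_len(len), function(i) {
      if (stats::runif(1L) < cfg$context_signal) sample(pool$adr, 1L)
      else sample(world$shared_adr, 1L)
    }, character(1L))
    units[[length(units) + 1L]] <- .unit(phrase, "adr")
  }
  if (stats::runif(1L) < cfg$indication_rate) {
    len <- sample(1:2, 1L)
    phrase <- vapply(seq_len(len), function(i) {
      if (stats::runif(1L) < cfg$context_signal) sample(pool$indication, 1L)
      else sample(world$shared_ind, 1L)
    }, character(1L))
    units[[length(units) + 1L]] <- .unit(phrase, "indication")
  }
  if (stats::runif(1L) < cfg$url_rate) {
    units[[length(units) + 1L]] <-
      .unit(paste0("http://t.co/", .syllable_word(3L)), "url")
  }
  if (stats::runif(1L) < cfg$mention_rate) {
    units[[length(units) + 1L]] <-
      .unit(paste0("@", .syllable_word(2L)), "mention")
  }
  if (stats::runif(1L) < cfg$emoticon_rate) {
    units[[length(units) + 1L]] <- .unit(sample(.emoticons, 1L), "emoticon")
  }
  units <- units[sample.int(length(units))]
  # typo: duplicate one letter of one plain context word
  if (stats::runif(1L) < cfg$typo_rate) {
    ctx_ids <- which(vapply(units, function(u) u$kind == "context",
                            logical(1L)))
    if (length(ctx_ids) > 0L) {
      j <- if (length(ctx_ids) == 1L) ctx_ids else sample(ctx_ids, 1L)
      w <- units[[j]]$words[1L]
      pos <- sample.int(nchar(w), 1L)
      typo <- paste0(substr(w, 1L, pos), substr(w, pos, nchar(w)))
      # never let a typo collide with a drug-name token
      if (!(typo %in% unlist(world$lex$entries))) units[[j]]$words[1L] <- typo
    }
  }
  units
}

# Render units into raw text with surface noise, recording for each phrase
# unit the 0-based half-open character interval of its clean words in the
# raw text.
.render_units <- function(units, cfg) {
  parts <- character(0L)
  pos <- 0L
  ann <- data.frame(start = integer(), end = integer(), label = character(),
                    text = character(), stringsAsFactors = FALSE)
  for (u in units) {
    word_starts <- integer(0L); word_ends <- integer(0L)
    rendered <- character(0L)
    for (w in u$words) {
      suffix <- ""
      if (u$kind %in% c("context", "adr", "indication") &&
          stats::runif(1L) < cfg$punct_rate) {
        suffix <- sample(c(",", "!", ".", "?"), 1L)
      }
      word_starts <- c(word_starts, pos)
      word_ends <- c(word_ends, pos + nchar(w))
      rendered <- c(rendered, paste0(w, suffix))
      pos <- pos + nchar(w) + nchar(suffix) + 1L  # + separating space
    }
    parts <- c(parts, rendered)
    if (u$kind %in% c("adr", "indication")) {
      from <- u$skip + 1L  # trigger words stay outside the annotated span
      ann <- rbind(ann, data.frame(
        start = word_starts[from], end = word_ends[length(word_ends)],
        label = if (u$kind == "adr") "ADR" else "Indication",
        text = paste(u$words[from:length(u$words)], collapse = " "),
        stringsAsFactors = FALSE))
    }
  }
  list(text = paste(parts, collapse = " "), ann = ann)
}

#' Generate the unlabeled corpus
#'
#' Each document contains exactly one drug mention; context words are drawn
#' from the drug's private pool with probability `context_signal` and from
#' the shared pool otherwise, with URL / user-mention / emoticon / typo /
#' punctuation noise at the configured rates. Unlabeled documents follow
#' exactly the same distribution as the labeled corpus -- including
#' (unannotated) ADR and Indication phrases -- so that pretraining sees the
#' vocabulary and phrase structure the tagger is later scored on.
#'
#' @param cfg An [generator_config()].
#' @param world Optional pre-built [generate_world()] (rebuilt from `cfg`
#'   when omitted).
#' @return A list of raw documents (`doc_id`, `text`) with attribute
#'   `drug`: the true drug key per document (the generator's own ground
#'   truth, used by oracle checks).
#' @export
generate_unlabeled <- function(cfg, world = NULL) {
  if (is.null(world)) world <- generate_world(cfg)
  set.seed(cfg$seed + 2L)
  drugs <- sample(world$drug_keys, cfg$n_unlabeled, replace = TRUE)
  docs <- vector("list", cfg$n_unlabeled)
  for (i in seq_len(cfg$n_unlabeled)) {
    units <- .sample_units(world, drugs[i])
    docs[[i]] <- list(doc_id = sprintf("u%05d", i),
                      text = .render_units(units, cfg)$text)
  }
  attr(docs, "drug") <- drugs
  docs
}

#' Generate the labeled corpus and its span annotations
#'
#' Labeled documents follow the same construction as the unlabeled corpus
#' but carry ADR phrases (1-4 tokens) and Indication phrases (1-2 tokens)
#' composed from the same drug-conditioned pools, with character offsets
#' recorded against the raw text.
#'
#' @param cfg An [generator_config()].
#' @param world Optional pre-built [generate_world()].
#' @param n Number of documents (default `cfg$n_labeled`).
#' @return List with `docs` (raw documents, with attribute `drug`) and
#'   `annotations` (data frame `doc_id`, `start`, `end`, `label`, `text`;
#'   offsets 0-based half-open into the raw text).
#' @export
generate_labeled <- function(cfg, world = NULL, n = cfg$n_labeled) {
  if (is.null(world)) world <- generate_world(cfg)
  set.seed(cfg$seed + 3L)
  drugs <- sample(world$drug_keys, n, replace = TRUE)
  docs <- vector("list", n)
  anns <- list()
  for (i in seq_len(n)) {
    units <- .sample_units(world, drugs[i])
    rend <- .render_units(units, cfg)
    id <- sprintf("l%05d", i)
    docs[[i]] <- list(doc_id = id, text = rend$text)
    if (nrow(rend$ann) > 0L) {
      anns[[length(anns) + 1L]] <- cbind(doc_id = id, rend$ann)
    }
  }
  annotations <- if (length(anns) > 0L) do.call(rbind, anns) else
    data.frame(doc_id = character(), start = integer(), end = integer(),
               label = character(), text = character(),
               stringsAsFactors = FALSE)
  attr(docs, "drug") <- drugs
  list(docs = docs, annotations = annotations)
}

#' Write a synthetic benchmark to disk
#'
#' Writes `lexicon.txt`, `unlabeled.txt` (one `id<TAB>text` per line),
#' `labeled.txt` and `labeled.ann.tsv` in the package's corpus and
#' annotation formats.
#'
#' @param cfg An [generator_config()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_synthetic_corpus <- function(cfg, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  world <- generate_world(cfg)
  unl <- generate_unlabeled(cfg, world)
  lab <- generate_labeled(cfg, world)
  writeLines(world$lex$keys, file.path(dir, "lexicon.txt"))
  writeLines(vapply(unl, function(d) paste(d$doc_id, d$text, sep = "\t"),
                    character(1L)),
             file.path(dir, "unlabeled.txt"))
  writeLines(vapply(lab$docs, function(d) paste(d$doc_id, d$text, sep = "\t"),
                    character(1L)),
             file.path(dir, "labeled.txt"))
  utils::write.table(lab$annotations, file.path(dir, "labeled.ann.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
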