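toy_pretrain_data <- function(seed = 11L, n_unlabeled = 150L, n_drugs = 4L,
                              signal = 1) {
  gen <- generator_config(n_drugs = n_drugs, n_unlabeled = n_unlabeled,
                          n_labeled = 20L, context_signal = signal,
                          seed = seed)
  world <- generate_world(gen)
  docs <- docs_from_raw(generate_unlabeled(gen, world))
  masked <- mask_corpus(docs, world$lex)
  vocab <- build_vocabulary(docs, stopwords = default_stopwords())
  list(gen = gen, world = world, docs = docs, masked = masked, vocab = vocab)
}

test_that("word2vec text files round-trip and errors name the bad line", {
  path <- tempfile(fileext = ".txt")
  writeLines(c("2 3", "rash 0.1 -0.2 0.3", "gain 1 2 3"), path)
  w <- read_word2vec(path)
  expect_identical(w$words, c("rash", "gain"))
  expect_equal(w$vectors[1, ], c(0.1, -0.2, 0.3))
  bad <- tempfile(fileext = ".txt")
  writeLines(c("2 3", "rash 0.1 -0.2 0.3", "gain 1 oops 3"), bad)
  expect_error(read_word2vec(bad), "line 3")
  short <- tempfile(fileext = ".txt")
  writeLines(c("5 3", "rash 0.1 -0.2 0.3"), short)
  expect_error(read_word2vec(short), "promises")
})

test_that("word2vec binary files are read back exactly", {
  path <- tempfile(fileext = ".bin")
  con <- file(path, "wb")
  writeBin(charToRaw("2 3\n"), con)
  writeBin(charToRaw("rash "), con)
  writeBin(c(0.5, -1.25, 2), con, size = 4L, endian = "little")
  writeBin(charToRaw("\ngain "), con)
  writeBin(c(1, 2, 3), con, size = 4L, endian = "little")
  close(con)
  w <- read_word2vec(path)
  expect_identical(w$words, c("rash", "gain"))
  expect_equal(w$vectors[1, ], c(0.5, -1.25, 2), tolerance = 1e-7)
  expect_equal(w$vectors[2, ], c(1, 2, 3), tolerance = 1e-7)
})

test_that("embedding initialization copies file vectors and zeroes <PAD>", {
  v <- build_vocabulary(list(c("rash", "gain", "novel")), max_size = 10)
  path <- tempfile(fileext = ".txt")
  writeLines(c("3 4", "rash 1 2 3 4", "gain -1 -2 -3 -4",
               "elsewhere 9 9 9 9"), path)
  set.seed(2)
  E <- init_embeddings(v, path, 4L)
  expect_equal(E[v$index[["rash"]] + 1L, ], c(1, 2, 3, 4))
  expect_equal(E[v$index[["gain"]] + 1L, ], c(-1, -2, -3, -4))
  expect_identical(E[v$index[[PAD_TOK]] + 1L, ], rep(0, 4))
  novel_row <- E[v$index[["novel"]] + 1L, ]
  expect_true(all(abs(novel_row) <= 0.05))
  # coverage equals the set-intersection fraction
  expect_equal(attr(E, "coverage"),
               length(intersect(v$tokens, c("rash", "gain", "elsewhere"))) /
                 vocab_size(v))
  expect_error(init_embeddings(v, path, 5L), "dimension")
})

test_that("pretraining is seed-reproducible and rejects degenerate corpora", {
  d <- toy_pretrain_data()
  cfg <- model_config(token_vocab_size = vocab_size(d$vocab),
                      embed_dim = 8L, hidden_dim = 8L)
  tr <- train_config(phase1 = list(epochs = 2L, batch_size = 32L), seed = 3L)
  p1 <- pretrain(d$masked, d$vocab, cfg, tr)
  p2 <- pretrain(d$masked, d$vocab, cfg, tr)
  expect_identical(p1$log, p2$log)
  expect_identical(p1$encoder, p2$encoder)
  expect_identical(p1$drug_head, p2$drug_head)
  expect_true(all(is.finite(p1$log$loss)))
  one_class <- Filter(function(m) m$target_drug == d$masked[[1]]$target_drug,
                      d$masked)
  expect_error(pretrain(one_class, d$vocab, cfg, tr), "two distinct")
})

test_that("zero pretraining epochs return the seeded initialization", {
  d <- toy_pretrain_data()
  cfg <- model_config(token_vocab_size = vocab_size(d$vocab),
                      embed_dim = 8L, hidden_dim = 8L)
  tr0 <- train_config(phase1 = list(epochs = 0L), seed = 5L)
  p0 <- pretrain(d$masked, d$vocab, cfg, tr0)
  set.seed(5L)
  cfg2 <- cfg
  cfg2$token_vocab_size <- vocab_size(d$vocab)
  cfg2$drug_vocab_size <- length(p0$drugs)
  E <- init_embeddings(d$vocab, "random", 8L)
  ref <- init_encoder(cfg2, embeddings = E)
  expect_identical(p0$encoder$E, ref$E)
  expect_identical(p0$encoder$fwd, ref$fwd)
  expect_identical(nrow(p0$log), 0L)
})

test_that("separable pretraining loss is non-increasing early on", {
  d <- toy_pretrain_data(signal = 1)
  cfg <- model_config(token_vocab_size = vocab_size(d$vocab),
                      embed_dim = 16L, hidden_dim = 16L)
  tr <- train_config(phase1 = list(epochs = 5L, batch_size = 32L), seed = 1L)
  p <- pretrain(d$masked, d$vocab, cfg, tr)
  expect_true(all(diff(p$log$loss) <= 1e-6))
})

test_that("fine-tuning with zero epochs keeps the transferred encoder", {
  d <- toy_pretrain_data()
  cfg <- model_config(token_vocab_size = vocab_size(d$vocab),
                      embed_dim = 8L, hidden_dim = 8L)
  tr <- train_config(phase1 = list(epochs = 1L, batch_size = 32L),
                     phase2 = list(epochs = 0L), seed = 4L)
  pre <- pretrain(d$masked, d$vocab, cfg, tr)
  lab <- generate_labeled(d$gen, d$world)
  recs <- prepare_labeled_records(lab$docs, lab$annotations, d$vocab, 12L)
  tg <- finetune(recs, d$vocab, cfg, tr, encoder = pre)
  expect_identical(tg$encoder$E, pre$encoder$E)
  expect_identical(tg$encoder$fwd, pre$encoder$fwd)
})

test_that("one epoch of fine-tuning updates all transferred weight groups", {
  d <- toy_pretrain_data()
  cfg <- model_config(token_vocab_size = vocab_size(d$vocab),
                      embed_dim = 8L, hidden_dim = 8L)
  tr <- train_config(phase1 = list(epochs = 1L, batch_size = 32L),
                     phase2 = list(epochs = 1L), seed = 4L)
  pre <- pretrain(d$masked, d$vocab, cfg, tr)
  lab <- generate_labeled(d$gen, d$world)
  recs <- prepare_labeled_records(lab$docs, lab$annotations, d$vocab, 12L)
  tg <- finetune(recs, d$vocab, cfg, tr, encoder = pre)
  expect_gt(norm(tg$encoder$fwd$Wu - pre$encoder$fwd$Wu, "F"), 0)
  expect_gt(norm(tg$encoder$bwd$Ic - pre$encoder$bwd$Ic, "F"), 0)
  expect_gt(norm(tg$encoder$E - pre$encoder$E, "F"), 0)  # nothing frozen
})

test_that("fine-tuning is seed-reproducible and warns on all-O corpora", {
  d <- toy_pretrain_data()
  cfg <- model_config(token_vocab_size = vocab_size(d$vocab),
                      embed_dim = 8L, hidden_dim = 8L)
  tr <- train_config(phase2 = list(epochs = 2L), seed = 6L)
  lab <- generate_labeled(d$gen, d$world)
  recs <- prepare_labeled_records(lab$docs, lab$annotations, d$vocab, 12L)
  t1 <- finetune(recs, d$vocab, cfg, tr)
  t2 <- finetune(recs, d$vocab, cfg, tr)
  expect_identical(t1$encoder, t2$encoder)
  expect_identical(t1$tag_head, t2$tag_head)
  expect_identical(t1$log, t2$log)
  allo <- lapply(recs[1:3], function(r) {
    r$tags[r$tags != PAD_TOK] <- "O"
    r
  })
  expect_warning(finetune(allo, d$vocab, cfg,
                          train_config(phase2 = list(epochs = 1L), seed = 1L)),
                 "no entity tags")
})

test_that("YAML training configs mirror train_config()", {
  skip_if_not_installed("yaml")
  path <- tempfile(fileext = ".yaml")
  writeLines(c("phase1:", "  epochs: 7", "  batch_size: 64",
               "phase2:", "  epochs: 2", "seed: 42"), path)
  tr <- read_train_config(path)
  expect_identical(tr$phase1$epochs, 7L)
  expect_identical(tr$phase1$batch_size, 64L)
  expect_identical(tr$phase1$lr, 1e-3)  # default survives partial override
  expect_identical(tr$phase2$epochs, 2L)
  expect_identical(tr$phase2$batch_size, 1L)
  expect_identical(tr$seed, 42L)
  bad <- tempfile(fileext = ".yaml")
  writeLines("optimizer: sgd", bad)
  expect_error(read_train_config(bad), "unknown training-config field")
})

test_that("checkpoints round-trip through save and load", {
  d <- toy_pretrain_data()
  cfg <- model_config(token_vocab_size = vocab_size(d$vocab),
                      embed_dim = 8L, hidden_dim = 8L)
  tr <- train_config(phase1 = list(epochs = 1L, batch_size = 32L), seed = 2L)
  pre <- pretrain(d$masked, d$vocab, cfg, tr)
  path <- tempfile(fileext = ".rds")
  save_checkpoint(pre, path)
  back <- load_checkpoint(path)
  expect_identical(back$encoder, pre$encoder)
  junk <- tempfile(fileext = ".rds")
  saveRDS(list(1, 2), junk)
  expect_error(load_checkpoint(junk), "not an adrtag checkpoint")
})
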