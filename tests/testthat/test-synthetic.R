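test_that("synthetic corpora follow the configured class proportions", {
  cfg <- syntheticConfig(n = 1000, seed = 31)
  cp <- generateCorpus(cfg)
  expect_equal(nMessages(cp), 1000L)
  cd <- classDistribution(cp)
  for (cl in cd$label) {
    p <- cfg$proportions[[cl]]
    bounds <- qbinom(c(0.005, 0.995), 1000, p) # binomial 99% band
    cnt <- cd$count[cd$label == cl]
    expect_gte(cnt, bounds[1])
    expect_lte(cnt, bounds[2])
  }
})

test_that("with q = 0 every message uses keywords of exactly one class", {
  cfg <- syntheticConfig(n = 200, q = 0, seed = 32)
  cp <- generateCorpus(cfg)
  vocab <- ConcernFusion:::syntheticVocab
  labs <- messageLabels(cp)
  txts <- messageText(cp)
  for (id in messageIds(cp)) {
    toks <- strsplit(gsub("[[:punct:]]+", " ", tolower(txts[[id]])),
                     "[[:space:]]+")[[1]]
    for (other in setdiff(names(vocab), labs[[id]])) {
      expect_length(intersect(toks, vocab[[other]]$keywords), 0)
    }
  }
})

test_that("with q > 0 some messages carry a secondary topic, label unchanged", {
  cfg <- syntheticConfig(n = 300, q = 0.5, seed = 33)
  cp <- generateCorpus(cfg)
  vocab <- ConcernFusion:::syntheticVocab
  labs <- messageLabels(cp)
  multi <- vapply(messageIds(cp), function(id) {
    toks <- strsplit(gsub("[[:punct:]]+", " ",
                          tolower(messageText(cp)[[id]])),
                     "[[:space:]]+")[[1]]
    sum(vapply(names(vocab), function(cl) {
      length(intersect(toks, vocab[[cl]]$keywords)) > 0
    }, logical(1))) > 1
  }, logical(1))
  expect_gt(mean(multi), 0.3) # about half should touch a second topic
})

test_that("the generator is deterministic given its seed", {
  cfg <- syntheticConfig(n = 100, seed = 34)
  c1 <- generateCorpus(cfg); c2 <- generateCorpus(cfg)
  expect_identical(c1@messages, c2@messages)
  e1 <- generateEmbeddings(cfg, c1); e2 <- generateEmbeddings(cfg, c2)
  for (k in seq_along(e1)) {
    expect_identical(e1[[k]]@embedding, e2[[k]]@embedding)
  }
  cfgB <- syntheticConfig(n = 100, seed = 35)
  expect_false(identical(generateCorpus(cfgB)@messages, c1@messages))
})

test_that("vanishing noise with unit gains collapses classes to points", {
  cfg <- syntheticConfig(n = 60, dim = 8, sigma = 1e-9,
                         complementary = list(e1 = c("A", "L", "P", "U"),
                                              e2 = c("A", "L", "P", "U"),
                                              e3 = c("A", "L", "P", "U")),
                         seed = 36)
  cp <- generateCorpus(cfg)
  emb <- generateEmbeddings(cfg, cp)
  labs <- unname(messageLabels(cp))
  M <- emb[[1]]@embedding
  for (cl in unique(labs)) {
    rowsC <- M[labs == cl, , drop = FALSE]
    expect_lt(max(abs(sweep(rowsC, 2, rowsC[1, ]))), 1e-6)
  }
})

test_that("an encoder's complementary classes are easier for it to recall", {
  cfg <- syntheticConfig(n = 2000, seed = 37)
  cp <- generateCorpus(cfg)
  emb <- generateEmbeddings(cfg, cp)
  # encoder 2 resolves P only (gain 1) and everything else at gammaLow
  mdl <- fitBaselineHead(emb$enc2, cp, seed = 1)
  pr <- predict(mdl, emb$enc2)
  mr <- suppressWarnings(
    computeMetrics(unname(messageLabels(cp)),
                   unname(predictionLabels(pr)[messageIds(cp)]),
                   corpusSchema(cp)))
  pc <- mr@perClass
  recP <- pc$recall[pc$label == "P"]
  recOther <- mean(pc$recall[pc$label != "P"])
  expect_gte(recP - recOther, 0.2)
})

test_that("disagreement rate increases with the noise scale", {
  rateAt <- function(sigma) {
    cfg <- syntheticConfig(n = 600, sigma = sigma, seed = 38)
    cp <- generateCorpus(cfg)
    emb <- generateEmbeddings(cfg, cp)
    preds <- lapply(emb, function(e) {
      predict(fitBaselineHead(e, cp, seed = 2), e)
    })
    sp <- splitByAgreement(unname(preds))
    length(disagreedIds(sp)) / nMessages(cp)
  }
  rates <- vapply(c(0.5, 1, 2), rateAt, numeric(1))
  expect_true(all(diff(rates) > 0))
})

test_that("synthetic studies round-trip through their on-disk form", {
  dir <- withr::local_tempdir()
  cfg <- syntheticConfig(n = 50, dim = 6, seed = 39)
  study <- writeSyntheticStudy(cfg, dir)
  cp <- loadCorpus(file.path(dir, "corpus.jsonl"))
  expect_identical(cp@messages, study$corpus@messages)
  e1 <- readEmbeddingSet(file.path(dir, "embeddings_enc1.csv"))
  expect_equal(e1@embedding, study$embeddings$enc1@embedding,
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_true(file.exists(file.path(dir, "manifest.json")))
})
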