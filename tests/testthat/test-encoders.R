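test_that("mock encoding is deterministic and handles degenerate text", {
  sp <- encoderSpec("mock-a", dim = 16)
  cp <- corpus(id = c("m1", "m2", "m3", "m4"),
               text = c("knee pain today", "knee pain today", "", "   . , !"))
  e1 <- encodeMessages(sp, cp)
  e2 <- encodeMessages(sp, cp)
  expect_identical(embeddingMatrix(e1), embeddingMatrix(e2))
  M <- embeddingMatrix(e1)
  expect_equal(M["m1", ], M["m2", ])              # identical texts
  expect_equal(unname(M["m3", ]), rep(0, 16))     # empty text -> zero vector
  expect_equal(unname(M["m4", ]), rep(0, 16))     # punctuation only
})

test_that("mean pooling matches an independent token-hash oracle", {
  sp <- encoderSpec("mock-a", dim = 8, hashSeed = 4)
  cp <- corpus(id = c("m1", "m2", "m3"),
               text = c("pain", "pain pain", "Pain, pain!"))
  M <- embeddingMatrix(encodeMessages(sp, cp))
  # repeated / re-punctuated copies of one token pool to the same vector
  expect_equal(M["m1", ], M["m2", ])
  expect_equal(M["m1", ], M["m3", ])
  # independent re-derivation of the token vector: 31-bit polynomial hash
  # over UTF-8 bytes, seeded Gaussian draw, unit normalization
  h <- 17 + 4
  for (b in utf8ToInt("pain")) h <- (h * 31 + b) %% 2147483629
  v <- withr::with_seed(as.integer(h), rnorm(8))
  v <- v / sqrt(sum(v^2))
  expect_equal(unname(M["m1", ]), v, tolerance = 1e-12)
})

test_that("permuting input messages permutes embedding rows identically", {
  sp <- encoderSpec("mock-a", dim = 12)
  texts <- c(m1 = "refill the prescription", m2 = "schedule a visit",
             m3 = "pain and swelling")
  M <- embeddingMatrix(encodeMessages(sp, corpus(names(texts), texts)))
  perm <- c("m3", "m1", "m2")
  Mp <- embeddingMatrix(encodeMessages(sp, corpus(perm, texts[perm])))
  expect_equal(Mp, M[perm, ])
})

test_that("over-long texts are truncated with a warning, not an error", {
  sp <- encoderSpec("mock-a", dim = 8, maxTokens = 3)
  long <- paste(rep("word", 10), collapse = " ")
  cp <- corpus(id = c("m1", "m2"), text = c(long, "word word word"))
  expect_warning(M <- embeddingMatrix(encodeMessages(sp, cp)), "truncated")
  expect_equal(M["m1", ], M["m2", ])
})

test_that("encoding 1000 short messages is fast on one CPU", {
  sp <- encoderSpec("mock-a", dim = 64)
  texts <- paste("message number", 1:1000, "about pain refill visit")
  cp <- corpus(id = paste0("m", 1:1000), text = texts)
  el <- system.time(encodeMessages(sp, cp))[["elapsed"]]
  expect_lt(el, 5)
})

test_that("unavailable checkpoint backends error naming the checkpoint", {
  sp <- encoderSpec("rob", category = "generic", dim = 8,
                    backend = "some-org/some-checkpoint")
  expect_error(encodeMessages(sp, corpus("m1", "text")),
               "some-org/some-checkpoint")
})

test_that("baseline fine-tuning separates separable classes like a linear oracle", {
  fx <- separableEmbeddings(n = 120, dim = 8, seed = 7)
  mdl <- fitBaselineHead(fx$embeddings, fx$corpus, seed = 1)
  expect_gte(mdl@metadata$trainAccuracy, 0.95)
  # independent multinomial-logistic oracle confirms separability
  or <- nnet::multinom(label ~ ., decay = 1e-4, trace = FALSE,
                       data = data.frame(label = factor(unname(messageLabels(fx$corpus))),
                                         fx$embeddings@embedding))
  expect_gte(mean(predict(or) ==
                    unname(messageLabels(fx$corpus))), 0.95)
})

test_that("head training is deterministic given the seed", {
  fx <- separableEmbeddings(n = 40, dim = 6, seed = 8)
  m1 <- fitBaselineHead(fx$embeddings, fx$corpus, seed = 9)
  m2 <- fitBaselineHead(fx$embeddings, fx$corpus, seed = 9)
  expect_identical(m1@head, m2@head)
  m3 <- fitBaselineHead(fx$embeddings, fx$corpus, seed = 10)
  expect_false(identical(m1@head$W, m3@head$W))
})

test_that("training refuses a set that misses a schema class", {
  cp <- tinyCorpus(rep("A", 10))
  emb <- embeddingSet("e", messageIds(cp), matrix(rnorm(10 * 4), 10))
  expect_error(fitBaselineHead(emb, cp), "absent")
})

test_that("prediction sets derive labels by schema-order tie-broken argmax", {
  sch <- labelSchema()
  ps <- predictionSet("m", sch, c("x", "y"),
                      rbind(rep(0.25, 4), c(0.1, 0.7, 0.1, 0.1)))
  expect_equal(unname(predictionLabels(ps)), c("A", "L"))
  # alignment contract: n in, n out, id order preserved
  fx <- separableEmbeddings(n = 20, dim = 6, seed = 3)
  mdl <- fitBaselineHead(fx$embeddings, fx$corpus, seed = 2)
  pr <- predict(mdl, fx$embeddings)
  expect_equal(predictionIds(pr), messageIds(fx$corpus))
  expect_true(all(abs(rowSums(predictionProbs(pr)) - 1) < 1e-6))
})
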