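test_that("agreement routing follows the unanimity definition", {
  ids <- c("x", "y", "z")
  p1 <- hardPredictionSet("b1", ids, c("A", "A", "U"))
  p2 <- hardPredictionSet("b2", ids, c("A", "A", "U"))
  p3 <- hardPredictionSet("b3", ids, c("A", "L", "U"))
  sp <- splitByAgreement(list(p1, p2, p3))
  expect_setequal(agreedIds(sp), c("x", "z"))
  expect_equal(unname(consensusLabels(sp)[c("x", "z")]), c("A", "U"))
  expect_equal(disagreedIds(sp), "y")
  # unanimity everywhere -> empty disagreement
  spAll <- splitByAgreement(list(p1, p2))
  expect_length(disagreedIds(spAll), 0)
  # mismatched id sets are rejected with the symmetric difference
  p4 <- hardPredictionSet("b4", c("x", "w"), c("A", "A"))
  expect_error(splitByAgreement(list(p1, p4)), "w")
})

test_that("fusion training sets stack encoders in ascending name order", {
  ids <- c("x", "y", "z", "w")
  cp <- corpus(id = ids, text = "t", label = c("A", "L", "P", "U"))
  e2 <- embeddingSet("enc2", ids, matrix(seq_len(16), 4))
  e1 <- embeddingSet("enc1", ids, matrix(seq_len(16) + 100, 4))
  split <- new("DisagreementSplit", agreedIds = "w", consensus = "U",
               disagreedIds = c("x", "y", "z"))
  fts <- buildFusionTrainingSet(split, list(e2, e1), cp)
  expect_equal(dim(fts@stacks), c(3L, 2L, 4L))
  expect_equal(fts@encoderOrder, c("enc1", "enc2"))
  # row 1 of each stack belongs to enc1 regardless of input list order
  fts2 <- buildFusionTrainingSet(split, list(e1, e2), cp)
  expect_equal(fts@stacks, fts2@stacks)
  expect_equal(fts@stacks[1, 1, ], unname(embeddingMatrix(e1)["x", ]))
  expect_equal(fts@labels, c("A", "L", "P"))
  # missing embedding rows are reported as (encoder, id)
  e3 <- embeddingSet("enc1", c("x", "y"), matrix(0, 2, 4))
  expect_error(buildFusionTrainingSet(split, list(e3, e2), cp), "enc1")
})

test_that("an all-agreed split yields an empty training set with a warning", {
  cp <- corpus(id = c("x", "y"), text = "t", label = c("A", "L"))
  e1 <- embeddingSet("enc1", c("x", "y"), matrix(0, 2, 4))
  e2 <- embeddingSet("enc2", c("x", "y"), matrix(0, 2, 4))
  split <- new("DisagreementSplit", agreedIds = c("x", "y"),
               consensus = c("A", "L"), disagreedIds = character(0))
  expect_warning(fts <- buildFusionTrainingSet(split, list(e1, e2), cp),
                 "consensus")
  expect_length(fts@ids, 0)
  expect_error(trainFusion(fusionConfig("average", commonDim = 4), fts),
               "fallback")
})

test_that("dimension mismatches are reconciled by a recorded projection", {
  ids <- c("x", "y", "z")
  cp <- corpus(id = ids, text = "t", label = c("A", "L", "P"))
  e1 <- embeddingSet("enc1", ids, matrix(rnorm(9), 3, 3))
  e2 <- embeddingSet("enc2", ids, matrix(rnorm(18), 3, 6))
  split <- new("DisagreementSplit", agreedIds = character(0),
               consensus = character(0), disagreedIds = ids)
  fts <- buildFusionTrainingSet(split, list(e1, e2), cp, commonDim = 3)
  expect_equal(dim(fts@stacks), c(3L, 2L, 3L))
  expect_identical(fts@projections$enc1, "identity")
  expect_equal(dim(fts@projections$enc2), c(6L, 3L))
  expect_equal(fts@stacks[, 2, ],
               unname(embeddingMatrix(e2)) %*% fts@projections$enc2)
})

test_that("average fusion equals the row mean through the dense layer", {
  r <- c(1.5, -2, 0.5)
  stack <- rbind(r, r, r)
  W <- matrix(c(0.2, -0.1, 0.3, 0, 0.5, -0.4, 0.1, 0.2, -0.2, 0.4, 0, 0.1),
              3, 4)
  b <- c(0.1, -0.1, 0, 0.2)
  expect_equal(fuseAverage(stack, W, b),
               drop(exp(r %*% W + b) / sum(exp(r %*% W + b))),
               tolerance = 1e-12)
  # opposite rows cancel: probabilities reduce to softmax of the bias
  expect_equal(fuseAverage(rbind(r, -r), W, b), drop(exp(b) / sum(exp(b))),
               tolerance = 1e-12)
  # zero weights give uniform probabilities
  expect_equal(fuseAverage(stack, matrix(0, 3, 4), rep(0, 4)), rep(0.25, 4))
})

test_that("attention fusion matches a hand-computed softmax on a 2x2 stack", {
  stack <- rbind(c(1, 2), c(-1, 0.5))
  Wa <- rbind(c(0.3, -0.2), c(0.1, 0.4))
  v <- c(0.7, -0.5)
  W <- matrix(c(0.2, -0.3, 0.1, 0, 0.4, -0.1, 0.25, 0.05), 2, 4)
  b <- rep(0, 4)
  out <- fuseAttention(stack, Wa, v, W, b)
  scores <- as.numeric(tanh(stack %*% t(Wa)) %*% v)
  wExp <- exp(scores) / sum(exp(scores))
  expect_equal(out$weights, wExp, tolerance = 1e-12)
  expect_equal(sum(out$weights), 1, tolerance = 1e-9)
  fused <- colSums(wExp * stack)
  expect_equal(out$probs, drop(exp(fused %*% W) / sum(exp(fused %*% W))),
               tolerance = 1e-12)
  # identical rows share the weight equally
  same <- fuseAttention(rbind(c(1, 2), c(1, 2), c(1, 2)), Wa, v,
                        matrix(0, 2, 4), b)
  expect_equal(same$weights, rep(1 / 3, 3))
})

test_that("CNN fusion pooling matches a brute-force convolution oracle", {
  stack <- rbind(c(1, -2, 3), c(-0.5, 4, 0.25))
  f <- list(h = 2L, w = 2L,
            W = matrix(c(0.5, -1, 0.25, 2), 4, 1), b = 0.1)
  out <- fuseCnn(stack, list(f), denseW = matrix(1, 1, 4),
                 denseB = rep(0, 4))
  # brute force: every valid 2x2 patch, column-major flattening
  vals <- vapply(1:2, function(j) {
    patch <- as.vector(stack[1:2, j:(j + 1)])
    max(sum(patch * f$W[, 1]) + f$b, 0)
  }, numeric(1))
  expect_equal(out$pooled, max(vals), tolerance = 1e-12)
  # zero stack with zero-bias filters propagates to uniform probabilities
  zf <- list(h = 2L, w = 2L, W = matrix(1, 4, 2), b = c(0, 0))
  z <- fuseCnn(matrix(0, 2, 3), list(zf), denseW = matrix(1, 2, 4),
               denseB = rep(0, 4))
  expect_equal(z$probs, rep(0.25, 4))
  # filter taller than the stack is a configuration error
  bad <- list(h = 3L, w = 2L, W = matrix(1, 6, 1), b = 0)
  expect_error(fuseCnn(stack, list(bad), matrix(1, 1, 4), rep(0, 4)),
               "height")
})

test_that("fusion heads train to high accuracy on separable stacks", {
  # complementary construction: encoder 1 carries the signal for A/L,
  # encoder 2 for P/U; either alone is ambiguous, the stack is separable
  cls <- c("A", "L", "P", "U")
  n <- 160
  labels <- rep(cls, length.out = n)
  ids <- sprintf("d%03d", seq_len(n))
  cp <- corpus(id = ids, text = "t", label = labels)
  stacksFor <- function(seed) {
    withr::with_seed(seed, {
      e1 <- matrix(rnorm(n * 8, sd = 0.3), n, 8)
      e2 <- matrix(rnorm(n * 8, sd = 0.3), n, 8)
      i <- match(labels, cls)
      sel1 <- i <= 2
      e1[cbind(which(sel1), i[sel1])] <- e1[cbind(which(sel1), i[sel1])] + 4
      sel2 <- i > 2
      e2[cbind(which(sel2), i[sel2])] <- e2[cbind(which(sel2), i[sel2])] + 4
      list(embeddingSet("enc1", ids, e1), embeddingSet("enc2", ids, e2))
    })
  }
  emb <- stacksFor(31)
  split <- new("DisagreementSplit", agreedIds = character(0),
               consensus = character(0), disagreedIds = ids)
  fts <- buildFusionTrainingSet(split, emb, cp, commonDim = 8)
  for (strat in c("average", "attention", "cnn")) {
    cfg <- fusionConfig(strat, commonDim = 8, epochs = 200, seed = 4)
    fm <- trainFusion(cfg, fts)
    expect_gte(fm@metadata$trainAccuracy, 0.95)
    pr <- predict(fm, fts)
    expect_equal(predictionIds(pr), ids)
    expect_true(all(abs(rowSums(predictionProbs(pr)) - 1) < 1e-6))
    # deterministic given the seed
    fm2 <- trainFusion(cfg, fts)
    expect_identical(fm@params, fm2@params)
  }
  # a single-class training set is rejected
  oneClass <- new("FusionTrainingSet", ids = ids[labels == "A"],
                  stacks = fts@stacks[labels == "A", , , drop = FALSE],
                  labels = labels[labels == "A"],
                  encoderOrder = fts@encoderOrder, commonDim = 8L,
                  projections = fts@projections, schema = cp@schema)
  expect_error(trainFusion(fusionConfig("average", commonDim = 8), oneClass),
               "2 classes")
})

test_that("dropout is inactive at prediction time", {
  fx <- separableEmbeddings(n = 60, dim = 6, seed = 12, name = "enc1")
  e2 <- embeddingSet("enc2", messageIds(fx$corpus),
                     embeddingMatrix(fx$embeddings) + 0.1)
  split <- new("DisagreementSplit", agreedIds = character(0),
               consensus = character(0),
               disagreedIds = messageIds(fx$corpus))
  fts <- buildFusionTrainingSet(split, list(fx$embeddings, e2), fx$corpus,
                                commonDim = 6)
  fm <- trainFusion(fusionConfig("cnn", commonDim = 6, cnnDropout = 0.5,
                                 epochs = 60, seed = 2), fts)
  p1 <- predictionProbs(predict(fm, fts))
  rnorm(100) # perturb the RNG stream between calls
  p2 <- predictionProbs(predict(fm, fts))
  expect_identical(p1, p2)
})

test_that("combining restores full coverage with single-source provenance", {
  sch <- labelSchema()
  split <- new("DisagreementSplit", agreedIds = c("a1", "a2"),
               consensus = c("A", "U"), disagreedIds = "d1")
  fused <- hardPredictionSet("fusion_cnn", "d1", "P")
  out <- combinePredictions(split, fused)
  expect_setequal(predictionIds(out), c("a1", "a2", "d1"))
  lab <- predictionLabels(out)
  expect_equal(unname(lab[c("a1", "a2", "d1")]), c("A", "U", "P"))
  src <- predictionSource(out)
  expect_equal(unname(src[c("a1", "a2", "d1")]),
               c("consensus", "consensus", "fusion"))
  # every id has exactly one provenance source
  expect_true(all(src %in% c("consensus", "fusion")))
  # vacuous cases
  emptyFused <- predictionSet("f", sch, character(0), matrix(0, 0, 4))
  allAgreed <- new("DisagreementSplit", agreedIds = c("a1", "a2"),
                   consensus = c("A", "U"), disagreedIds = character(0))
  outA <- combinePredictions(allAgreed, emptyFused)
  expect_equal(unname(predictionSource(outA)), rep("consensus", 2))
  allDis <- new("DisagreementSplit", agreedIds = character(0),
                consensus = character(0), disagreedIds = "d1")
  outD <- combinePredictions(allDis, fused)
  expect_equal(unname(predictionSource(outD)), "fusion")
  # coverage mismatch is an error
  expect_error(combinePredictions(split, hardPredictionSet("f", "zz", "A")),
               "zz")
})

test_that("duplicating one row K times leaves the average head unchanged", {
  r <- c(0.3, -1.2, 0.8, 0.05)
  W <- withr::with_seed(1, matrix(rnorm(16), 4, 4))
  b <- withr::with_seed(2, rnorm(4))
  single <- fuseAverage(matrix(r, 1), W, b)
  for (K in 2:4) {
    stack <- matrix(rep(r, each = K), K) # K identical rows
    expect_equal(fuseAverage(stack, W, b), single, tolerance = 1e-12)
    # attention weights over identical rows are uniform, so it agrees too
    att <- fuseAttention(stack, Wa = matrix(0.3, 2, 4), v = c(1, -1), W, b)
    expect_equal(att$probs, single, tolerance = 1e-12)
    expect_equal(att$weights, rep(1 / K, K))
  }
})
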