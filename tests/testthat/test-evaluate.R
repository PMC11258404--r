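test_that("metrics match a hand-computed confusion matrix", {
  mr <- suppressWarnings(
    computeMetrics(c("A", "A", "L", "L"), c("A", "L", "A", "L")))
  expect_equal(mr@accuracy, 0.5)
  pc <- mr@perClass
  expect_equal(pc$f1[pc$label == "A"], 0.5)
  expect_equal(pc$f1[pc$label == "L"], 0.5)
  # perfect predictions
  mp <- suppressWarnings(computeMetrics(c("A", "L", "P", "U"),
                                        c("A", "L", "P", "U")))
  expect_equal(mp@accuracy, 1)
  expect_equal(unname(mp@macro["f1"]), 1)
  expect_error(computeMetrics(c("A", "L"), "A"), "length")
})

test_that("degenerate single-class predictions score zero elsewhere", {
  expect_warning(mr <- computeMetrics(c("A", "L", "P", "U"),
                                      rep("A", 4)), "zero denominator")
  pc <- mr@perClass
  expect_equal(pc$recall[pc$label == "A"], 1)
  expect_equal(pc$f1[pc$label != "A"], rep(0, 3))
})

test_that("macro-F1 is invariant to a consistent class renaming", {
  withr::with_seed(5, {
    truth <- sample(c("A", "L", "P", "U"), 200, replace = TRUE)
    preds <- ifelse(runif(200) < 0.7, truth,
                    sample(c("A", "L", "P", "U"), 200, replace = TRUE))
  })
  m1 <- suppressWarnings(computeMetrics(truth, preds))
  ren <- c(A = "P", L = "U", P = "A", U = "L")
  m2 <- suppressWarnings(computeMetrics(unname(ren[truth]),
                                        unname(ren[preds])))
  expect_equal(m1@macro, m2@macro, tolerance = 1e-12)
  expect_equal(m1@accuracy, m2@accuracy)
})

test_that("run aggregation reports mean, n-1 SD and a t-interval", {
  a <- aggregateRuns(c(0.7, 0.8))
  expect_equal(a$mean, 0.75)
  expect_equal(a$sd, 0.0707107, tolerance = 1e-6)
  expect_true(a$ciLo <= a$mean && a$mean <= a$ciHi)
  cst <- aggregateRuns(rep(0.6, 5))
  expect_equal(cst$sd, 0)
  expect_equal(cst$ciHi - cst$ciLo, 0)
  # CI always contains the mean; normal variant is narrower for small n
  withr::with_seed(2, {
    for (i in 1:10) {
      sc <- runif(sample(2:30, 1))
      at <- aggregateRuns(sc)
      expect_true(at$ciLo <= at$mean && at$mean <= at$ciHi)
      an <- aggregateRuns(sc, method = "normal")
      expect_lte(an$ciHi - an$ciLo, at$ciHi - at$ciLo + 1e-12)
    }
  })
  expect_error(aggregateRuns(0.5), "at least 2")
})

test_that("disagreement buckets follow the 0/2/3 distinct-label naming", {
  ids <- c("u", "v", "w")
  p1 <- hardPredictionSet("b1", ids, c("A", "A", "A"))
  p2 <- hardPredictionSet("b2", ids, c("A", "A", "L"))
  p3 <- hardPredictionSet("b3", ids, c("A", "L", "P"))
  bk <- bucketByDistinctLabels(list(p1, p2, p3))
  expect_equal(unname(bk[ids]), c(0L, 2L, 3L))
  expect_error(bucketByDistinctLabels(list(p1, p2)), "3 baselines")
})

test_that("bucket accuracies recombine exactly to overall accuracy", {
  withr::with_seed(11, {
    ids <- paste0("m", 1:300)
    truth <- stats::setNames(sample(c("A", "L", "P", "U"), 300,
                                    replace = TRUE), ids)
    preds <- lapply(1:3, function(k) randomPredictionSet(paste0("b", k),
                                                         ids, seed = k))
  })
  bk <- bucketByDistinctLabels(preds)
  br <- bucketReport(bk, truth, list(b1 = preds[[1]]))
  overall <- mean(unname(predictionLabels(preds[[1]])[ids]) == truth[ids])
  recombined <- sum(br$n * br$accuracy) / sum(br$n[!duplicated(br$bucket)])
  expect_equal(sum(br$n[!duplicated(br$bucket)]), 300)
  expect_equal(recombined, overall, tolerance = 1e-12)
})

test_that("per-category selection maximizes macro-F1 with accuracy tie-break", {
  agg <- function(f1, acc) list(macroF1 = list(mean = f1),
                                accuracy = list(mean = acc))
  aggs <- list(g1 = agg(0.70, 0.74), g2 = agg(0.71, 0.70),
               d1 = agg(0.65, 0.74), d2 = agg(0.65, 0.75),
               s1 = agg(0.60, 0.60))
  cats <- c(g1 = "generic", g2 = "generic", d1 = "domain", d2 = "domain",
            s1 = "source")
  best <- selectBestPerCategory(aggs, cats)
  expect_equal(best[["generic"]], "g2")  # higher macro-F1
  expect_equal(best[["domain"]], "d2")   # macro-F1 tie, higher accuracy
  expect_equal(best[["source"]], "s1")   # single member
  expect_error(selectBestPerCategory(aggs["g1"], c(x = "other")),
               "no models")
})

test_that("the cross-validated experiment runs end-to-end and is deterministic", {
  cfg <- syntheticConfig(n = 240, dim = 8, seed = 21)
  cp <- generateCorpus(cfg)
  emb <- generateEmbeddings(cfg, cp)
  plan <- makeFoldPlan(cp, nFolds = 3, nRepeats = 1, seed = 21)
  fc <- fusionConfig("cnn", commonDim = 8, epochs = 60, seed = 21)
  res <- runExperiment(cp, emb, fc, plan = plan, seed = 21,
                       headEpochs = 150)
  models <- unique(res$runScores$model)
  expect_setequal(models, c("enc1", "enc2", "enc3", "routed_fusion",
                            "mv_ensemble"))
  # one accuracy and one macro-F1 score per model per (repeat, fold)
  expect_equal(nrow(res$runScores), length(models) * 3 * 2)
  expect_true(all(res$runScores$value >= 0 & res$runScores$value <= 1))
  res2 <- runExperiment(cp, emb, fc, plan = plan, seed = 21,
                        headEpochs = 150)
  expect_identical(res$runScores, res2$runScores)
  expect_identical(res$aggregates, res2$aggregates)
  # audit trail: no test id leaks into any training stage
  for (run in res$audit) {
    trained <- unique(c(unlist(run$fineTuneIds), run$fusionTrainIds))
    expect_length(intersect(run$testIds, trained), 0)
  }
  # bucket totals recombine to the overall routed accuracy
  bt <- res$bucketTotals
  routedAcc <- res$runScores$value[res$runScores$model == "routed_fusion" &
                                     res$runScores$metric == "accuracy"]
  nTest <- sum(bt$n[bt$model == "routed_fusion"])
  expect_equal(sum(bt$correct[bt$model == "routed_fusion"]) / nTest,
               sum(routedAcc * 80) / 240, tolerance = 1e-9)
})
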