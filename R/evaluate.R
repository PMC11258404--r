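#' Accuracy and per-class precision / recall / F1
#'
#' Computes the confusion matrix of `preds` against `truth` over all
#' schema classes and derives overall accuracy, per-class precision
#' `TP/(TP+FP)`, recall `TP/(TP+FN)` and F1 (their harmonic mean), plus
#' macro averages (unweighted means over all schema classes, so rare
#' classes count as much as common ones). A class with a zero denominator
#' scores 0 for the affected metric, with a warning.
#'
#' @param truth character vector of gold labels.
#' @param preds character vector of predicted labels, aligned with
#'   `truth`.
#' @param schema a [LabelSchema-class].
#' @return A [MetricsReport-class].
#' @examples
#' computeMetrics(c("A", "A", "L", "L"), c("A", "L", "A", "L"))
#' @export
computeMetrics <- function(truth, preds, schema = labelSchema()) {
  if (length(truth) != length(preds)) {
    stopf("truth (%d) and preds (%d) must have the same length",
          length(truth), length(preds))
  }
  if (length(truth) == 0L) stopf("cannot score an empty set")
  cls <- schema@labels
  cm <- table(factor(truth, levels = cls), factor(preds, levels = cls))
  tp <- diag(cm)
  fp <- colSums(cm) - tp
  fn <- rowSums(cm) - tp
  zdiv <- function(num, den) ifelse(den > 0, num / den, 0)
  if (any(tp + fp == 0) || any(tp + fn == 0)) {
    warnf("class(es) with zero denominator score 0: %s",
          paste(cls[(tp + fp == 0) | (tp + fn == 0)], collapse = ", "))
  }
  precision <- zdiv(tp, tp + fp)
  recall <- zdiv(tp, tp + fn)
  f1 <- zdiv(2 * precision * recall, precision + recall)
  perClass <- data.frame(label = cls, precision = unname(precision),
                         recall = unname(recall), f1 = unname(f1),
                         stringsAsFactors = FALSE)
  new("MetricsReport", accuracy = sum(tp) / length(truth),
      perClass = perClass,
      macro = c(precision = mean(precision), recall = mean(recall),
                f1 = mean(f1)),
      n = length(truth))
}

#' Aggregate run-level scores: mean, SD and confidence interval
#'
#' Summarizes the scores of the cross-validation runs (e.g. the 30 runs of
#' 10 folds x 3 repeats): their mean, sample standard deviation (n-1
#' denominator) and a 95% confidence interval, t-based by default
#' (`mean +/- t_{0.975, n-1} * SD / sqrt(n)`) with a normal-approximation
#' alternative.
#'
#' @param scores numeric vector of n >= 2 run-level scores.
#' @param conf confidence level (default 0.95).
#' @param method `"t"` (default) or `"normal"`.
#' @return named list: `mean`, `sd`, `ciLo`, `ciHi`, `n`.
#' @examples
#' aggregateRuns(c(0.7, 0.8))
#' @export
aggregateRuns <- function(scores, conf = 0.95, method = c("t", "normal")) {
  method <- match.arg(method)
  n <- length(scores)
  if (n < 2L) stopf("need at least 2 run scores, got %d", n)
  m <- mean(scores)
  s <- stats::sd(scores)
  q <- if (method == "t") stats::qt(1 - (1 - conf) / 2, df = n - 1)
       else stats::qnorm(1 - (1 - conf) / 2)
  half <- q * s / sqrt(n)
  list(mean = m, sd = s, ciLo = m - half, ciHi = m + half, n = n)
}

#' Bucket messages by the number of distinct baseline labels
#'
#' Groups messages by how many distinct labels the 3 baseline models
#' predicted for them, using the bucket naming "0 different labels"
#' (unanimous), "2 different labels" and "3 different labels": bucket 0,
#' 2 or 3 respectively.
#'
#' @param preds list of exactly 3 [PredictionSet-class] objects over
#'   identical ids (the bucket scheme is defined for 3 baselines).
#' @return integer vector of buckets (0, 2 or 3) named by message id.
#' @export
bucketByDistinctLabels <- function(preds) {
  if (length(preds) != 3L) {
    stopf("bucket analysis is defined for exactly 3 baselines, got %d",
          length(preds))
  }
  ids <- preds[[1]]@ids
  for (p in preds[-1]) {
    if (!setequal(p@ids, ids)) stopf("prediction sets cover different ids")
  }
  labMat <- vapply(preds, function(p) unname(predictionLabels(p)[ids]),
                   character(length(ids)))
  labMat <- matrix(labMat, nrow = length(ids))
  distinct <- apply(labMat, 1L, function(r) length(unique(r)))
  stats::setNames(ifelse(distinct == 1L, 0L, distinct), ids)
}

#' Per-bucket accuracy of one or more models
#'
#' For each disagreement bucket (0 / 2 / 3 distinct baseline labels),
#' reports the message count and each model's accuracy on that bucket.
#' Because buckets partition the messages, the count-weighted mean of the
#' bucket accuracies recombines exactly to overall accuracy.
#'
#' @param buckets named bucket vector from [bucketByDistinctLabels()].
#' @param truth named character vector of gold labels (ids as names).
#' @param preds named list of [PredictionSet-class] objects to score.
#' @return data.frame with columns `bucket`, `n`, `model`, `accuracy`.
#' @export
bucketReport <- function(buckets, truth, preds) {
  ids <- names(buckets)
  out <- list()
  for (b in sort(unique(buckets))) {
    sel <- ids[buckets == b]
    for (nm in names(preds)) {
      pl <- predictionLabels(preds[[nm]])[sel]
      out[[length(out) + 1L]] <- data.frame(
        bucket = b, n = length(sel), model = nm,
        accuracy = mean(pl == truth[sel]), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Select the best model per encoder category
#'
#' Picks, within each category (generic / domain-specific /
#' source-specific), the model with the highest mean macro-F1; mean
#' accuracy breaks ties.
#'
#' @param aggregates named list (by model) of lists containing `macroF1`
#'   and `accuracy` elements with a `mean` entry each (as produced by
#'   [aggregateRuns()]).
#' @param categories named character vector mapping model name to
#'   category.
#' @return named character vector mapping category to the winning model.
#' @export
selectBestPerCategory <- function(aggregates, categories) {
  cats <- unique(categories)
  out <- character(0)
  for (cat in cats) {
    models <- names(categories)[categories == cat]
    models <- intersect(models, names(aggregates))
    if (length(models) == 0L) stopf("category '%s' has no models", cat)
    f1 <- vapply(models, function(m) aggregates[[m]]$macroF1$mean,
                 numeric(1))
    acc <- vapply(models, function(m) aggregates[[m]]$accuracy$mean,
                  numeric(1))
    best <- models[order(-f1, -acc)][1L]
    out[cat] <- best
  }
  out
}

#' Run the full routed-fusion experiment under repeated stratified CV
#'
#' For every (repeat, fold) pair of the plan: fine-tune one baseline head
#' per encoder on the training folds (with the chosen rebalancing), route
#' the training messages by baseline agreement, train the fusion head on
#' the training-side disagreement examples, route the test fold the same
#' way, and score (a) each baseline, (b) the routed fusion model and (c)
#' the majority-vote ensemble of the baselines on the held-out fold. Test
#' folds are never touched by fine-tuning, oversampling or fusion
#' training; the returned audit trail records the ids each stage consumed
#' so this can be asserted.
#'
#' If the baselines agree on every training message, the fusion head
#' cannot be trained and the routed model degrades to consensus labels
#' (logged prominently).
#'
#' @param corpus a fully labeled [Corpus-class].
#' @param encoders either a list of mock [EncoderSpec-class] objects (the
#'   corpus texts are encoded once) or a list of precomputed
#'   [EmbeddingSet-class] objects covering the corpus.
#' @param fusionCfg a [FusionConfig-class].
#' @param rebalance a [RebalanceSpec-class] applied to baseline and fusion
#'   training.
#' @param plan a [FoldPlan-class] over the corpus ids.
#' @param seed base seed for all per-run training randomness.
#' @param headLr,headEpochs baseline head hyperparameters.
#' @return list with elements:
#'   \describe{
#'     \item{runScores}{data.frame (model, rep, fold, metric, value) of
#'       run-level scores (accuracy and macro-F1 per model and run).}
#'     \item{aggregates}{per model, [aggregateRuns()] summaries of
#'       accuracy and macro-F1 (list with `accuracy` and `macroF1`).}
#'     \item{bucketTotals}{data.frame (bucket, model, n, correct) summed
#'       over all runs, for the disagreement-bucket analysis.}
#'     \item{audit}{per run, the test ids and the ids used by each
#'       training stage.}
#'     \item{disagreementRate}{mean share of test messages routed to the
#'       fusion model.}
#'   }
#' @export
runExperiment <- function(corpus, encoders, fusionCfg,
                          rebalance = rebalanceSpec("class_weight"),
                          plan = makeFoldPlan(corpus), seed = 1L,
                          headLr = 0.05, headEpochs = 300L) {
  labs <- messageLabels(corpus)
  embeddings <- lapply(encoders, function(e) {
    if (is(e, "EmbeddingSet")) e else encodeMessages(e, corpus)
  })
  encNames <- vapply(embeddings, encoderName, character(1))
  names(embeddings) <- encNames
  scores <- list(); bucketRows <- list(); audit <- list()
  disRates <- numeric(0)
  modelNames <- c(encNames, "routed_fusion", "mv_ensemble")
  for (r in seq_len(plan@nRepeats)) {
    fa <- foldAssignment(plan, r)
    for (f in seq_len(plan@nFolds)) {
      testIds <- names(fa)[fa == f]
      trainIds <- names(fa)[fa != f]
      runSeed <- deriveSeed(seed, r, f)
      trainCorpus <- subsetCorpus(corpus, trainIds)
      baselines <- list(); trainPreds <- list(); testPreds <- list()
      usedIds <- list()
      for (k in seq_along(embeddings)) {
        nm <- encNames[k]
        embTrain <- subsetEmbeddings(embeddings[[k]], trainIds)
        mdl <- fitBaselineHead(embTrain, trainCorpus, rebalance = rebalance,
                               lr = headLr, epochs = headEpochs,
                               seed = deriveSeed(runSeed, k))
        baselines[[nm]] <- mdl
        usedIds[[nm]] <- mdl@metadata$trainedIds
        trainPreds[[nm]] <- predict(mdl, embTrain)
        testPreds[[nm]] <- predict(mdl, subsetEmbeddings(embeddings[[k]],
                                                         testIds))
      }
      trainSplit <- splitByAgreement(trainPreds)
      testSplit <- splitByAgreement(testPreds)
      fusionSeedCfg <- fusionCfg
      fusionSeedCfg@training$seed <- deriveSeed(runSeed, 99L)
      fused <- NULL
      fusionTrainIds <- character(0)
      if (length(trainSplit@disagreedIds) > 0L &&
          length(unique(messageLabels(trainCorpus)[trainSplit@disagreedIds]))
            >= 2L) {
        fts <- buildFusionTrainingSet(trainSplit, embeddings, trainCorpus,
                                      commonDim = fusionCfg@commonDim,
                                      projectionSeed = deriveSeed(seed, 17L))
        fmod <- trainFusion(fusionSeedCfg, fts, rebalance = rebalance)
        fusionTrainIds <- fmod@metadata$trainedIds
        if (length(testSplit@disagreedIds) > 0L) {
          fused <- predict(fmod, embeddings, ids = testSplit@disagreedIds)
        }
      } else {
        message(sprintf(
          "[rep %d fold %d] baselines agree on (nearly) all training messages; routed model falls back to consensus labels",
          r, f))
      }
      routed <- if (length(testSplit@disagreedIds) == 0L) {
        combinePredictions(testSplit,
                           predictionSet("fusion", corpus@schema,
                                         character(0),
                                         matrix(0, 0,
                                                length(schemaLabels(corpus)))),
                           idOrder = testIds)
      } else if (is.null(fused)) {
        # fallback: no trained fusion head; disagreed test messages keep the
        # first baseline's prediction
        fb <- testPreds[[1]]
        keep <- match(testSplit@disagreedIds, fb@ids)
        combinePredictions(testSplit,
                           predictionSet("fusion", fb@schema,
                                         testSplit@disagreedIds,
                                         fb@probs[keep, , drop = FALSE]),
                           idOrder = testIds)
      } else {
        combinePredictions(testSplit, fused, idOrder = testIds)
      }
      mv <- ensemblePredict(unname(testPreds), modelName = "mv_ensemble")
      allPreds <- c(testPreds, list(routed_fusion = routed,
                                    mv_ensemble = mv))
      for (nm in names(allPreds)) {
        mr <- computeMetrics(unname(labs[testIds]),
                             unname(predictionLabels(allPreds[[nm]])[testIds]),
                             corpus@schema)
        scores[[length(scores) + 1L]] <- data.frame(
          model = nm, rep = r, fold = f,
          metric = c("accuracy", "macro_f1"),
          value = c(mr@accuracy, unname(mr@macro["f1"])),
          stringsAsFactors = FALSE)
      }
      if (length(testPreds) == 3L) {
        bk <- bucketByDistinctLabels(unname(testPreds))
        br <- bucketReport(bk, labs[testIds], allPreds)
        br$correct <- round(br$accuracy * br$n)
        br$rep <- r; br$fold <- f
        bucketRows[[length(bucketRows) + 1L]] <- br
      }
      disRates <- c(disRates,
                    length(testSplit@disagreedIds) / length(testIds))
      audit[[sprintf("r%d_f%d", r, f)]] <- list(
        rep = r, fold = f, testIds = testIds, trainIds = trainIds,
        fineTuneIds = usedIds, fusionTrainIds = fusionTrainIds)
    }
  }
  runScores <- do.call(rbind, scores)
  aggregates <- lapply(stats::setNames(nm = modelNames), function(nm) {
    acc <- runScores$value[runScores$model == nm &
                             runScores$metric == "accuracy"]
    f1 <- runScores$value[runScores$model == nm &
                            runScores$metric == "macro_f1"]
    list(accuracy = aggregateRuns(acc), macroF1 = aggregateRuns(f1))
  })
  bucketTotals <- NULL
  if (length(bucketRows)) {
    allB <- do.call(rbind, bucketRows)
    bucketTotals <- stats::aggregate(
      cbind(n, correct) ~ bucket + model, data = allB, FUN = sum)
  }
  list(runScores = runScores, aggregates = aggregates,
       bucketTotals = bucketTotals, audit = audit,
       disagreementRate = mean(disRates))
}

# Subset helpers keeping object invariants intact.
subsetCorpus <- function(x, ids) {
  m <- x@messages[match(ids, x@messages$id), , drop = FALSE]
  rownames(m) <- NULL
  new("Corpus", schema = x@schema, messages = m)
}

subsetEmbeddings <- function(es, ids) {
  pos <- match(ids, es@ids)
  if (anyNA(pos)) stopf("id(s) missing from embedding set '%s'",
                        es@encoderName)
  embeddingSet(es@encoderName, ids, es@embedding[pos, , drop = FALSE])
}
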