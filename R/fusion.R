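#' Partition messages by baseline agreement
#'
#' The router at the heart of the framework: a message is *agreed* iff all
#' K baseline models predict the same label for it (that shared label is
#' its consensus label) and *disagreed* otherwise. Only disagreed messages
#' are sent to the fusion model; agreed messages keep the consensus label.
#'
#' @param preds list of K >= 2 [PredictionSet-class] objects covering
#'   identical id sets.
#' @return A [DisagreementSplit-class].
#' @examples
#' sch <- labelSchema()
#' p1 <- predictionSet("m1", sch, c("x", "y"), rbind(c(1,0,0,0), c(1,0,0,0)))
#' p2 <- predictionSet("m2", sch, c("x", "y"), rbind(c(1,0,0,0), c(0,1,0,0)))
#' splitByAgreement(list(p1, p2))
#' @export
splitByAgreement <- function(preds) {
  if (length(preds) < 2L) stopf("need at least 2 prediction sets")
  ids <- preds[[1]]@ids
  for (p in preds[-1]) {
    if (!setequal(p@ids, ids)) {
      diff <- c(setdiff(ids, p@ids), setdiff(p@ids, ids))
      stopf("prediction sets cover different ids; symmetric difference: %s",
            paste(diff, collapse = ", "))
    }
  }
  labMat <- vapply(preds, function(p) unname(predictionLabels(p)[ids]),
                   character(length(ids)))
  labMat <- matrix(labMat, nrow = length(ids))
  agree <- apply(labMat, 1L, function(r) all(r == r[1]))
  new("DisagreementSplit",
      agreedIds = ids[agree], consensus = labMat[agree, 1L],
      disagreedIds = ids[!agree])
}

# Per-encoder projection to the common dimension: identity when the
# encoder dimension already matches, otherwise a fixed seeded Gaussian
# matrix with variance 1/commonDim (norm-preserving in expectation).
makeProjection <- function(encName, dimK, commonDim, seed) {
  if (dimK == commonDim) return("identity")
  withSeed(deriveSeed(seed, stringHash31(encName)), {
    matrix(stats::rnorm(dimK * commonDim, sd = 1 / sqrt(commonDim)),
           dimK, commonDim)
  })
}

# Stack embeddings for the given ids into an n x K x d array, encoders in
# encoderOrder, applying the recorded projections.
buildStacks <- function(ids, embeddings, encoderOrder, projections,
                        commonDim) {
  n <- length(ids)
  K <- length(encoderOrder)
  stacks <- array(0, dim = c(n, K, commonDim))
  names(embeddings) <- vapply(embeddings, encoderName, character(1))
  for (k in seq_len(K)) {
    es <- embeddings[[encoderOrder[k]]]
    pos <- match(ids, es@ids)
    if (anyNA(pos)) {
      stopf("embedding row missing for (encoder '%s', id '%s')",
            encoderOrder[k], ids[which(is.na(pos))[1]])
    }
    E <- es@embedding[pos, , drop = FALSE]
    P <- projections[[encoderOrder[k]]]
    if (!identical(P, "identity")) E <- E %*% P
    stacks[, k, ] <- E
  }
  stacks
}

#' Assemble the fusion training set from disagreement messages
#'
#' For every disagreed message, stacks the per-encoder embeddings into a
#' K x d matrix (encoders in ascending name order — the recorded stack
#' order) and attaches the gold label from `truth`. Encoders whose
#' dimension differs from `commonDim` are reconciled through a fixed
#' seeded Gaussian projection recorded in the result.
#'
#' @param split a [DisagreementSplit-class] computed on training-set
#'   predictions.
#' @param embeddings list of K [EmbeddingSet-class] objects (one per
#'   encoder) covering all disagreed ids.
#' @param truth a [Corpus-class] providing gold labels.
#' @param commonDim target common dimension (defaults to the first
#'   encoder's dimension).
#' @param projectionSeed seed of the dimension-reconciliation projections.
#' @return A [FusionTrainingSet-class]; empty (with a warning) when the
#'   baselines agreed on every message, in which case downstream code must
#'   fall back to consensus labels.
#' @export
buildFusionTrainingSet <- function(split, embeddings, truth,
                                   commonDim = NULL, projectionSeed = 1L) {
  if (length(embeddings) < 2L) stopf("need at least 2 encoders (K >= 2)")
  encNames <- vapply(embeddings, encoderName, character(1))
  encoderOrder <- sortLex(encNames)
  commonDim <- as.integer(commonDim %||% ncol(embeddings[[1]]@embedding))
  names(embeddings) <- encNames
  projections <- lapply(encoderOrder, function(nm) {
    makeProjection(nm, ncol(embeddings[[nm]]@embedding), commonDim,
                   projectionSeed)
  })
  names(projections) <- encoderOrder
  ids <- split@disagreedIds
  if (length(ids) == 0L) {
    warnf(paste("baselines agree on every message; fusion training set is",
                "empty — the pipeline will fall back to consensus labels"))
    return(new("FusionTrainingSet", ids = character(0),
               stacks = array(0, dim = c(0L, length(encoderOrder), commonDim)),
               labels = character(0), encoderOrder = encoderOrder,
               commonDim = commonDim, projections = projections,
               schema = truth@schema))
  }
  labs <- messageLabels(truth)[ids]
  if (anyNA(labs)) {
    stopf("disagreed id(s) unlabeled in truth: %s",
          paste(ids[is.na(labs)], collapse = ", "))
  }
  stacks <- buildStacks(ids, embeddings, encoderOrder, projections,
                        commonDim)
  new("FusionTrainingSet", ids = ids, stacks = stacks,
      labels = unname(labs), encoderOrder = encoderOrder,
      commonDim = commonDim, projections = projections,
      schema = truth@schema)
}

# ---------------------------------------------------------------------------
# Fusion-head forward passes (single stack, explicit parameters). These are
# the reference forms the trainers and predict methods share; they are
# exported so the arithmetic can be checked against hand-set weights.
# ---------------------------------------------------------------------------

#' Average-pooling fusion head
#'
#' Column-wise mean over the K encoder rows, then a single fully connected
#' layer + softmax.
#'
#' @param stack K x d numeric matrix of per-encoder embeddings.
#' @param W d x C dense weight matrix.
#' @param b length-C bias.
#' @return numeric probability vector of length C.
#' @examples
#' fuseAverage(rbind(c(1, 0), c(0, 1)), W = matrix(0, 2, 4), b = rep(0, 4))
#' @export
fuseAverage <- function(stack, W, b) {
  fused <- colMeans(stack)
  drop(softmaxRows(matrix(drop(fused %*% W) + b, 1L)))
}

#' Additive-attention fusion head
#'
#' Scores each encoder row `e_k` as `v' tanh(Wa e_k)`, softmax-normalizes
#' the scores into attention weights (summing to 1), forms the weighted sum
#' of the rows, and applies a dense softmax layer.
#'
#' @param stack K x d numeric matrix.
#' @param Wa h x d attention weight matrix.
#' @param v length-h attention scoring vector.
#' @param W d x C dense weight matrix.
#' @param b length-C bias.
#' @return list with `probs` (length C) and `weights` (length K, sums
#'   to 1).
#' @export
fuseAttention <- function(stack, Wa, v, W, b) {
  scores <- drop(tanh(stack %*% t(Wa)) %*% v)
  w <- drop(softmaxRows(matrix(scores, 1L)))
  fused <- colSums(w * stack)
  list(probs = drop(softmaxRows(matrix(drop(fused %*% W) + b, 1L))),
       weights = w)
}

#' 2-D CNN fusion head
#'
#' Treats the K x d stack as a single-channel 2-D grid. For each filter of
#' size (h, w) with h <= K: valid-mode 2-D convolution, ReLU, global max
#' pooling. Pooled features from all filters are concatenated and mapped
#' through a dense softmax layer (dropout is a training-time-only
#' regularizer and is inactive here).
#'
#' @param stack K x d numeric matrix.
#' @param filters list of filter banks, each a list with integer `h`, `w`,
#'   weight matrix `W` of shape (h*w) x F (patch values column-major, rows
#'   fastest) and length-F bias `b`.
#' @param denseW Ftot x C dense weight matrix (Ftot = total filters).
#' @param denseB length-C bias.
#' @return list with `probs` (length C) and `pooled` (length Ftot, the
#'   max-pooled features).
#' @export
fuseCnn <- function(stack, filters, denseW, denseB) {
  K <- nrow(stack); d <- ncol(stack)
  pooled <- unlist(lapply(filters, function(f) {
    if (f$h > K) stopf("filter height %d exceeds the number of encoders %d",
                       f$h, K)
    if (f$w > d) stopf("filter width %d exceeds the embedding dimension %d",
                       f$w, d)
    idx <- patchIndices(K, d, f$h, f$w)
    Pm <- matrix(stack[idx], nrow = nrow(idx))
    A <- pmax(sweep(Pm %*% f$W, 2L, f$b, "+"), 0)
    apply(A, 2L, max)
  }), use.names = FALSE)
  list(probs = drop(softmaxRows(matrix(drop(pooled %*% denseW) + denseB, 1L))),
       pooled = pooled)
}

# npos x (h*w) matrix of linear indices into a K x d matrix, one row per
# valid filter position (row offset fastest), patch entries column-major.
patchIndices <- function(K, d, h, w) {
  ph <- K - h + 1L; pw <- d - w + 1L
  pos <- expand.grid(i = seq_len(ph), j = seq_len(pw))
  off <- expand.grid(r = 0:(h - 1L), c = 0:(w - 1L))
  idx <- matrix(0L, nrow(pos), nrow(off))
  for (q in seq_len(nrow(off))) {
    idx[, q] <- (pos$i + off$r[q]) + (pos$j + off$c[q] - 1L) * K
  }
  idx
}

# ---------------------------------------------------------------------------
# Training
# ---------------------------------------------------------------------------

#' Train a fusion head on disagreement examples
#'
#' Fits the configured fusion head (average, attention or 2-D CNN) on the
#' stacked embeddings of the disagreement training set, using gold labels
#' and the chosen rebalancing strategy. Training is full-batch Adam on
#' analytic gradients and is deterministic given the seed in
#' `config@training`.
#'
#' @param config a [FusionConfig-class]; `commonDim` must match the
#'   training set.
#' @param trainSet a non-empty [FusionTrainingSet-class] containing at
#'   least two classes.
#' @param rebalance a [RebalanceSpec-class].
#' @return A [FittedFusion-class].
#' @export
trainFusion <- function(config, trainSet, rebalance = rebalanceSpec("none")) {
  n <- length(trainSet@ids)
  if (n == 0L) {
    stopf(paste("fusion training set is empty (baselines agreed everywhere);",
                "use the consensus fallback path instead of training"))
  }
  if (length(unique(trainSet@labels)) < 2L) {
    stopf("fusion training requires at least 2 classes, got only '%s'",
          unique(trainSet@labels))
  }
  if (config@commonDim != trainSet@commonDim) {
    stopf("config commonDim (%d) does not match training set (%d)",
          config@commonDim, trainSet@commonDim)
  }
  fit <- switch(config@strategy,
    average = trainFusionAverage(config, trainSet, rebalance),
    attention = trainFusionAttention(config, trainSet, rebalance),
    cnn = trainFusionCnn(config, trainSet, rebalance))
  new("FittedFusion", config = config, schema = fit$schema,
      encoderOrder = trainSet@encoderOrder,
      projections = trainSet@projections, params = fit$params,
      metadata = fit$metadata)
}

fusionSchema <- function(trainSet) trainSet@schema

trainFusionAverage <- function(config, trainSet, rebalance) {
  schema <- fusionSchema(trainSet)
  fused <- meanOverEncoders(trainSet@stacks)
  fit <- fitSoftmaxHead(fused, trainSet@labels, schema,
                        rebalance = rebalance, lr = config@training$lr,
                        epochs = config@training$epochs,
                        seed = config@training$seed)
  list(schema = schema, params = list(W = fit$W, b = fit$b),
       metadata = list(finalLoss = fit$loss,
                       trainAccuracy = fit$trainAccuracy,
                       n = length(trainSet@ids),
                       trainedIds = trainSet@ids[fit$trainedRows],
                       seed = config@training$seed,
                       rebalance = rebalance@strategy))
}

meanOverEncoders <- function(stacks) {
  K <- dim(stacks)[2]
  out <- stacks[, 1L, , drop = TRUE]
  if (is.null(dim(out))) out <- matrix(out, nrow = dim(stacks)[1])
  if (K > 1L) for (k in 2:K) out <- out + stacks[, k, ]
  out / K
}

# Rebalance bookkeeping shared by the attention / CNN trainers: resampled
# row indices (oversample) and per-class alpha weights.
fusionTrainRows <- function(trainSet, rebalance, schema, seed) {
  rows <- seq_along(trainSet@ids)
  if (rebalance@strategy == "oversample") {
    rows <- as.integer(oversample(as.character(rows), trainSet@labels,
                                  seed = deriveSeed(seed, 5L)))
  }
  counts <- table(factor(trainSet@labels,
                         levels = intersect(schema@labels,
                                            unique(trainSet@labels))))
  alphaVec <- stats::setNames(rep(1, length(schema@labels)), schema@labels)
  av <- resolveAlpha(rebalance@alpha, counts)
  alphaVec[names(av)] <- av
  list(rows = rows, alphaVec = alphaVec)
}

trainFusionAttention <- function(config, trainSet, rebalance) {
  schema <- fusionSchema(trainSet)
  seed <- config@training$seed
  rb <- fusionTrainRows(trainSet, rebalance, schema, seed)
  stacks <- trainSet@stacks[rb$rows, , , drop = FALSE]
  yIdx <- match(trainSet@labels[rb$rows], schema@labels)
  n <- dim(stacks)[1]; K <- dim(stacks)[2]; d <- dim(stacks)[3]
  C <- length(schema@labels)
  h <- config@attention$hidden
  par <- withSeed(deriveSeed(seed, 2L), list(
    Wa = matrix(stats::rnorm(h * d, sd = 1 / sqrt(d)), h, d),
    v = stats::rnorm(h, sd = 1 / sqrt(h)),
    W = matrix(stats::rnorm(d * C, sd = 0.01), d, C),
    b = rep(0, C)))
  st <- adamInit(par)
  E <- lapply(seq_len(K), function(k) stacks[, k, , drop = TRUE])
  E <- lapply(E, function(e) if (is.null(dim(e))) matrix(e, n) else e)
  loss <- NA_real_
  for (t in seq_len(config@training$epochs)) {
    Tk <- vector("list", K); S <- matrix(0, n, K)
    for (k in seq_len(K)) {
      Tk[[k]] <- tanh(E[[k]] %*% t(par$Wa))
      S[, k] <- Tk[[k]] %*% par$v
    }
    Wt <- softmaxRows(S)
    fused <- matrix(0, n, d)
    for (k in seq_len(K)) fused <- fused + Wt[, k] * E[[k]]
    Z <- sweep(fused %*% par$W, 2L, par$b, "+")
    lg <- headLossGrad(Z, yIdx, rebalance@strategy, rebalance@gamma,
                       rb$alphaVec)
    loss <- lg$loss
    G <- lg$grad
    dW <- crossprod(fused, G); db <- colSums(G)
    dfused <- tcrossprod(G, par$W)
    dWt <- matrix(0, n, K)
    for (k in seq_len(K)) dWt[, k] <- rowSums(dfused * E[[k]])
    dS <- Wt * (dWt - rowSums(Wt * dWt))
    dWa <- matrix(0, h, d); dv <- numeric(h)
    for (k in seq_len(K)) {
      dv <- dv + drop(crossprod(Tk[[k]], dS[, k]))
      dU <- tcrossprod(dS[, k], par$v) * (1 - Tk[[k]]^2)
      dWa <- dWa + crossprod(dU, E[[k]])
    }
    upd <- adamStep(par, list(Wa = dWa, v = dv, W = dW, b = db), st,
                    config@training$lr, t)
    par <- upd$par; st <- upd$st
  }
  acc <- attentionTrainAccuracy(par, E, yIdx, schema)
  list(schema = schema, params = par,
       metadata = list(finalLoss = loss, trainAccuracy = acc,
                       n = length(trainSet@ids),
                       trainedIds = trainSet@ids[rb$rows], seed = seed,
                       rebalance = rebalance@strategy))
}

attentionTrainAccuracy <- function(par, E, yIdx, schema) {
  n <- nrow(E[[1]]); K <- length(E); d <- ncol(E[[1]])
  S <- matrix(0, n, K)
  for (k in seq_len(K)) S[, k] <- tanh(E[[k]] %*% t(par$Wa)) %*% par$v
  Wt <- softmaxRows(S)
  fused <- matrix(0, n, d)
  for (k in seq_len(K)) fused <- fused + Wt[, k] * E[[k]]
  Z <- sweep(fused %*% par$W, 2L, par$b, "+")
  mean(schema@labels[apply(Z, 1L, which.max)] == schema@labels[yIdx])
}

trainFusionCnn <- function(config, trainSet, rebalance) {
  schema <- fusionSchema(trainSet)
  seed <- config@training$seed
  rb <- fusionTrainRows(trainSet, rebalance, schema, seed)
  stacks <- trainSet@stacks[rb$rows, , , drop = FALSE]
  yIdx <- match(trainSet@labels[rb$rows], schema@labels)
  n <- dim(stacks)[1]; K <- dim(stacks)[2]; d <- dim(stacks)[3]
  C <- length(schema@labels)
  heights <- unique(pmin(config@cnn$heights, K)) # cap at the encoder count
  width <- min(config@cnn$width, d)
  nF <- config@cnn$nFilters
  rate <- config@cnn$dropout
  Sflat <- matrix(stacks, nrow = n) # columns: encoder fastest, then dim
  sizes <- lapply(heights, function(hh) {
    idx <- patchIndices(K, d, hh, width)
    # n*npos x (h*w) patch matrix, examples fastest within a position block
    Pm <- matrix(0, n * nrow(idx), ncol(idx))
    for (q in seq_len(ncol(idx))) {
      Pm[, q] <- as.vector(Sflat[, idx[, q], drop = FALSE])
    }
    list(h = hh, w = width, npos = nrow(idx), Pm = Pm)
  })
  Ftot <- nF * length(sizes)
  par <- withSeed(deriveSeed(seed, 3L), {
    p <- list(Wd = matrix(stats::rnorm(Ftot * C, sd = 0.01), Ftot, C),
              bd = rep(0, C))
    for (s in seq_along(sizes)) {
      hw <- sizes[[s]]$h * sizes[[s]]$w
      p[[paste0("Wf", s)]] <- matrix(stats::rnorm(hw * nF, sd = 1 / sqrt(hw)),
                                     hw, nF)
      p[[paste0("bf", s)]] <- rep(0, nF)
    }
    p
  })
  st <- adamInit(par)
  loss <- NA_real_
  for (t in seq_len(config@training$epochs)) {
    pooledList <- vector("list", length(sizes))
    fwd <- vector("list", length(sizes))
    for (s in seq_along(sizes)) {
      sz <- sizes[[s]]
      Conv <- sweep(sz$Pm %*% par[[paste0("Wf", s)]], 2L,
                    par[[paste0("bf", s)]], "+")
      A <- pmax(Conv, 0)
      pooled <- A[seq_len(n), , drop = FALSE]
      widx <- matrix(1L, n, nF)
      if (sz$npos > 1L) for (p in 2:sz$npos) {
        Bp <- A[(p - 1L) * n + seq_len(n), , drop = FALSE]
        m <- Bp > pooled
        pooled[m] <- Bp[m]; widx[m] <- p
      }
      pooledList[[s]] <- pooled
      fwd[[s]] <- list(reluMask = Conv > 0, widx = widx)
    }
    H0 <- do.call(cbind, pooledList)
    mask <- if (rate > 0) {
      withSeed(deriveSeed(seed, 7L, t), {
        matrix((stats::runif(n * Ftot) >= rate) / (1 - rate), n, Ftot)
      })
    } else matrix(1, n, Ftot)
    H <- H0 * mask
    Z <- sweep(H %*% par$Wd, 2L, par$bd, "+")
    lg <- headLossGrad(Z, yIdx, rebalance@strategy, rebalance@gamma,
                       rb$alphaVec)
    loss <- lg$loss
    G <- lg$grad
    grad <- list(Wd = crossprod(H, G), bd = colSums(G))
    dH <- tcrossprod(G, par$Wd) * mask
    for (s in seq_along(sizes)) {
      sz <- sizes[[s]]
      dpool <- dH[, (s - 1L) * nF + seq_len(nF), drop = FALSE]
      dA <- matrix(0, n * sz$npos, nF)
      widx <- fwd[[s]]$widx
      for (p in seq_len(sz$npos)) {
        sel <- which(widx == p)
        if (!length(sel)) next
        i0 <- ((sel - 1L) %% n) + 1L
        j0 <- ((sel - 1L) %/% n) + 1L
        dA[cbind((p - 1L) * n + i0, j0)] <- dpool[sel]
      }
      dA[!fwd[[s]]$reluMask] <- 0
      grad[[paste0("Wf", s)]] <- crossprod(sz$Pm, dA)
      grad[[paste0("bf", s)]] <- colSums(dA)
    }
    upd <- adamStep(par, grad, st, config@training$lr, t)
    par <- upd$par; st <- upd$st
  }
  filters <- lapply(seq_along(sizes), function(s) {
    list(h = sizes[[s]]$h, w = sizes[[s]]$w, W = par[[paste0("Wf", s)]],
         b = par[[paste0("bf", s)]])
  })
  params <- list(filters = filters, denseW = par$Wd, denseB = par$bd)
  probs <- forwardCnn(stacks, params)
  acc <- mean(schema@labels[apply(probs, 1L, which.max)] ==
                schema@labels[yIdx])
  list(schema = schema, params = params,
       metadata = list(finalLoss = loss, trainAccuracy = acc,
                       n = length(trainSet@ids),
                       trainedIds = trainSet@ids[rb$rows], seed = seed,
                       rebalance = rebalance@strategy))
}

# Vectorized CNN forward pass over an n x K x d stack array (no dropout).
forwardCnn <- function(stacks, params) {
  n <- dim(stacks)[1]; K <- dim(stacks)[2]; d <- dim(stacks)[3]
  Sflat <- matrix(stacks, nrow = n)
  pooledList <- lapply(params$filters, function(f) {
    idx <- patchIndices(K, d, f$h, f$w)
    Pm <- matrix(0, n * nrow(idx), ncol(idx))
    for (q in seq_len(ncol(idx))) {
      Pm[, q] <- as.vector(Sflat[, idx[, q], drop = FALSE])
    }
    A <- pmax(sweep(Pm %*% f$W, 2L, f$b, "+"), 0)
    pooled <- A[seq_len(n), , drop = FALSE]
    if (nrow(idx) > 1L) for (p in 2:nrow(idx)) {
      Bp <- A[(p - 1L) * n + seq_len(n), , drop = FALSE]
      m <- Bp > pooled
      pooled[m] <- Bp[m]
    }
    pooled
  })
  H <- do.call(cbind, pooledList)
  softmaxRows(sweep(H %*% params$denseW, 2L, params$denseB, "+"))
}

forwardAttention <- function(stacks, params) {
  n <- dim(stacks)[1]; K <- dim(stacks)[2]; d <- dim(stacks)[3]
  S <- matrix(0, n, K)
  E <- lapply(seq_len(K), function(k) {
    e <- stacks[, k, , drop = TRUE]
    if (is.null(dim(e))) matrix(e, n) else e
  })
  for (k in seq_len(K)) S[, k] <- tanh(E[[k]] %*% t(params$Wa)) %*% params$v
  Wt <- softmaxRows(S)
  fused <- matrix(0, n, d)
  for (k in seq_len(K)) fused <- fused + Wt[, k] * E[[k]]
  softmaxRows(sweep(fused %*% params$W, 2L, params$b, "+"))
}

forwardAverage <- function(stacks, params) {
  fused <- meanOverEncoders(stacks)
  softmaxRows(sweep(fused %*% params$W, 2L, params$b, "+"))
}

#' Predict with a trained fusion model
#'
#' @param object a [FittedFusion-class].
#' @param newdata either a [FusionTrainingSet-class] (its stacks are used
#'   directly) or a list of [EmbeddingSet-class] objects, in which case
#'   `ids` selects the messages and stacks are built with the model's
#'   recorded encoder order and projections.
#' @param ids message ids (required when `newdata` is a list of embedding
#'   sets).
#' @param ... unused.
#' @return A [PredictionSet-class] with source `"fusion"`.
#' @export
setMethod("predict", "FittedFusion", function(object, newdata, ids = NULL,
                                              ...) {
  if (is(newdata, "FusionTrainingSet")) {
    if (!identical(newdata@encoderOrder, object@encoderOrder)) {
      stopf("encoder order of newdata does not match the fitted model")
    }
    stacks <- newdata@stacks
    ids <- newdata@ids
  } else {
    if (is.null(ids)) stopf("ids must be given with raw embedding sets")
    stacks <- buildStacks(ids, newdata, object@encoderOrder,
                          object@projections, object@config@commonDim)
  }
  probs <- switch(object@config@strategy,
                  average = forwardAverage(stacks, object@params),
                  attention = forwardAttention(stacks, object@params),
                  cnn = forwardCnn(stacks, object@params))
  predictionSet(paste0("fusion_", object@config@strategy), object@schema,
                ids, probs, source = "fusion")
})

#' Combine consensus labels with fusion predictions
#'
#' Reassembles the final prediction over all messages: agreed messages
#' carry their consensus label (by convention with probability 1 on it),
#' disagreed messages carry the fusion model's prediction. Every message's
#' label thus comes from exactly one source, recorded per id as
#' `"consensus"` or `"fusion"`.
#'
#' @param split the [DisagreementSplit-class] of the evaluation set.
#' @param fused a [PredictionSet-class] covering exactly the disagreed
#'   ids.
#' @param modelName name for the combined prediction set.
#' @param idOrder optional id ordering of the output (defaults to agreed
#'   ids followed by disagreed ids).
#' @return A [PredictionSet-class] over all ids of the split.
#' @export
combinePredictions <- function(split, fused, modelName = "routed_fusion",
                               idOrder = NULL) {
  if (!setequal(fused@ids, split@disagreedIds)) {
    diff <- c(setdiff(split@disagreedIds, fused@ids),
              setdiff(fused@ids, split@disagreedIds))
    stopf("fused predictions must cover exactly the disagreed ids; mismatch: %s",
          paste(diff, collapse = ", "))
  }
  schema <- fused@schema
  cls <- schema@labels
  allIds <- c(split@agreedIds, split@disagreedIds)
  idOrder <- idOrder %||% allIds
  if (!setequal(idOrder, allIds)) stopf("idOrder must cover all split ids")
  n <- length(idOrder)
  probs <- matrix(0, n, length(cls))
  src <- character(n)
  consMap <- consensusLabels(split)
  fusedProbs <- predictionProbs(fused)
  for (i in seq_len(n)) {
    id <- idOrder[i]
    if (id %in% names(consMap)) {
      probs[i, match(consMap[[id]], cls)] <- 1
      src[i] <- "consensus"
    } else {
      probs[i, ] <- fusedProbs[id, ]
      src[i] <- "fusion"
    }
  }
  predictionSet(modelName, schema, idOrder, probs, source = src)
}
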