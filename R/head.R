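# Shared softmax classification head: full-batch Adam on analytic
# gradients, with the three rebalancing strategies plugged in at the loss.
# Used both for baseline fine-tuning (frozen encoder -> head only) and as
# the dense output layer of the fusion heads.

# Resolve the alpha field of a RebalanceSpec into per-class weights.
resolveAlpha <- function(alpha, counts) {
  if (is.character(alpha) && identical(alpha, "inverse_frequency")) {
    return(inverseFrequencyWeights(counts))
  }
  if (is.numeric(alpha)) {
    if (is.null(names(alpha)) || !all(names(counts) %in% names(alpha))) {
      stopf("numeric alpha must be named and cover every class")
    }
    return(alpha[names(counts)])
  }
  stats::setNames(rep(1, length(counts)), names(counts))
}

# Mean loss and gradient wrt logits Z (n x C) for true-class indices yIdx.
# exWeight: per-example loss weights (class_weight strategy); for focal the
# gradient is d/dz of -alpha (1-p)^gamma log p through the softmax.
headLossGrad <- function(Z, yIdx, strategy, gamma, alphaVec) {
  n <- nrow(Z); C <- ncol(Z)
  P <- softmaxRows(Z)
  iy <- cbind(seq_len(n), yIdx)
  Y <- matrix(0, n, C); Y[iy] <- 1
  p <- pmin(pmax(P[iy], 1e-12), 1 - 1e-12)
  if (strategy == "focal") {
    a <- alphaVec[yIdx]
    loss <- mean(-a * (1 - p)^gamma * log(p))
    cc <- a * (gamma * (1 - p)^(gamma - 1) * log(p) - (1 - p)^gamma / p)
    G <- (cc * p) * (Y - P) / n
  } else {
    w <- if (strategy == "class_weight") alphaVec[yIdx] else rep(1, n)
    loss <- mean(-w * log(p))
    G <- w * (P - Y) / n
  }
  list(loss = loss, grad = G, probs = P)
}

# One Adam step over parallel lists of parameter / gradient arrays.
adamStep <- function(par, grad, st, lr, t, beta1 = 0.9, beta2 = 0.999,
                     eps = 1e-8) {
  for (k in names(par)) {
    st$m[[k]] <- beta1 * st$m[[k]] + (1 - beta1) * grad[[k]]
    st$v[[k]] <- beta2 * st$v[[k]] + (1 - beta2) * grad[[k]]^2
    mhat <- st$m[[k]] / (1 - beta1^t)
    vhat <- st$v[[k]] / (1 - beta2^t)
    par[[k]] <- par[[k]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(par = par, st = st)
}

adamInit <- function(par) {
  zeros <- lapply(par, function(p) array(0, dim = dim(p) %||% length(p)))
  list(m = zeros, v = zeros)
}

# Fit a linear softmax head on an n x d feature matrix. Returns W (d x C),
# b (C), final loss, training accuracy and the (possibly resampled) row
# indices actually trained on.
fitSoftmaxHead <- function(X, y, schema, rebalance = rebalanceSpec("none"),
                           lr = 0.05, epochs = 300L, l2 = 1e-4, seed = 1L) {
  cls <- schema@labels
  rows <- seq_len(nrow(X))
  if (rebalance@strategy == "oversample") {
    rows <- as.integer(oversample(as.character(rows), y,
                                  seed = deriveSeed(seed, 5L)))
  }
  Xt <- X[rows, , drop = FALSE]
  yt <- y[rows]
  yIdx <- match(yt, cls)
  counts <- table(factor(y, levels = intersect(cls, unique(y))))
  alphaVec <- stats::setNames(rep(1, length(cls)), cls)
  av <- resolveAlpha(rebalance@alpha, counts)
  alphaVec[names(av)] <- av
  d <- ncol(X); C <- length(cls)
  par <- list(
    W = withSeed(deriveSeed(seed, 1L), matrix(stats::rnorm(d * C, sd = 0.01),
                                              d, C)),
    b = rep(0, C))
  st <- adamInit(par)
  loss <- NA_real_
  for (t in seq_len(epochs)) {
    Z <- sweep(Xt %*% par$W, 2L, par$b, "+")
    lg <- headLossGrad(Z, yIdx, rebalance@strategy, rebalance@gamma, alphaVec)
    loss <- lg$loss + l2 * sum(par$W^2) / 2
    grad <- list(W = crossprod(Xt, lg$grad) + l2 * par$W,
                 b = colSums(lg$grad))
    upd <- adamStep(par, grad, st, lr, t)
    par <- upd$par; st <- upd$st
  }
  Z <- sweep(Xt %*% par$W, 2L, par$b, "+")
  acc <- mean(cls[apply(Z, 1L, which.max)] == yt)
  list(W = par$W, b = par$b, loss = loss, trainAccuracy = acc,
       trainedRows = rows)
}
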