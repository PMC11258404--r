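#' Encode messages into per-encoder embeddings
#'
#' With the `"mock"` backend, encoding is a deterministic, dependency-free
#' stand-in for a sentence transformer: the text is lower-cased, stripped
#' of punctuation and whitespace-tokenized; each token maps through a fixed
#' 31-bit string hash to a unit-norm Gaussian vector of length `dim`; the
#' message embedding is the mean of its token vectors (mean pooling of the
#' "last hidden layer"), and an empty token list yields the zero vector.
#' Texts longer than `maxTokens` tokens are truncated with a warning.
#'
#' Real transformer checkpoints are referenced by identifier in
#' `spec@backend`; no backend for them ships with this package, so such
#' specs raise an error naming the checkpoint.
#'
#' @param spec an [EncoderSpec-class].
#' @param x a [Corpus-class] (or a named character vector of texts, names
#'   as ids).
#' @return An [EmbeddingSet-class], rows aligned to message ids in input
#'   order.
#' @examples
#' sp <- encoderSpec("mock-a", dim = 8)
#' cp <- corpus(id = c("m1", "m2"), text = c("knee pain", ""))
#' encodeMessages(sp, cp)
#' @export
encodeMessages <- function(spec, x) {
  if (is(x, "Corpus")) {
    ids <- messageIds(x)
    texts <- x@messages$text
  } else {
    if (is.null(names(x))) stopf("texts must be named by message id")
    ids <- names(x)
    texts <- unname(x)
  }
  if (length(ids) == 0L) stopf("no messages to encode")
  if (spec@backend != "mock") {
    stopf("no backend available for checkpoint '%s'; use a mock encoder",
          spec@backend)
  }
  cache <- new.env(parent = emptyenv(), hash = TRUE)
  emb <- matrix(0, length(ids), spec@dim)
  truncated <- 0L
  for (i in seq_along(texts)) {
    toks <- mockTokenize(texts[i])
    if (length(toks) > spec@maxTokens) {
      toks <- toks[seq_len(spec@maxTokens)]
      truncated <- truncated + 1L
    }
    if (length(toks) == 0L) next # zero vector
    acc <- numeric(spec@dim)
    for (tk in toks) {
      v <- cache[[tk]]
      if (is.null(v)) {
        v <- mockTokenVector(tk, spec@dim, spec@hashSeed)
        cache[[tk]] <- v
      }
      acc <- acc + v
    }
    emb[i, ] <- acc / length(toks)
  }
  if (truncated > 0L) {
    warnf("%d message(s) exceeded maxTokens=%d and were truncated",
          truncated, spec@maxTokens)
  }
  embeddingSet(spec@name, ids, emb)
}

# Lowercase, strip punctuation, split on whitespace.
mockTokenize <- function(text) {
  s <- gsub("[[:punct:]]+", " ", tolower(text))
  toks <- strsplit(trimws(s), "[[:space:]]+")[[1]]
  toks[nzchar(toks)]
}

# Fixed unit-norm Gaussian vector per token, seeded by a stable string
# hash so the mapping is identical across processes and platforms.
mockTokenVector <- function(token, dim, hashSeed = 1L) {
  h <- stringHash31(token, init = 17L + hashSeed)
  v <- withSeed(h, stats::rnorm(dim))
  v / sqrt(sum(v^2))
}

#' Fine-tune a baseline classifier over one encoder
#'
#' Builds one baseline model: the encoder described by `spec` plus a
#' softmax classification head over the schema classes, trained with the
#' chosen rebalancing strategy. With the mock backend the encoder is
#' frozen, so fine-tuning fits the head only and completes in seconds.
#'
#' @param spec an [EncoderSpec-class].
#' @param train a fully labeled [Corpus-class]; every schema class must be
#'   present.
#' @param rebalance a [RebalanceSpec-class] (default: no rebalancing).
#' @param lr,epochs head training hyperparameters.
#' @param seed RNG seed; the same inputs give identical parameters.
#' @return A [FittedBaseline-class].
#' @seealso [fitBaselineHead()] for training directly on precomputed
#'   embeddings.
#' @export
fineTuneBaseline <- function(spec, train, rebalance = rebalanceSpec("none"),
                             lr = 0.05, epochs = 300L, seed = 1L) {
  emb <- encodeMessages(spec, train)
  fitBaselineHead(emb, train, rebalance = rebalance, lr = lr,
                  epochs = epochs, seed = seed, spec = spec)
}

#' Fit a baseline head on precomputed embeddings
#'
#' The embedding-level entry point behind [fineTuneBaseline()]: trains the
#' softmax head of a baseline model on an existing [EmbeddingSet-class]
#' (e.g. synthetic embeddings, or embeddings exported from an external
#' encoder).
#'
#' @param embeddings an [EmbeddingSet-class] covering the training ids.
#' @param train a fully labeled [Corpus-class]; every schema class must be
#'   present among the embedded ids.
#' @param rebalance a [RebalanceSpec-class].
#' @param lr,epochs head training hyperparameters.
#' @param seed RNG seed.
#' @param spec optional [EncoderSpec-class]; synthesized from the
#'   embedding set when omitted.
#' @param category encoder category recorded when `spec` is synthesized.
#' @return A [FittedBaseline-class].
#' @export
fitBaselineHead <- function(embeddings, train,
                            rebalance = rebalanceSpec("none"),
                            lr = 0.05, epochs = 300L, seed = 1L,
                            spec = NULL, category = "mock") {
  schema <- train@schema
  labs <- messageLabels(train)[embeddings@ids]
  if (anyNA(labs)) {
    stopf("unlabeled or missing training id(s): %s",
          paste(embeddings@ids[is.na(labs)], collapse = ", "))
  }
  missing <- setdiff(schema@labels, unique(labs))
  if (length(missing)) {
    stopf("class(es) absent from the training set: %s",
          paste(missing, collapse = ", "))
  }
  if (is.null(spec)) {
    spec <- encoderSpec(embeddings@encoderName, category = category,
                        dim = ncol(embeddings@embedding),
                        backend = "precomputed")
  }
  fit <- fitSoftmaxHead(embeddings@embedding, unname(labs), schema,
                        rebalance = rebalance, lr = lr,
                        epochs = as.integer(epochs), seed = seed)
  new("FittedBaseline", spec = spec, schema = schema,
      head = list(W = fit$W, b = fit$b),
      metadata = list(seed = as.integer(seed), epochs = as.integer(epochs),
                      lr = lr, rebalance = rebalance@strategy,
                      finalLoss = fit$loss,
                      trainAccuracy = fit$trainAccuracy,
                      trainIds = embeddings@ids,
                      trainedIds = embeddings@ids[fit$trainedRows]))
}

#' Predict labels and class probabilities with a fitted baseline
#'
#' @param object a [FittedBaseline-class].
#' @param newdata a [Corpus-class] (encoded with the model's encoder) or an
#'   [EmbeddingSet-class] of precomputed embeddings.
#' @param ... unused.
#' @return A [PredictionSet-class]; ids preserved in input order, labels
#'   are the schema-order tie-broken argmax of the probabilities.
#' @export
setMethod("predict", "FittedBaseline", function(object, newdata, ...) {
  emb <- if (is(newdata, "EmbeddingSet")) newdata
         else encodeMessages(object@spec, newdata)
  Z <- sweep(emb@embedding %*% object@head$W, 2L, object@head$b, "+")
  predictionSet(object@spec@name, object@schema, emb@ids, softmaxRows(Z))
})
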