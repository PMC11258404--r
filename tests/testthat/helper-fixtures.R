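# Fixtures built in code: tiny corpora, separable embeddings and random
# prediction sets used across test files.

tinyCorpus <- function(labels, schema = labelSchema()) {
  corpus(id = sprintf("m%03d", seq_along(labels)),
         text = paste("text", seq_along(labels)),
         label = labels, schema = schema)
}

# Linearly separable 4-class embeddings: class mean on its own axis, small
# noise. Returns list(corpus, embedding set).
separableEmbeddings <- function(n = 80, dim = 8, sep = 5, noise = 0.2,
                                seed = 42, name = "sepenc") {
  cls <- c("A", "L", "P", "U")
  labels <- rep(cls, length.out = n)
  cp <- tinyCorpus(labels)
  E <- withr::with_seed(seed, {
    m <- matrix(rnorm(n * dim, sd = noise), n, dim)
    m[cbind(seq_len(n), match(labels, cls))] <-
      m[cbind(seq_len(n), match(labels, cls))] + sep
    m
  })
  list(corpus = cp, embeddings = embeddingSet(name, messageIds(cp), E))
}

# Prediction set with the given hard labels (probability ~1 on the label).
hardPredictionSet <- function(modelName, ids, labels,
                              schema = labelSchema()) {
  cls <- schemaLabels(schema)
  probs <- matrix(0.01 / (length(cls) - 1), length(ids), length(cls))
  probs[cbind(seq_along(ids), match(labels, cls))] <- 0.99
  probs <- probs / rowSums(probs)
  predictionSet(modelName, schema, ids, probs)
}

randomPredictionSet <- function(modelName, ids, seed,
                                schema = labelSchema()) {
  cls <- schemaLabels(schema)
  probs <- withr::with_seed(seed, {
    m <- matrix(rexp(length(ids) * length(cls)), length(ids))
    m / rowSums(m)
  })
  predictionSet(modelName, schema, ids, probs)
}

# Independent majority-vote oracle: count, then lexicographic minimum
# among the labels tied for the maximum count.
oracleMajorityVote <- function(labels, schemaLabels) {
  counts <- vapply(schemaLabels, function(l) sum(labels == l), integer(1))
  tied <- schemaLabels[counts == max(counts)]
  min(sort(tied, method = "radix"))
}
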