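#' Accessors for ConcernFusion classes
#'
#' Small accessor functions are the supported way to read the package's S4
#' objects; slot layout is not part of the API.
#'
#' @param x an object of the documented class.
#' @return The requested component.
#' @name accessors
NULL

#' @rdname accessors
setMethod("schemaLabels", "LabelSchema", function(x) x@labels)
#' @rdname accessors
setMethod("schemaLabels", "Corpus", function(x) x@schema@labels)
#' @rdname accessors
setMethod("schemaLabels", "PredictionSet", function(x) x@schema@labels)

#' @rdname accessors
setMethod("corpusSchema", "Corpus", function(x) x@schema)

#' @rdname accessors
setMethod("messageIds", "Corpus", function(x) x@messages$id)
#' @rdname accessors
setMethod("messageText", "Corpus", function(x) {
  stats::setNames(x@messages$text, x@messages$id)
})
#' @rdname accessors
setMethod("messageLabels", "Corpus", function(x) {
  stats::setNames(x@messages$label, x@messages$id)
})
#' @rdname accessors
setMethod("nMessages", "Corpus", function(x) nrow(x@messages))

#' @rdname accessors
setMethod("encoderName", "EncoderSpec", function(x) x@name)
#' @rdname accessors
setMethod("encoderName", "EmbeddingSet", function(x) x@encoderName)
#' @rdname accessors
setMethod("embeddingIds", "EmbeddingSet", function(x) x@ids)
#' @rdname accessors
setMethod("embeddingMatrix", "EmbeddingSet", function(x) {
  m <- x@embedding
  rownames(m) <- x@ids
  m
})

#' @rdname accessors
setMethod("predictionIds", "PredictionSet", function(x) x@ids)
#' @rdname accessors
setMethod("predictionLabels", "PredictionSet", function(x) {
  stats::setNames(x@labels, x@ids)
})
#' @rdname accessors
setMethod("predictionProbs", "PredictionSet", function(x) {
  m <- x@probs
  rownames(m) <- x@ids
  m
})
#' @rdname accessors
setMethod("predictionSource", "PredictionSet", function(x) {
  stats::setNames(x@source, x@ids)
})

#' @rdname accessors
setMethod("agreedIds", "DisagreementSplit", function(x) x@agreedIds)
#' @rdname accessors
setMethod("disagreedIds", "DisagreementSplit", function(x) x@disagreedIds)
#' @rdname accessors
setMethod("consensusLabels", "DisagreementSplit", function(x) {
  stats::setNames(x@consensus, x@agreedIds)
})

# ---------------------------------------------------------------------------
# show methods
# ---------------------------------------------------------------------------

setMethod("show", "LabelSchema", function(object) {
  cat("LabelSchema with", length(object@labels), "classes:",
      paste(object@labels, collapse = " < "), "(tie-break order)\n")
})

setMethod("show", "Corpus", function(object) {
  m <- object@messages
  nlab <- sum(!is.na(m$label))
  cat("Corpus with", nrow(m), "messages (", nlab, "labeled ) over schema {",
      paste(object@schema@labels, collapse = ", "), "}\n")
  if (nlab) {
    tab <- table(factor(m$label, levels = object@schema@labels))
    cat("  class counts:",
        paste(sprintf("%s=%d", names(tab), as.integer(tab)), collapse = " "),
        "\n")
  }
})

setMethod("show", "FoldPlan", function(object) {
  cat("FoldPlan:", object@nFolds, "folds x", object@nRepeats,
      "repeats over", length(unique(object@assignment$id)),
      "ids (seed", paste0(object@seed, ")\n"))
})

setMethod("show", "EncoderSpec", function(object) {
  cat(sprintf("EncoderSpec '%s' [%s] dim=%d maxTokens=%d backend=%s pooling=%s\n",
              object@name, object@category, object@dim, object@maxTokens,
              object@backend, object@pooling))
})

setMethod("show", "EmbeddingSet", function(object) {
  cat(sprintf("EmbeddingSet '%s': %d messages x %d dims\n",
              object@encoderName, length(object@ids),
              ncol(object@embedding)))
})

setMethod("show", "FittedBaseline", function(object) {
  cat(sprintf("FittedBaseline over encoder '%s' (%d classes; rebalance=%s)\n",
              object@spec@name, length(object@schema@labels),
              object@metadata$rebalance %||% "none"))
})

setMethod("show", "PredictionSet", function(object) {
  cat(sprintf("PredictionSet '%s': %d messages, %d classes\n",
              object@modelName, length(object@ids),
              length(object@schema@labels)))
  if (length(object@ids)) {
    tab <- table(factor(object@labels, levels = object@schema@labels))
    cat("  predicted:",
        paste(sprintf("%s=%d", names(tab), as.integer(tab)), collapse = " "),
        "\n")
  }
})

setMethod("show", "DisagreementSplit", function(object) {
  n <- length(object@agreedIds) + length(object@disagreedIds)
  cat(sprintf("DisagreementSplit: %d agreed / %d disagreed (of %d; %.1f%% routed to fusion)\n",
              length(object@agreedIds), length(object@disagreedIds), n,
              if (n) 100 * length(object@disagreedIds) / n else 0))
})

setMethod("show", "FusionConfig", function(object) {
  cat(sprintf("FusionConfig: strategy=%s commonDim=%d\n", object@strategy,
              object@commonDim))
})

setMethod("show", "FittedFusion", function(object) {
  cat(sprintf("FittedFusion (%s head) over encoders: %s\n",
              object@config@strategy,
              paste(object@encoderOrder, collapse = ", ")))
})

setMethod("show", "RebalanceSpec", function(object) {
  cat("RebalanceSpec:", object@strategy)
  if (object@strategy == "focal") cat(" (gamma =", object@gamma, ")")
  cat("\n")
})

setMethod("show", "MetricsReport", function(object) {
  cat(sprintf("MetricsReport over %d messages: accuracy %.4f, macro-F1 %.4f\n",
              object@n, object@accuracy, object@macro["f1"]))
  print(object@perClass, row.names = FALSE, digits = 4)
})
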