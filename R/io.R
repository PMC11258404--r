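#' Read and write prediction sets as CSV
#'
#' The CSV layout is `id,label,source,p_<class1>,...,p_<classC>` with one
#' probability column per schema class in schema order.
#'
#' @param x a [PredictionSet-class].
#' @param path CSV file path.
#' @param modelName model name recorded when reading.
#' @param schema a [LabelSchema-class] used to interpret the probability
#'   columns when reading.
#' @return `writePredictionSet` returns `path` invisibly;
#'   `readPredictionSet` returns a [PredictionSet-class].
#' @export
writePredictionSet <- function(x, path) {
  df <- data.frame(id = x@ids, label = x@labels, source = x@source,
                   stringsAsFactors = FALSE)
  probs <- x@probs
  colnames(probs) <- paste0("p_", x@schema@labels)
  utils::write.csv(cbind(df, probs), path, row.names = FALSE)
  invisible(path)
}

#' @rdname writePredictionSet
#' @export
readPredictionSet <- function(path, modelName = basename(path),
                              schema = labelSchema()) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  cols <- paste0("p_", schema@labels)
  if (!all(cols %in% names(df))) {
    stopf("prediction CSV must contain columns: %s",
          paste(cols, collapse = ", "))
  }
  predictionSet(modelName, schema, df$id,
                as.matrix(df[, cols, drop = FALSE]),
                source = df$source %||% "model")
}

#' Read and write embedding sets as CSV
#'
#' Plain-text persistence of an n x dim embedding matrix: an `id` column
#' followed by one numeric column per dimension.
#'
#' @param x an [EmbeddingSet-class].
#' @param path CSV file path.
#' @param encoderName encoder name recorded when reading (defaults to the
#'   file name stem).
#' @return `writeEmbeddingSet` returns `path` invisibly;
#'   `readEmbeddingSet` returns an [EmbeddingSet-class].
#' @export
writeEmbeddingSet <- function(x, path) {
  utils::write.csv(data.frame(id = x@ids, x@embedding,
                              stringsAsFactors = FALSE),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeEmbeddingSet
#' @export
readEmbeddingSet <- function(path, encoderName = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (is.null(encoderName)) {
    encoderName <- sub("^embeddings_", "", sub("\\.csv$", "", basename(path)))
  }
  embeddingSet(encoderName, as.character(df$id),
               as.matrix(df[, -1, drop = FALSE]))
}
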