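#' @import methods
NULL

# ---------------------------------------------------------------------------
# LabelSchema
# ---------------------------------------------------------------------------

#' Ordered set of class labels
#'
#' A `LabelSchema` holds the class labels of a classification problem in
#' ascending lexicographic order. That order is load-bearing: it is the
#' tie-break order used everywhere a tie must be resolved (majority voting,
#' argmax over equal probabilities), so that e.g. a three-way disagreement
#' between A, L and P resolves to A.
#'
#' @slot labels character vector of unique labels, sorted ascending.
#' @export
setClass("LabelSchema", representation(labels = "character"))

setValidity("LabelSchema", function(object) {
  l <- object@labels
  if (length(l) == 0L) return("schema must contain at least one label")
  if (anyDuplicated(l)) return("schema labels must be unique")
  if (any(!nzchar(l))) return("schema labels must be non-empty strings")
  if (!identical(l, sortLex(l))) {
    return("schema labels must be stored in ascending lexicographic order")
  }
  TRUE
})

# Locale-independent ascending sort (C collation) so the tie-break order is
# stable across platforms.
sortLex <- function(x) sort(x, method = "radix")

#' Construct a label schema
#'
#' Labels are sorted into ascending lexicographic order on construction;
#' the stored order is the tie-break order.
#'
#' @param labels character vector of unique class labels.
#' @return A [LabelSchema-class] object.
#' @examples
#' labelSchema()             # default portal-message schema A, L, P, U
#' labelSchema(c("no", "yes"))
#' @export
labelSchema <- function(labels = c("A", "L", "P", "U")) {
  new("LabelSchema", labels = sortLex(as.character(labels)))
}

# ---------------------------------------------------------------------------
# Corpus
# ---------------------------------------------------------------------------

#' Labeled message corpus
#'
#' A `Corpus` is the unit every split and metric in the package is defined
#' over: a set of short free-text messages with unique ids and (optionally)
#' a class label per message drawn from the corpus schema.
#'
#' @slot schema the [LabelSchema-class] of the corpus.
#' @slot messages data.frame with character columns `id`, `text`, `label`
#'   (`NA` for unlabeled messages), one row per message, original order
#'   preserved.
#' @export
setClass("Corpus",
         representation(schema = "LabelSchema", messages = "data.frame"))

setValidity("Corpus", function(object) {
  m <- object@messages
  if (!all(c("id", "text", "label") %in% names(m))) {
    return("messages must have columns id, text, label")
  }
  if (nrow(m) == 0L) return(TRUE)
  if (any(!nzchar(m$id))) return("message ids must be non-empty")
  if (anyDuplicated(m$id)) {
    return(sprintf("duplicate message id(s): %s",
                   paste(unique(m$id[duplicated(m$id)]), collapse = ", ")))
  }
  bad <- !is.na(m$label) & !(m$label %in% object@schema@labels)
  if (any(bad)) {
    return(sprintf("label(s) outside schema: %s",
                   paste(sprintf("id '%s' has label '%s'",
                                 m$id[bad], m$label[bad]), collapse = "; ")))
  }
  TRUE
})

#' Construct a corpus from vectors of ids, texts and labels
#'
#' @param id character vector of unique message ids.
#' @param text character vector of message texts.
#' @param label optional character vector of labels (NA allowed for
#'   unlabeled messages); every non-NA label must belong to `schema`.
#' @param schema a [LabelSchema-class]; defaults to the A/L/P/U schema.
#' @return A [Corpus-class] object.
#' @examples
#' corpus(id = c("m1", "m2"), text = c("knee pain", "refill please"),
#'        label = c("A", "P"))
#' @export
corpus <- function(id, text, label = NA_character_, schema = labelSchema()) {
  n <- length(id)
  messages <- data.frame(id = as.character(id),
                         text = as.character(text),
                         label = rep_len(as.character(label), n),
                         stringsAsFactors = FALSE)
  new("Corpus", schema = schema, messages = messages)
}

# ---------------------------------------------------------------------------
# FoldPlan
# ---------------------------------------------------------------------------

#' Repeated stratified cross-validation plan
#'
#' Maps every (repeat, message id) pair to a fold index. Folds are
#' stratified: within each repeat, fold sizes differ by at most one and
#' per-fold class counts differ from a perfectly stratified allocation by
#' at most one per class.
#'
#' @slot nFolds number of folds per repeat.
#' @slot nRepeats number of independent repeats.
#' @slot seed base seed; repeat r uses `seed + r`.
#' @slot assignment data.frame with columns `rep`, `id`, `fold`.
#' @export
setClass("FoldPlan",
         representation(nFolds = "integer", nRepeats = "integer",
                        seed = "integer", assignment = "data.frame"))

setValidity("FoldPlan", function(object) {
  a <- object@assignment
  if (!all(c("rep", "id", "fold") %in% names(a))) {
    return("assignment must have columns rep, id, fold")
  }
  for (r in seq_len(object@nRepeats)) {
    sub <- a[a$rep == r, ]
    if (anyDuplicated(sub$id)) return("an id appears twice within a repeat")
    if (any(sub$fold < 1L | sub$fold > object@nFolds)) {
      return("fold index out of range")
    }
  }
  TRUE
})

# ---------------------------------------------------------------------------
# Encoders and embeddings
# ---------------------------------------------------------------------------

#' Sentence-encoder specification
#'
#' Describes one encoder backend. The package ships a deterministic `mock`
#' backend (token-hash embeddings) so every downstream stage runs offline;
#' real transformer checkpoints are referenced by identifier and must be
#' served by an external backend.
#'
#' @slot name unique encoder name (also the baseline model name).
#' @slot category one of `"generic"`, `"domain"`, `"source"`, `"mock"`.
#' @slot dim embedding dimension (> 0).
#' @slot maxTokens maximum token count; longer texts are truncated with a
#'   warning.
#' @slot backend checkpoint identifier, or `"mock"`.
#' @slot pooling `"mean"` (default) or `"cls"`; how token vectors of the
#'   last hidden layer are pooled into one message vector.
#' @slot hashSeed integer seed of the mock token-hash tables.
#' @export
setClass("EncoderSpec",
         representation(name = "character", category = "character",
                        dim = "integer", maxTokens = "integer",
                        backend = "character", pooling = "character",
                        hashSeed = "integer"))

setValidity("EncoderSpec", function(object) {
  if (object@dim <= 0L) return("dim must be positive")
  if (!object@category %in% c("generic", "domain", "source", "mock")) {
    return("category must be one of generic, domain, source, mock")
  }
  if (!object@pooling %in% c("mean", "cls")) {
    return("pooling must be 'mean' or 'cls'")
  }
  TRUE
})

#' Construct an encoder specification
#'
#' @param name encoder name.
#' @param category `"generic"`, `"domain"`, `"source"` or `"mock"`.
#' @param dim embedding dimension.
#' @param maxTokens truncation length in tokens.
#' @param backend checkpoint identifier or `"mock"` (default).
#' @param pooling `"mean"` or `"cls"`.
#' @param hashSeed seed of the mock token-hash table.
#' @return An [EncoderSpec-class].
#' @examples
#' encoderSpec("mock-generic", category = "generic", dim = 32)
#' @export
encoderSpec <- function(name, category = "mock", dim = 64L, maxTokens = 256L,
                        backend = "mock", pooling = "mean", hashSeed = 1L) {
  new("EncoderSpec", name = as.character(name), category = category,
      dim = as.integer(dim), maxTokens = as.integer(maxTokens),
      backend = backend, pooling = pooling, hashSeed = as.integer(hashSeed))
}

#' Per-encoder message embeddings
#'
#' An n x dim matrix of message embeddings, row-aligned to message ids.
#'
#' @slot encoderName name of the producing encoder.
#' @slot ids ordered message ids, one per matrix row.
#' @slot embedding numeric matrix, `length(ids)` rows, all values finite.
#' @export
setClass("EmbeddingSet",
         representation(encoderName = "character", ids = "character",
                        embedding = "matrix"))

setValidity("EmbeddingSet", function(object) {
  if (nrow(object@embedding) != length(object@ids)) {
    return("embedding must have one row per id")
  }
  if (length(object@ids) && anyDuplicated(object@ids)) {
    return("ids must be unique")
  }
  if (length(object@embedding) && !all(is.finite(object@embedding))) {
    return("all embedding values must be finite")
  }
  TRUE
})

#' Construct an embedding set
#'
#' @param encoderName name of the producing encoder.
#' @param ids message ids, one per row of `embedding`.
#' @param embedding numeric matrix of embeddings.
#' @return An [EmbeddingSet-class].
#' @export
embeddingSet <- function(encoderName, ids, embedding) {
  rownames(embedding) <- NULL
  new("EmbeddingSet", encoderName = as.character(encoderName),
      ids = as.character(ids), embedding = as.matrix(embedding))
}

#' Fine-tuned baseline classifier
#'
#' One encoder plus a softmax classification head over the schema classes.
#' With the mock backend the encoder is frozen and fine-tuning fits the head
#' only.
#'
#' @slot spec the [EncoderSpec-class] of the underlying encoder.
#' @slot schema the label schema the head predicts over.
#' @slot head list with weight matrix `W` (dim x nClasses) and bias `b`.
#' @slot metadata training metadata (seed, epochs, rebalance strategy,
#'   final loss, training ids).
#' @export
setClass("FittedBaseline",
         representation(spec = "EncoderSpec", schema = "LabelSchema",
                        head = "list", metadata = "list"))

setValidity("FittedBaseline", function(object) {
  if (ncol(object@head$W) != length(object@schema@labels)) {
    return("head output dimension must equal the number of schema classes")
  }
  TRUE
})

# ---------------------------------------------------------------------------
# Predictions
# ---------------------------------------------------------------------------

#' Per-model predictions with class probabilities
#'
#' @slot modelName name of the producing model.
#' @slot schema the label schema.
#' @slot ids message ids, one per prediction.
#' @slot labels predicted label per id; always the schema-order tie-broken
#'   argmax of the corresponding probability row.
#' @slot probs n x nClasses probability matrix (rows sum to 1 within 1e-6),
#'   columns in schema order.
#' @slot source per-id provenance, e.g. `"model"`, `"consensus"`, `"fusion"`.
#' @export
setClass("PredictionSet",
         representation(modelName = "character", schema = "LabelSchema",
                        ids = "character", labels = "character",
                        probs = "matrix", source = "character"))

setValidity("PredictionSet", function(object) {
  n <- length(object@ids)
  cls <- object@schema@labels
  if (length(object@labels) != n || nrow(object@probs) != n ||
      length(object@source) != n) {
    return("ids, labels, probs rows and source must have equal length")
  }
  if (ncol(object@probs) != length(cls)) {
    return("probs must have one column per schema class")
  }
  if (n == 0L) return(TRUE)
  if (anyDuplicated(object@ids)) return("ids must be unique")
  if (any(abs(rowSums(object@probs) - 1) > 1e-6)) {
    return("every probability row must sum to 1 within 1e-6")
  }
  want <- cls[apply(object@probs, 1L, which.max)]
  if (!identical(unname(want), unname(object@labels))) {
    return("labels must equal the schema-order tie-broken argmax of probs")
  }
  TRUE
})

#' Construct a prediction set
#'
#' Labels are derived from the probability matrix: per row, the argmax with
#' ties broken by schema order.
#'
#' @param modelName model name.
#' @param schema the [LabelSchema-class].
#' @param ids message ids.
#' @param probs probability matrix (n x nClasses, schema column order).
#' @param source per-id provenance tag (recycled).
#' @return A [PredictionSet-class].
#' @export
predictionSet <- function(modelName, schema, ids, probs, source = "model") {
  probs <- as.matrix(probs)
  colnames(probs) <- schema@labels
  rownames(probs) <- NULL
  labels <- if (nrow(probs)) schema@labels[apply(probs, 1L, which.max)]
            else character(0)
  new("PredictionSet", modelName = as.character(modelName), schema = schema,
      ids = as.character(ids), labels = labels, probs = probs,
      source = rep_len(as.character(source), length(ids)))
}

# ---------------------------------------------------------------------------
# Fusion
# ---------------------------------------------------------------------------

#' Partition of messages by baseline agreement
#'
#' The router's output: messages on which all baseline classifiers predict
#' the same label keep that consensus label; the rest are routed to the
#' fusion model.
#'
#' @slot agreedIds ids on which all baselines agree.
#' @slot consensus the shared label per agreed id (aligned to `agreedIds`).
#' @slot disagreedIds ids with at least two distinct baseline labels.
#' @export
setClass("DisagreementSplit",
         representation(agreedIds = "character", consensus = "character",
                        disagreedIds = "character"))

setValidity("DisagreementSplit", function(object) {
  if (length(object@agreedIds) != length(object@consensus)) {
    return("consensus must align with agreedIds")
  }
  if (length(intersect(object@agreedIds, object@disagreedIds))) {
    return("agreed and disagreed ids must be disjoint")
  }
  TRUE
})

#' Training set for a fusion head
#'
#' Per message a K x d stack of per-encoder embeddings (encoders in a fixed
#' recorded order, projected to a common dimension) plus the gold label.
#' Only disagreement messages appear.
#'
#' @slot ids message ids (disagreed messages only).
#' @slot stacks numeric array n x K x d.
#' @slot labels gold label per id.
#' @slot encoderOrder encoder names in stack row order (ascending by name).
#' @slot commonDim the common embedding dimension d.
#' @slot projections per-encoder projection: `"identity"` or a dim_k x d
#'   matrix used to reconcile mismatched dimensions.
#' @slot schema the full [LabelSchema-class] predictions must cover (gold
#'   labels may touch only a subset of it).
#' @export
setClass("FusionTrainingSet",
         representation(ids = "character", stacks = "array",
                        labels = "character", encoderOrder = "character",
                        commonDim = "integer", projections = "list",
                        schema = "LabelSchema"))

setValidity("FusionTrainingSet", function(object) {
  d <- dim(object@stacks)
  if (length(d) != 3L) return("stacks must be an n x K x d array")
  if (d[1] != length(object@ids)) return("stacks must have one slab per id")
  if (d[2] != length(object@encoderOrder)) {
    return("stacks must have one row per encoder")
  }
  if (d[3] != object@commonDim) return("stack width must equal commonDim")
  if (length(object@stacks) && !all(is.finite(object@stacks))) {
    return("all stack values must be finite")
  }
  TRUE
})

#' Fusion head configuration
#'
#' @slot strategy `"average"`, `"attention"` or `"cnn"`.
#' @slot commonDim common embedding dimension after reconciliation.
#' @slot cnn list: `heights` (filter heights, capped at K), `width`
#'   (filter width along the embedding axis), `nFilters` (filters per
#'   size), `dropout` (rate applied to pooled features during training).
#' @slot attention list: `hidden` (width of the additive-attention layer).
#' @slot training list: `lr`, `epochs`, `seed`.
#' @export
setClass("FusionConfig",
         representation(strategy = "character", commonDim = "integer",
                        cnn = "list", attention = "list", training = "list"))

setValidity("FusionConfig", function(object) {
  if (!object@strategy %in% c("average", "attention", "cnn")) {
    return("strategy must be one of average, attention, cnn")
  }
  if (object@commonDim <= 0L) return("commonDim must be positive")
  TRUE
})

#' Construct a fusion configuration
#'
#' Defaults follow a TextCNN-style convention for the 2-D head: filter
#' heights 2 and 3 (capped at the number of encoders), width 5 along the
#' embedding axis, 64 filters per size, dropout 0.1 before the dense
#' softmax layer.
#'
#' @param strategy `"average"`, `"attention"` or `"cnn"`.
#' @param commonDim common embedding dimension (default 768, the dimension
#'   shared by the usual BERT-family encoders).
#' @param cnnHeights,cnnWidth,cnnFilters,cnnDropout 2-D CNN head settings.
#' @param attentionHidden width of the additive attention layer.
#' @param lr,epochs,seed training hyperparameters of the head.
#' @return A [FusionConfig-class].
#' @examples
#' fusionConfig("cnn", commonDim = 16)
#' @export
fusionConfig <- function(strategy = c("cnn", "attention", "average"),
                         commonDim = 768L,
                         cnnHeights = c(2L, 3L), cnnWidth = 5L,
                         cnnFilters = 64L, cnnDropout = 0.1,
                         attentionHidden = 64L,
                         lr = 0.01, epochs = 150L, seed = 1L) {
  strategy <- match.arg(strategy)
  new("FusionConfig", strategy = strategy, commonDim = as.integer(commonDim),
      cnn = list(heights = as.integer(cnnHeights), width = as.integer(cnnWidth),
                 nFilters = as.integer(cnnFilters), dropout = cnnDropout),
      attention = list(hidden = as.integer(attentionHidden)),
      training = list(lr = lr, epochs = as.integer(epochs),
                      seed = as.integer(seed)))
}

#' Trained fusion model
#'
#' @slot config the [FusionConfig-class] used for training.
#' @slot schema the label schema.
#' @slot encoderOrder encoder names in stack row order.
#' @slot projections per-encoder projection used to build stacks.
#' @slot params fitted parameters (strategy-specific).
#' @slot metadata training metadata (seed, final loss, n, class counts).
#' @export
setClass("FittedFusion",
         representation(config = "FusionConfig", schema = "LabelSchema",
                        encoderOrder = "character", projections = "list",
                        params = "list", metadata = "list"))

# ---------------------------------------------------------------------------
# Rebalancing
# ---------------------------------------------------------------------------

#' Class-rebalancing specification
#'
#' Selects one of the training-time strategies that counter class
#' imbalance: per-class loss weights inversely proportional to class
#' frequency, random oversampling of minority classes up to the majority
#' count, or focal loss.
#'
#' @slot strategy `"none"`, `"class_weight"`, `"oversample"` or `"focal"`.
#' @slot gamma focal-loss focusing parameter (>= 0, default 2).
#' @slot alpha `"inverse_frequency"` or a named positive numeric vector of
#'   per-class weights.
#' @export
setClass("RebalanceSpec",
         representation(strategy = "character", gamma = "numeric",
                        alpha = "ANY"))

setValidity("RebalanceSpec", function(object) {
  if (!object@strategy %in% c("none", "class_weight", "oversample", "focal")) {
    return("strategy must be one of none, class_weight, oversample, focal")
  }
  if (object@gamma < 0) return("gamma must be >= 0")
  if (is.numeric(object@alpha) && any(object@alpha <= 0)) {
    return("alpha weights must be positive")
  }
  TRUE
})

#' Construct a rebalancing specification
#'
#' @param strategy `"none"`, `"class_weight"`, `"oversample"` or `"focal"`.
#' @param gamma focal focusing parameter (default 2).
#' @param alpha `"inverse_frequency"` (default) or named per-class weights.
#' @return A [RebalanceSpec-class].
#' @examples
#' rebalanceSpec("focal", gamma = 2)
#' @export
rebalanceSpec <- function(strategy = c("none", "class_weight", "oversample",
                                       "focal"),
                          gamma = 2, alpha = "inverse_frequency") {
  new("RebalanceSpec", strategy = match.arg(strategy), gamma = gamma,
      alpha = alpha)
}

# ---------------------------------------------------------------------------
# Metrics
# ---------------------------------------------------------------------------

#' Classification metrics over one evaluation set
#'
#' @slot accuracy overall accuracy.
#' @slot perClass data.frame with columns `label`, `precision`, `recall`,
#'   `f1` (one row per schema class; zero-denominator classes score 0).
#' @slot macro named numeric vector: unweighted means `precision`,
#'   `recall`, `f1` over all schema classes.
#' @slot n number of evaluated messages.
#' @export
setClass("MetricsReport",
         representation(accuracy = "numeric", perClass = "data.frame",
                        macro = "numeric", n = "integer"))
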