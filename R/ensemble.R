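#' Majority vote with alphabetical tie-breaking
#'
#' Returns the plurality label among the K member labels. When several
#' labels tie for the top count (including the K all-distinct case, where
#' majority voting alone fails), the tied label that comes first in the
#' schema's ascending order wins — for the default schema the order A, L,
#' P, U, so a three-way (L, P, U) disagreement resolves to L.
#'
#' @param labels character vector of K >= 2 member labels, all within the
#'   schema.
#' @param schema a [LabelSchema-class].
#' @return single winning label.
#' @examples
#' majorityVote(c("A", "A", "P"))  # strict majority: A
#' majorityVote(c("L", "P", "U"))  # three-way tie: alphabetical first, L
#' @export
majorityVote <- function(labels, schema = labelSchema()) {
  if (length(labels) < 2L) stopf("majority vote needs K >= 2 members")
  bad <- setdiff(labels, schema@labels)
  if (length(bad)) {
    stopf("label(s) outside schema: %s", paste(bad, collapse = ", "))
  }
  counts <- table(factor(labels, levels = schema@labels))
  top <- names(counts)[counts == max(counts)]
  top[1L] # schema levels are already in tie-break order
}

#' Majority-vote ensemble of prediction sets
#'
#' Per message, the ensemble label is the majority vote of the member
#' labels (ties broken alphabetically by schema order) and the ensemble
#' probability vector is the vote share per class.
#'
#' @param members list of K >= 2 [PredictionSet-class] objects covering
#'   identical id sets.
#' @param modelName name for the ensemble prediction set.
#' @return A [PredictionSet-class].
#' @export
ensemblePredict <- function(members, modelName = "majority_vote") {
  if (length(members) < 2L) stopf("ensemble needs at least 2 members")
  ids <- members[[1]]@ids
  schema <- members[[1]]@schema
  for (p in members[-1]) {
    if (!setequal(p@ids, ids)) {
      diff <- c(setdiff(ids, p@ids), setdiff(p@ids, ids))
      stopf("member predictions cover different ids; mismatch: %s",
            paste(diff, collapse = ", "))
    }
  }
  labMat <- vapply(members, function(p) unname(predictionLabels(p)[ids]),
                   character(length(ids)))
  labMat <- matrix(labMat, nrow = length(ids))
  K <- ncol(labMat)
  probs <- if (length(ids) == 0L) matrix(0, 0L, length(schema@labels))
           else t(apply(labMat, 1L, function(r) {
             as.numeric(table(factor(r, levels = schema@labels))) / K
           }))
  predictionSet(modelName, schema, ids, probs, source = "ensemble")
}
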