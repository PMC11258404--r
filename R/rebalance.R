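#' Inverse-frequency class weights
#'
#' Weights the importance of each class inversely proportional to its
#' frequency: `w_c = N / (K * n_c)` with `N` the total count and `K` the
#' number of classes, so that `sum_c w_c * n_c = N` and balanced classes
#' all get weight 1.
#'
#' @param counts named positive integer vector of per-class counts.
#' @return named numeric vector of weights, same names as `counts`.
#' @examples
#' inverseFrequencyWeights(c(A = 991, L = 315, P = 301, U = 632))
#' @export
inverseFrequencyWeights <- function(counts) {
  if (any(counts <= 0)) {
    stopf("class(es) with zero count: %s",
          paste(names(counts)[counts <= 0], collapse = ", "))
  }
  N <- sum(counts)
  K <- length(counts)
  stats::setNames(N / (K * as.numeric(counts)), names(counts))
}

#' Random oversampling to the majority-class count
#'
#' Augments every minority class by drawing duplicates of its own ids
#' uniformly with replacement until each class matches the majority class
#' count. All original items are retained; the output is an id multiset.
#'
#' @param ids character vector of item ids.
#' @param labels class label per id (aligned with `ids`).
#' @param seed RNG seed; same inputs give the same multiset.
#' @return character vector of ids: the originals followed by the sampled
#'   duplicates.
#' @examples
#' oversample(c("a1", "a2", "a3", "p1"), c("A", "A", "A", "P"), seed = 1)
#' @export
oversample <- function(ids, labels, seed = 1L) {
  if (length(ids) == 0L) stopf("cannot oversample an empty input")
  if (length(ids) != length(labels)) stopf("ids and labels must align")
  counts <- table(labels)
  target <- max(counts)
  extra <- withSeed(deriveSeed(seed, 911L), {
    unlist(lapply(names(counts), function(cl) {
      need <- target - counts[[cl]]
      if (need == 0L) return(character(0))
      pool <- ids[labels == cl]
      pool[sample.int(length(pool), need, replace = TRUE)]
    }), use.names = FALSE)
  })
  c(ids, extra)
}

#' Focal loss
#'
#' The focal loss `-alpha * (1 - p)^gamma * log(p)` of the probability `p`
#' assigned to the true class. It down-weights well-classified examples so
#' training focuses on hard-to-learn ones; with `gamma = 0` and
#' `alpha = 1` it reduces exactly to cross-entropy `-log(p)`.
#'
#' @param pTrue probability assigned to the true class, in (0, 1];
#'   vectorized. Callers must clamp probabilities away from 0 first.
#' @param gamma focusing parameter, >= 0 (default 2).
#' @param alpha per-example (true-class) weight, > 0 (default 1).
#' @return numeric vector of losses.
#' @examples
#' focalLoss(0.9, gamma = 2)          # (0.1)^2 * -log(0.9)
#' focalLoss(0.5, gamma = 0)          # log(2): plain cross-entropy
#' @export
focalLoss <- function(pTrue, gamma = 2, alpha = 1) {
  if (gamma < 0) stopf("gamma must be >= 0")
  if (any(pTrue <= 0 | pTrue > 1)) {
    stopf("pTrue must lie in (0, 1]; clamp probabilities before calling")
  }
  -alpha * (1 - pTrue)^gamma * log(pTrue)
}
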