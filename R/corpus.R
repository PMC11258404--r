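#' Read a labeled message corpus from JSONL or CSV
#'
#' JSONL (one JSON object per line with keys `id`, `text` and optionally
#' `label`) is the canonical format; CSV with header `id,text,label`
#' (RFC-4180 quoting, UTF-8) is also accepted. Record order is preserved.
#'
#' @param path path to the corpus file.
#' @param format `"jsonl"` or `"csv"`; default guesses from the file
#'   extension (`.csv` means CSV, anything else JSONL).
#' @param schema a [LabelSchema-class]; every label in the file must belong
#'   to it.
#' @return A [Corpus-class]. Duplicate ids and labels outside the schema
#'   are hard errors naming the offending id/label.
#' @examples
#' f <- tempfile(fileext = ".jsonl")
#' writeLines(c('{"id":"m1","text":"knee pain","label":"A"}',
#'              '{"id":"m2","text":"refill please","label":"P"}'), f)
#' loadCorpus(f)
#' @seealso [writeCorpus()], [classDistribution()]
#' @export
loadCorpus <- function(path, format = c("auto", "jsonl", "csv"),
                       schema = labelSchema()) {
  format <- match.arg(format)
  if (!file.exists(path)) stopf("corpus file not found: %s", path)
  if (format == "auto") {
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "jsonl"
  }
  if (format == "jsonl") {
    lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    recs <- lapply(lines, jsonlite::fromJSON)
    df <- data.frame(
      id = vapply(recs, function(r) as.character(r$id %||% ""), character(1)),
      text = vapply(recs, function(r) as.character(r$text %||% ""),
                    character(1)),
      label = vapply(recs, function(r) {
        if (is.null(r$label) || is.na(r$label)) NA_character_
        else as.character(r$label)
      }, character(1)),
      stringsAsFactors = FALSE)
  } else {
    df <- utils::read.csv(path, colClasses = "character",
                          fileEncoding = "UTF-8")
    if (!all(c("id", "text") %in% names(df))) {
      stopf("CSV corpus must have columns id and text")
    }
    if (is.null(df$label)) df$label <- NA_character_
    df$label[!is.na(df$label) & df$label == ""] <- NA_character_
    df <- df[, c("id", "text", "label")]
  }
  if (nrow(df) == 0L) {
    return(new("Corpus", schema = schema,
               messages = data.frame(id = character(0), text = character(0),
                                     label = character(0),
                                     stringsAsFactors = FALSE)))
  }
  if (any(!nzchar(df$id))) stopf("record without an id in %s", path)
  new("Corpus", schema = schema, messages = df)
}

#' Write a corpus to JSONL or CSV
#'
#' @param x a [Corpus-class].
#' @param path output file path.
#' @param format `"jsonl"` (canonical) or `"csv"`.
#' @return `path`, invisibly.
#' @export
writeCorpus <- function(x, path, format = c("jsonl", "csv")) {
  format <- match.arg(format)
  m <- x@messages
  if (format == "jsonl") {
    lines <- vapply(seq_len(nrow(m)), function(i) {
      rec <- list(id = m$id[i], text = m$text[i])
      if (!is.na(m$label[i])) rec$label <- m$label[i]
      jsonlite::toJSON(rec, auto_unbox = TRUE)
    }, character(1))
    writeLines(lines, path, useBytes = TRUE)
  } else {
    utils::write.csv(m, path, row.names = FALSE, fileEncoding = "UTF-8",
                     na = "")
  }
  invisible(path)
}

#' Per-class counts and percentages of a labeled corpus
#'
#' Percentages are `100 * count / total`, rounded half-up to one decimal —
#' the convention used when such corpora are reported (e.g. a class of 991
#' messages out of 2239 is 44.3%).
#'
#' @param x a fully labeled, non-empty [Corpus-class].
#' @return data.frame with columns `label`, `count`, `percent`, one row per
#'   schema class in schema order.
#' @examples
#' cp <- corpus(id = paste0("m", 1:4), text = "t",
#'              label = c("A", "A", "L", "U"))
#' classDistribution(cp)
#' @export
classDistribution <- function(x) {
  m <- x@messages
  if (nrow(m) == 0L) stopf("corpus is empty")
  if (anyNA(m$label)) {
    stopf("unlabeled message(s): %s",
          paste(m$id[is.na(m$label)], collapse = ", "))
  }
  cls <- x@schema@labels
  counts <- as.integer(table(factor(m$label, levels = cls)))
  data.frame(label = cls, count = counts,
             percent = roundHalfUp(100 * counts / nrow(m), 1L),
             stringsAsFactors = FALSE)
}

#' Plan repeated stratified k-fold cross-validation
#'
#' Within each repeat, the ids of every class are shuffled with a
#' repeat-specific seed (`seed + r` for repeat `r`) and dealt round-robin
#' into folds, continuing the dealing position across classes. This
#' guarantees that fold sizes differ by at most one and per-fold class
#' counts differ from a perfectly stratified allocation by at most one.
#'
#' @param x a fully labeled [Corpus-class]; every class must have at least
#'   `nFolds` members.
#' @param nFolds number of folds (default 10).
#' @param nRepeats number of repeats (default 3).
#' @param seed base seed; the plan is a pure function of its inputs.
#' @return A [FoldPlan-class].
#' @examples
#' cp <- corpus(id = paste0("m", 1:40), text = "t",
#'              label = rep(c("A", "L", "P", "U"), 10))
#' makeFoldPlan(cp, nFolds = 10, nRepeats = 2, seed = 7)
#' @export
makeFoldPlan <- function(x, nFolds = 10L, nRepeats = 3L, seed = 1L) {
  nFolds <- as.integer(nFolds); nRepeats <- as.integer(nRepeats)
  if (nFolds < 2L) stopf("nFolds must be >= 2")
  m <- x@messages
  if (anyNA(m$label)) stopf("fold planning requires a fully labeled corpus")
  counts <- table(factor(m$label, levels = x@schema@labels))
  small <- names(counts)[counts < nFolds]
  if (length(small)) {
    stopf("class(es) with fewer than nFolds members: %s",
          paste(small, collapse = ", "))
  }
  rows <- vector("list", nRepeats)
  for (r in seq_len(nRepeats)) {
    ord <- withSeed(deriveSeed(seed + r), {
      unlist(lapply(x@schema@labels, function(cl) {
        ids <- m$id[m$label == cl]
        sample(ids, length(ids))
      }), use.names = FALSE)
    })
    # deal the class-blocked, within-class-shuffled sequence round-robin,
    # continuing the fold pointer across class blocks
    folds <- ((seq_along(ord) - 1L) %% nFolds) + 1L
    rows[[r]] <- data.frame(rep = r, id = ord, fold = folds,
                            stringsAsFactors = FALSE)
  }
  new("FoldPlan", nFolds = nFolds, nRepeats = nRepeats,
      seed = as.integer(seed), assignment = do.call(rbind, rows))
}

#' Extract one repeat's fold assignment as a named vector
#'
#' @param plan a [FoldPlan-class].
#' @param rep repeat index (1-based).
#' @return integer vector of fold indices named by message id.
#' @export
foldAssignment <- function(plan, rep = 1L) {
  sub <- plan@assignment[plan@assignment$rep == rep, ]
  if (nrow(sub) == 0L) stopf("repeat %d not in plan", rep)
  stats::setNames(sub$fold, sub$id)
}

#' Serialize / deserialize a fold plan as JSON
#'
#' The JSON form (nFolds, nRepeats, seed, assignment triples) makes an
#' experiment exactly replayable.
#'
#' @param plan a [FoldPlan-class].
#' @param path output (input) file path.
#' @return `path` invisibly; `readFoldPlan` returns the [FoldPlan-class].
#' @export
writeFoldPlan <- function(plan, path) {
  jsonlite::write_json(
    list(nFolds = plan@nFolds, nRepeats = plan@nRepeats, seed = plan@seed,
         assignment = plan@assignment),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeFoldPlan
#' @export
readFoldPlan <- function(path) {
  x <- jsonlite::fromJSON(path)
  a <- as.data.frame(x$assignment, stringsAsFactors = FALSE)
  a$rep <- as.integer(a$rep); a$fold <- as.integer(a$fold)
  new("FoldPlan", nFolds = as.integer(x$nFolds),
      nRepeats = as.integer(x$nRepeats), seed = as.integer(x$seed),
      assignment = a)
}
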