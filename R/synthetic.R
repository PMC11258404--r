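# Per-class template fragments and keyword vocabularies used to assemble
# synthetic portal-style messages. Purely synthetic text; no patient data.
syntheticVocab <- list(
  A = list(keywords = c("pain", "symptom", "dizzy", "swelling", "rash",
                        "fever", "nausea", "headache", "cough", "fatigue"),
           templates = c("i have been having %s and %s for a few days",
                         "the %s is getting worse and now i also notice %s",
                         "experiencing %s along with %s since last week")),
  L = list(keywords = c("appointment", "schedule", "billing", "insurance",
                        "referral", "paperwork", "reschedule", "records",
                        "clinic", "visit"),
           templates = c("can you help me with my %s and the %s question",
                         "i need to change the %s and ask about %s",
                         "question about %s and also the %s process")),
  P = list(keywords = c("prescription", "refill", "medication", "dose",
                        "pharmacy", "tablets", "pills", "dosage", "generic",
                        "side-effects"),
           templates = c("i need a %s for my %s please",
                         "is the %s correct or should the %s change",
                         "running low on my %s can you send a %s")),
  U = list(keywords = c("update", "thanks", "doing", "well", "improved",
                        "stable", "normal", "grateful", "progress",
                        "checkin"),
           templates = c("just an %s i am %s since the checkup",
                         "quick %s everything has been %s lately",
                         "sending an %s feeling %s overall")))

#' Configuration of the synthetic corpus / embedding generator
#'
#' The generator emulates the statistical structure the fusion framework
#' assumes: a 4-class message corpus with realistic imbalance (default
#' proportions 44.3 / 13.4 / 14.1 / 28.2% for A / P / L / U), messages
#' that with probability `q` also mention a secondary topic from another
#' class (the primary label is unchanged), and K encoders with
#' complementary class-specific signal: encoder k embeds class c as
#' `s * g_k(c) * mu_c + sigma * noise` with orthogonal class directions
#' `mu_c`, gain 1 on the classes in its complementary set and `gammaLow`
#' elsewhere.
#'
#' @param n number of messages.
#' @param proportions named class proportions (must sum to 1).
#' @param K number of encoders.
#' @param dim embedding dimension (>= number of classes).
#' @param s signal strength (default 3).
#' @param sigma noise scale (default 1; s/sigma = 3 by default).
#' @param complementary list mapping encoder name to the classes it
#'   resolves well; defaults to encoder 1 -> {A, U}, encoder 2 -> {P},
#'   encoder 3 -> {L} so that the sets cover all classes.
#' @param gammaLow gain on classes outside an encoder's set (default
#'   0.3).
#' @param q probability that a message mentions a secondary topic from
#'   another class (default 0.3).
#' @param seed generator seed.
#' @return list of class `syntheticConfig`.
#' @export
syntheticConfig <- function(n = 2000L,
                            proportions = c(A = 0.443, P = 0.134,
                                            L = 0.141, U = 0.282),
                            K = 3L, dim = 16L, s = 3, sigma = 1,
                            complementary = NULL, gammaLow = 0.3,
                            q = 0.3, seed = 1L) {
  if (abs(sum(proportions) - 1) > 1e-9) {
    stopf("class proportions must sum to 1")
  }
  if (s <= 0 || sigma <= 0) stopf("s and sigma must be positive")
  if (q < 0 || q > 1) stopf("q must lie in [0, 1]")
  if (is.null(complementary)) {
    complementary <- list(enc1 = c("A", "U"), enc2 = "P", enc3 = "L")
    complementary <- complementary[seq_len(min(K, 3L))]
    if (K > 3L) for (k in 4:K) {
      complementary[[paste0("enc", k)]] <- names(proportions)
    }
  }
  structure(list(n = as.integer(n), proportions = proportions,
                 K = as.integer(K), dim = as.integer(dim), s = s,
                 sigma = sigma, complementary = complementary,
                 gammaLow = gammaLow, q = q, seed = as.integer(seed)),
            class = "syntheticConfig")
}

#' Generate a synthetic labeled message corpus
#'
#' Labels are drawn from the configured class proportions; each message
#' text is assembled from per-class template sentences and keyword
#' vocabularies, and with probability `q` a secondary-topic sentence from
#' a different class is appended (the primary label is unchanged),
#' emulating the multi-topic character of real portal messages.
#' Deterministic given the config seed.
#'
#' @param config a [syntheticConfig()] list.
#' @return A [Corpus-class] of `config$n` messages.
#' @export
generateCorpus <- function(config) {
  cls <- names(config$proportions)
  schema <- labelSchema(cls)
  withSeed(deriveSeed(config$seed, 101L), {
    labels <- sample(cls, config$n, replace = TRUE,
                     prob = config$proportions)
    texts <- vapply(labels, function(cl) {
      txt <- syntheticSentence(cl)
      if (stats::runif(1) < config$q) {
        other <- sample(setdiff(cls, cl), 1L)
        txt <- paste(txt, syntheticSentence(other), sep = ". ")
      }
      txt
    }, character(1), USE.NAMES = FALSE)
    corpus(id = sprintf("msg%05d", seq_len(config$n)), text = texts,
           label = labels, schema = schema)
  })
}

syntheticSentence <- function(cl) {
  voc <- syntheticVocab[[cl]]
  tpl <- sample(voc$templates, 1L)
  kws <- sample(voc$keywords, 2L)
  sprintf(tpl, kws[1], kws[2])
}

#' Generate complementary multi-encoder embeddings for labeled messages
#'
#' For encoder k and a message of class c, the embedding is
#' `s * g_k(c) * mu_c + sigma * eps` with `mu_c` fixed axis-aligned
#' orthogonal unit vectors, `eps` standard Gaussian noise, and gain
#' `g_k(c) = 1` when c belongs to encoder k's complementary set and
#' `gammaLow` otherwise. Deterministic given the config seed.
#'
#' @param config a [syntheticConfig()] list.
#' @param corpus a labeled [Corpus-class] (typically from
#'   [generateCorpus()]); its ids and labels are used.
#' @return named list of K [EmbeddingSet-class] objects.
#' @export
generateEmbeddings <- function(config, corpus) {
  cls <- names(config$proportions)
  if (config$dim < length(cls)) {
    stopf("dim must be at least the number of classes")
  }
  ids <- messageIds(corpus)
  labs <- unname(messageLabels(corpus))
  if (anyNA(labs)) stopf("corpus must be fully labeled")
  n <- length(ids)
  encNames <- names(config$complementary)
  out <- vector("list", config$K)
  for (k in seq_len(config$K)) {
    nm <- encNames[k]
    gains <- ifelse(labs %in% config$complementary[[nm]], 1, config$gammaLow)
    E <- withSeed(deriveSeed(config$seed, 300L + k), {
      matrix(stats::rnorm(n * config$dim, sd = config$sigma), n, config$dim)
    })
    mu <- match(labs, cls) # axis-aligned class directions
    E[cbind(seq_len(n), mu)] <- E[cbind(seq_len(n), mu)] +
      config$s * gains
    out[[k]] <- embeddingSet(nm, ids, E)
  }
  stats::setNames(out, encNames)
}

#' Write a synthetic study to disk
#'
#' Writes the corpus (JSONL), one embedding CSV per encoder (id column
#' followed by the embedding values) and a JSON manifest of all config
#' values, so a simulated experiment is exactly replayable.
#'
#' @param config a [syntheticConfig()] list.
#' @param dir output directory (created if needed).
#' @return invisible list with the generated corpus and embeddings.
#' @export
writeSyntheticStudy <- function(config, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cp <- generateCorpus(config)
  emb <- generateEmbeddings(config, cp)
  writeCorpus(cp, file.path(dir, "corpus.jsonl"))
  for (nm in names(emb)) {
    df <- data.frame(id = emb[[nm]]@ids, emb[[nm]]@embedding)
    utils::write.csv(df, file.path(dir, paste0("embeddings_", nm, ".csv")),
                     row.names = FALSE)
  }
  manifest <- unclass(config)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(corpus = cp, embeddings = emb))
}
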