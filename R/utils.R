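# Internal numeric / RNG helpers shared across modules.

# Half-up decimal rounding (R's round() is banker's rounding).
roundHalfUp <- function(x, digits = 1L) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# Derive a child seed from a parent seed and integer offsets. Keeps the
# result strictly inside 32-bit integer range so set.seed() accepts it.
deriveSeed <- function(seed, ...) {
  m <- 2147483629 # prime < 2^31
  h <- as.numeric(seed) %% m
  for (k in c(...)) {
    h <- (h * 69069 + as.numeric(k) + 1) %% m
  }
  as.integer(h)
}

# Evaluate expr under a fixed seed without disturbing the global RNG stream.
withSeed <- function(seed, expr) {
  withr::with_seed(as.integer(seed), expr)
}

# Numerically stable row-wise softmax of a matrix of logits.
softmaxRows <- function(z) {
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

# Stable 31-bit polynomial string hash over UTF-8 bytes (platform-independent,
# unlike R's internal randomized-environment hashing).
stringHash31 <- function(x, init = 17L) {
  m <- 2147483629
  vapply(x, function(s) {
    h <- as.numeric(init) %% m
    for (b in as.integer(utf8ToInt(enc2utf8(s)))) {
      h <- (h * 31 + b) %% m
    }
    as.integer(h)
  }, integer(1), USE.NAMES = FALSE)
}

# argmax over a probability vector with ties broken by column (schema) order.
argmaxFirst <- function(p) which.max(p)

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
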