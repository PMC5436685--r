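## Internal helpers: deterministic seed derivation and light hashing for the
## run manifest.  No cryptographic strength intended; FNV-1a is enough to
## detect artifact drift between pipeline runs.

mul32 <- function(a, b) {
  ## 32-bit modular multiply without losing precision in doubles
  lo <- a %% 65536
  hi <- (a - lo) / 65536
  (((hi * b) %% 65536) * 65536 + lo * b) %% 4294967296
}

fnv1a <- function(bytes) {
  h <- 2166136261
  for (b in as.integer(bytes)) {
    h <- bitwXor(as.integer(h %% 2147483648), b) + (h >= 2147483648) * 2147483648
    h <- mul32(h, 16777619)
  }
  h
}

#' Hash an R object (stable across sessions)
#'
#' FNV-1a over the serialized object, returned as a hex string.  Used by the
#' pipeline manifest to checksum configurations and artifacts.
#'
#' @param x any serializable R object
#' @return a character scalar, 8 hex digits
#' @export
hashObject <- function(x) {
  raw <- serialize(x, NULL, version = 2)
  ## drop the serialization header (R-version dependent)
  raw <- raw[-seq_len(14)]
  n <- length(raw)
  ## large objects: hash length plus a deterministic byte subsample, keeping
  ## manifest computation O(1)-ish while still catching drift
  if (n > 8192) raw <- c(raw[seq(1L, n, by = max(1L, n %/% 8192L))], as.raw(n %% 256))
  sprintf("%08x", as.integer(fnv1a(c(raw, as.raw(n %% 251))) %% 2147483647))
}

#' Derive a reproducible sub-seed
#'
#' Hashes a master seed together with an arbitrary set of string/numeric
#' labels (stage name, subject id, ...) into an integer seed below 2^31,
#' so that every stochastic stage of a run consumes a seed that is a pure
#' function of the master seed and its position in the pipeline.
#'
#' @param masterSeed integer master seed
#' @param ... labels identifying the consumer (coerced to character)
#' @return an integer in `[1, 2^31 - 2]`
#' @export
deriveSeed <- function(masterSeed, ...) {
  key <- paste(c(masterSeed, ...), collapse = "\x1f")
  as.integer(fnv1a(utf8ToInt(key) %% 256) %% 2147483645 + 1)
}

## Cheap deterministic fingerprint of a (possibly huge) artifact: large
## numeric payloads are summarized by shape, moments and a strided probe, so
## manifest checksums stay O(1) in the artifact size while still catching
## value drift.
.fingerprint <- function(x) {
  if (is.numeric(x) && length(x) > 4096L) {
    list(.fp = "numeric", dim = dim(x), n = length(x), sum = sum(x),
         ss = sum(x * x), probe = x[unique(as.integer(seq(1L, length(x), length.out = 64L)))])
  } else if (isS4(x)) {
    out <- lapply(methods::slotNames(class(x)), function(s) .fingerprint(methods::slot(x, s)))
    names(out) <- methods::slotNames(class(x))
    c(list(.class = class(x)[1]), out)
  } else if (is.list(x) && !is.data.frame(x)) {
    lapply(x, .fingerprint)
  } else x
}

## consistent stop() with call suppressed
.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

.assertFinite <- function(x, what) {
  if (!all(is.finite(x))) .stopf("%s contains non-finite values", what)
}
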