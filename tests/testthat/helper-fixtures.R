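# Shared fixtures, all generated in code.

tinyGrid <- function() voxelGrid(c(12L, 12L, 6L))

tinyConfig <- function(nHigh = 3L, nLow = 3L, nVolumesRaw = 60L, seed = 1L, ...) {
  cohortConfig(nHigh = nHigh, nLow = nLow, nVolumesRaw = nVolumesRaw,
               grid = tinyGrid(), masterSeed = seed, ...)
}

# planted sparse-source mixture on a small grid; returns data + true loadings
plantedMixture <- function(nSources = 4L, nTimepoints = 500L, snr = 2,
                           seed = 1L, grid = tinyGrid()) {
  simulateSourceData(nSources = nSources, nSubjects = 1L,
                     nTimepoints = nTimepoints, grid = grid,
                     supportVoxels = 40L, snr = snr, seed = seed)
}

# match estimated to true maps by maximum absolute correlation (greedy);
# returns the matched absolute correlations
matchMaps <- function(est, truth) {
  k <- nrow(truth)
  cors <- abs(stats::cor(t(est), t(truth)))
  out <- numeric(k)
  for (i in seq_len(k)) {
    best <- which(cors == max(cors), arr.ind = TRUE)[1, ]
    out[best[2]] <- cors[best[1], best[2]]
    cors[best[1], ] <- -1
    cors[, best[2]] <- -1
  }
  out
}

# independent conditional-GC reference: two explicit lm() regressions
referenceCGC <- function(ts, src, tgt, cnd, m = 1L) {
  Tn <- nrow(ts)
  rows <- (m + 1L):Tn
  lagm <- function(cols) do.call(cbind, lapply(seq_len(m), function(l)
    ts[rows - l, cols, drop = FALSE]))
  y <- ts[rows, tgt]
  dR <- data.frame(y = y, lagm(c(tgt, cnd)))
  dF <- data.frame(y = y, lagm(c(tgt, cnd, src)))
  rssR <- sum(stats::residuals(stats::lm(y ~ ., dR))^2)
  rssF <- sum(stats::residuals(stats::lm(y ~ ., dF))^2)
  log(rssR / rssF)
}

# simulate a VAR(p) with given lag matrices (list) and unit innovations
simVARp <- function(Alist, Tn, seed = 1L, burn = 100L) {
  d <- nrow(Alist[[1]])
  p <- length(Alist)
  set.seed(seed)
  X <- matrix(0, Tn + burn, d)
  for (t in (p + 1):(Tn + burn)) {
    x <- stats::rnorm(d)
    for (l in seq_len(p)) x <- x + Alist[[l]] %*% X[t - l, ]
    X[t, ] <- x
  }
  X[(burn + 1):(burn + Tn), , drop = FALSE]
}
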