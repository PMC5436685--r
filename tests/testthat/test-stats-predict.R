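# Pearson screen, FDR adjustment, and LOOCV support-vector regression.

test_that("Pearson correlation matches hand arithmetic and flags degeneracy", {
  x <- c(1, 2, 3, 4)
  expect_equal(pearsonCorr(x, x)$r, 1)
  expect_equal(pearsonCorr(x, -2 * x + 7)$r, -1)
  expect_equal(pearsonCorr(x, c(2, 1, 4, 3))$r, 0.6)
  # p from the t transform with n - 2 df
  r <- 0.6; n <- 4
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  expect_equal(pearsonCorr(x, c(2, 1, 4, 3))$p, 2 * stats::pt(-tstat, n - 2))
  expect_error(pearsonCorr(x, rep(1, 4)), "zero-variance")
  expect_error(pearsonCorr(x, c(1, 2)), "equal lengths")
})

test_that("BH adjustment reproduces the step-up hand computation", {
  res <- fdrBH(c(0.01, 0.02, 0.04, 0.50), q = 0.05)
  expect_equal(res$padj, c(0.04, 0.04, 0.04 / 3 * 4, 0.50))
  expect_equal(res$significant, c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(fdrBH(0.031)$padj, 0.031)            # m = 1 identity
  expect_true(all(fdrBH(rep(0, 5))$significant))
  expect_error(fdrBH(c(0.2, 1.2)), "\\[0, 1\\]")
})

test_that("LOOCV SVR realizes a noiseless affine relation and not permuted labels", {
  set.seed(19)
  x <- matrix(stats::rnorm(12), 12, 1)
  y <- 3 * x[, 1] + 50
  pr <- svrLoocvPredict(x, y, C = 1000, epsilon = 0.01)
  expect_lt(rmsep(pr), 0.02)
  expect_gt(pr@r, 0.999)
  expect_length(predictedScores(pr), 12L)

  # permuted labels carry no signal: the informative fit beats essentially
  # every permutation, and the permutation r's never trend positive (their
  # center sits below zero because each held-out prediction leans on the
  # training fold's mean, which excludes the held-out score)
  rs <- vapply(1:20, function(s) {
    set.seed(s)
    svrLoocvPredict(x, sample(y), C = 1, epsilon = 0.1)@r
  }, 0)
  expect_lt(mean(rs), 0.2)
  expect_gt(pr@r, max(rs))
})

test_that("held-out predictions agree with an independent SVR implementation", {
  skip_if_not_installed("kernlab")
  set.seed(42)
  n <- 6
  x <- matrix(stats::rnorm(n), n, 1)
  y <- 50 + 8 * x[, 1] + stats::rnorm(n)
  pr <- svrLoocvPredict(x, y, C = 1, epsilon = 0.1)
  ref <- numeric(n)
  for (i in seq_len(n)) {
    mu <- mean(x[-i, 1]); sd <- stats::sd(x[-i, 1])
    fit <- kernlab::ksvm(matrix((x[-i, 1] - mu) / sd), y[-i], type = "eps-svr",
                         kernel = "vanilladot", C = 1, epsilon = 0.1,
                         scaled = FALSE, kpar = list())
    ref[i] <- kernlab::predict(fit, matrix((x[i, 1] - mu) / sd))
  }
  expect_equal(pr@predicted, ref, tolerance = 1e-6)
})

test_that("LOOCV is deterministic, leak-free, and RMSEP recomputes exactly", {
  set.seed(23)
  x <- matrix(stats::rnorm(20), 10, 2)
  y <- 40 + 5 * x[, 1] + stats::rnorm(10)
  a <- svrLoocvPredict(x, y)
  b <- svrLoocvPredict(x, y)
  expect_identical(predictedScores(a), predictedScores(b))
  expect_identical(rmsep(a), sqrt(mean((predictedScores(a) - y)^2)))

  # no leakage: each fold's prediction equals a from-scratch fit that never
  # saw the held-out subject, even when that subject is an extreme outlier
  xo <- x; xo[4, ] <- xo[4, ] * 50
  pro <- svrLoocvPredict(xo, y)
  for (i in c(1L, 4L, 7L)) {
    mu <- colMeans(xo[-i, ]); sd <- apply(xo[-i, ], 2, stats::sd)
    trZ <- sweep(sweep(xo[-i, ], 2, mu), 2, sd, "/")
    fit <- e1071::svm(trZ, y[-i], type = "eps-regression", kernel = "linear",
                      cost = 1, epsilon = 0.1, scale = FALSE)
    expect_equal(predictedScores(pro)[i],
                 unname(stats::predict(fit, matrix((xo[i, ] - mu) / sd, 1))),
                 tolerance = 1e-12)
  }

  # constant feature in a fold is dropped and logged
  xc <- cbind(x[, 1], c(rep(2, 9), 99))
  prc <- svrLoocvPredict(xc, y)
  expect_equal(prc@droppedFeatures[[1]]$fold, 10L)
  expect_equal(prc@droppedFeatures[[1]]$features, 2L)
})

test_that("the correlation screen recovers planted slopes and honors alignment", {
  # construct GC matrices directly: z linear in loneliness for one edge
  mkGC <- function(seed) {
    set.seed(seed)
    n <- 15L
    lon <- sample(46:65, n, replace = TRUE)
    edges <- data.frame(source = c("AfN", "DAN"), target = c("VN", "VAN"),
                        label = c("AfN->VN", "DAN->VAN"))
    z <- cbind(10 - 0.35 * lon + stats::rnorm(n, sd = 1),
               stats::rnorm(n, sd = 1))
    colnames(z) <- edges$label
    gc <- new("GCMatrix", edges = edges, influence = abs(z), zscores = z,
              order = 1L, subjectIds = sprintf("s%02d", 1:n),
              groups = rep("high", n))
    beh <- data.frame(subjectId = sprintf("s%02d", 1:n), group = "high",
                      Loneliness = lon, STAI = sample(30:60, n, TRUE),
                      SDS = sample(30:57, n, TRUE), IRI_C = sample(40:70, n, TRUE),
                      Trust = sample(60:100, n, TRUE), SSRS = sample(30:50, n, TRUE))
    list(gc = gc, beh = beh)
  }
  hits <- 0L
  nullFlags <- 0L; nullTotal <- 0L
  for (s in 1:20) {
    f <- mkGC(s)
    scr <- correlationScreen(f$gc, f$beh, q = 0.05)
    lonRow <- scr[scr$edge == "AfN->VN" & scr$scale == "Loneliness", ]
    if (lonRow$significant && lonRow$r < 0) hits <- hits + 1L
    nullRows <- scr[scr$scale != "Loneliness", ]
    nullFlags <- nullFlags + sum(nullRows$significant)
    nullTotal <- nullTotal + nrow(nullRows)
  }
  expect_gte(hits, 16L)                       # >= 80% of cohort seeds
  expect_lte(nullFlags / nullTotal, 0.05)     # independent scales stay quiet

  f <- mkGC(1)
  bad <- f$beh; bad$subjectId <- rev(bad$subjectId)
  expect_error(correlationScreen(f$gc, bad), "misaligned")
})
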