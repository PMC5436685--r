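# Conditional Granger causality: VAR fitting, order selection, influence
# terms, surrogate normalization, group tests.

test_that("VAR least squares is exact on noiseless data and null on white noise", {
  A <- matrix(c(0.6, 0.2, -0.1, 0.5), 2, 2, byrow = TRUE)
  set.seed(3)
  X <- matrix(0, 20, 2)
  X[1, ] <- stats::rnorm(2)
  for (t in 2:20) X[t, ] <- A %*% X[t - 1, ]
  fit <- fitVAR(X, 1L)
  expect_lt(max(abs(fit@coefficients[[1]] - A)), 1e-8)

  set.seed(4)
  W <- matrix(stats::rnorm(2000 * 2), 2000, 2)
  fitW <- fitVAR(W, 1L)
  expect_lt(max(abs(fitW@coefficients[[1]])), 0.1)
  expect_equal(fitW@nEffective, 1999L)
})

test_that("VAR coefficients match an explicit normal-equations solve", {
  set.seed(6)
  Y <- matrix(stats::rnorm(12 * 2), 12, 2)
  fit <- fitVAR(Y, 1L)
  # oracle: (X'X)^{-1} X'Y written out directly
  Xd <- cbind(1, Y[1:11, ])
  B <- solve(crossprod(Xd), crossprod(Xd, Y[2:12, ]))
  expect_equal(fit@intercept, unname(B[1, ]), tolerance = 1e-10)
  expect_equal(unname(fit@coefficients[[1]]), unname(t(B[2:3, ])), tolerance = 1e-10)
  res <- Y[2:12, ] - Xd %*% B
  expect_equal(unname(fit@residCov), unname(crossprod(res) / 11), tolerance = 1e-10)
})

test_that("Schwarz criterion recovers the generative order", {
  spec <- defaultCouplingSpec()
  picks <- vapply(1:10, function(s) {
    ts <- simulateNetworkTimecourses(spec, score = 50, nSteps = 250L, seed = s)
    selectOrderSC(ts, maxOrder = 5L)
  }, 0L)
  expect_gte(sum(picks == 1L), 9L)

  # strong lag-2 structure at T = 1000 selects order 2
  A1 <- diag(0.2, 3)
  A2 <- matrix(c(0.45, 0.3, 0, 0, 0.45, 0.3, 0, 0, 0.45), 3, 3, byrow = TRUE)
  picks2 <- vapply(1:10, function(s)
    selectOrderSC(simVARp(list(A1, A2), 1000L, seed = s), maxOrder = 4L), 0L)
  expect_gte(sum(picks2 == 2L), 9L)

  # SC curve matches per-order fits on the common presample, and the
  # returned order is always the first minimizer (small orders win ties)
  for (s in 1:5) {
    set.seed(s)
    w <- matrix(stats::rnorm(300), 100, 3)
    cur <- selectOrderSC(w, maxOrder = 3L, returnCurve = TRUE)
    expect_equal(cur$sc[2], fitVAR(w, 2L, presample = 3L)@sc)
    expect_equal(cur$order, which(cur$sc == min(cur$sc))[1])
  }
})

test_that("conditional influence is nonnegative, null-calibrated and matches a two-regression oracle", {
  set.seed(8)
  X <- matrix(stats::rnorm(2000 * 3), 2000, 3)
  f <- conditionalGC(X, source = 2, target = 1, order = 1L)
  expect_lt(abs(f), 2 * 3 * 1 / 2000)

  # agreement with an independent lm()-based implementation
  for (s in 1:5) {
    ts <- simulateNetworkTimecourses(defaultCouplingSpec(), score = 50,
                                     nSteps = 250L, seed = 100 + s)
    mine <- conditionalGC(ts, "AfN", "VN", order = 1L)
    ref <- referenceCGC(ts, 3, 4, c(1, 2), m = 1L)
    expect_equal(mine, max(ref, 0), tolerance = 1e-10)
    expect_gte(mine, 0)
  }

  expect_error(conditionalGC(X, 1, 1), "disjoint")

  # planted coupling is detected consistently across seeds
  fs <- vapply(1:20, function(s)
    conditionalGC(simulateNetworkTimecourses(defaultCouplingSpec(), score = 50,
                                             nSteps = 250L, seed = s),
                  "AfN", "VN", order = 1L), 0)
  expect_lt(stats::t.test(fs, alternative = "greater")$p.value, 0.01)
})

test_that("conditioning removes mediated influence on a chain", {
  # chain: Z -> Y -> X with no direct Z -> X link
  A <- matrix(0, 3, 3, dimnames = rep(list(c("X", "Y", "Z")), 2))
  diag(A) <- 0.3
  A["Y", "Z"] <- 0.6
  A["X", "Y"] <- 0.6
  ts <- simulateNetworkTimecourses(couplingSpec(A, c("X", "Y", "Z")),
                                   nSteps = 50000L, seed = 12L)
  # order 2 so the lagged Z -> X path is visible to the pairwise model
  fCond <- conditionalGC(ts, "Z", "X", cond = "Y", order = 2L)
  fPair <- conditionalGC(ts, "Z", "X", cond = integer(0), order = 2L)
  expect_gt(fPair, 0.05)
  expect_lt(fCond, 0.1 * fPair)
})

test_that("influence terms are invariant to positive rescaling of any series", {
  ts <- simulateNetworkTimecourses(defaultCouplingSpec(), score = 50,
                                   nSteps = 250L, seed = 33L)
  base <- gcAllPairs(ts, order = 1L)
  for (j in 1:4) {
    tsS <- ts
    tsS[, j] <- ts[, j] * 1000
    expect_lt(max(abs(gcAllPairs(tsS, order = 1L)$F - base$F)), 1e-10)
  }
})

test_that("the asymptotic null distribution of T*F is chi-squared", {
  rej <- 0L
  Tn <- 250L
  for (s in 1:200) {
    set.seed(s)
    X <- matrix(stats::rnorm(Tn * 3), Tn, 3)
    f <- conditionalGC(X, source = 2, target = 1, order = 1L)
    if ((Tn - 1L) * f > stats::qchisq(0.95, df = 1)) rej <- rej + 1L
  }
  expect_gte(rej / 200, 0.025)
  expect_lte(rej / 200, 0.10)
})

test_that("all-pairs output has the contracted shape and ranks planted edges first", {
  ts <- simulateNetworkTimecourses(defaultCouplingSpec(), score = 50,
                                   nSteps = 250L, seed = 2L)
  ap <- gcAllPairs(ts, order = 1L)
  expect_equal(nrow(ap), 12L)
  expect_false(any(ap$source == ap$target))

  Fbar <- 0
  for (s in 1:20) {
    tsS <- simulateNetworkTimecourses(defaultCouplingSpec(), score = 50,
                                      nSteps = 250L, seed = 200 + s)
    Fbar <- Fbar + gcAllPairs(tsS, order = 1L)$F / 20
  }
  planted <- c("DAN->VAN", "DAN->VN", "AfN->VAN", "AfN->VN")
  expect_setequal(ap$label[order(Fbar, decreasing = TRUE)][1:4], planted)
})

test_that("surrogate normalization separates coupled from null edges deterministically", {
  ts <- simulateNetworkTimecourses(defaultCouplingSpec(), score = 50,
                                   nSteps = 250L, seed = 44L)
  strong <- gcNormalize(ts, "AfN", "VN", order = 1L, nSurrogates = 99L, seed = 9L)
  expect_gt(strong$z, 3)

  zs <- vapply(1:20, function(s) {
    set.seed(s)
    X <- matrix(stats::rnorm(250 * 4), 250, 4)
    colnames(X) <- c("a", "b", "c", "d")
    gcNormalize(X, "a", "b", order = 1L, nSurrogates = 49L, seed = s)$z
  }, 0)
  expect_lt(abs(mean(zs)), 0.5)

  again <- gcNormalize(ts, "AfN", "VN", order = 1L, nSurrogates = 99L, seed = 9L)
  expect_identical(strong$z, again$z)
})

test_that("edge-level group tests control the null and detect a single planted edge", {
  # global null: surviving edges stay near or below q * 12 on average
  surv <- numeric(50)
  for (s in 1:50) {
    set.seed(s)
    z <- matrix(stats::rnorm(15 * 12), 15, 12,
                dimnames = list(NULL, paste0("e", 1:12)))
    surv[s] <- sum(groupGCTest(z, q = 0.05)$significant)
  }
  expect_lte(mean(surv), 0.6)

  # one strongly coupled edge among null edges: the planted edge is always
  # detected, and false edges stay rare (the surrogate-normalized null is
  # right-skewed, so an occasional spurious edge is expected)
  A <- matrix(0, 4, 4, dimnames = rep(list(c("a", "b", "c", "d")), 2))
  diag(A) <- 0.3
  A["b", "a"] <- 0.45
  spec <- couplingSpec(A, c("a", "b", "c", "d"))
  detected <- 0L
  extras <- 0L
  for (s in 1:20) {
    tsL <- lapply(1:8, function(i)
      simulateNetworkTimecourses(spec, nSteps = 250L, seed = 1000 * s + i))
    gc <- gcCohort(tsL, groups = rep("all", 8), order = 1L,
                   nSurrogates = 29L, seed = s)
    sig <- groupGCTest(gc, q = 0.05)
    found <- sig$edge[sig$significant]
    detected <- detected + ("a->b" %in% found)
    extras <- extras + length(setdiff(found, "a->b"))
  }
  expect_equal(detected, 20L)
  expect_lte(extras / 20, 1.5)
})
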