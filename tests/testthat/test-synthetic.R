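# Synthetic cohort generator: templates, coupled time courses, subjects,
# preprocessing, cohorts.

test_that("templates are disjoint, nonempty, deterministic, and fail on tiny grids", {
  grid <- voxelGrid(c(20L, 20L, 10L))
  tpl <- makeTemplates(grid, nNetworks = 4L, blobsPerNetwork = 2L,
                       blobRadius = 2, seed = 7L)
  m <- templateMasks(tpl)
  expect_true(all(colSums(m) > 0))
  expect_true(all(rowSums(m) <= 1L))          # pairwise disjoint
  tpl2 <- makeTemplates(grid, nNetworks = 4L, blobsPerNetwork = 2L,
                        blobRadius = 2, seed = 7L)
  expect_identical(m, templateMasks(tpl2))

  # radius-1 sphere on an integer grid holds exactly 7 voxels (interior center)
  one <- makeTemplates(voxelGrid(c(9L, 9L, 9L)), nNetworks = 1L,
                       blobsPerNetwork = 1L, blobRadius = 1, seed = 3L)
  expect_equal(sum(templateMasks(one)), 7L)

  expect_error(makeTemplates(voxelGrid(c(3L, 3L, 1L)), nNetworks = 4L,
                             blobsPerNetwork = 2L, blobRadius = 2, seed = 1L),
               "grid too small")
})

test_that("white-noise coupling has no lag-1 structure", {
  spec <- couplingSpec(matrix(0, 2, 2), c("a", "b"))
  x <- simulateNetworkTimecourses(spec, nSteps = 2000L, seed = 5L)
  Tn <- nrow(x)
  cc <- stats::cor(x[-1, ], x[-Tn, ])
  expect_true(max(abs(cc)) < 0.1)
})

test_that("simulated lag-1 covariance matches the Lyapunov solution", {
  A <- matrix(c(0.3, 0, 0.5, 0.3), 2, 2, byrow = TRUE)  # A[2,1] = 0.5
  spec <- couplingSpec(A, c("x0", "x1"))
  x <- simulateNetworkTimecourses(spec, nSteps = 5000L, seed = 11L)
  Sigma <- var1StationaryCov(A, diag(2))
  lag1True <- A %*% Sigma                     # E[x_t x_{t-1}']
  Tn <- nrow(x)
  lag1Emp <- crossprod(x[-1, , drop = FALSE], x[-Tn, , drop = FALSE]) / (Tn - 1)
  expect_lt(abs(lag1Emp[2, 1] - lag1True[2, 1]) / abs(lag1True[2, 1]), 0.10)
  # and the contemporaneous covariance agrees too
  expect_lt(max(abs(stats::cov(x) - Sigma)) / max(Sigma), 0.10)
})

test_that("score modulation is monotone, clamps, and rejects non-stationary specs", {
  spec <- defaultCouplingSpec()
  A70 <- effectiveCoupling(spec, 70)
  A20 <- effectiveCoupling(spec, 20)
  expect_lt(A70["VN", "AfN"], A20["VN", "AfN"])
  expect_lt(A70["VAN", "DAN"], A20["VAN", "DAN"])
  expect_equal(A20["VN", "AfN"], 0.9)         # saturates at the clamp
  # scores within the high group move the edge linearly (R^2 = 1)
  sc <- 46:65
  vals <- vapply(sc, function(s) effectiveCoupling(spec, s)["VN", "AfN"], 0)
  expect_gt(stats::cor(vals, sc)^2, 0.99)
  fit <- stats::lm(vals ~ sc)
  expect_equal(unname(stats::coef(fit)[2]), -0.025, tolerance = 1e-12)

  wild <- couplingSpec(matrix(0.5, 1, 1), "a",
                       modulatedEdges = data.frame(source = "a", target = "a",
                                                   slope = 0.1),
                       scoreRef = 0, clampRange = c(0, 5))
  expect_error(simulateNetworkTimecourses(wild, score = 10, nSteps = 10L),
               "non-stationary")
})

test_that("generated time courses stay bounded at 10x the default length", {
  spec <- defaultCouplingSpec()
  for (score in c(20, 47, 65)) {
    x <- simulateNetworkTimecourses(spec, score = score, nSteps = 2500L,
                                    seed = score)
    expect_lt(max(abs(x)), 50)
  }
})

test_that("noiseless subjects recover the true spatial loadings by regression", {
  cfg <- tinyConfig(snr = Inf, nNuisance = 0L)
  scores <- c(Loneliness = 50, STAI = 40, SDS = 40, IRI_C = 50, Trust = 70, SSRS = 40)
  ds <- simulateSubject(cfg, scores, "high", "s1", seed = 9L)
  S <- simulateNetworkTimecourses(cfg@coupling, score = 50,
                                  nSteps = cfg@nVolumesRaw,
                                  seed = deriveSeed(9L, "timecourses"))
  Mhat <- solve(crossprod(S), crossprod(S, ds@data))
  Mtrue <- rsnflow:::.cohortLoadings(cfg)
  expect_lt(max(abs(Mhat - Mtrue)), 1e-8)
})

test_that("subject simulation is deterministic and honors the volume count", {
  cfg <- tinyConfig(nVolumesRaw = 255L)
  scores <- c(Loneliness = 50, STAI = 40, SDS = 40, IRI_C = 50, Trust = 70, SSRS = 40)
  a <- simulateSubject(cfg, scores, "high", "s1", seed = 4L)
  b <- simulateSubject(cfg, scores, "high", "s1", seed = 4L)
  expect_identical(a@data, b@data)
  expect_equal(nVolumes(a), 255L)
  expect_error(simulateSubject(cfg, scores, "low", "s1", seed = 4L),
               "inconsistent")
})

test_that("initial-volume discard follows the steady-state convention", {
  cfg <- tinyConfig(nVolumesRaw = 255L)
  scores <- c(Loneliness = 20, STAI = 40, SDS = 40, IRI_C = 50, Trust = 70, SSRS = 40)
  ds <- simulateSubject(cfg, scores, "low", "s1", seed = 2L)
  expect_equal(nVolumes(discardInitialVolumes(ds, 5L)), 250L)
  expect_identical(discardInitialVolumes(ds, 0L), ds)
  short <- discardInitialVolumes(ds, 245L)
  expect_error(discardInitialVolumes(short, 10L), "cannot discard")
})

test_that("spatial smoothing matches dense reflective convolution and conserves mass", {
  grid <- voxelGrid(c(5L, 5L, 5L))
  set.seed(31)
  vol <- stats::rnorm(125)
  ds <- new("SubjectDataset", data = matrix(vol, 1L), tr = 2,
            behavioral = c(Loneliness = 50, STAI = 40, SDS = 40, IRI_C = 50,
                           Trust = 70, SSRS = 40),
            group = "high", subjectId = "s", seed = 1L)
  sm <- smoothSpatial(ds, grid, fwhmMm = 8)

  # brute-force oracle: direct dense convolution with reflected indexing
  sigma <- 8 / (2 * sqrt(2 * log(2))) / 3
  r <- max(1L, ceiling(4 * sigma))
  w <- stats::dnorm(-r:r, sd = sigma); w <- w / sum(w)
  reflect <- function(j, n) {
    j <- (j - 1L) %% (2L * n)
    ifelse(j < n, j + 1L, 2L * n - j)
  }
  arr <- array(vol, c(5, 5, 5))
  for (ax in 1:3) {
    out <- array(0, dim(arr))
    for (i in 1:5) for (j in 1:5) for (k in 1:5) {
      idx <- c(i, j, k)
      acc <- 0
      for (o in -r:r) {
        src <- idx
        src[ax] <- reflect(idx[ax] + o, 5L)
        acc <- acc + w[o + r + 1] * arr[src[1], src[2], src[3]]
      }
      out[i, j, k] <- acc
    }
    arr <- out
  }
  expect_equal(as.numeric(sm@data[1, ]), as.numeric(arr), tolerance = 1e-12)
  expect_lt(abs(sum(sm@data) - sum(vol)) / abs(sum(vol)), 1e-6)

  # identity and impulse behavior
  expect_identical(smoothSpatial(ds, grid, 0)@data, ds@data)
  imp <- ds
  imp@data <- matrix(0, 1L, 125L)
  ctr <- 63L                                  # (3,3,3) is the grid center
  imp@data[1, ctr] <- 1
  smi <- smoothSpatial(imp, grid, 8)
  expect_equal(which.max(smi@data[1, ]), ctr)
  a3 <- array(smi@data[1, ], c(5, 5, 5))
  expect_equal(a3[2, 3, 3], a3[4, 3, 3])      # symmetric decay
  expect_error(smoothSpatial(ds, grid, -1), "nonnegative")
})

test_that("cohorts honor group sizes, score thresholds, and the planted linkage", {
  cfg <- tinyConfig(nHigh = 5L, nLow = 5L, nVolumesRaw = 20L, seed = 21L)
  co <- simulateCohort(cfg)
  beh <- behavioralScores(co)
  expect_equal(sum(beh$group == "high"), 5L)
  expect_equal(sum(beh$group == "low"), 5L)
  expect_true(all(beh$Loneliness[beh$group == "high"] > 45))
  expect_true(all(beh$Loneliness[beh$group == "low"] < 28))

  co2 <- simulateCohort(cfg)
  expect_identical(subjects(co)[[1]]@data, subjects(co2)[[1]]@data)
  expect_identical(beh, behavioralScores(co2))

  # planted monotone linkage: loneliness vs the true AfN->VN coupling
  afnvn <- vapply(co@couplingTruth, function(A) A["VN", "AfN"], 0)
  expect_lt(stats::cor(beh$Loneliness, afnvn), 0)
})
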