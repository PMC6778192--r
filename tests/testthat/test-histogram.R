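test_that("Gaussian smoothing respects identity, uniformity and mass", {
  set.seed(2)
  vals <- matrix(runif(400), 20, 20)
  valid <- matrix(TRUE, 20, 20); valid[1:3, 1:3] <- FALSE
  v2 <- vals; v2[!valid] <- NA
  map <- new("RedoxMap", values = v2, valid = valid, meta = list())
  expect_identical(smoothRedoxMap(map, 0), map)       # sigma 0: exact identity
  expect_identical(validMask(smoothRedoxMap(map, 2)), valid)
  uni <- new("RedoxMap", values = matrix(0.4, 9, 9),
             valid = matrix(TRUE, 9, 9), meta = list())
  for (sg in c(0.5, 1, 3))
    expect_equal(redoxValues(smoothRedoxMap(uni, sg)),
                 redoxValues(uni))                    # uniform maps unchanged
  # single bright pixel, all-valid interior: mass conserved (kernel sums 1)
  spike <- matrix(0, 21, 21); spike[11, 11] <- 1
  mp <- new("RedoxMap", values = spike, valid = matrix(TRUE, 21, 21),
            meta = list())
  sm <- smoothRedoxMap(mp, 1)
  expect_equal(sum(redoxValues(sm)), 1, tolerance = 1e-6)
})

test_that("smoothing excludes invalid pixels from the kernel support", {
  vals <- matrix(0.2, 7, 7)
  valid <- matrix(TRUE, 7, 7)
  vals[4, 4] <- NA; valid[4, 4] <- FALSE  # an (excluded) silk pixel
  map <- new("RedoxMap", values = vals, valid = valid, meta = list())
  sm <- smoothRedoxMap(map, 1)
  # neighbours keep 0.2 exactly: the masked pixel contributes nothing
  expect_equal(redoxValues(sm)[valid], rep(0.2, sum(valid)))
})

test_that("the 50-bin histogram places values per the edge convention", {
  h <- makeRedoxHistogram(rep(0.5, 10))
  expect_equal(sum(h@density), 1)
  expect_equal(h@density[26], 1)        # 0.5 falls in bin 26 ([0.5, 0.52))
  h1 <- makeRedoxHistogram(c(1.0, 0.999, 0))
  expect_equal(h1@density[50], 2 / 3)   # closed last bin catches 1.0
  expect_equal(h1@density[1], 1 / 3)
  expect_error(makeRedoxHistogram(numeric(0)), "no valid")
  expect_error(makeRedoxHistogram(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("uniform pixels bin to approximately equal densities", {
  set.seed(11)
  h <- makeRedoxHistogram(runif(1e5))
  tol <- 5 * sqrt(0.02 * 0.98 / 1e5)
  expect_true(all(abs(h@density - 0.02) < tol))
})

test_that("a single-Gaussian truth is recovered by the basis fit", {
  set.seed(21)
  v <- pmin(1, pmax(0, rnorm(5e4, 0.5, 0.05)))
  b <- fitBasis(makeRedoxHistogram(v), K = 1, seed = 2)
  expect_equal(componentMeans(b), 0.5, tolerance = 0.005 / 0.5)
  expect_equal(componentSds(b), 0.05, tolerance = 0.10)
})

test_that("two well-separated components are recovered with their weights", {
  set.seed(22)
  v <- c(rnorm(3e4, 0.25, 0.05), rnorm(2e4, 0.75, 0.05))
  h <- makeRedoxHistogram(pmin(1, pmax(0, v)))
  b <- fitBasis(h, K = 2, seed = 5)
  expect_lt(max(abs(componentMeans(b) - c(0.25, 0.75))), 0.02)
  expect_lt(max(abs(componentSds(b) / 0.05 - 1)), 0.20)
  w <- fitWeights(h, b)
  expect_equal(sum(w), 100, tolerance = 1e-6)
  expect_lt(max(abs(w - c(60, 40))), 3)
  # determinism and label order
  expect_identical(b, fitBasis(h, K = 2, seed = 5))
  expect_false(is.unsorted(componentMeans(b)))
})

test_that("basis means agree with an independent raw-sample mixture fit", {
  skip_if_not_installed("mclust")
  suppressMessages(library(mclust))  # Mclust needs its namespace attached
  set.seed(23)
  v <- pmin(1, pmax(0, c(rnorm(2e4, 0.3, 0.06), rnorm(2e4, 0.7, 0.06))))
  b <- fitBasis(makeRedoxHistogram(v), K = 2, seed = 7)
  mc <- mclust::Mclust(v, G = 2, modelNames = "V", verbose = FALSE)
  expect_equal(componentMeans(b), sort(unname(mc$parameters$mean)),
               tolerance = 0.02)
})

test_that("frozen-basis weights match a grid-search likelihood maximizer", {
  set.seed(24)
  basis <- new("GaussianBasis", means = c(0.3, 0.7), sds = c(0.06, 0.06),
               nIterations = 1, seeds = 1)
  v <- c(rnorm(2e4, 0.3, 0.06), rnorm(3e4, 0.7, 0.06))
  h <- makeRedoxHistogram(pmin(1, pmax(0, v)))
  w <- fitWeights(h, basis)
  centers <- (h@edges[-1] + h@edges[-51]) / 2
  ll <- function(p1)
    sum(h@density * log(p1 * dnorm(centers, 0.3, 0.06) +
                        (1 - p1) * dnorm(centers, 0.7, 0.06)))
  grid <- seq(0.001, 0.999, by = 1e-4)
  p1hat <- grid[which.max(vapply(grid, ll, numeric(1)))]
  expect_lt(abs(w[["Component1"]] - 100 * p1hat), 0.5)
})

test_that("weights degenerate and hand-computed ratio cases hold", {
  basis1 <- new("GaussianBasis", means = 0.5, sds = 0.05,
                nIterations = 1, seeds = 1)
  w1 <- fitWeights(makeRedoxHistogram(runif(100)), basis1)
  expect_identical(unname(w1), 100)        # K = 1: exactly 100
  # histogram generated purely from component 1 of a 2-component basis
  set.seed(25)
  basis <- new("GaussianBasis", means = c(0.25, 0.75), sds = c(0.05, 0.05),
               nIterations = 1, seeds = 1)
  pure <- makeRedoxHistogram(pmin(1, pmax(0, rnorm(2e4, 0.25, 0.05))))
  expect_gte(fitWeights(pure, basis)[["Component1"]], 99)
  expect_equal(unname(weightRatios(c(25, 25, 25, 25))), rep(1 / 3, 4))
  r <- weightRatios(c(100, 0, 0, 0))
  expect_identical(unname(r), c(Inf, 0, 0, 0))
  r2 <- weightRatios(c(40, 30, 20, 10))
  expect_equal(unname(r2), c(40 / 60, 30 / 70, 20 / 80, 10 / 90))
  expect_error(weightRatios(c(50, 40)), "sum to 100")
})
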