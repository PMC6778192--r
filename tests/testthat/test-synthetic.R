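test_that("scene generation honors degenerate mixtures and is deterministic", {
  sc <- makeScene(uniformScene(seed = 3, mean_redox = 0.5, sd_redox = 0))
  expect_true(all(sc@trueRedox[sc@labels > 0] == 0.5))
  sc2 <- makeScene(uniformScene(seed = 3, mean_redox = 0.5, sd_redox = 0))
  expect_identical(sc, sc2)
  # different seed gives a different draw when sd > 0
  a <- makeScene(uniformScene(seed = 1, sd_redox = 0.05))
  b <- makeScene(uniformScene(seed = 2, sd_redox = 0.05))
  expect_false(identical(a@trueRedox, b@trueRedox))
})

test_that("per-population empirical redox means obey the law of large numbers", {
  n <- 128L  # 16384 pixels per population half
  p1 <- populationSpec("lo", data.frame(mean = 0.25, sd = 0.05, weight = 1), 100)
  p2 <- populationSpec("hi", data.frame(mean = 0.75, sd = 0.05, weight = 1), 100)
  spec <- sceneSpec(n, n, populations = list(
    list(spec = p1, footprint = rectFootprint(0, 0, n / 2, n)),
    list(spec = p2, footprint = rectFootprint(n / 2, 0, n / 2, n))),
    silk = NULL, noise = FALSE, seed = 42)
  sc <- makeScene(spec)
  npx <- n * n / 2
  tol <- 3 * 0.05 / sqrt(npx)
  expect_lt(abs(mean(sc@trueRedox[sc@labels == 1L]) - 0.25), tol)
  expect_lt(abs(mean(sc@trueRedox[sc@labels == 2L]) - 0.75), tol)
  expect_lt(sc@clipFraction, 1e-4)  # means far from [0, 1] edges
})

test_that("overlapping population footprints raise an error naming the pair", {
  p <- function(nm) populationSpec(nm, data.frame(mean = .5, sd = 0, weight = 1), 50)
  spec <- sceneSpec(16, 16, populations = list(
    list(spec = p("alpha"), footprint = rectFootprint(0, 0, 10, 10)),
    list(spec = p("beta"), footprint = rectFootprint(5, 5, 10, 10))),
    silk = NULL, noise = FALSE, seed = 1)
  expect_error(makeScene(spec), "alpha.*beta|overlap")
})

test_that("footprints outside the image bounds are rejected", {
  p <- populationSpec("a", data.frame(mean = .5, sd = 0, weight = 1), 50)
  spec <- sceneSpec(16, 16, populations = list(
    list(spec = p, footprint = rectFootprint(10, 10, 10, 10))),
    silk = NULL, noise = FALSE, seed = 1)
  expect_error(makeScene(spec), "bounds")
})

test_that("rendering inverts the redox definition and conserves intensity", {
  sc <- makeScene(texturedScene(seed = 5, noise = FALSE))
  acq <- acquisitionSpec(power_nadh = 1, power_fad = 1)
  f <- renderChannels(sc, acq)
  cell <- sc@labels > 0
  # conservation: NADH + FAD == total expected intensity (unit scaling)
  expect_equal(nadh(f)[cell] + fad(f)[cell], sc@totalIntensity[cell])
  # ratio returns true redox exactly at zero shift, noise off
  r <- fad(f)[cell] / (fad(f)[cell] + nadh(f)[cell])
  expect_equal(r, sc@trueRedox[cell])
  # r = 1 gives a dark NADH channel
  sc1 <- makeScene(uniformScene(seed = 2, mean_redox = 1, sd_redox = 0))
  f1 <- renderChannels(sc1, acq)
  expect_true(all(nadh(f1) == 0))
})

test_that("expected counts scale with the square of excitation power", {
  sc <- makeScene(uniformScene(seed = 9, mean_redox = 0.4))
  f1 <- renderChannels(sc, acquisitionSpec(power_fad = 1, power_nadh = 1))
  f2 <- renderChannels(sc, acquisitionSpec(power_fad = 2, power_nadh = 1))
  expect_equal(fad(f2), 4 * fad(f1))
  expect_equal(nadh(f2), nadh(f1))
})

test_that("Poisson noise gives variance approximately equal to the mean", {
  sc <- makeScene(uniformScene(seed = 7, mean_redox = 0.5, sd_redox = 0,
                               size = 128L, noise = TRUE, intensity = 100))
  f <- renderChannels(sc, acquisitionSpec(power_nadh = 1, power_fad = 1))
  x <- as.vector(nadh(f))  # 16384 i.i.d. Poisson(50) draws
  expect_equal(mean(x), 50, tolerance = 0.02)
  expect_equal(var(x), 50, tolerance = 0.08)
})

test_that("renders are reproducible bit-exactly under a fixed seed", {
  sc <- makeScene(texturedScene(seed = 11, noise = TRUE))
  acq <- acquisitionSpec(n_time_bins = 64L)
  expect_identical(renderChannels(sc, acq), renderChannels(sc, acq))
  expect_identical(renderDecays(sc, acq), renderDecays(sc, acq))
  expect_false(identical(renderChannels(sc, acq, seed = 1),
                         renderChannels(sc, acq, seed = 2)))
})

test_that("a lifetime much shorter than the bin width puts all counts first", {
  st <- monoExpStack(tau = 1e-3, n_bins = 16L)
  tot <- apply(decayCounts(st), c(1, 2), sum)
  expect_equal(decayCounts(st)[, , 1], tot, tolerance = 1e-12)
})

test_that("singleton cohorts are valid and cohorts record ground truth", {
  des <- cohortDesign(conditions = list(only = uniformCondition(0.5)),
                      n_samples = 2, fields_per_sample = 1,
                      width = 16, height = 16, field_sd = 0)
  co <- makeCohort(des, seed = 1)
  expect_length(co$entries, 2L)
  expect_equal(nrow(co$truth), 2L)
  expect_true(all(co$truth$true_mean_redox == 0.5))
  expect_error(cohortDesign(conditions = list(only = uniformCondition(0.5)),
                            n_samples = 1), "n_samples")
})

test_that("condition ordering in truth propagates to recovered field means", {
  des <- cohortDesign(
    conditions = list(A = uniformCondition(0.55), B = uniformCondition(0.45)),
    n_samples = 3, fields_per_sample = 4, width = 24, height = 24,
    field_sd = 0.02)
  ok <- vapply(1:10, function(s) {
    an <- analyzeCohort(makeCohort(des, seed = s))
    m <- tapply(an$samples$sample_mean, an$samples$condition, mean)
    m[["A"]] > m[["B"]]
  }, logical(1))
  expect_gte(sum(ok), 9L)  # 0.10 effect vs 0.02 field noise: near-certain
})
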