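test_that("normalization divides by power^exponent * gain and inverts", {
  sc <- makeScene(texturedScene(seed = 1))
  # powers = gains = 1: identity
  f1 <- renderChannels(sc, acquisitionSpec(power_nadh = 1, power_fad = 1))
  n1 <- normalizeField(f1)
  expect_equal(nadh(n1), nadh(f1))
  # gain 2, power 1, exponent 2: halved
  f2 <- renderChannels(sc, acquisitionSpec(power_nadh = 1, power_fad = 1,
                                           gain_nadh = 2, gain_fad = 2))
  n2 <- normalizeField(f2)
  expect_equal(nadh(n2), nadh(f2) / 2)
  # invertibility: raw = normalized * divisor
  f3 <- renderChannels(sc, acquisitionSpec(power_nadh = 17, gain_fad = 3.5))
  n3 <- normalizeField(f3)
  expect_equal(nadh(n3) * n3@divisors[["nadh"]], nadh(f3))
  expect_equal(fad(n3) * n3@divisors[["fad"]], fad(f3))
  expect_error(normalizeField(n3), "already normalized")
})

test_that("raw fields acquired at different powers normalize to equal images", {
  sc <- makeScene(texturedScene(seed = 13, noise = FALSE))
  fa <- renderChannels(sc, acquisitionSpec(power_fad = 1))
  fb <- renderChannels(sc, acquisitionSpec(power_fad = 2))
  expect_equal(fad(normalizeField(fa)), fad(normalizeField(fb)))
})

test_that("applyShift is a pure translation with a validity mask", {
  m <- matrix(1:12, 3, 4)
  id <- applyShift(m, c(0, 0))
  expect_equal(id$image, m)
  expect_true(all(id$valid))
  # involution on the joint-valid region
  sh <- applyShift(m, c(2, -1))
  back <- applyShift(sh$image, c(-2, 1))
  jv <- back$valid & !is.na(back$image)
  expect_equal(back$image[jv], m[jv])
  # shifting past the frame invalidates everything
  gone <- applyShift(m, c(ncol(m) + 1, 0))
  expect_false(any(gone$valid))
  expect_error(applyShift(m, c(0.5, 0)), "integer")
})

test_that("registration recovers the inverse of the applied shift", {
  # proportional channels: correlation at the optimum is exactly 1
  sc0 <- makeScene(proportionalScene(seed = 21, shift = c(0L, 0L)))
  f0 <- renderChannels(sc0, acquisitionSpec(power_nadh = 1, power_fad = 1))
  r0 <- registerChannels(nadh(f0), fad(f0), max_shift = 4)
  expect_identical(r0@shift, c(0L, 0L))
  expect_equal(r0@score, 1.0)
  sc <- makeScene(proportionalScene(seed = 21, shift = c(3L, -2L)))
  f <- renderChannels(sc, acquisitionSpec(power_nadh = 1, power_fad = 1))
  r <- registerChannels(nadh(f), fad(f), max_shift = 6)
  expect_identical(r@shift, c(-3L, 2L))
  expect_gte(r@score, 0.999)
})

test_that("a zero-variance overlap scores 0 and returns the zero shift", {
  flat <- matrix(5, 16, 16)
  r <- registerChannels(flat, matrix(runif(256), 16, 16), max_shift = 3)
  expect_identical(r@shift, c(0L, 0L))
  expect_equal(r@score, 0)
})

test_that("registration is antisymmetric on noise-free pairs", {
  sc <- makeScene(texturedScene(seed = 31, shift = c(4L, 1L)))
  f <- renderChannels(sc, acquisitionSpec())
  ab <- registerChannels(nadh(f), fad(f), max_shift = 6)
  ba <- registerChannels(fad(f), nadh(f), max_shift = 6)
  expect_identical(ab@shift, -ba@shift)
})

test_that("shift recovery is exact across random noise-free fields", {
  set.seed(99)
  shifts <- matrix(sample(-10:10, 2 * 20, replace = TRUE), ncol = 2)
  hits <- vapply(seq_len(nrow(shifts)), function(i) {
    sc <- makeScene(texturedScene(seed = 500 + i, shift = shifts[i, ]))
    f <- renderChannels(sc, acquisitionSpec())
    r <- registerChannels(nadh(f), fad(f), max_shift = 10)
    identical(r@shift, as.integer(-shifts[i, ]))
  }, logical(1))
  expect_equal(sum(hits), 20L)
})

test_that("normalization commutes with registration", {
  sc <- makeScene(texturedScene(seed = 41, shift = c(-5L, 3L)))
  f <- renderChannels(sc, acquisitionSpec(power_nadh = 15, power_fad = 25,
                                          gain_nadh = 2, gain_fad = 0.5))
  rRaw <- registerChannels(nadh(f), fad(f), max_shift = 7)
  nf <- normalizeField(f)
  rNorm <- registerChannels(nadh(nf), fad(nf), max_shift = 7)
  expect_identical(rRaw@shift, rNorm@shift)
  # same final field either order
  alignedThenNorm <- applyShift(fad(f), rRaw@shift)$image /
    nf@divisors[["fad"]]
  normThenAligned <- applyShift(fad(nf), rNorm@shift)$image
  jv <- !is.na(alignedThenNorm)
  expect_equal(alignedThenNorm[jv], normThenAligned[jv])
})

test_that("an overlap below the minimum pixel count is an error", {
  m <- matrix(runif(64), 8, 8)
  expect_error(registerChannels(m, m, max_shift = 7, min_overlap = 65),
               "overlap")
})
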