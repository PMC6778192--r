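test_that("a delta-like decay maps to the (1, 0) corner of phasor space", {
  st <- monoExpStack(tau = 1e-3, n_bins = 512L)
  ph <- phasorTransform(st)
  expect_equal(ph@g[1, 1], 1, tolerance = 1e-2)
  expect_equal(ph@s[1, 1], 0, tolerance = 1e-2)
})

test_that("phasors of mono-exponentials match the closed form", {
  omega <- 2 * pi * 0.080
  for (tau in c(0.4, 1 / omega, 1.0, 2.8)) {
    st <- monoExpStack(tau, n_bins = 512L)
    ph <- phasorTransform(st)
    cf <- phasorClosedForm(tau, omega)
    expect_equal(ph@g[1, 1], unname(cf["g"]), tolerance = 1e-2)
    expect_equal(ph@s[1, 1], unname(cf["s"]), tolerance = 1e-2)
  }
  # omega * tau = 1 sits at the top of the semicircle: (0.5, 0.5)
  st <- monoExpStack(1 / omega, n_bins = 512L)
  ph <- phasorTransform(st)
  expect_equal(ph@g[1, 1], 0.5, tolerance = 5e-3)
  expect_equal(ph@s[1, 1], 0.5, tolerance = 5e-3)
})

test_that("the phasor transform is linear under count-weighted decay mixing", {
  set.seed(5)
  nt <- 128L
  mk <- function(tau, amp) {
    e <- seq(0, 12.5, length.out = nt + 1)
    amp * (exp(-e[-(nt + 1)] / tau) - exp(-e[-1] / tau))
  }
  for (i in 1:5) {
    d1 <- mk(runif(1, 0.3, 3), runif(1, 50, 500))
    d2 <- mk(runif(1, 0.3, 3), runif(1, 50, 500))
    counts <- array(0, c(1, 3, nt))
    counts[1, 1, ] <- d1; counts[1, 2, ] <- d2; counts[1, 3, ] <- d1 + d2
    st <- new("DecayStack", counts = counts, binWidthNs = 12.5 / nt,
              t0OffsetNs = 0)
    ph <- phasorTransform(st)
    w <- c(sum(d1), sum(d2))
    expect_equal(ph@g[1, 3], sum(w * ph@g[1, 1:2]) / sum(w), tolerance = 1e-12)
    expect_equal(ph@s[1, 3], sum(w * ph@s[1, 1:2]) / sum(w), tolerance = 1e-12)
  }
})

test_that("semicircle deviation shrinks monotonically with bin count", {
  dev <- vapply(c(64L, 256L, 1024L), function(nb) {
    ph <- phasorTransform(monoExpStack(1.0, n_bins = nb))
    abs((ph@g[1, 1] - 0.5)^2 + ph@s[1, 1]^2 - 0.25)
  }, numeric(1))
  expect_true(all(diff(dev) < 0))
  expect_lt(dev[3], 1e-5)
})

test_that("zero-count pixels are undefined, not NaN-propagating", {
  counts <- array(0, c(2, 2, 32))
  counts[1, 1, ] <- 10
  st <- new("DecayStack", counts = counts, binWidthNs = 12.5 / 32)
  ph <- phasorTransform(st, min_counts = 1)
  expect_true(ph@defined[1, 1])
  expect_false(any(ph@defined[-1]))
  tau <- apparentLifetime(ph)
  expect_false(is.na(tau[1, 1]))
  expect_true(all(is.na(tau[-1])))
})

test_that("apparent lifetime is s / (omega g) and recovers generating tau", {
  ph <- new("PhasorField", g = matrix(0.5), s = matrix(0.5),
            defined = matrix(TRUE), omega = 0.5, totalCounts = matrix(100))
  expect_equal(apparentLifetime(ph)[1, 1], 2.0)
  ph0 <- new("PhasorField", g = matrix(1), s = matrix(0),
             defined = matrix(TRUE), omega = 0.5, totalCounts = matrix(100))
  expect_equal(apparentLifetime(ph0)[1, 1], 0)
  # synthetic silk at 2.8 ns, first harmonic of 80 MHz: within 2%
  st <- monoExpStack(2.8, n_bins = 512L)
  tau <- apparentLifetime(phasorTransform(st))
  expect_equal(tau[1, 1], 2.8, tolerance = 0.02)
})

test_that("silk filter removes silk, keeps cells, and is monotone in cutoff", {
  taus <- matrix(1.0, 4, 4)
  none <- silkFilter(taus, 2.0)
  expect_true(all(validMask(none)))
  expect_equal(none@fractionRemoved, 0)
  all_gone <- silkFilter(taus, 0.5)
  expect_false(any(validMask(all_gone)))
  expect_equal(all_gone@fractionRemoved, 1)
  # scene-level fidelity, noiseless
  sc <- makeScene(texturedScene(seed = 17))
  st <- renderDecays(sc, acquisitionSpec(n_time_bins = 256L))
  tau <- apparentLifetime(phasorTransform(st))
  sf <- silkFilter(tau, 2.0)
  expect_gte(mean(!validMask(sf)[sc@silkMask]), 0.99)
  expect_lte(mean(!validMask(sf)[sc@labels > 0]), 0.01)
  # monotone: raising the cutoff never removes more pixels
  set.seed(3)
  taus2 <- matrix(runif(400, 0.2, 4), 20, 20)
  cuts <- c(0.5, 1, 2, 3)
  removed <- vapply(cuts, function(ct) sum(!validMask(silkFilter(taus2, ct))),
                    numeric(1))
  expect_true(all(diff(removed) <= 0))
})
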