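# Separable convolution with zero padding; k is an odd-length 1-D kernel.
.convSep <- function(m, k) {
  R <- (length(k) - 1L) %/% 2L
  h <- nrow(m); w <- ncol(m)
  tmp <- matrix(0, h, w)
  for (o in -R:R) {  # columns
    c0 <- max(1L, 1L + o); c1 <- min(w, w + o)
    if (c0 <= c1)
      tmp[, c0:c1] <- tmp[, c0:c1] + k[o + R + 1L] * m[, (c0:c1) - o]
  }
  out <- matrix(0, h, w)
  for (o in -R:R) {  # rows
    r0 <- max(1L, 1L + o); r1 <- min(h, h + o)
    if (r0 <= r1)
      out[r0:r1, ] <- out[r0:r1, ] + k[o + R + 1L] * tmp[(r0:r1) - o, ]
  }
  out
}

#' Gaussian low-pass filter of a redox map
#'
#' Spatial Gaussian smoothing applied to the redox map before histogramming,
#' respecting the validity mask: invalid pixels (silk, background) are
#' excluded from the kernel support by normalized convolution, i.e. the
#' filtered value is the Gaussian-weighted mean of the *valid* neighbours
#' only, so masked regions neither bleed in nor shift cell values. The valid
#' mask itself is unchanged. `sigma_px = 0` returns the input exactly.
#'
#' @param map a [RedoxMap-class].
#' @param sigma_px Gaussian sigma in pixels (default 1; kernel truncated at
#'   4 sigma).
#' @return a smoothed [RedoxMap-class].
#' @export
smoothRedoxMap <- function(map, sigma_px = 1) {
  stopifnot(is(map, "RedoxMap"))
  if (sigma_px < 0) stop("sigma_px must be >= 0")
  if (sigma_px == 0) return(map)
  R <- as.integer(ceiling(4 * sigma_px))
  k <- stats::dnorm(-R:R, 0, sigma_px)
  k <- k / sum(k)
  vm <- map@valid * 1
  vals <- map@values
  vals[!map@valid] <- 0
  num <- .convSep(vals, k)
  den <- .convSep(vm, k)
  out <- map@values
  out[map@valid] <- pmin(1, pmax(0, num[map@valid] / den[map@valid]))
  initialize(map, values = out)
}

#' Bin a redox map into the standard 50-bin histogram
#'
#' Valid redox values are binned into 50 equal bins between 0 and 1. Bins
#' are half-open `[a, b)` except the last, which is closed so a ratio of
#' exactly 1.0 is counted in bin 50 rather than falling out of range.
#'
#' @param x a [RedoxMap-class], or a numeric vector of redox values in
#'   \[0, 1\].
#' @param meta metadata list carried onto the histogram (defaults to the
#'   map's metadata).
#' @return a [RedoxHistogram-class].
#' @export
makeRedoxHistogram <- function(x, meta = NULL) {
  if (is(x, "RedoxMap")) {
    if (is.null(meta)) meta <- x@meta
    x <- x@values[x@valid]
  }
  x <- x[!is.na(x)]
  if (!length(x)) stop("no valid pixels to bin")
  if (min(x) < 0 || max(x) > 1) stop("redox values must lie in [0, 1]")
  nb <- 50L
  idx <- pmin(floor(x * nb) + 1L, nb)  # closed last bin
  counts <- tabulate(idx, nbins = nb)
  new("RedoxHistogram", edges = seq(0, 1, length.out = nb + 1L),
      density = counts / length(x), nPixels = as.numeric(length(x)),
      meta = if (is.null(meta)) list() else meta)
}

.binCenters <- function(hist) (hist@edges[-1L] + hist@edges[-length(hist@edges)]) / 2

# Pool histograms (weighted by pixel count) into per-bin counts.
.pooledCounts <- function(histograms) {
  if (is(histograms, "RedoxHistogram")) histograms <- list(histograms)
  ref <- histograms[[1]]@edges
  counts <- 0
  for (h in histograms) {
    stopifnot(is(h, "RedoxHistogram"))
    if (!isTRUE(all.equal(h@edges, ref)))
      stop("histograms must share the same bin edges")
    counts <- counts + h@density * h@nPixels
  }
  counts
}

# Weighted univariate Gaussian-mixture EM on binned data. Returns list
# (means, sds, props, loglik, iterations) or NULL on degeneracy.
.emMixture <- function(centers, weights, mu, sigma, prop,
                       sd_floor = 1e-4, max_iter = 1000L, tol = 1e-10) {
  W <- sum(weights)
  K <- length(mu)
  ll0 <- -Inf
  for (it in seq_len(max_iter)) {
    dens <- vapply(seq_len(K),
                   function(k) prop[k] * stats::dnorm(centers, mu[k], sigma[k]),
                   numeric(length(centers)))
    rowsum <- rowSums(dens)
    dead <- rowsum <= 0 & weights > 0
    if (any(dead)) {
      # far-tail bins: assign to the nearest component to keep EM finite
      nearest <- vapply(centers[dead], function(c0) which.min(abs(mu - c0)), 1L)
      dens[cbind(which(dead), nearest)] <- 1
      rowsum <- rowSums(dens)
    }
    resp <- dens / rowsum
    Nk <- colSums(weights * resp)
    if (any(Nk < W * 1e-10)) return(NULL)
    mu <- colSums(weights * resp * centers) / Nk
    sigma <- sqrt(colSums(weights * resp * outer(centers, mu, "-")^2) / Nk)
    if (any(sigma < sd_floor)) return(NULL)
    prop <- Nk / W
    ll <- sum(weights[rowsum > 0] * log(rowsum[rowsum > 0]))
    if (is.finite(ll0) && abs(ll - ll0) < tol * (abs(ll) + 1)) break
    ll0 <- ll
  }
  list(means = mu, sds = sigma, props = prop, loglik = ll, iterations = it)
}

#' Fit the shared Gaussian component basis to pooled histograms
#'
#' Images from all groups are compiled into one aggregate histogram and
#' decomposed into `K` Gaussian components by expectation-maximization on
#' the bin-center-weighted samples — the fit is a function of the histogram
#' alone. The EM is run from `n_iter` independent random initializations;
#' each run's components are sorted by ascending mean, and the returned
#' basis is the element-wise average of the sorted means and SDs across
#' runs. A degenerate run (vanishing component or collapsing SD) is
#' restarted from a fresh sub-seed; more than `max_restarts` restarts is an
#' error. `K` is user-chosen (default 4, the Components 1–4 analysis); the
#' BIC of the averaged basis is reported informationally, no model selection
#' is performed.
#'
#' @param histograms a [RedoxHistogram-class] or list of them (all groups
#'   pooled).
#' @param K number of components (>= 1).
#' @param n_iter number of independent EM initializations averaged
#'   (default 10).
#' @param seed integer seed; the per-run sub-seeds are recorded on the
#'   result.
#' @param max_restarts restart budget across all runs (default 50).
#' @return a [GaussianBasis-class].
#' @export
fitBasis <- function(histograms, K = 4L, n_iter = 10L, seed = 1L,
                     max_restarts = 50L) {
  if (K < 1L) stop("K must be >= 1")
  counts <- .pooledCounts(histograms)
  hist1 <- if (is(histograms, "RedoxHistogram")) histograms else histograms[[1]]
  centers <- .binCenters(hist1)
  n <- sum(counts)
  if (n < 50 * K)
    stop("pooled pixel count (", round(n), ") must be at least 50 * K")
  wmean <- sum(counts * centers) / n
  wsd <- sqrt(sum(counts * (centers - wmean)^2) / n)
  fits <- vector("list", n_iter)
  seeds <- integer(n_iter)
  restarts <- 0L
  for (i in seq_len(n_iter)) {
    repeat {
      sub <- .subSeed(seed, 100L * i + restarts)
      fit <- .withSeed(sub, {
        mu0 <- sample(centers, K, replace = FALSE, prob = counts + 1e-12)
        sigma0 <- rep(max(wsd / K, 0.01), K)
        .emMixture(centers, counts, mu0, sigma0, rep(1 / K, K))
      })
      if (!is.null(fit)) break
      restarts <- restarts + 1L
      if (restarts > max_restarts)
        stop("EM degenerate in more than ", max_restarts, " restarts")
      message("fitBasis: degenerate EM run restarted (", restarts, ")")
    }
    ord <- order(fit$means)
    fits[[i]] <- list(means = fit$means[ord], sds = fit$sds[ord])
    seeds[i] <- sub
  }
  means <- colMeans(do.call(rbind, lapply(fits, `[[`, "means")))
  sds <- colMeans(do.call(rbind, lapply(fits, `[[`, "sds")))
  basis <- new("GaussianBasis", means = means, sds = sds,
               nIterations = as.numeric(n_iter), seeds = as.numeric(seeds))
  # informational BIC: averaged basis with refitted proportions, 3K - 1 params
  ph <- new("RedoxHistogram", edges = hist1@edges, density = counts / n,
            nPixels = n, meta = list())
  wfit <- fitWeights(ph, basis)
  prop <- as.numeric(wfit) / 100
  dens <- vapply(seq_len(K),
                 function(k) prop[k] * stats::dnorm(centers, means[k], sds[k]),
                 numeric(length(centers)))
  mix <- rowSums(dens)
  ll <- sum(counts[mix > 0] * log(mix[mix > 0]))
  basis@bic <- -2 * ll + (3 * K - 1) * log(n)
  basis
}

#' Fit per-image component weights against a frozen basis
#'
#' Estimates the relative weight of each shared Gaussian component in one
#' image's redox histogram, with the component means and SDs frozen: EM over
#' the mixture proportions only (responsibility-weighted bin counts iterated
#' to convergence, tolerance 1e-8 on the weights), then normalized to sum to
#' 100%.
#'
#' @param histogram a [RedoxHistogram-class].
#' @param basis a [GaussianBasis-class].
#' @param tol convergence tolerance on the weight vector (default 1e-8, on
#'   the proportion scale).
#' @param max_iter iteration cap.
#' @return named numeric vector `Component1..ComponentK` of percentages
#'   summing to 100.
#' @export
fitWeights <- function(histogram, basis, tol = 1e-8, max_iter = 10000L) {
  stopifnot(is(histogram, "RedoxHistogram"), is(basis, "GaussianBasis"))
  K <- length(basis@means)
  centers <- .binCenters(histogram)
  wts <- histogram@density
  if (sum(wts) <= 0) stop("histogram is empty")
  if (K == 1L) {
    out <- 100
    names(out) <- "Component1"
    return(out)
  }
  phi <- vapply(seq_len(K),
                function(k) stats::dnorm(centers, basis@means[k], basis@sds[k]),
                numeric(length(centers)))
  # far-tail bins where every component underflows: nearest component wins
  deadRows <- rowSums(phi) <= 0 & wts > 0
  if (any(deadRows)) {
    nearest <- vapply(centers[deadRows],
                      function(c0) which.min(abs(basis@means - c0)), 1L)
    phi[cbind(which(deadRows), nearest)] <- 1
  }
  prop <- rep(1 / K, K)
  for (it in seq_len(max_iter)) {
    dens <- sweep(phi, 2L, prop, `*`)
    rs <- rowSums(dens)
    keep <- rs > 0 & wts > 0
    resp <- dens[keep, , drop = FALSE] / rs[keep]
    newProp <- colSums(wts[keep] * resp)
    newProp <- newProp / sum(newProp)
    if (max(abs(newProp - prop)) < tol) {
      prop <- newProp
      break
    }
    prop <- newProp
  }
  out <- 100 * prop / sum(prop)
  names(out) <- paste0("Component", seq_len(K))
  out
}

#' Image-wise component weight ratios
#'
#' The contrast statistic for group comparisons of histogram composition:
#' for each component `k`, its weight over the summed weight of all other
#' components, e.g. `W1 / (W2 + W3 + W4)`. Given the 100% normalization this
#' equals `Wk / (100 - Wk)`; a component carrying all the weight yields
#' `Inf`.
#'
#' @param weights named percentage vector from [fitWeights()] (sums to 100).
#' @return named numeric vector of ratios, one per component.
#' @examples
#' weightRatios(c(Component1 = 40, Component2 = 30,
#'                Component3 = 20, Component4 = 10))
#' @export
weightRatios <- function(weights) {
  if (abs(sum(weights) - 100) > 1e-6)
    stop("weights must sum to 100 (got ", sum(weights), ")")
  if (any(weights < 0)) stop("weights must be non-negative")
  r <- ifelse(weights == 100, Inf, weights / (100 - weights))
  names(r) <- if (!is.null(names(weights))) names(weights)
              else paste0("Component", seq_along(weights))
  r
}
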