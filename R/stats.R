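#' Pooled-variance unpaired two-tailed t-test
#'
#' Classical Student t-test on per-sample values, two-tailed, with the
#' pooled-variance degrees of freedom `n1 + n2 - 2` (so two groups of 3
#' samples give df = 4). Welch's unequal-variance form is available behind
#' `welch = TRUE`. Degenerate inputs follow a fixed contract: two identical
#' groups give t = 0, p = 1; zero pooled variance with unequal means gives
#' the p = 0 sentinel with a warning.
#'
#' @param a,b numeric vectors of per-sample values (each length >= 2).
#' @param welch use Welch's t instead of the pooled-variance form.
#' @return list with `statistic`, `df`, `p_two_tailed`, `group_means`,
#'   `group_sds`, `n`, `test_name`.
#' @examples
#' unpairedT(c(1, 2, 3), c(4, 5, 6))  # t = -3.674, df = 4
#' @export
unpairedT <- function(a, b, welch = FALSE) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 2L || length(b) < 2L)
    stop("each group needs at least 2 samples")
  if (any(!is.finite(a)) || any(!is.finite(b)))
    stop("values must be finite")
  res <- list(group_means = c(mean(a), mean(b)),
              group_sds = c(stats::sd(a), stats::sd(b)),
              n = c(length(a), length(b)),
              test_name = if (welch) "Welch two-tailed t-test"
                          else "Unpaired two-tailed t-test (pooled variance)")
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    if (mean(a) == mean(b)) {
      res$statistic <- 0; res$df <- length(a) + length(b) - 2L
      res$p_two_tailed <- 1
    } else {
      warning("zero variance in both groups with unequal means; p = 0 sentinel")
      res$statistic <- sign(mean(a) - mean(b)) * Inf
      res$df <- length(a) + length(b) - 2L
      res$p_two_tailed <- 0
    }
    return(res)
  }
  tt <- stats::t.test(a, b, var.equal = !welch)
  res$statistic <- unname(tt$statistic)
  res$df <- unname(tt$parameter)
  res$p_two_tailed <- tt$p.value
  res
}

#' One-way ANOVA with Tukey HSD post-hoc comparisons
#'
#' Fixed-effects one-way ANOVA across three or more groups of per-sample
#' values, followed by Tukey's honestly-significant-difference test for all
#' pairwise comparisons (adjusted p from the studentized-range
#' distribution). Exactly two groups is an error pointing to [unpairedT()].
#'
#' @param groups named list of numeric vectors (>= 3 groups, each n >= 2).
#' @param alpha significance threshold recorded on the rows (default 0.05).
#' @return list with `F`, `df` (pair: between, within), `p`, and `pairs`, a
#'   data.frame of Tukey rows (`contrast`, `diff`, `p_adj`, `significant`,
#'   `direction`).
#' @export
anovaTukey <- function(groups, alpha = 0.05) {
  if (length(groups) == 2L)
    stop("two groups: use unpairedT() instead of ANOVA")
  if (length(groups) < 3L) stop("ANOVA needs at least 3 groups")
  if (is.null(names(groups)) || any(names(groups) == ""))
    names(groups) <- paste0("group", seq_along(groups))
  n <- vapply(groups, length, 1L)
  if (any(n < 2L)) stop("each group needs at least 2 samples")
  dat <- data.frame(
    value = unlist(groups, use.names = FALSE),
    group = factor(rep(names(groups), n), levels = names(groups)))
  combs <- utils::combn(names(groups), 2)  # matches TukeyHSD row order
  if (stats::var(dat$value) == 0) {
    pairs <- data.frame(
      contrast = paste(combs[2, ], combs[1, ], sep = "-"),
      group_1 = combs[2, ], group_2 = combs[1, ],
      diff = 0, p_adj = 1, significant = FALSE, direction = "=",
      stringsAsFactors = FALSE)
    return(list(F = 0, df = c(length(groups) - 1L, sum(n) - length(groups)),
                p = 1, pairs = pairs))
  }
  fit <- stats::aov(value ~ group, data = dat)
  an <- summary(fit)[[1]]
  tk <- stats::TukeyHSD(fit)$group
  pairs <- data.frame(
    contrast = rownames(tk),
    group_1 = combs[2, ], group_2 = combs[1, ],
    diff = unname(tk[, "diff"]),
    p_adj = unname(tk[, "p adj"]),
    stringsAsFactors = FALSE)
  pairs$significant <- pairs$p_adj < alpha
  pairs$direction <- ifelse(pairs$diff > 0, "+", ifelse(pairs$diff < 0, "-", "="))
  list(F = an[1, "F value"],
       df = c(an[1, "Df"], an[2, "Df"]),
       p = an[1, "Pr(>F)"],
       pairs = pairs)
}

#' Build the group-comparison report
#'
#' Runs the configured contrasts on per-sample summaries and emits one
#' deterministic row per comparison, in the figure-legend format: statistic,
#' degrees of freedom, two-tailed p, group means/SDs and the direction of
#' the difference. Two-group contrasts use the pooled-variance t-test;
#' an `anova` entry across >= 3 groups uses ANOVA + Tukey, one row per pair.
#'
#' @param samples data.frame of per-sample values with a grouping column and
#'   a value column (e.g. the output of [sampleRedox()]).
#' @param value_col name of the value column (default `"sample_mean"`).
#' @param group_col name of the grouping column (default `"condition"`).
#' @param contrasts list of character pairs to t-test, e.g.
#'   `list(c("CLG1", "HA"))`; `NULL` means all pairs in group order.
#' @param anova if `TRUE` and there are >= 3 groups, report Tukey-adjusted
#'   pairwise rows from a one-way ANOVA instead of raw t-tests.
#' @param alpha significance threshold (default 0.05).
#' @return data.frame with columns `contrast`, `test`, `statistic`, `df`,
#'   `p`, `mean_1`, `mean_2`, `sd_1`, `sd_2`, `n_1`, `n_2`, `direction`,
#'   `significant`; zero rows (header only) for an empty cohort.
#' @export
buildReport <- function(samples, value_col = "sample_mean",
                        group_col = "condition", contrasts = NULL,
                        anova = FALSE, alpha = 0.05) {
  empty <- data.frame(contrast = character(), test = character(),
                      statistic = numeric(), df = numeric(), p = numeric(),
                      mean_1 = numeric(), mean_2 = numeric(),
                      sd_1 = numeric(), sd_2 = numeric(),
                      n_1 = integer(), n_2 = integer(),
                      direction = character(), significant = logical(),
                      stringsAsFactors = FALSE)
  if (is.null(samples) || nrow(samples) == 0L) return(empty)
  stopifnot(all(c(value_col, group_col) %in% names(samples)))
  groups <- split(samples[[value_col]], as.character(samples[[group_col]]))
  groups <- groups[unique(as.character(samples[[group_col]]))]
  if (anova && length(groups) >= 3L) {
    at <- anovaTukey(groups, alpha)
    rows <- lapply(seq_len(nrow(at$pairs)), function(i) {
      nm <- c(at$pairs$group_1[i], at$pairs$group_2[i])
      g1 <- groups[[nm[1]]]; g2 <- groups[[nm[2]]]
      data.frame(contrast = paste(nm[1], "vs", nm[2]),
                 test = "One-way ANOVA + Tukey HSD",
                 statistic = at$F, df = at$df[2], p = at$pairs$p_adj[i],
                 mean_1 = mean(g1), mean_2 = mean(g2),
                 sd_1 = stats::sd(g1), sd_2 = stats::sd(g2),
                 n_1 = length(g1), n_2 = length(g2),
                 direction = at$pairs$direction[i],
                 significant = at$pairs$p_adj[i] < alpha,
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    return(out[order(out$contrast), , drop = FALSE])
  }
  if (is.null(contrasts)) {
    if (length(groups) < 2L) return(empty)
    combs <- utils::combn(names(groups), 2, simplify = FALSE)
    contrasts <- combs
  }
  rows <- lapply(contrasts, function(cn) {
    g1 <- groups[[cn[1]]]; g2 <- groups[[cn[2]]]
    if (is.null(g1) || is.null(g2))
      stop("unknown group in contrast: ", paste(cn, collapse = " vs "))
    tt <- unpairedT(g1, g2)
    data.frame(contrast = paste(cn[1], "vs", cn[2]), test = tt$test_name,
               statistic = tt$statistic, df = tt$df, p = tt$p_two_tailed,
               mean_1 = tt$group_means[1], mean_2 = tt$group_means[2],
               sd_1 = tt$group_sds[1], sd_2 = tt$group_sds[2],
               n_1 = tt$n[1], n_2 = tt$n[2],
               direction = if (tt$group_means[1] > tt$group_means[2]) "+"
                           else if (tt$group_means[1] < tt$group_means[2]) "-"
                           else "=",
               significant = tt$p_two_tailed < alpha,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$contrast), , drop = FALSE]
}
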