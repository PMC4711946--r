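#' Number of two-group membership assignments
#'
#' The number of distinct ways to split `n_1 + n_2` observations into groups
#' of sizes `n_1` and `n_2`:
#' \deqn{\frac{(n_1 + n_2)!}{n_1!\, n_2!}}
#' the size of the exact permutation-test reference set. Computed by the
#' multiplicative binomial recurrence, whose intermediates stay integral; if
#' the exact value would exceed the largest exactly representable double
#' (2^53), the log-gamma approximation is returned with a warning.
#'
#' @param n_1,n_2 Nonnegative integer group sizes.
#' @return The combination count as a double (exact below 2^53).
#' @export
n_combinations <- function(n_1, n_2) {
  if (n_1 < 0 || n_2 < 0) stop("group sizes must be nonnegative")
  n_1 <- as.numeric(n_1); n_2 <- as.numeric(n_2)
  k <- min(n_1, n_2); big <- max(n_1, n_2)
  res <- 1
  for (i in seq_len(k)) {
    if (res * (big + i) > 2^53) {
      warning("combination count exceeds 2^53; returning approximation")
      return(exp(lgamma(n_1 + n_2 + 1) - lgamma(n_1 + 1) - lgamma(n_2 + 1)))
    }
    res <- res * (big + i) / i
  }
  res
}

#' Monte-Carlo permutation p-value
#'
#' With `m` random resamplings out of the full combination set and `b` of
#' them yielding a statistic at least as extreme as observed, the p-value is
#' estimated as
#' \deqn{p = (b + 1) / (m + 1),}
#' which can never be exactly zero: the observed grouping itself always
#' counts as one "at least as extreme" outcome. The attainable values are
#' spaced 1/(m+1) apart, the resolution of the estimate.
#'
#' @param b Number of resamples at least as extreme as observed (0 <= b <= m).
#' @param m Number of resamplings (>= 1).
#' @return The p-value, in \[1/(m+1), 1\].
#' @export
mc_pvalue <- function(b, m) {
  if (m < 1) stop("m must be >= 1")
  if (b < 0 || b > m) stop("b must satisfy 0 <= b <= m")
  (b + 1) / (m + 1)
}

#' Confidence interval for a Monte-Carlo p-value
#'
#' Treats the `b` exceedances among `m` resamples as binomial, giving the
#' normal-approximation interval
#' `p_hat +/- z * sqrt(p_hat * (1 - p_hat) / m)` with `z` the standard-normal
#' quantile at `(1 + level) / 2`, clipped to \[0, 1\]. An exact
#' Clopper-Pearson interval is available via `method = "exact"`.
#'
#' @param p_hat Estimated p-value in \[0, 1\].
#' @param m Number of resamplings.
#' @param level Confidence level in (0, 1).
#' @param method `"normal"` (default) or `"exact"`.
#' @return Numeric `c(lower, upper)`.
#' @export
pvalue_ci <- function(p_hat, m, level = 0.95, method = c("normal", "exact")) {
  method <- match.arg(method)
  if (level <= 0 || level >= 1) stop("level must be in (0, 1)")
  if (p_hat < 0 || p_hat > 1) stop("p_hat must be in [0, 1]")
  if (m < 1) stop("m must be >= 1")
  if (method == "normal") {
    z <- stats::qnorm((1 + level) / 2)
    hw <- z * sqrt(p_hat * (1 - p_hat) / m)
    ci <- c(p_hat - hw, p_hat + hw)
  } else {
    x <- round(p_hat * m)
    alpha <- 1 - level
    lo <- if (x == 0) 0 else stats::qbeta(alpha / 2, x, m - x + 1)
    hi <- if (x == m) 1 else stats::qbeta(1 - alpha / 2, x + 1, m - x)
    ci <- c(lo, hi)
  }
  pmin(1, pmax(0, ci))
}

perm_statistic <- function(name) {
  switch(name,
    mean_difference = function(g1, g2) mean(g1) - mean(g2),
    median_difference = function(g1, g2) stats::median(g1) - stats::median(g2),
    F = function(g1, g2) {
      n1 <- length(g1); n2 <- length(g2); n <- n1 + n2
      m1 <- mean(g1); m2 <- mean(g2); gm <- (n1 * m1 + n2 * m2) / n
      ssb <- n1 * (m1 - gm)^2 + n2 * (m2 - gm)^2
      ssw <- sum((g1 - m1)^2) + sum((g2 - m2)^2)
      if (ssw == 0) return(if (ssb == 0) 0 else Inf)
      (ssb / 1) / (ssw / (n - 2))
    },
    stop(sprintf("unknown statistic '%s'", name))
  )
}

#' Monte-Carlo permutation test for two groups
#'
#' Under the null hypothesis of no group difference the two groups are
#' merged, and the pooled sample is resampled without replacement `m` times
#' into pseudo-groups of the original sizes; the statistic of interest is
#' recomputed on each resample, building its null sampling distribution. The
#' p-value follows [mc_pvalue()] with `b` the number of resamples at least
#' as extreme (`>=`, ties included) as the observed statistic — on
#' `|statistic|` for the two-tailed test, on the signed statistic for the
#' one-tailed test.
#'
#' Resampling is split into fixed-size chunks, each driven by its own
#' L'Ecuyer-CMRG RNG substream derived from `seed`, so the result is a pure
#' function of `(data, m, statistic, tail, seed)` — identical for any
#' `n_workers` and any worker scheduling. The caller's RNG state is left
#' untouched.
#'
#' @param values_1,values_2 Numeric vectors of per-group observations.
#' @param m Number of resamplings (>= 1).
#' @param statistic `"mean_difference"` (default), `"median_difference"` or
#'   `"F"` (two-group between/within variance ratio).
#' @param tail `"two_tailed"` (default) or `"one_tailed"`.
#' @param seed Integer RNG seed.
#' @param n_workers Parallel workers (forked; 1 = sequential).
#' @param ci_level Confidence level for the binomial p-value interval.
#' @param chunk_size Resamples per RNG substream chunk.
#' @return A `permutation_result`: list with `observed`, `b`, `m`,
#'   `p_value`, `ci`, `statistic`, `tail`, `seed`, `n_1`, `n_2`.
#' @export
permutation_test <- function(values_1, values_2, m = 10000L,
                             statistic = c("mean_difference",
                                           "median_difference", "F"),
                             tail = c("two_tailed", "one_tailed"),
                             seed = 1L, n_workers = 1L, ci_level = 0.95,
                             chunk_size = 10000L) {
  statistic <- match.arg(statistic)
  tail <- match.arg(tail)
  stopifnot(m >= 1, n_workers >= 1, chunk_size >= 1)
  v1 <- as.numeric(values_1); v2 <- as.numeric(values_2)
  if (length(v1) < 1 || length(v2) < 1 || !all(is.finite(c(v1, v2)))) {
    stop("both groups need at least one finite value")
  }
  n1 <- length(v1); n2 <- length(v2)
  pool <- c(v1, v2)
  sfun <- perm_statistic(statistic)
  t_obs <- sfun(v1, v2)

  result <- function(b) {
    p <- mc_pvalue(b, m)
    structure(list(observed = t_obs, b = b, m = m, p_value = p,
                   ci = pvalue_ci(p, m, ci_level),
                   statistic = statistic, tail = tail, seed = seed,
                   n_1 = n1, n_2 = n2),
              class = "permutation_result")
  }

  if (length(unique(pool)) == 1L) {
    warning("degenerate data: all pooled values equal; p-value = 1")
    return(result(m))
  }

  sizes <- rep(chunk_size, m %/% chunk_size)
  if (m %% chunk_size > 0) sizes <- c(sizes, m %% chunk_size)
  streams <- chunk_streams(seed, length(sizes))

  extreme <- if (tail == "two_tailed") {
    cut <- abs(t_obs)
    function(t) abs(t) >= cut
  } else {
    function(t) t >= t_obs
  }

  # Resampling is canonicalized — pooled values sorted, the smaller
  # pseudo-group drawn — so that b depends only on the pooled multiset and
  # the group sizes, making the two-tailed result invariant under swapping
  # the group labels.
  pool_s <- sort(pool)
  n_total <- n1 + n2
  k_draw <- min(n1, n2)
  draw_is_g1 <- n1 <= n2

  run_chunk <- function(i) {
    assign(".Random.seed", streams[[i]], envir = globalenv())
    cnt <- 0L
    for (r in seq_len(sizes[i])) {
      idx <- sample.int(n_total, k_draw)
      t_perm <- if (draw_is_g1) sfun(pool_s[idx], pool_s[-idx])
                else sfun(pool_s[-idx], pool_s[idx])
      if (extreme(t_perm)) cnt <- cnt + 1L
    }
    cnt
  }

  counts <- with_preserved_rng(
    if (n_workers > 1L && .Platform$OS.type == "unix") {
      parallel::mclapply(seq_along(sizes), run_chunk, mc.cores = n_workers)
    } else {
      lapply(seq_along(sizes), run_chunk)
    }
  )
  result(sum(unlist(counts)))
}

# One L'Ecuyer-CMRG substream per chunk, chained from the master seed.
chunk_streams <- function(seed, n_chunks) {
  with_preserved_rng({
    suppressWarnings(set.seed(as.integer(seed), kind = "L'Ecuyer-CMRG"))
    s <- get(".Random.seed", envir = globalenv())
    streams <- vector("list", n_chunks)
    for (i in seq_len(n_chunks)) {
      streams[[i]] <- s
      s <- parallel::nextRNGStream(s)
    }
    streams
  })
}

with_preserved_rng <- function(expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  expr
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf(
    "<permutation_result %s (%s), n = (%d, %d)\n  observed = %.6g, b = %d, m = %d, p = %.7g, CI [%.7g, %.7g]>\n",
    x$statistic, x$tail, x$n_1, x$n_2, x$observed, x$b, x$m, x$p_value,
    x$ci[1], x$ci[2]))
  invisible(x)
}

#' Exact permutation test by full enumeration
#'
#' Enumerates every one of the `n_combinations(n_1, n_2)` group-membership
#' assignments and returns the exact permutation p-value: the fraction of
#' assignments whose statistic is at least as extreme as the observed one
#' (the original assignment is in the reference set, so the p-value is never
#' zero). Practical for modest sample sizes; serves as the exact reference
#' for the Monte-Carlo engine.
#'
#' @inheritParams permutation_test
#' @param max_combinations Safety cap on the enumeration size.
#' @return The exact p-value.
#' @export
exhaustive_permutation_test <- function(values_1, values_2,
                                        statistic = c("mean_difference",
                                                      "median_difference", "F"),
                                        tail = c("two_tailed", "one_tailed"),
                                        max_combinations = 1e6) {
  statistic <- match.arg(statistic)
  tail <- match.arg(tail)
  v1 <- as.numeric(values_1); v2 <- as.numeric(values_2)
  n1 <- length(v1); n2 <- length(v2)
  total <- n_combinations(n1, n2)
  if (total > max_combinations) {
    stop("too many combinations for enumeration; use permutation_test()")
  }
  pool <- c(v1, v2)
  sfun <- perm_statistic(statistic)
  t_obs <- sfun(v1, v2)
  combos <- utils::combn(n1 + n2, n1)
  stats_all <- apply(combos, 2, function(idx) sfun(pool[idx], pool[-idx]))
  b <- if (tail == "two_tailed") sum(abs(stats_all) >= abs(t_obs))
       else sum(stats_all >= t_obs)
  b / total
}

#' Pairwise permutation comparison of group ratios
#'
#' Runs a two-group permutation test for every unordered pair of groups and
#' each ratio column, producing the pairwise p-value table used to compare
#' vein segment classes. No multiple-testing correction is applied across
#' the pairwise matrix; interpret the individual p-values accordingly.
#'
#' Each cell derives its own seed deterministically from `seed`, the
#' component name and the (sorted) pair of group names, so results do not
#' depend on group ordering and adding a group never perturbs existing cells.
#'
#' @param table Data frame with a `group` column and the ratio columns named
#'   in `components`.
#' @param components Ratio columns to test (default `ratio_SMF`, `ratio_ECM`).
#' @param m,statistic,tail,n_workers,ci_level Passed to [permutation_test()].
#' @param seed Master seed for the per-cell substreams.
#' @return Data frame with one row per (component, group pair): columns
#'   `component`, `group1`, `group2`, `observed`, `b`, `m`, `p_value`,
#'   `ci_lower`, `ci_upper`, `seed`.
#' @export
compare_groups <- function(table, components = c("ratio_SMF", "ratio_ECM"),
                           m = 10000L, statistic = "mean_difference",
                           tail = "two_tailed", seed = 1L, n_workers = 1L,
                           ci_level = 0.95) {
  stopifnot(is.data.frame(table), "group" %in% names(table))
  missing_cols <- setdiff(components, names(table))
  if (length(missing_cols) > 0) {
    stop("missing component columns: ", paste(missing_cols, collapse = ", "))
  }
  groups <- sort(unique(as.character(table$group)))
  if (length(groups) < 2) stop("need at least 2 groups")
  counts <- table(table$group)
  if (any(counts < 2)) stop("every group needs at least 2 samples")

  rows <- list()
  for (comp in components) {
    for (i in seq_len(length(groups) - 1)) {
      for (j in seq(i + 1, length(groups))) {
        g1 <- groups[i]; g2 <- groups[j]
        v1 <- table[[comp]][table$group == g1]
        v2 <- table[[comp]][table$group == g2]
        cell_seed <- derive_seed(seed, paste(comp, g1, g2, sep = "|"))
        res <- permutation_test(v1, v2, m = m, statistic = statistic,
                                tail = tail, seed = cell_seed,
                                n_workers = n_workers, ci_level = ci_level)
        rows[[length(rows) + 1L]] <- data.frame(
          component = comp, group1 = g1, group2 = g2,
          observed = res$observed, b = res$b, m = res$m,
          p_value = res$p_value, ci_lower = res$ci[1], ci_upper = res$ci[2],
          seed = cell_seed, stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}
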