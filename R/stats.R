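# Exact small-sample nonparametric tests used for left-vs-right comparisons.

.phreno_cache <- new.env(parent = emptyenv())

# Null distribution of the rank sum W of the first sample: counts[k] = number
# of n1-subsets of ranks 1..N whose sum equals (k - 1 + min_sum). Classic
# subset-sum DP, equivalent to enumerating all choose(N, n1) assignments.
ranksum_null_counts <- function(n1, n2) {
  key <- paste0(n1, "_", n2)
  hit <- .phreno_cache[[key]]
  if (!is.null(hit)) return(hit)
  N <- n1 + n2
  min_sum <- n1 * (n1 + 1) / 2
  max_sum <- sum((N - n1 + 1):N)
  width <- max_sum - min_sum + 1L
  # f[j, s] = number of j-subsets of ranks seen so far with sum s
  f <- matrix(0, n1 + 1L, max_sum + 1L)
  f[1L, 1L] <- 1  # empty subset, sum 0 (offset by 1)
  for (r in seq_len(N)) {
    jmax <- min(r, n1)
    for (j in jmax:1L) {
      src <- seq_len(max_sum + 1L - r)
      f[j + 1L, src + r] <- f[j + 1L, src + r] + f[j, src]
    }
  }
  counts <- f[n1 + 1L, (min_sum:max_sum) + 1L]
  res <- list(counts = counts, min_sum = min_sum, total = choose(N, n1))
  .phreno_cache[[key]] <- res
  res
}

exact_ranksum_p <- function(w, n1, n2, alternative) {
  d <- ranksum_null_counts(n1, n2)
  i <- round(w - d$min_sum) + 1L
  p_le <- sum(d$counts[seq_len(i)]) / d$total
  p_ge <- sum(d$counts[i:length(d$counts)]) / d$total
  switch(alternative,
         greater = p_ge,
         less = p_le,
         two.sided = min(1, 2 * min(p_le, p_ge)))
}

#' Mann-Whitney (Wilcoxon rank-sum) test
#'
#' Exact p-value by complete enumeration of all `choose(n1+n2, n1)` group
#' assignments when the pooled sample has at most 20 tie-free observations;
#' otherwise a normal approximation on midranks with tie and continuity
#' corrections. The U statistic counts (x, y) pairs with x > y.
#'
#' @param x,y numeric samples (e.g. right and left measurements from
#'   different embryos).
#' @param alternative `"two.sided"` (doubled smaller exact tail, capped at
#'   1), `"greater"` (x tends larger) or `"less"`.
#' @param exact_max_n largest pooled size for the exact path (default 20).
#' @return Object of class `phreno_test` with fields `statistic` (U),
#'   `p_value`, `method`, `alternative`, `n1`, `n2`.
#' @export
mann_whitney <- function(x, y, alternative = c("two.sided", "greater",
                                               "less"), exact_max_n = 20L) {
  alternative <- match.arg(alternative)
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) < 1L || length(y) < 1L)
    phreno_stop("EmptySample", "both samples need at least one value")
  if (!all(is.finite(c(x, y))))
    phreno_stop("InvalidParams", "samples must be finite")
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  pooled <- c(x, y)
  ties <- anyDuplicated(pooled) > 0L
  rk <- rank(pooled)
  w <- sum(rk[seq_len(n1)])
  u <- w - n1 * (n1 + 1) / 2
  if (!ties && N <= exact_max_n) {
    p <- exact_ranksum_p(w, n1, n2, alternative)
    method <- "exact"
  } else {
    mu <- n1 * n2 / 2
    tie_tab <- table(pooled)
    sig2 <- n1 * n2 / 12 * ((N + 1) -
                              sum(tie_tab^3 - tie_tab) / (N * (N - 1)))
    z_num <- u - mu
    cc <- 0.5  # continuity correction towards the mean
    p <- switch(alternative,
                greater = stats::pnorm((z_num - cc) / sqrt(sig2),
                                       lower.tail = FALSE),
                less = stats::pnorm((z_num + cc) / sqrt(sig2)),
                two.sided = min(1, 2 * stats::pnorm(
                  (abs(z_num) - cc) / sqrt(sig2), lower.tail = FALSE)))
    method <- "normal_approx"
  }
  structure(list(statistic = u, statistic_name = "U", p_value = p,
                 method = method, alternative = alternative,
                 n1 = n1, n2 = n2),
            class = "phreno_test")
}

# Null distribution of the positive-rank sum W+ over all 2^n sign
# assignments, via the generating function prod_r (1 + z^r). Ranks are
# doubled so midranks become integers.
signedrank_null_counts <- function(ranks2) {
  tot <- sum(ranks2)
  counts <- numeric(tot + 1L)
  counts[1L] <- 1
  for (r in ranks2) {
    shifted <- c(numeric(r), counts[seq_len(tot + 1L - r)])
    counts <- counts + shifted
  }
  counts
}

#' Wilcoxon signed-rank test
#'
#' Paired test for left-versus-right measurements from the same embryos.
#' Exact p-value by enumeration of all `2^n` sign assignments (via the
#' rank generating function) for up to 20 nonzero differences; normal
#' approximation with tie and continuity corrections beyond. Zero
#' differences are dropped (Wilcoxon's convention); the Pratt variant keeps
#' them in the ranking.
#'
#' @param x numeric: paired differences, or the first member of each pair
#'   when `y` is given.
#' @param y optional second member; differences are `x - y`.
#' @param alternative `"two.sided"`, `"greater"` (differences tend positive)
#'   or `"less"`.
#' @param zeros `"drop"` (default) or `"pratt"`.
#' @param exact_max_n largest number of nonzero differences for the exact
#'   path (default 20).
#' @return Object of class `phreno_test` with fields `statistic` (W+, sum of
#'   positive-difference ranks), `p_value`, `method`, `alternative`, `n`.
#' @export
wilcoxon_signed_rank <- function(x, y = NULL,
                                 alternative = c("two.sided", "greater",
                                                 "less"),
                                 zeros = c("drop", "pratt"),
                                 exact_max_n = 20L) {
  alternative <- match.arg(alternative)
  zeros <- match.arg(zeros)
  d <- if (is.null(y)) as.numeric(x) else as.numeric(x) - as.numeric(y)
  if (!all(is.finite(d)))
    phreno_stop("InvalidParams", "differences must be finite")
  n_zero <- sum(d == 0)
  if (all(d == 0))
    phreno_stop("AllZeroDifferences", "all paired differences are zero")
  if (zeros == "drop") {
    d <- d[d != 0]
    rk <- rank(abs(d))
  } else {
    rk <- rank(abs(d))
    rk <- rk[d != 0]
    d <- d[d != 0]
  }
  n <- length(d)
  w_plus <- sum(rk[d > 0])
  ties <- anyDuplicated(abs(d)) > 0L
  if (n <= exact_max_n) {
    r2 <- round(2 * rk)
    counts <- signedrank_null_counts(r2)
    tot <- 2^n
    i <- round(2 * w_plus) + 1L
    p_le <- sum(counts[seq_len(i)]) / tot
    p_ge <- sum(counts[i:length(counts)]) / tot
    p <- switch(alternative,
                greater = p_ge, less = p_le,
                two.sided = min(1, 2 * min(p_le, p_ge)))
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    sig2 <- sum(rk^2) / 4
    cc <- 0.5
    z_num <- w_plus - mu
    p <- switch(alternative,
                greater = stats::pnorm((z_num - cc) / sqrt(sig2),
                                       lower.tail = FALSE),
                less = stats::pnorm((z_num + cc) / sqrt(sig2)),
                two.sided = min(1, 2 * stats::pnorm(
                  (abs(z_num) - cc) / sqrt(sig2), lower.tail = FALSE)))
    method <- "normal_approx"
  }
  structure(list(statistic = w_plus, statistic_name = "W+", p_value = p,
                 method = method, alternative = alternative, n = n,
                 n_zero_dropped = if (zeros == "drop") n_zero else 0L),
            class = "phreno_test")
}

#' @export
print.phreno_test <- function(x, ...) {
  cat(sprintf("<phreno_test> %s = %g, p = %.5g (%s, %s)\n",
              x$statistic_name, x$statistic, x$p_value, x$method,
              x$alternative))
  invisible(x)
}

#' Mean and standard error of the mean
#'
#' SEM uses the n-1 sample standard deviation divided by sqrt(n); with a
#' single value the SEM is undefined and returned as `NA`.
#'
#' @param values numeric vector, n >= 1.
#' @return List with `mean`, `sem`, `n`.
#' @export
mean_sem <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 1L || !all(is.finite(values)))
    phreno_stop("InvalidParams", "`values` must be non-empty and finite")
  n <- length(values)
  list(mean = mean(values),
       sem = if (n == 1L) NA_real_ else stats::sd(values) / sqrt(n),
       n = n)
}
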