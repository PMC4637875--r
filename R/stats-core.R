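#' Two-sample Kolmogorov-Smirnov test
#'
#' Compares the empirical cumulative distribution functions of two numeric
#' samples via their maximum vertical distance \eqn{D}. The two-sided p-value
#' is computed either asymptotically, from the Kolmogorov limiting
#' distribution with a small-sample correction to the effective sample size,
#' or exactly, by full enumeration of every assignment of the pooled values
#' to the two labels.
#'
#' The statistic is
#' \deqn{D = \max_t |F_x(t) - F_y(t)|}
#' evaluated at every distinct pooled value, so ties between and within
#' samples are handled by construction. The asymptotic p-value is
#' \eqn{Q(\lambda) = 2 \sum_{j \ge 1} (-1)^{j-1} e^{-2 j^2 \lambda^2}} with
#' \eqn{\lambda = (\sqrt{n_e} + 0.12 + 0.11/\sqrt{n_e})\, D} and effective
#' size \eqn{n_e = n_1 n_2 / (n_1 + n_2)}. The exact p-value is the fraction
#' of the \eqn{C(n_1+n_2, n_1)} label assignments whose statistic is at least
#' the observed \eqn{D}; it is tie-aware because enumeration permutes the
#' actual pooled values. Under ties the asymptotic p-value is approximate
#' (conservative), which is recorded in the returned method string.
#'
#' @param x,y Numeric vectors, each non-empty, all values finite.
#' @param method `"auto"` (exact when `length(x) + length(y) <= 16`, else
#'   asymptotic), `"asymptotic"`, or `"exact"`.
#' @return An object of class `ks_result`: a list with elements `D`, `p`,
#'   `n1`, `n2` and `method` (`"asymptotic"` or `"exact-permutation"`).
#' @examples
#' ks_two_sample(c(1, 2, 3), c(4, 5, 6))          # D = 1, exact p = 0.1
#' ks_two_sample(rnorm(100), rnorm(100, 1))$p
#' @export
ks_two_sample <- function(x, y, method = c("auto", "asymptotic", "exact")) {
  method <- match.arg(method)
  if (length(x) < 1L || length(y) < 1L)
    stop("both samples must be non-empty")
  if (!is.numeric(x) || !is.numeric(y) || anyNA(x) || anyNA(y) ||
      any(!is.finite(x)) || any(!is.finite(y)))
    stop("samples must be finite numeric vectors without NA/NaN")
  n1 <- length(x)
  n2 <- length(y)
  D <- ks_statistic(x, y)
  exact <- switch(method,
    exact = TRUE,
    asymptotic = FALSE,
    auto = (n1 + n2) <= 16L
  )
  if (exact) {
    p <- ks_exact_pvalue(x, y, D)
    meth <- "exact-permutation"
  } else {
    p <- ks_asymptotic_pvalue(D, n1, n2)
    meth <- "asymptotic"
  }
  structure(
    list(D = D, p = p, n1 = n1, n2 = n2, method = meth),
    class = "ks_result"
  )
}

#' @export
print.ks_result <- function(x, ...) {
  cat(sprintf("Two-sample KS test (%s): D = %.4g, p = %.4g (n1 = %d, n2 = %d)\n",
              x$method, x$D, x$p, x$n1, x$n2))
  invisible(x)
}

# Max |ECDF_x - ECDF_y| over all distinct pooled values; findInterval on the
# sorted samples counts values <= t, so ties collapse correctly.
ks_statistic <- function(x, y) {
  pts <- sort(unique(c(x, y)))
  Fx <- findInterval(pts, sort(x)) / length(x)
  Fy <- findInterval(pts, sort(y)) / length(y)
  max(abs(Fx - Fy))
}

# Kolmogorov limiting distribution Q(lambda) with the Stephens small-sample
# correction applied to sqrt(n_e).
ks_asymptotic_pvalue <- function(D, n1, n2) {
  if (D == 0) return(1)
  ne <- n1 * n2 / (n1 + n2)
  lambda <- (sqrt(ne) + 0.12 + 0.11 / sqrt(ne)) * D
  j <- seq_len(200)
  terms <- 2 * (-1)^(j - 1) * exp(-2 * j^2 * lambda^2)
  p <- sum(terms)
  min(max(p, 0), 1)
}

# Exact permutation p: enumerate all C(n1+n2, n1) assignments of the pooled
# values to the x-label and count those with statistic >= observed D.
# Tolerance guards against float noise in the >= comparison.
ks_exact_pvalue <- function(x, y, D_obs) {
  pooled <- c(x, y)
  n1 <- length(x)
  n <- length(pooled)
  if (choose(n, n1) > 5e5)
    stop("exact enumeration infeasible for n1 + n2 = ", n)
  idx <- utils::combn(n, n1)
  hits <- 0L
  for (j in seq_len(ncol(idx))) {
    xs <- pooled[idx[, j]]
    ys <- pooled[-idx[, j]]
    if (ks_statistic(xs, ys) >= D_obs - 1e-12) hits <- hits + 1L
  }
  hits / ncol(idx)
}

#' One-sided Fisher exact test (hypergeometric upper tail)
#'
#' Computes the probability of observing an overlap at least as large as `k`
#' between a query set of size `n` and a signature of size `K` drawn from a
#' universe of `N` genes:
#' \deqn{p = \sum_{j=k}^{\min(K,n)} \binom{K}{j}\binom{N-K}{n-j} /
#'   \binom{N}{n}.}
#' Terms are computed in log space via log-gamma so genome-scale universes
#' (N around 20,000) do not overflow.
#'
#' @param k Overlap count.
#' @param K Signature size.
#' @param n Query-set size.
#' @param N Universe size.
#' @return The upper-tail p-value, in (0, 1].
#' @examples
#' fisher_one_sided(3, 5, 5, 10)  # 0.5
#' fisher_one_sided(0, 5, 5, 10)  # 1
#' @export
fisher_one_sided <- function(k, K, n, N) {
  counts <- c(k = k, K = K, n = n, N = N)
  if (anyNA(counts) || any(counts < 0) || any(counts != round(counts)))
    stop("k, K, n, N must be non-negative integers")
  if (K > N || n > N)
    stop("signature and query sizes cannot exceed the universe size")
  if (k > min(K, n))
    stop("overlap k cannot exceed min(K, n)")
  if (k < max(0, K + n - N))
    stop("overlap k below the minimum forced by the table margins")
  j <- seq.int(k, min(K, n))
  # support restriction: terms with n - j > N - K are zero
  j <- j[n - j <= N - K]
  log_terms <- lchoose(K, j) + lchoose(N - K, n - j) - lchoose(N, n)
  m <- max(log_terms)
  p <- exp(m) * sum(exp(log_terms - m))
  min(max(p, 0), 1)
}

#' Pearson product-moment correlation
#'
#' Standard Pearson correlation computed from the definition
#' \eqn{r = \sum (x_i-\bar x)(y_i-\bar y) /
#'   \sqrt{\sum (x_i-\bar x)^2 \sum (y_i-\bar y)^2}}.
#'
#' @param x,y Numeric vectors of equal length at least 3, each with positive
#'   variance.
#' @return The correlation, clamped to \eqn{[-1, 1]} against rounding noise.
#' @examples
#' pearson_r(1:4, c(1, 2, 3, 5))
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y))
    stop("x and y must have equal length")
  if (length(x) < 3L)
    stop("need at least 3 paired observations")
  if (anyNA(x) || anyNA(y) || any(!is.finite(c(x, y))))
    stop("values must be finite and non-missing")
  dx <- x - mean(x)
  dy <- y - mean(y)
  sx <- sum(dx^2)
  sy <- sum(dy^2)
  if (sx == 0 || sy == 0)
    stop("correlation undefined: zero variance in at least one input")
  r <- sum(dx * dy) / sqrt(sx * sy)
  min(max(r, -1), 1)
}

#' Benjamini-Hochberg q-values
#'
#' Step-up false discovery rate adjustment:
#' \eqn{q_i = \min_{j : p_j \ge p_i} m \, p_j / \mathrm{rank}(p_j)},
#' clipped at 1. The output preserves the ordering of the input p-values.
#'
#' @param p Numeric vector of p-values in \eqn{[0, 1]}.
#' @return q-values in the same order as `p`.
#' @examples
#' bh_qvalues(c(0.01, 0.02, 0.03, 0.04))  # all 0.04
#' @export
bh_qvalues <- function(p) {
  if (length(p) == 0L) return(numeric(0))
  if (anyNA(p) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1] with no missing values")
  m <- length(p)
  ord <- order(p, decreasing = TRUE)
  ranked <- m / seq.int(m, 1) * p[ord]
  q <- pmin(1, cummin(ranked))
  q[order(ord)]
}
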