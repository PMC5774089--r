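# Exact small-sample nonparametric inference, built from first principles:
# mid-rank (average-rank) tie handling throughout, exact null distributions
# by complete enumeration at the sample sizes of a typical preclinical
# cohort, and a tie-corrected normal approximation beyond the enumeration
# bound. Two-sided p-values use the doubling convention,
# p = min(1, 2 * min(lower tail, upper tail)).

# Enumeration results are cached per pooled-rank multiset: cohorts of
# continuous biomarkers are almost always tie-free, so repeated calls at the
# same group sizes (power/type-I simulations) reuse one enumeration.
.exact_cache <- new.env(parent = emptyenv())

rank_key <- function(prefix, m, ranks) {
  # mid-ranks are multiples of 1/2; doubling makes the key integral
  paste(prefix, m, paste(sort(as.integer(round(2 * ranks))), collapse = ","),
        sep = "|")
}

two_sided_p <- function(lower, upper) min(1, 2 * min(lower, upper))

#' Exact Mann-Whitney U test
#'
#' Rank-sum test for two independent samples with mid-rank tie handling.
#' For combined samples up to `exact_limit` the two-sided p-value is exact:
#' the null distribution of the rank sum is built by complete enumeration
#' of all `choose(m + n, m)` assignments of the pooled mid-ranks to the
#' first group, which conditions on the observed tie pattern. Beyond the
#' bound, a tie-corrected normal approximation (no continuity correction)
#' is used and tagged as such.
#'
#' @param x,y numeric samples, each non-empty.
#' @param exact_limit largest combined sample size for which the exact
#'   distribution is enumerated (default 25).
#' @return An `exact_test` list: `statistic` (U for `x`), `p_value`
#'   (two-sided), `method` (`"exact"` or `"asymptotic"`), `n` (per-group
#'   sizes).
#' @examples
#' mann_whitney_exact(c(1, 2), c(3, 4))  # U = 0, p = 1/3
#' @export
mann_whitney_exact <- function(x, y, exact_limit = 25L) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) < 1L || length(y) < 1L) {
    stop("mann_whitney_exact: both samples must be non-empty", call. = FALSE)
  }
  if (anyNA(x) || anyNA(y)) stop("mann_whitney_exact: NA in input", call. = FALSE)
  m <- length(x); n <- length(y); N <- m + n
  r <- rank(c(x, y), ties.method = "average")
  rs <- sum(r[seq_len(m)])
  U <- rs - m * (m + 1) / 2

  if (N <= exact_limit) {
    key <- rank_key("mw", m, r)
    dist <- .exact_cache[[key]]
    if (is.null(dist)) {
      cmb <- utils::combn(N, m)
      dist <- colSums(matrix(r[cmb], nrow = m))
      .exact_cache[[key]] <- dist
    }
    eps <- 1e-9
    p <- two_sided_p(mean(dist <= rs + eps), mean(dist >= rs - eps))
    method <- "exact"
  } else {
    mu <- m * n / 2
    ties <- table(r)
    tie_term <- sum(ties^3 - ties) / (N * (N - 1))
    sigma2 <- m * n / 12 * (N + 1 - tie_term)
    if (sigma2 <= 0) {  # all observations tied: no separation possible
      p <- 1
    } else {
      z <- (U - mu) / sqrt(sigma2)
      p <- 2 * stats::pnorm(-abs(z))
    }
    method <- "asymptotic"
  }
  structure(list(statistic = U, p_value = p, method = method, n = c(m, n)),
            class = "exact_test")
}

#' Exact Wilcoxon signed-rank test
#'
#' Paired test on `after - before` differences with mid-rank tie handling.
#' Zero differences are dropped before ranking (the classical convention;
#' `zero_method = "pratt"` instead ranks them with the rest and then
#' discards their contribution). For up to `exact_limit` nonzero
#' differences the null distribution of W+ (sum of positive-difference
#' ranks) is exact over all `2^n` sign assignments, computed by convolving
#' the per-rank generating functions — identical to full enumeration but
#' linear-space. Beyond the bound, a tie-corrected normal approximation is
#' used.
#'
#' @param before,after equal-length paired samples; alternatively pass the
#'   differences as `before` and leave `after = NULL`.
#' @param zero_method `"drop"` (default) or `"pratt"`.
#' @param exact_limit largest number of nonzero differences for the exact
#'   distribution (default 25).
#' @return An `exact_test` list: `statistic` (W+), `p_value`, `method`,
#'   `n` (number of nonzero differences used).
#' @examples
#' wilcoxon_signed_rank_exact(1:5, 1:5 + c(2, 1, 3, 2, 4))  # all positive
#' @export
wilcoxon_signed_rank_exact <- function(before, after = NULL,
                                       zero_method = c("drop", "pratt"),
                                       exact_limit = 25L) {
  zero_method <- match.arg(zero_method)
  d <- if (is.null(after)) as.numeric(before)
       else {
         if (length(before) != length(after)) {
           stop("wilcoxon_signed_rank_exact: paired samples differ in length",
                call. = FALSE)
         }
         as.numeric(after) - as.numeric(before)
       }
  if (anyNA(d)) stop("wilcoxon_signed_rank_exact: NA in differences", call. = FALSE)
  nz <- d != 0
  if (!any(nz)) {
    stop("wilcoxon_signed_rank_exact: all differences are zero", call. = FALSE)
  }
  if (zero_method == "drop") {
    d <- d[nz]
    r <- rank(abs(d), ties.method = "average")
  } else {
    r_all <- rank(abs(d), ties.method = "average")
    r <- r_all[nz]
    d <- d[nz]
  }
  n <- length(d)
  W <- sum(r[d > 0])

  if (n <= exact_limit) {
    key <- rank_key(paste0("wsr", substr(zero_method, 1, 1)), n, r)
    dist <- .exact_cache[[key]]
    if (is.null(dist)) {
      dist <- signed_rank_distribution(r)
      .exact_cache[[key]] <- dist
    }
    w2 <- as.integer(round(2 * W))
    lower <- sum(dist$prob[dist$w2 <= w2])
    upper <- sum(dist$prob[dist$w2 >= w2])
    p <- two_sided_p(lower, upper)
    method <- "exact"
  } else {
    mu <- sum(r) / 2
    sigma2 <- sum(r^2) / 4  # mid-ranks already absorb the tie correction
    z <- (W - mu) / sqrt(sigma2)
    p <- 2 * stats::pnorm(-abs(z))
    method <- "asymptotic"
  }
  structure(list(statistic = W, p_value = p, method = method, n = n),
            class = "exact_test")
}

# Exact null distribution of W+ for signed ranks `r` (mid-ranks, multiples
# of 1/2). Works on doubled ranks so all masses sit on integers; the
# generating function prod_i (1 + z^(2 r_i)) / 2^n is built by convolution.
# Returns data.frame(w2 = doubled statistic values, prob).
signed_rank_distribution <- function(r) {
  r2 <- as.integer(round(2 * r))
  total <- sum(r2)
  f <- numeric(total + 1L)  # index k+1 holds P(2W = k) * 2^n
  f[1L] <- 1
  for (rk in r2) {
    g <- f
    g[(rk + 1L):(total + 1L)] <- g[(rk + 1L):(total + 1L)] + f[1L:(total - rk + 1L)]
    f <- g
  }
  data.frame(w2 = 0:total, prob = f / sum(f))
}

#' Tie-aware Spearman rank correlation
#'
#' `rho` is the product-moment correlation of the mid-ranks, which reduces
#' to `1 - 6 * sum(d^2) / (n (n^2 - 1))` when there are no ties. The
#' two-sided p-value is exact by complete permutation enumeration for
#' `n <= exact_limit` (default 10), and otherwise uses the t approximation
#' `t = rho * sqrt((n - 2) / (1 - rho^2))` on `n - 2` degrees of freedom.
#'
#' @param x,y equal-length numeric vectors, `n >= 3`, neither constant.
#' @param exact_limit largest n for exact permutation enumeration.
#' @return A `correlation_result` list: `rho`, `p_value`, `method`, `n`.
#' @examples
#' spearman_cor(1:8, c(2, 1, 4, 3, 6, 5, 8, 7))
#' @export
spearman_cor <- function(x, y, exact_limit = 10L) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) {
    stop("spearman_cor: input lengths differ", call. = FALSE)
  }
  n <- length(x)
  if (n < 3L) stop("spearman_cor: need n >= 3", call. = FALSE)
  if (anyNA(x) || anyNA(y)) stop("spearman_cor: NA in input", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("spearman_cor: rank correlation is undefined for a constant vector",
         call. = FALSE)
  }
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  rho <- stats::cor(rx, ry)
  if (n <= exact_limit) {
    cnt <- spearman_perm_counts(rx, ry)
    p <- two_sided_p(cnt[1] / cnt[3], cnt[2] / cnt[3])
    method <- "exact"
  } else {
    if (abs(rho) >= 1) {
      p <- 0
    } else {
      t <- rho * sqrt((n - 2) / (1 - rho^2))
      p <- 2 * stats::pt(-abs(t), df = n - 2)
    }
    method <- "t-approximation"
  }
  structure(list(rho = rho, p_value = p, method = method, n = n),
            class = "correlation_result")
}

#' Bonferroni adjustment
#'
#' Adjusted p-values `min(1, m * p)` and reject/accept decisions against
#' `alpha`. The family size `m` defaults to the number of p-values supplied
#' but can be set explicitly when the confirmatory family is larger than
#' the vector at hand.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @param alpha significance level (default 0.05).
#' @param m family size (default `length(p)`).
#' @return A data frame with `p`, `p_adjusted`, `reject`.
#' @export
bonferroni_adjust <- function(p, alpha = 0.05, m = length(p)) {
  p <- as.numeric(p)
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    stop("bonferroni_adjust: p-values must lie in [0, 1]", call. = FALSE)
  }
  if (m < length(p)) {
    stop("bonferroni_adjust: family size `m` smaller than the number of p-values",
         call. = FALSE)
  }
  adj <- pmin(1, m * p)
  data.frame(p = p, p_adjusted = adj, reject = adj < alpha)
}

#' @export
print.exact_test <- function(x, ...) {
  cat("<exact_test> statistic = ", signif(x$statistic, 5), ", p = ",
      signif(x$p_value, 4), " (", x$method, ", n = ",
      paste(x$n, collapse = "/"), ")\n", sep = "")
  invisible(x)
}

#' @export
print.correlation_result <- function(x, ...) {
  cat("<correlation_result> rho = ", signif(x$rho, 4), ", p = ",
      signif(x$p_value, 4), " (", x$method, ", n = ", x$n, ")\n", sep = "")
  invisible(x)
}
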