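#' Spearman rank correlation with exact small-sample p-values
#'
#' Computes Spearman's rho with average ranks for ties, after pairwise
#' deletion of missing values. The two-sided p-value is computed from the
#' exact permutation null distribution when `n <= exact_max` (all `n!`
#' orderings of one margin are enumerated) and from the t-approximation
#' `t = rho * sqrt((n - 2) / (1 - rho^2))` on `n - 2` degrees of freedom
#' otherwise. Cohort sizes in MSC expansion studies are small (7-36
#' samples), so exact nulls matter at the low end.
#'
#' @param x,y Numeric vectors of equal length. Pairs with a missing value
#'   in either vector are dropped.
#' @param exact_max Largest n for which the exact permutation null is
#'   enumerated (default 9; `9!` orderings).
#' @return A list of class `"correlation_result"` with elements `rho`,
#'   `p`, `n` and `method`.
#' @examples
#' spearman_cor(1:6, c(2, 1, 4, 3, 6, 5))
#' @export
spearman_cor <- function(x, y, exact_max = 9L) {
  stopifnot(length(x) == length(y))
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3L) stop("spearman_cor() needs at least 3 complete pairs")
  if (length(unique(x)) == 1L || length(unique(y)) == 1L) {
    return(structure(list(rho = NA_real_, p = NA_real_, n = n,
                          method = "undefined (constant input)"),
                     class = "correlation_result"))
  }
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)
  if (n <= exact_max) {
    p <- spearman_exact_p(rx, ry)
    method <- "exact permutation"
  } else {
    tt <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tt), df = n - 2)
    method <- "t approximation"
  }
  structure(list(rho = rho, p = min(1, p), n = n, method = method),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("Spearman rho = %.4f, p = %.4g (n = %d, %s)\n",
              x$rho, x$p, x$n, x$method))
  invisible(x)
}

# Exact two-sided permutation p-value: proportion of the n! orderings of
# one rank vector whose |rho| is at least the observed |rho| (ties kept
# as average ranks, so the null conditions on the observed tie pattern).
spearman_exact_p <- function(rx, ry) {
  n <- length(rx)
  obs <- abs(stats::cor(rx, ry))
  perms <- all_permutations(n)
  # rho for every permutation of ry against fixed rx
  sx <- rx - mean(rx); sy <- ry - mean(ry)
  denom <- sqrt(sum(sx^2) * sum(sy^2))
  stat <- abs((matrix(sy[perms], nrow = nrow(perms)) %*% sx) / denom)
  mean(stat >= obs - 1e-12)
}

# All permutations of 1..n as a matrix with n! rows (n <= 9).
all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, nrow(sub) * n, n)
  for (k in seq_len(n)) {
    rows <- (k - 1L) * nrow(sub) + seq_len(nrow(sub))
    out[rows, ] <- cbind(sub + (sub >= k), k)
  }
  out
}

#' Wilcoxon signed-rank test for paired data
#'
#' Two-sided signed-rank test on paired differences. Zero differences are
#' dropped (with a message). For `n <= exact_max` nonzero differences the
#' exact null distribution of the positive-rank sum is computed by
#' convolution over all `2^n` sign assignments (average ranks are used for
#' tied magnitudes, so the exact null conditions on the tie pattern);
#' above that a normal approximation with tie correction and continuity
#' correction is used.
#'
#' @param x,y Paired numeric vectors, or `y = NULL` to treat `x` as the
#'   differences.
#' @param exact_max Largest number of nonzero differences for which the
#'   exact distribution is used (default 25).
#' @return A list with `statistic` (positive-rank sum W), `p`, `n`
#'   (nonzero differences) and `method`.
#' @examples
#' wilcoxon_signed_rank(c(5, 6, 7, 8, 9, 10, 11, 12), rep(4, 8))
#' @export
wilcoxon_signed_rank <- function(x, y = NULL, exact_max = 25L) {
  d <- if (is.null(y)) x else x - y
  d <- d[is.finite(d)]
  nz <- d != 0
  if (any(!nz)) message(sum(!nz), " zero difference(s) dropped")
  d <- d[nz]
  n <- length(d)
  if (n == 0L) {
    message("all differences are zero; p = 1 by convention")
    return(list(statistic = 0, p = 1, n = 0L, method = "degenerate"))
  }
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  if (n <= exact_max) {
    # exact distribution of W over the 2^n equiprobable sign assignments,
    # on the 2x-scaled integer support so that average ranks stay exact
    support <- round(2 * r)
    f <- signrank_null_pmf(support)
    wobs <- round(2 * w)
    lo <- sum(f[seq_len(wobs + 1L)])          # P(W* <= wobs), zero-based support
    hi <- sum(f[(wobs + 1L):length(f)])       # P(W* >= wobs)
    p <- min(1, 2 * min(lo, hi))
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (w - mu - sign(w - mu) * 0.5) / sqrt(sig2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "normal approximation"
  }
  list(statistic = w, p = p, n = n, method = method)
}

# PMF of the signed-rank sum on integer support 0..sum(weights), built by
# convolving (1 + x^w_i)/2 terms.
signrank_null_pmf <- function(weights) {
  total <- sum(weights)
  f <- numeric(total + 1L)
  f[1L] <- 1
  for (w in weights) {
    g <- f
    g[(w + 1L):(total + 1L)] <- g[(w + 1L):(total + 1L)] + f[1L:(total + 1L - w)]
    f <- g / 2
  }
  f
}

#' Mann-Whitney (Wilcoxon rank-sum) test for two independent groups
#'
#' Two-sided rank-sum test. The exact null distribution is used when the
#' smaller group has at most `exact_max` observations and there are no
#' ties; otherwise a normal approximation with tie correction and
#' continuity correction.
#'
#' @param a,b Numeric vectors (both nonempty).
#' @param exact_max Largest min(n) for the exact distribution (default 8).
#' @return A list with `statistic` (U for group `a`), `p` and `method`.
#' @examples
#' mann_whitney(c(1, 2, 3, 4), c(10, 11, 12, 13))
#' @export
mann_whitney <- function(a, b, exact_max = 8L) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  if (length(a) == 0L || length(b) == 0L) stop("both groups must be nonempty")
  na <- length(a); nb <- length(b)
  r <- rank(c(a, b))
  u <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  ties <- any(duplicated(c(a, b)))
  if (min(na, nb) <= exact_max && !ties) {
    p <- min(1, 2 * min(stats::pwilcox(u, na, nb),
                        stats::pwilcox(u - 1, na, nb, lower.tail = FALSE)))
    method <- "exact"
  } else {
    mu <- na * nb / 2
    nn <- na + nb
    tie_tab <- table(r)
    sig2 <- na * nb / 12 * ((nn + 1) - sum(tie_tab^3 - tie_tab) / (nn * (nn - 1)))
    z <- (u - mu - sign(u - mu) * 0.5) / sqrt(sig2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "normal approximation"
  }
  list(statistic = u, p = p, method = method)
}

#' Least-squares line with t-based confidence and prediction bands
#'
#' Ordinary least squares of `y` on `x` with the classical bands:
#' half-width at `x0` is `t(1 - alpha/2, n - 2) * s * sqrt(q + 1/n +
#' (x0 - xbar)^2 / Sxx)` with `q = 0` for the band on the regression mean
#' and `q = 1` for the prediction band on a new observation.
#'
#' @param x,y Numeric vectors; pairs with missing values are dropped.
#' @return An object of class `"ols_line"`: list with `slope`,
#'   `intercept`, `sigma` (residual SD), `n`, `x_mean`, `sxx`, `df`,
#'   `r_squared` and `band(x0, level, type)`.
#' @examples
#' fit <- ols_line(1:10, 2 * (1:10) + rnorm(10))
#' fit$band(5, type = "confidence")
#' @export
ols_line <- function(x, y) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3L) stop("ols_line() needs at least 3 complete pairs")
  if (length(unique(x)) == 1L) stop("x is constant; slope undefined")
  xb <- mean(x); yb <- mean(y)
  sxx <- sum((x - xb)^2)
  slope <- sum((x - xb) * (y - yb)) / sxx
  intercept <- yb - slope * xb
  res <- y - intercept - slope * x
  df <- n - 2L
  sigma <- sqrt(sum(res^2) / df)
  sst <- sum((y - yb)^2)
  fit <- list(
    slope = slope, intercept = intercept, sigma = sigma, n = n,
    x_mean = xb, sxx = sxx, df = df,
    r_squared = if (sst > 0) 1 - sum(res^2) / sst else NA_real_
  )
  fit$band <- function(x0, level = 0.95, type = c("confidence", "prediction")) {
    type <- match.arg(type)
    q <- if (type == "prediction") 1 else 0
    tq <- stats::qt(1 - (1 - level) / 2, df)
    tq * sigma * sqrt(q + 1 / n + (x0 - xb)^2 / sxx)
  }
  class(fit) <- "ols_line"
  fit
}

#' @export
print.ols_line <- function(x, ...) {
  cat(sprintf("y = %.4f x + %.4f  (n = %d, residual SD = %.4f, R^2 = %.3f)\n",
              x$slope, x$intercept, x$n, x$sigma, x$r_squared))
  invisible(x)
}

# significance stars at the conventional thresholds
significance_stars <- function(p) {
  cut(p, breaks = c(-Inf, 1e-4, 1e-3, 1e-2, 5e-2, Inf),
      labels = c("****", "***", "**", "*", ""), right = FALSE)
}
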