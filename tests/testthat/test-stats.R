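test_that("spearman_cor matches rank-product definition and exact enumeration", {
  expect_equal(spearman_cor(1:6, 1:6)$rho, 1)
  expect_equal(spearman_cor(1:6, 6:1)$rho, -1)
  set.seed(11)
  for (i in 1:6) {
    n <- sample(4:7, 1)
    x <- rnorm(n)
    y <- if (i %% 2 == 0) rnorm(n) else sample(c(1, 1, 2:(n - 1)))  # ties too
    got <- spearman_cor(x, y)
    expect_equal(got$rho, oracle_spearman_rho(x, y), tolerance = 1e-12)
    expect_equal(got$p, oracle_spearman_p(x, y), tolerance = 1e-12)
  }
})

test_that("spearman_cor is invariant under strictly monotone transforms", {
  set.seed(12)
  x <- rnorm(15); y <- x + rnorm(15)
  a <- spearman_cor(x, y)
  b <- spearman_cor(exp(x), y^3 + 10 * y)
  expect_equal(a$rho, b$rho)
  expect_equal(a$p, b$p)
})

test_that("spearman_cor agrees with cor() ranks and flags degenerate input", {
  set.seed(13)
  x <- rnorm(30); y <- rnorm(30)
  expect_equal(spearman_cor(x, y)$rho, cor(x, y, method = "spearman"))
  res <- spearman_cor(rep(1, 5), 1:5)
  expect_true(is.na(res$rho))
  expect_error(spearman_cor(1:2, 2:1), "at least 3")
})

test_that("wilcoxon_signed_rank is exact: enumeration oracle, zeros, ties", {
  # all-positive differences, n = 8: two-sided p = 2 / 2^8
  expect_equal(wilcoxon_signed_rank(rep(1.5, 8))$p, 2 / 256)
  set.seed(21)
  for (i in 1:6) {
    n <- sample(5:9, 1)
    d <- round(rnorm(n), if (i %% 2 == 0) 0 else 3)  # tied magnitudes too
    d <- d[d != 0]
    if (length(d) < 2) next
    expect_equal(wilcoxon_signed_rank(d)$p, oracle_signrank_p(d),
                 tolerance = 1e-12)
  }
  # agrees with the reference implementation when no ties/zeros
  x <- c(2.1, -0.4, 1.7, 3.2, -1.1, 0.6, 2.9, -2.4)
  expect_equal(wilcoxon_signed_rank(x)$p,
               wilcox.test(x, exact = TRUE)$p.value)
  expect_message(res <- wilcoxon_signed_rank(c(0, 0, 0)), "zero")
  expect_equal(res$p, 1)
  expect_equal(suppressMessages(wilcoxon_signed_rank(c(1, 2, 3), c(1, 2, 3)))$p, 1)
})

test_that("mann_whitney: exact null, symmetry, degenerate groups", {
  # fully separated groups of 4: exact two-sided p = 2 / choose(8, 4)
  expect_equal(mann_whitney(1:4, 11:14)$p, 2 / 70)
  set.seed(31)
  for (i in 1:6) {
    a <- rnorm(sample(3:6, 1)); b <- rnorm(sample(3:6, 1))
    expect_equal(mann_whitney(a, b)$p, oracle_mannwhitney_p(a, b),
                 tolerance = 1e-12)
    expect_equal(mann_whitney(a, b)$p, mann_whitney(b, a)$p)
  }
  # tie-corrected normal approximation agrees with the reference
  a <- c(1, 2, 2, 3, 5, 7, 7, 9, 11, 12)
  b <- c(2, 4, 4, 6, 8, 8, 10, 10, 13, 15)
  expect_equal(mann_whitney(a, b)$p,
               suppressWarnings(wilcox.test(a, b, correct = TRUE)$p.value),
               tolerance = 1e-10)
  expect_equal(mann_whitney(c(1, 2, 3), c(1, 2, 3))$p, 1)
  expect_error(mann_whitney(numeric(0), 1:3), "nonempty")
})

test_that("ols_line solves the normal equations with classical t bands", {
  x <- c(0.3, 1.7, 2.2, 4.9)
  y <- c(1.1, 0.4, 2.6, 3.3)
  fit <- ols_line(x, y)
  o <- oracle_ols(x, y)
  expect_equal(fit$slope, o$slope, tolerance = 1e-12)
  expect_equal(fit$intercept, o$intercept, tolerance = 1e-12)
  # band half-width from the textbook formula
  n <- 4; xb <- mean(x); sxx <- sum((x - xb)^2)
  s <- sqrt(sum((y - o$intercept - o$slope * x)^2) / (n - 2))
  hw <- qt(0.975, n - 2) * s * sqrt(1 / n + (1 - xb)^2 / sxx)
  expect_equal(fit$band(1), hw, tolerance = 1e-12)
  # collinear data: zero residual, zero band
  fitc <- ols_line(1:5, 2 * (1:5) + 3)
  expect_equal(fitc$sigma, 0)
  expect_equal(fitc$band(10), 0)
  # band is minimal at the mean of x; prediction band is wider
  grid <- seq(-2, 8, by = 0.5)
  expect_equal(grid[which.min(fit$band(grid))], grid[which.min(abs(grid - xb))])
  expect_true(all(fit$band(grid, type = "prediction") > fit$band(grid)))
  expect_error(ols_line(rep(2, 4), 1:4), "constant")
})
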