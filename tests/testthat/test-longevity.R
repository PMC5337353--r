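test_that("composite score multiplies or reciprocates by island direction", {
  expect_equal(composite_score(50, 10, -1), 5)
  expect_equal(round(composite_score(33.2, 83, -1), 1), 0.4)
  expect_equal(composite_score(50, 0.1, +1), 5)
  # homogeneous in SPARC for both directions
  set.seed(81)
  s <- runif(6, 1, 500); m <- runif(6, 5, 95); c <- 3.7
  expect_equal(composite_score(c * s, m, -1), c * composite_score(s, m, -1))
  expect_equal(composite_score(c * s, m, +1), c * composite_score(s, m, +1))
  expect_error(composite_score(50, 0, -1), "positive")
  expect_error(composite_score(-1, 10), "positive")
})

test_that("calibration matches the least-squares oracle and handles collinearity", {
  fit <- calibrate_longevity(c(1, 2, 3, 1.5, 2.5, 1.2, 2.8, 1.7, 2.2, 1.9),
                             10 * c(1, 2, 3, 1.5, 2.5, 1.2, 2.8, 1.7, 2.2, 1.9))
  expect_equal(fit$slope, 10, tolerance = 1e-12)
  expect_equal(fit$intercept, 0, tolerance = 1e-10)
  expect_equal(fit$fit$band(2.2), 0)   # zero-width band on collinear data
  set.seed(82)
  x <- runif(12, 0.5, 20); y <- 18 - 0.8 * x + rnorm(12)
  fit2 <- calibrate_longevity(x, y)
  o <- oracle_ols(x, y)
  expect_equal(coef(fit2)[["slope"]], o$slope, tolerance = 1e-12)
  expect_equal(coef(fit2)[["intercept"]], o$intercept, tolerance = 1e-12)
  expect_equal(residuals(fit2), y - o$intercept - o$slope * x)
  expect_error(calibrate_longevity(rep(2, 10), 1:10), "constant")
  expect_error(calibrate_longevity(1:5, 1:5), "at least")
})

test_that("predict_remaining subtracts the band half-width, clamped at zero", {
  # zero-width band: lower bound equals the point estimate
  s <- c(1, 2, 3, 1.5, 2.5, 1.2, 2.8, 1.7, 2.2, 1.9)
  fit <- calibrate_longevity(s, 22 - 2 * s)
  pr <- predict_remaining(fit, 2)
  expect_equal(pr$pd_bs, 18)
  expect_equal(pr$pd_bs_lower, pr$pd_bs)
  # noisy fit: lower bound = point - half-width (affine oracle), >= 0
  set.seed(83)
  x <- runif(15, 0.5, 12); y <- pmax(0, 20 - 1.6 * x + rnorm(15, 0, 2))
  fit2 <- calibrate_longevity(x, y)
  pr2 <- predict_remaining(fit2, 5)
  expect_equal(pr2$pd_bs_lower, pr2$pd_bs - fit2$fit$band(5))
  grid <- c(2, 8, 11)
  prg <- predict_remaining(fit2, grid)
  expect_true(all(prg$pd_bs_lower <= prg$pd_bs))
  expect_equal(prg$pd_bs_lower,
               pmax(0, prg$pd_bs - fit2$fit$band(grid)))  # clamped at 0
  expect_warning(predict_remaining(fit2, 50), "extrapolates")
  expect_equal(predict(fit2, score = 5), pr2)   # S3 predict method
})

test_that("threshold classification is boundary-inclusive and rank-stable", {
  cl <- threshold_classify(c(0.4, 5, 5.01))
  expect_equal(as.character(cl),
               c("guaranteed-reserve", "guaranteed-reserve", "no-guarantee"))
  # stable under a strictly increasing re-parameterisation
  set.seed(84)
  s <- exp(runif(20, -1, 3))
  expect_equal(threshold_classify(s, 5), threshold_classify(s^2, 25))
  expect_equal(threshold_classify(s, 5), threshold_classify(sqrt(s), sqrt(5)))
  expect_error(threshold_classify(-2), "positive")
})

test_that("six-island scores: directions, CFU-O ranking, degenerate input", {
  sc <- shared_scores()
  res <- score_all_islands(sc$sparc, sc$meth, sc$pd, sc$pd_bs, cfuo = sc$cfuo)
  expect_equal(colnames(res$scores), CPG_ISLANDS)
  expect_equal(unname(res$scores[, "PRAMEF2"]), unname(sc$score))
  # PRAMEF2 score has the strongest CFU-O correlation among the six
  expect_equal(res$summary$island[which.max(abs(res$summary$rho_cfuo))],
               "PRAMEF2")
  # every island score correlates with PD and PD-BS on the default cohort
  expect_true(all(res$summary$p_pd < 0.05))
  expect_true(all(res$summary$p_pdbs < 0.05))
  # single sample: scores returned, correlations undefined
  one <- score_all_islands(sc$sparc[1], sc$meth[1, , drop = FALSE],
                           sc$pd[1], sc$pd_bs[1])
  expect_equal(dim(one$scores), c(1L, 6L))
  expect_true(all(is.na(one$summary$rho_pd)))
})

test_that("noiseless single-donor cohort: composite correlations are exact", {
  # one donor removes lifespan heterogeneity, so with zero noise every
  # island score is exactly monotone in PD (and in PD-BS)
  cfg <- cohort_config(donor_ages = 30, seed = 5, lifespan_sd = 0,
                       p0_pd_sd = 0, expression_noise_cv = 0,
                       methylation_noise_sd = 0, cfuo_sd = 0, ca_sd = 0,
                       telomere_bp_sd = 0, telomere_shift_sdlog = 0,
                       ct_hprt_sd = 0, donor_effects = 0,
                       n_expression_samples = 6L, n_methylation_samples = 6L,
                       n_telomere_pairs = 4L, n_telomere_donors = 1L)
  co <- generate_cohort(cfg)
  cul <- annotate_culture(co$culture)
  key <- cul[!is.na(cul$pd_bs), ]
  basal <- panel_quantify(co$expression_ct)
  basal <- basal[basal$condition == "basal", ]
  sparc <- basal[basal$gene == "SPARC", ]
  mw <- msclong:::meth_wide(co$methylation)
  common <- intersect(sparc$sample_id, rownames(mw))
  pd <- key$accrued_pd[match(common, key$sample_id)]
  pdbs <- key$pd_bs[match(common, key$sample_id)]
  res <- score_all_islands(sparc$rel_expr[match(common, sparc$sample_id)],
                           mw[common, ], pd, pdbs)
  expect_true(all(abs(res$summary$rho_pd) == 1))
  expect_true(all(abs(res$summary$rho_pdbs) == 1))
})

test_that("model methods print, summarise and plot without error", {
  sc <- shared_scores()
  fit <- calibrate_longevity(sc$score, sc$pd_bs, cfuo = sc$cfuo, pd = sc$pd)
  expect_output(print(fit), "Spearman rho\\(score, PD-BS\\)")
  expect_output(summary(fit), "lower 95% bound")
  expect_named(coef(fit), c("intercept", "slope", "cfuo_intercept", "cfuo_slope"))
  pdf(NULL)
  on.exit(dev.off())
  expect_no_error(plot(fit))
})
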