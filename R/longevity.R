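#' Composite longevity score from SPARC expression and CpG methylation
#'
#' The score couples SPARC relative mRNA expression with the methylation
#' percent of one CpG island: islands whose methylation rises with accrued
#' PD (CASR, GRM7) multiply, islands whose methylation falls with PD
#' (PRAMEF2, SELP, CASP14, KRTAP13-3) enter reciprocally. The headline
#' score is `SPARC x 1/PRAMEF2`.
#'
#' @param sparc SPARC relative expression (> 0).
#' @param island Methylation percent (> 0) of the chosen island.
#' @param direction `+1` (multiply; island rises with PD) or `-1`
#'   (reciprocal; island falls with PD). Default `-1`, the PRAMEF2 case.
#' @return Dimensionless score (> 0).
#' @examples
#' composite_score(50, 10)        # 5, the threshold boundary
#' composite_score(50, 0.1, +1)   # 5
#' @export
composite_score <- function(sparc, island, direction = -1) {
  if (!all(direction %in% c(-1, 1))) stop("direction must be +1 or -1")
  if (any(!is.finite(sparc)) || any(sparc <= 0))
    stop("sparc must be positive")
  if (any(!is.finite(island)) || any(island <= 0))
    stop("island methylation must be positive (reciprocal undefined at 0)")
  n <- max(length(sparc), length(island))
  direction <- rep_len(direction, n)
  ifelse(direction == 1, sparc * island, sparc / island)
}

#' Island score directions of the composite panel
#'
#' `+1` for islands whose methylation rises with accrued PD (score
#' multiplies), `-1` for islands whose methylation falls (score divides).
#' @export
ISLAND_DIRECTIONS <- c(GRM7 = 1, CASR = 1, PRAMEF2 = -1, SELP = -1,
                       CASP14 = -1, `KRTAP13-3` = -1)

#' Calibrate the composite score against remaining lifespan and potency
#'
#' Fits the prediction model at the heart of the package: ordinary least
#' squares of PD-BS (and optionally CFU-O) on the composite score, with
#' t-based 95% bands, plus Spearman correlations of the score against
#' PD-BS, PD and CFU-O. The fitted object predicts remaining lifespan
#' (and osteogenic capacity) for new scores via [predict_remaining()] /
#' `predict()`.
#'
#' @param score Composite scores (see [composite_score()]).
#' @param pd_bs Remaining lifespan (PD before senescence) per sample.
#' @param cfuo Optional CFU-O per 500 MSCs per sample.
#' @param pd Optional accrued PD per sample (reported correlation only).
#' @param min_points Minimum complete points (default 10).
#' @param band Default band type for prediction: `"confidence"` (band on
#'   the regression mean; calibration uncertainty) or `"prediction"` (band
#'   on a new observation; where individual points fall).
#' @return Object of class `"longevity_model"`.
#' @examples
#' set.seed(1)
#' s <- exp(runif(20, -1, 3.5))
#' fit <- calibrate_longevity(s, 18 - 3 * log(s) + rnorm(20), pd = 30 - (18 - 3 * log(s)))
#' fit
#' predict(fit, score = 5)
#' @export
calibrate_longevity <- function(score, pd_bs, cfuo = NULL, pd = NULL,
                                min_points = 10L,
                                band = c("confidence", "prediction")) {
  band <- match.arg(band)
  ok <- is.finite(score) & is.finite(pd_bs)
  if (sum(ok) < min_points)
    stop("calibration needs at least ", min_points, " complete points")
  if (length(unique(score[ok])) == 1L) stop("scores are constant; cannot calibrate")
  fit <- ols_line(score[ok], pd_bs[ok])
  rho_pdbs <- spearman_cor(score[ok], pd_bs[ok])
  rho_pd <- if (!is.null(pd)) {
    k <- ok & is.finite(pd); spearman_cor(score[k], pd[k])
  } else NULL
  cfuo_fit <- rho_cfuo <- NULL
  if (!is.null(cfuo)) {
    k <- is.finite(score) & is.finite(cfuo)
    cfuo_fit <- ols_line(score[k], cfuo[k])
    rho_cfuo <- spearman_cor(score[k], cfuo[k])
  }
  structure(list(
    slope = fit$slope, intercept = fit$intercept, fit = fit,
    cfuo_slope = if (!is.null(cfuo_fit)) cfuo_fit$slope,
    cfuo_intercept = if (!is.null(cfuo_fit)) cfuo_fit$intercept,
    cfuo_fit = cfuo_fit,
    rho_pdbs = rho_pdbs, rho_pd = rho_pd, rho_cfuo = rho_cfuo,
    n = fit$n, band = band, level = 0.95,
    score_range = range(score[ok]),
    data = data.frame(score = score[ok], pd_bs = pd_bs[ok]),
    call = match.call()
  ), class = "longevity_model")
}

#' Predict remaining lifespan (and osteogenic capacity) from a score
#'
#' Evaluates the calibration line at new composite scores and subtracts
#' the band half-width at that score to give the guaranteed lower bound.
#' Lower bounds are clamped at 0 PD (0 CFU-O); scores outside the
#' calibration range are flagged as extrapolation.
#'
#' @param model A fitted [calibrate_longevity()] model.
#' @param score New composite score(s).
#' @param level Band level (default the model's, 0.95).
#' @param band `"confidence"` or `"prediction"`; default the model's.
#' @return Data frame: `score`, `pd_bs`, `pd_bs_lower`, and if the model
#'   carries a CFU-O line `cfuo`, `cfuo_lower`, plus `extrapolated`.
#' @examples
#' # see calibrate_longevity()
#' @export
predict_remaining <- function(model, score, level = model$level,
                              band = model$band) {
  stopifnot(inherits(model, "longevity_model"))
  pt <- model$intercept + model$slope * score
  hw <- model$fit$band(score, level = level, type = band)
  out <- data.frame(score = score, pd_bs = pt,
                    pd_bs_lower = pmax(0, pt - hw))
  if (!is.null(model$cfuo_fit)) {
    cpt <- model$cfuo_intercept + model$cfuo_slope * score
    chw <- model$cfuo_fit$band(score, level = level, type = band)
    out$cfuo <- cpt
    out$cfuo_lower <- pmax(0, cpt - chw)
  }
  out$extrapolated <- score < model$score_range[1] | score > model$score_range[2]
  if (any(out$extrapolated))
    warning("score(s) outside the calibrated range [",
            signif(model$score_range[1], 3), ", ",
            signif(model$score_range[2], 3), "]; prediction extrapolates")
  out
}

#' @export
predict.longevity_model <- function(object, score, ...) {
  predict_remaining(object, score, ...)
}

#' Classify a composite score against the reserve threshold
#'
#' Scores at or below the threshold (default 5) carry a guaranteed
#' proliferative reserve at the band's confidence level; higher scores
#' offer no such guarantee.
#'
#' @param score Composite score(s) (> 0).
#' @param threshold Decision threshold (default 5; boundary inclusive).
#' @return Factor with levels `"guaranteed-reserve"`, `"no-guarantee"`.
#' @examples
#' threshold_classify(c(0.4, 5, 5.01))
#' @export
threshold_classify <- function(score, threshold = 5) {
  if (any(!is.finite(score)) || any(score <= 0)) stop("scores must be positive")
  factor(ifelse(score <= threshold, "guaranteed-reserve", "no-guarantee"),
         levels = c("guaranteed-reserve", "no-guarantee"))
}

#' Composite scores for all six islands with a correlation summary
#'
#' Computes the SPARC x island score for each panel island (direction per
#' [ISLAND_DIRECTIONS]) and summarises each score's Spearman correlation
#' with accrued PD and PD-BS (and CFU-O when supplied). With fewer than 3
#' samples the scores are still returned but correlations are `NA`.
#'
#' @param sparc SPARC relative expression per sample (> 0).
#' @param methylation Long methylation table (`sample_id`, `island`,
#'   `percent`) covering the same samples, or a samples x islands matrix.
#' @param accrued_pd,pd_bs Per-sample measures aligned with `sparc`.
#' @param cfuo Optional CFU-O per 500 MSCs.
#' @return List with `scores` (samples x islands matrix) and `summary`
#'   (data frame: island, direction, rho_pd, p_pd, rho_pdbs, p_pdbs and
#'   optionally rho_cfuo, p_cfuo).
#' @export
score_all_islands <- function(sparc, methylation, accrued_pd, pd_bs,
                              cfuo = NULL) {
  m <- if (is.matrix(methylation)) methylation else meth_wide(methylation)
  if (length(sparc) != nrow(m))
    stop("sparc and methylation sample counts differ")
  scores <- vapply(colnames(m), function(isl) {
    composite_score(sparc, m[, isl], ISLAND_DIRECTIONS[[isl]])
  }, numeric(length(sparc)))
  scores <- matrix(scores, nrow = length(sparc),
                   dimnames = list(rownames(m), colnames(m)))
  cor_or_na <- function(x, y) {
    ok <- is.finite(x) & is.finite(y)
    if (sum(ok) < 3L) list(rho = NA_real_, p = NA_real_)
    else spearman_cor(x[ok], y[ok])
  }
  summary <- do.call(rbind, lapply(colnames(m), function(isl) {
    a <- cor_or_na(scores[, isl], accrued_pd)
    b <- cor_or_na(scores[, isl], pd_bs)
    row <- data.frame(island = isl, direction = ISLAND_DIRECTIONS[[isl]],
                      rho_pd = a$rho, p_pd = a$p,
                      rho_pdbs = b$rho, p_pdbs = b$p)
    if (!is.null(cfuo)) {
      cc <- cor_or_na(scores[, isl], cfuo)
      row$rho_cfuo <- cc$rho; row$p_cfuo <- cc$p
    }
    row
  }))
  rownames(summary) <- summary$island
  list(scores = scores, summary = summary)
}

#' @export
print.longevity_model <- function(x, ...) {
  cat("Composite-score longevity calibration (n =", x$n, "points)\n")
  cat(sprintf("  PD-BS = %.4f + %.4f x score   (residual SD %.3f PD)\n",
              x$intercept, x$slope, x$fit$sigma))
  if (!is.null(x$cfuo_fit))
    cat(sprintf("  CFU-O = %.4f + %.4f x score   (residual SD %.3f)\n",
                x$cfuo_intercept, x$cfuo_slope, x$cfuo_fit$sigma))
  cat(sprintf("  Spearman rho(score, PD-BS) = %.3f (p = %.3g)\n",
              x$rho_pdbs$rho, x$rho_pdbs$p))
  if (!is.null(x$rho_pd))
    cat(sprintf("  Spearman rho(score, PD)    = %.3f (p = %.3g)\n",
                x$rho_pd$rho, x$rho_pd$p))
  if (!is.null(x$rho_cfuo))
    cat(sprintf("  Spearman rho(score, CFU-O) = %.3f (p = %.3g)\n",
                x$rho_cfuo$rho, x$rho_cfuo$p))
  cat("  Band:", x$band, "at level", x$level, "\n")
  invisible(x)
}

#' @export
summary.longevity_model <- function(object, threshold = 5, ...) {
  pred <- predict_remaining(object, threshold)
  cat("Composite-score longevity model\n")
  print(object)
  cat(sprintf("\nAt score = %g: point estimate %.1f PD-BS, lower %g%% bound %.1f PD-BS\n",
              threshold, pred$pd_bs, 100 * object$level, pred$pd_bs_lower))
  if (!is.null(object$cfuo_fit))
    cat(sprintf("               %.1f CFU-O/500 MSCs, lower bound %.1f\n",
                pred$cfuo, pred$cfuo_lower))
  invisible(object)
}

#' @export
coef.longevity_model <- function(object, ...) {
  out <- c(intercept = object$intercept, slope = object$slope)
  if (!is.null(object$cfuo_fit))
    out <- c(out, cfuo_intercept = object$cfuo_intercept,
             cfuo_slope = object$cfuo_slope)
  out
}

#' @export
residuals.longevity_model <- function(object, ...) {
  with(object$data, pd_bs - (object$intercept + object$slope * score))
}

#' Plot a longevity calibration with its 95% band
#'
#' Scatter of PD-BS against composite score with the fitted line and the
#' model's band (confidence or prediction), plus the decision threshold.
#'
#' @param x A `longevity_model`.
#' @param threshold Decision threshold to mark (default 5).
#' @param band Band type to draw (default the model's).
#' @param ... Passed to [graphics::plot()].
#' @export
plot.longevity_model <- function(x, threshold = 5, band = x$band, ...) {
  d <- x$data
  grid <- seq(min(d$score), max(d$score), length.out = 200)
  pt <- x$intercept + x$slope * grid
  hw <- x$fit$band(grid, level = x$level, type = band)
  graphics::plot(d$score, d$pd_bs, xlab = "composite score",
                 ylab = "PD before senescence",
                 ylim = range(c(d$pd_bs, pt - hw, pt + hw)), ...)
  graphics::lines(grid, pt)
  graphics::lines(grid, pt - hw, lty = 3)
  graphics::lines(grid, pt + hw, lty = 3)
  graphics::abline(v = threshold, col = "grey60", lty = 2)
  invisible(x)
}
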