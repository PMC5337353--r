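#' The six CpG islands of the senescence methylation panel
#' @export
CPG_ISLANDS <- c("GRM7", "CASR", "PRAMEF2", "SELP", "CASP14", "KRTAP13-3")

# long (sample_id, island, percent) -> wide matrix, samples x islands
meth_wide <- function(methylation, islands = CPG_ISLANDS) {
  needed <- c("sample_id", "island", "percent")
  if (!all(needed %in% names(methylation)))
    stop("methylation table needs columns: ", paste(needed, collapse = ", "))
  samples <- unique(methylation$sample_id)
  m <- matrix(NA_real_, length(samples), length(islands),
              dimnames = list(samples, islands))
  idx <- cbind(match(methylation$sample_id, samples),
               match(methylation$island, islands))
  ok <- !is.na(idx[, 2])
  m[idx[ok, , drop = FALSE]] <- methylation$percent[ok]
  m
}

#' Predicted passage number (PPN) from six-CpG methylation
#'
#' Linear clock: `PPN = intercept + sum(weights * percent)` over the six
#' panel islands. The clock coefficients are pluggable -- externally
#' published coefficients can be supplied as a `clock_model`, or a model
#' can be fitted from labelled samples with [fit_clock()].
#'
#' @param record Named numeric vector (or single-row data frame / list) of
#'   methylation percents for all six islands, or a long methylation table
#'   with `sample_id`, `island`, `percent` (one PPN per sample).
#' @param model A `clock_model`: list with `intercept` (passages) and
#'   named `weights` (passages per percent) for all six islands.
#' @return Predicted passage number(s); named by sample for table input.
#' @examples
#' m <- clock_model(intercept = 0,
#'                  weights = c(GRM7 = 0, CASR = 0, PRAMEF2 = 0.1,
#'                              SELP = 0, CASP14 = 0, `KRTAP13-3` = 0))
#' predicted_passage_number(
#'   c(GRM7 = 10, CASR = 20, PRAMEF2 = 50, SELP = 30, CASP14 = 40,
#'     `KRTAP13-3` = 25), m)   # 5
#' @export
predicted_passage_number <- function(record, model) {
  stopifnot(inherits(model, "clock_model"))
  tabular <- is.data.frame(record) &&
    all(c("sample_id", "island") %in% names(record))
  if (tabular) {
    m <- meth_wide(record)
  } else {
    record <- unlist(record)
    m <- matrix(record, 1L, dimnames = list(NULL, names(record)))
  }
  islands <- names(model$weights)
  if (!all(islands %in% colnames(m)) || anyNA(m[, islands]))
    stop("missing island value(s); the clock requires all six islands (no imputation)")
  out <- drop(model$intercept + m[, islands, drop = FALSE] %*% model$weights)
  if (!tabular) unname(out) else out
}

#' Construct a methylation clock model
#'
#' @param intercept Passages.
#' @param weights Named numeric vector, passages per methylation percent,
#'   one entry per panel island.
#' @param provenance Optional character note on where the coefficients
#'   come from (publication, training run, ...).
#' @return Object of class `"clock_model"`.
#' @export
clock_model <- function(intercept, weights, provenance = "user-supplied") {
  if (!all(is.finite(c(intercept, weights))))
    stop("clock coefficients must be finite")
  if (is.null(names(weights)) || any(!nzchar(names(weights))))
    stop("weights must be named by island")
  structure(list(intercept = unname(intercept), weights = weights,
                 provenance = provenance),
            class = "clock_model")
}

#' @export
print.clock_model <- function(x, ...) {
  cat("Six-CpG passage clock (", x$provenance, ")\n", sep = "")
  cat(sprintf("  intercept: %.4f passages\n", x$intercept))
  for (i in names(x$weights))
    cat(sprintf("  %-10s %+.5f passages/%%\n", i, x$weights[[i]]))
  invisible(x)
}

#' Fit a linear six-CpG passage clock by ordinary least squares
#'
#' Regresses known passage numbers on the six island methylation percents.
#' If the design is rank deficient (collinear islands or too few distinct
#' samples) the fit falls back to a PRAMEF2-only model with a warning.
#'
#' @param methylation Long methylation table (`sample_id`, `island`,
#'   `percent`).
#' @param passage Named numeric vector of passage labels (names =
#'   sample_id), or unnamed in the order of unique sample ids.
#' @param min_samples Minimum labelled samples (default 8).
#' @return A `clock_model` with training provenance.
#' @export
fit_clock <- function(methylation, passage, min_samples = 8L) {
  m <- meth_wide(methylation)
  if (!is.null(names(passage))) {
    m <- m[names(passage)[names(passage) %in% rownames(m)], , drop = FALSE]
    passage <- passage[rownames(m)]
  }
  if (nrow(m) < min_samples)
    stop("fit_clock() needs at least ", min_samples, " labelled samples")
  if (nrow(m) != length(passage)) stop("labels do not match samples")
  df <- as.data.frame(m, check.names = FALSE)
  df$.passage <- as.numeric(passage)
  fit <- stats::lm(.passage ~ ., data = df)
  cf <- stats::coef(fit)
  if (anyNA(cf)) {
    warning("rank-deficient design; falling back to a PRAMEF2-only clock")
    fit <- stats::lm(.passage ~ PRAMEF2, data = df)
    w <- stats::setNames(numeric(ncol(m)), colnames(m))
    w["PRAMEF2"] <- stats::coef(fit)[["PRAMEF2"]]
    return(clock_model(stats::coef(fit)[[1L]], w,
                       provenance = sprintf("PRAMEF2-only OLS fallback (n = %d)", nrow(m))))
  }
  clock_model(cf[[1L]], stats::setNames(cf[-1L], colnames(m)),
              provenance = sprintf("six-island OLS fit (n = %d)", nrow(m)))
}

#' Island-level correlation report against PD and PD-BS
#'
#' Per-island Spearman correlations of methylation percent against accrued
#' PD and against PD-BS, mirroring the usual two-column reporting of
#' expansion studies. Pairs with a missing value are deleted pairwise.
#'
#' @param methylation Long methylation table (`sample_id`, `island`,
#'   `percent`).
#' @param accrued_pd,pd_bs Named numeric vectors (names = sample_id) or
#'   vectors aligned with the unique sample ids of `methylation`.
#' @param min_pairs Minimum paired observations per island (default 5).
#' @return Data frame with one row per island: `rho_pd`, `p_pd`,
#'   `rho_pdbs`, `p_pdbs`, `n`. Islands with constant methylation get `NA`
#'   correlations.
#' @export
island_report <- function(methylation, accrued_pd, pd_bs, min_pairs = 5L) {
  m <- meth_wide(methylation)
  accrued_pd <- align_by_sample(accrued_pd, rownames(m), "accrued_pd")
  pd_bs <- align_by_sample(pd_bs, rownames(m), "pd_bs")
  rows <- lapply(colnames(m), function(isl) {
    v <- m[, isl]
    ok <- is.finite(v)
    if (sum(ok & is.finite(accrued_pd)) < min_pairs)
      stop("fewer than ", min_pairs, " paired observations for island ", isl)
    if (length(unique(v[ok])) == 1L) {
      return(data.frame(island = isl, rho_pd = NA_real_, p_pd = NA_real_,
                        rho_pdbs = NA_real_, p_pdbs = NA_real_, n = sum(ok)))
    }
    a <- spearman_cor(v, accrued_pd)
    b <- spearman_cor(v, pd_bs)
    data.frame(island = isl, rho_pd = a$rho, p_pd = a$p,
               rho_pdbs = b$rho, p_pdbs = b$p, n = a$n)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- out$island
  out
}

# align a possibly-named vector of per-sample values with sample ids
align_by_sample <- function(v, sample_ids, what) {
  if (!is.null(names(v))) {
    if (!all(sample_ids %in% names(v)))
      stop(what, " lacks values for some samples")
    return(v[sample_ids])
  }
  if (length(v) != length(sample_ids))
    stop(what, " length does not match the number of samples")
  v
}
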