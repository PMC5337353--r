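#' Telomere to single-copy-gene (T/S) ratio from qPCR Cts
#'
#' Relative telomere content: amplification of telomere repeats (T)
#' against the single copy gene 36B4 (S), `2^-((ct_t - ct_s) -
#' calibrator_delta)`. The calibrator delta (cycles) re-expresses samples
#' relative to a plate calibrator; 0 leaves the ratio plate-relative.
#'
#' @param ct_t Telomere-repeat Ct (cycles).
#' @param ct_s 36B4 Ct (cycles).
#' @param calibrator_delta Calibrator (ct_t - ct_s), cycles; default 0.
#' @return Dimensionless T/S ratio.
#' @examples
#' ts_ratio(20, 21)   # 2
#' @export
ts_ratio <- function(ct_t, ct_s, calibrator_delta = 0) {
  if (any(!is.finite(ct_t)) || any(!is.finite(ct_s)))
    stop("missing Ct; T/S ratio undefined")
  2^(-((ct_t - ct_s) - calibrator_delta))
}

#' Convert a T/S ratio to telomere length in base pairs
#'
#' Affine conversion against an external standard curve: `bp = slope * ts
#' + intercept`. The published standard-curve coefficients are assay
#' specific, so they are arguments (the package defaults map T/S of
#' 0.5-2.5 onto roughly 3.6-6.7 kb, a plausible somatic range).
#'
#' @param ts T/S ratio(s).
#' @param slope Base pairs per T/S unit (> 0), default 1540.
#' @param intercept Base pairs at T/S = 0, default 2830.
#' @return Telomere length in bp. Nonpositive results trigger a warning
#'   (implausible) but are returned.
#' @examples
#' ts_to_bp(1.7)   # 5448 bp
#' @export
ts_to_bp <- function(ts, slope = 1540, intercept = 2830) {
  if (!is.finite(slope) || slope <= 0) stop("slope must be positive")
  bp <- slope * ts + intercept
  if (any(bp <= 0, na.rm = TRUE))
    warning("nonpositive telomere length(s); check the conversion coefficients")
  bp
}

#' Paired telomere shift between undifferentiated and osteoinduced samples
#'
#' Median within-pair difference in telomere length (undifferentiated
#' minus osteoinduced, bp) with a two-sided Wilcoxon signed-rank p-value
#' (exact for up to 25 pairs, see [wilcoxon_signed_rank()]).
#'
#' @param undiff,osteo Paired telomere lengths in bp (same length, same
#'   order).
#' @param min_pairs Minimum pairs required for a p-value (default 6);
#'   below this the median is still returned with `p = NA`.
#' @return List with `median_shift` (bp), `p`, and `n` pairs.
#' @examples
#' paired_shift(c(6000, 6100, 6050, 5900, 6210, 6000),
#'              c(5900, 6010, 5940, 5820, 6100, 5910))
#' @export
paired_shift <- function(undiff, osteo, min_pairs = 6L) {
  if (length(undiff) != length(osteo))
    stop("unmatched pairs: undiff and osteo lengths differ")
  keep <- is.finite(undiff) & is.finite(osteo)
  d <- undiff[keep] - osteo[keep]
  n <- length(d)
  if (n == 0L) stop("no complete pairs")
  med <- stats::median(d)
  p <- if (n >= min_pairs) {
    if (all(d == 0)) 1 else wilcoxon_signed_rank(d)$p
  } else NA_real_
  list(median_shift = med, p = p, n = n)
}
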