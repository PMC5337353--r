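#' Population doublings achieved by the primary (p0) culture
#'
#' The p0 culture is seeded from a marrow aspirate; its doubling count is
#' `log2(cell count at harvest / CFU-F count at seeding)`, with the
#' colony-forming unit-fibroblast (CFU-F) count standing in for the number
#' of clonogenic cells actually seeded.
#'
#' @param cell_count Cells harvested (day 21), > 0.
#' @param cfu_f CFU-F colonies at day 0, >= 1.
#' @return Population doublings (PD).
#' @examples
#' p0_population_doublings(1024, 1)   # 10 PD
#' @export
p0_population_doublings <- function(cell_count, cfu_f) {
  if (any(!is.finite(cell_count)) || any(cell_count <= 0))
    stop("cell_count must be positive and finite")
  if (any(!is.finite(cfu_f)) || any(cfu_f < 1))
    stop("cfu_f must be >= 1 (a culture cannot be seeded from zero colonies)")
  log2(cell_count / cfu_f)
}

#' Accrue population doublings over a passage series
#'
#' Running total of per-passage PD gains for one donor. Records must be
#' ordered by contiguous passage index starting at 0 (the p0 culture).
#'
#' @param pd_gain Numeric vector of per-passage PD gains; element 1 is the
#'   p0 gain (from [p0_population_doublings()]).
#' @param passage Optional integer passage indices used to check
#'   contiguity (default `0:(length(pd_gain) - 1)`).
#' @return Numeric vector of accrued PD per timepoint.
#' @examples
#' accrue(c(10, 3, 2))   # 10 13 15
#' @export
accrue <- function(pd_gain, passage = seq_along(pd_gain) - 1L) {
  if (anyNA(pd_gain)) stop("pd_gain contains missing values")
  if (length(passage) != length(pd_gain) ||
      !isTRUE(all.equal(as.integer(passage), seq_along(pd_gain) - 1L)))
    stop("passage indices must be contiguous 0,1,2,... without gaps or duplicates")
  cumsum(pd_gain)
}

#' Detect the senescent passage of a culture series
#'
#' A passage is senescent when it achieves less than `threshold` (default
#' 1) PD per `window` (default 7) days; the previous passage is the
#' presenescent one. Gains are normalised to the window before the strict
#' comparison, i.e. `rate = pd_gain * window / days < threshold`.
#'
#' @param pd_gain Per-passage PD gains.
#' @param days Per-passage elapsed days (> 0).
#' @param threshold PD per window below which a passage is senescent.
#' @param window Normalisation window in days.
#' @return List with `senescent` and `presenescent` passage indices
#'   (0-based, `NA` if no passage qualifies) and the normalised `rate`
#'   vector.
#' @examples
#' detect_senescence(c(5, 3, 0.8), c(7, 7, 7))   # senescent at index 2
#' @export
detect_senescence <- function(pd_gain, days, threshold = 1, window = 7) {
  if (any(!is.finite(days)) || any(days <= 0)) stop("days must be positive")
  if (length(pd_gain) != length(days)) stop("pd_gain and days lengths differ")
  rate <- pd_gain * window / days
  idx <- which(rate < threshold)
  if (length(idx) == 0L)
    return(list(senescent = NA_integer_, presenescent = NA_integer_, rate = rate))
  s <- idx[1L] - 1L                       # 0-based passage index
  list(senescent = s,
       presenescent = if (s >= 1L) s - 1L else NA_integer_,
       rate = rate)
}

#' Population doublings before senescence (PD-BS) per timepoint
#'
#' The culture's total lifespan is taken as the PD accrued at the
#' presenescent passage (the last passage before the one achieving < 1
#' PD/7 days); molecular data from the senescent passage itself are not
#' used. PD-BS at timepoint k is then `lifespan - accrued_pd[k]`, so the
#' presenescent passage has PD-BS 0.
#'
#' @param accrued_pd Accrued PD per timepoint (nondecreasing).
#' @param senescent 0-based senescent passage index, e.g. from
#'   [detect_senescence()]. If the series has a single record it is
#'   treated as already (pre)senescent and PD-BS is 0.
#' @return Numeric vector of PD-BS; timepoints at or beyond the senescent
#'   passage are `NA` (PD-BS is only defined up to the presenescent
#'   passage).
#' @examples
#' pd_before_senescence(c(10, 20, 29), senescent = 2)   # 10 0 NA
#' @export
pd_before_senescence <- function(accrued_pd, senescent) {
  n <- length(accrued_pd)
  if (n == 1L) return(0)
  if (is.na(senescent))
    stop("senescence not detected; PD-BS unavailable for this series")
  if (senescent < 1L || senescent > n - 1L)
    stop("senescent index out of range")
  lifespan <- accrued_pd[senescent]       # presenescent passage, 1-based = senescent
  out <- lifespan - accrued_pd
  out[seq_len(n) > senescent] <- NA_real_ # senescent passage and beyond
  out
}

#' Annotate a culture log with accrued PD, senescence and PD-BS
#'
#' Takes a long culture log (one row per donor passage) and adds the
#' derived columns used downstream: `pd_gain` for p0 computed from
#' `cell_count`/`cfu_f` where missing, `accrued_pd`, the per-donor
#' senescence flags, `lifespan` (accrued PD at the presenescent passage)
#' and `pd_bs`.
#'
#' @param culture Data frame with columns `donor_id`, `passage`, `days`,
#'   `pd_gain`, and for passage 0 `cell_count` and `cfu_f`.
#' @param threshold,window Senescence rule, see [detect_senescence()].
#' @return The input with columns `accrued_pd`, `rate`, `senescent`
#'   (logical), `presenescent` (logical), `lifespan`, `pd_bs` added, and a
#'   `sample_id` column (`<donor>_p<passage>`) if absent.
#' @export
annotate_culture <- function(culture, threshold = 1, window = 7) {
  needed <- c("donor_id", "passage", "days", "pd_gain")
  missing_cols <- setdiff(needed, names(culture))
  if (length(missing_cols))
    stop("culture log lacks columns: ", paste(missing_cols, collapse = ", "))
  parts <- split(culture, culture$donor_id)
  out <- lapply(parts, function(d) {
    d <- d[order(d$passage), , drop = FALSE]
    if (anyNA(d$pd_gain)) {
      i0 <- which(d$passage == 0 & is.na(d$pd_gain))
      if (length(i0))
        d$pd_gain[i0] <- p0_population_doublings(d$cell_count[i0], d$cfu_f[i0])
      if (anyNA(d$pd_gain)) stop("pd_gain missing beyond passage 0 for donor ",
                                 d$donor_id[1])
    }
    d$accrued_pd <- accrue(d$pd_gain, d$passage)
    sen <- detect_senescence(d$pd_gain, d$days, threshold, window)
    d$rate <- sen$rate
    d$senescent <- !is.na(sen$senescent) & d$passage == sen$senescent
    d$presenescent <- !is.na(sen$presenescent) & d$passage == sen$presenescent
    if (!is.na(sen$senescent)) {
      d$lifespan <- d$accrued_pd[sen$senescent]   # 1-based row of presenescent
      d$pd_bs <- pd_before_senescence(d$accrued_pd, sen$senescent)
    } else {
      d$lifespan <- NA_real_
      d$pd_bs <- NA_real_
    }
    d
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  if (!"sample_id" %in% names(res))
    res$sample_id <- paste0(res$donor_id, "_p", res$passage)
  res
}
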