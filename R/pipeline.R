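#' Validate the pipeline's input CSV files
#'
#' Schema and range checks for the five input tables. Report-only: every
#' problem is returned as a row; nothing stops. Severity `"error"` rows
#' would stop [run_pipeline()].
#'
#' @param paths Named list/vector with any of `culture`, `expression`,
#'   `methylation`, `telomere`, `clonal` pointing at CSV files.
#' @param ct_cutoff Detection cutoff used to warn about undetected-heavy
#'   genes.
#' @return Data frame with columns `file`, `row`, `column`, `severity`,
#'   `message` (zero rows when everything is well formed).
#' @export
validate_inputs <- function(paths, ct_cutoff = 40) {
  issues <- list()
  add <- function(file, row, column, severity, message) {
    issues[[length(issues) + 1L]] <<- data.frame(
      file = file, row = row, column = column,
      severity = severity, message = message)
  }
  read_or_flag <- function(name, required_cols) {
    if (is.null(paths[[name]]) || is.na(paths[[name]])) return(NULL)
    if (!file.exists(paths[[name]])) {
      add(name, NA_integer_, NA_character_, "error", "file does not exist")
      return(NULL)
    }
    d <- utils::read.csv(paths[[name]], stringsAsFactors = FALSE)
    missing <- setdiff(required_cols, names(d))
    if (length(missing)) {
      add(name, NA_integer_, paste(missing, collapse = ","), "error",
          "missing required column(s)")
      return(NULL)
    }
    d
  }
  check_range <- function(d, name, column, lo, hi, allow_na = TRUE) {
    v <- d[[column]]
    bad <- which(!is.na(v) & (!is.finite(v) | v < lo | v > hi))
    if (!allow_na) bad <- union(bad, which(is.na(v)))
    for (r in bad)
      add(name, r, column, "error",
          sprintf("value %s outside [%g, %g]", format(v[r]), lo, hi))
  }
  cul <- read_or_flag("culture", c("donor_id", "passage", "days", "pd_gain"))
  if (!is.null(cul)) {
    check_range(cul, "culture", "days", 1e-9, Inf, allow_na = FALSE)
    check_range(cul, "culture", "passage", 0, Inf, allow_na = FALSE)
    if ("cfu_f" %in% names(cul)) check_range(cul, "culture", "cfu_f", 1, Inf)
    if ("cell_count" %in% names(cul))
      check_range(cul, "culture", "cell_count", 1, Inf)
  }
  expr <- read_or_flag("expression", c("sample_id", "gene", "condition", "ct"))
  if (!is.null(expr)) {
    check_range(expr, "expression", "ct", 1e-9, 60)
    bad_cond <- which(!expr$condition %in% c("basal", "osteoinduced"))
    for (r in bad_cond)
      add("expression", r, "condition", "error",
          "condition must be 'basal' or 'osteoinduced'")
    undet <- tapply(!is.finite(expr$ct) | expr$ct >= ct_cutoff, expr$gene, mean)
    for (g in names(undet)[undet > 0.5 & names(undet) != "HPRT"])
      add("expression", NA_integer_, "ct", "warning",
          sprintf("gene %s undetected in %.0f%% of wells", g, 100 * undet[[g]]))
  }
  met <- read_or_flag("methylation", c("sample_id", "island", "percent"))
  if (!is.null(met)) check_range(met, "methylation", "percent", 0, 100,
                                 allow_na = FALSE)
  tel <- read_or_flag("telomere", c("pair_id", "state", "ct_t", "ct_s"))
  if (!is.null(tel)) {
    check_range(tel, "telomere", "ct_t", 1e-9, 60, allow_na = FALSE)
    check_range(tel, "telomere", "ct_s", 1e-9, 60, allow_na = FALSE)
  }
  clo <- read_or_flag("clonal", c("sample_id", "cfu_o", "ca"))
  if (!is.null(clo)) {
    check_range(clo, "clonal", "cfu_o", 0, Inf)
    check_range(clo, "clonal", "ca", 0, Inf)
  }
  if (length(issues) == 0L)
    return(data.frame(file = character(), row = integer(),
                      column = character(), severity = character(),
                      message = character()))
  do.call(rbind, issues)
}

#' Run the full longevity-prediction pipeline
#'
#' Either loads the five input CSVs (`inputs` a named list of paths) or
#' simulates a synthetic cohort (`inputs = NULL`), then runs every stage:
#' culture accounting, panel quantification, island report, passage
#' clock, marker screening, composite scoring, calibration and prediction
#' at the decision threshold. All module outputs plus a manifest are
#' written to `out_dir` when given. The pipeline is a pure function of
#' (inputs, config, seed).
#'
#' @param inputs `NULL` (simulate) or a named list with paths `culture`,
#'   `expression`, `methylation`, `telomere`, `clonal`.
#' @param out_dir Optional output directory for the report bundle.
#' @param config A [cohort_config()] used when simulating (also carries
#'   the seed).
#' @param ct_cutoff,score_threshold,p_cut,rho_strong Pipeline thresholds:
#'   detection cutoff (cycles), composite-score decision threshold,
#'   candidature p-value, strong-candidate |rho| vs PD-BS.
#' @param ts_slope,ts_intercept T/S-to-bp conversion coefficients.
#' @param clock Optional external [clock_model()]; default fits one from
#'   the methylation table and culture-derived passage labels.
#' @return List of class `"msclong_pipeline"` with elements `culture`,
#'   `expression`, `islands`, `clock`, `ppn`, `candidates`, `induction`,
#'   `folds`, `scores`, `model`, `prediction`, `telomere`, `groups` and
#'   `manifest`.
#' @export
run_pipeline <- function(inputs = NULL, out_dir = NULL,
                         config = default_config(),
                         ct_cutoff = 40, score_threshold = 5,
                         p_cut = 0.05, rho_strong = 0.6,
                         ts_slope = 1540, ts_intercept = 2830,
                         clock = NULL) {
  if (is.null(inputs)) {
    cohort <- generate_cohort(config)
    tabs <- list(culture = cohort$culture,
                 expression = cohort$expression_ct,
                 methylation = cohort$methylation,
                 telomere = cohort$telomere,
                 clonal = cohort$clonal)
  } else {
    issues <- validate_inputs(inputs, ct_cutoff = ct_cutoff)
    if (any(issues$severity == "error")) {
      stop("input validation failed:\n",
           paste(utils::capture.output(print(issues[issues$severity == "error", ])),
                 collapse = "\n"))
    }
    tabs <- lapply(inputs, function(p) utils::read.csv(p, stringsAsFactors = FALSE))
  }

  culture <- annotate_culture(tabs$culture)
  cul_key <- culture[!is.na(culture$pd_bs),
                     c("sample_id", "passage", "accrued_pd", "pd_bs", "lifespan")]

  expr <- panel_quantify(tabs$expression, ct_cutoff = ct_cutoff)
  basal <- expr[expr$condition == "basal", ]
  measures <- merge(cul_key, stats::aggregate(
    tabs$clonal[, c("cfu_o", "ca")],
    by = list(sample_id = tabs$clonal$sample_id), FUN = mean),
    by = "sample_id")
  names(measures)[names(measures) == "accrued_pd"] <- "pd"
  names(measures)[names(measures) == "cfu_o"] <- "cfuo"

  # methylation stage
  meth <- tabs$methylation
  msamples <- unique(meth$sample_id)
  midx <- match(msamples, cul_key$sample_id)
  if (anyNA(midx)) stop("methylation samples missing from the culture log")
  m_pd <- stats::setNames(cul_key$accrued_pd[midx], msamples)
  m_pdbs <- stats::setNames(cul_key$pd_bs[midx], msamples)
  islands <- island_report(meth, m_pd, m_pdbs)
  if (is.null(clock)) {
    m_pass <- stats::setNames(cul_key$passage[midx], msamples)
    clock <- fit_clock(meth, m_pass)
  }
  ppn <- predicted_passage_number(meth, clock)

  # marker screen
  candidates <- screen_markers(basal, measures, p_cut = p_cut,
                               rho_strong = rho_strong)
  induction <- induction_table(expr, p_cut = p_cut)
  folds <- presenescence_fold(stage_pairs(basal, culture), p_cut = p_cut)

  # composite score on samples having both SPARC and PRAMEF2
  sparc <- basal[basal$gene == "SPARC" & is.finite(basal$rel_expr), ]
  mw <- meth_wide(meth)
  common <- intersect(sparc$sample_id, rownames(mw))
  score <- composite_score(sparc$rel_expr[match(common, sparc$sample_id)],
                           mw[common, "PRAMEF2"], direction = -1)
  sc_pd <- cul_key$accrued_pd[match(common, cul_key$sample_id)]
  sc_pdbs <- cul_key$pd_bs[match(common, cul_key$sample_id)]
  sc_cfuo <- measures$cfuo[match(common, measures$sample_id)]
  model <- calibrate_longevity(score, sc_pdbs, cfuo = sc_cfuo, pd = sc_pd)
  prediction <- predict_remaining(model, score_threshold)
  groups <- mann_whitney(sc_pdbs[score <= score_threshold],
                         sc_pdbs[score > score_threshold])

  # telomere stage
  tel <- tabs$telomere
  tel$bp <- ts_to_bp(ts_ratio(tel$ct_t, tel$ct_s), ts_slope, ts_intercept)
  und <- tel[tel$state == "undifferentiated", ]
  ost <- tel[tel$state == "osteoinduced", ]
  pid <- intersect(und$pair_id, ost$pair_id)
  telomere <- paired_shift(und$bp[match(pid, und$pair_id)],
                           ost$bp[match(pid, ost$pair_id)])

  res <- structure(list(
    culture = culture, expression = expr, islands = islands,
    clock = clock, ppn = ppn, candidates = candidates,
    induction = induction, folds = folds,
    scores = data.frame(sample_id = common, score = score,
                        pd_bs = sc_pdbs,
                        class = threshold_classify(score, score_threshold)),
    model = model, prediction = prediction, groups = groups,
    telomere = telomere,
    manifest = list(package = "msclong",
                    version = as.character(utils::packageVersion("msclong")),
                    seed = config$seed,
                    simulated = is.null(inputs),
                    thresholds = list(ct_cutoff = ct_cutoff,
                                      score_threshold = score_threshold,
                                      p_cut = p_cut, rho_strong = rho_strong))
  ), class = "msclong_pipeline")
  if (!is.null(out_dir)) write_bundle(res, out_dir)
  res
}

# pair each donor's p0 and presenescent basal expression for fold analysis
stage_pairs <- function(basal, culture) {
  pre_ids <- culture$sample_id[culture$presenescent]
  p0_ids <- culture$sample_id[culture$passage == 0]
  out <- basal[basal$sample_id %in% c(pre_ids, p0_ids), ]
  out$stage <- ifelse(out$sample_id %in% p0_ids, "p0", "presenescent")
  out
}

#' @export
print.msclong_pipeline <- function(x, ...) {
  cat("MSC longevity pipeline run (seed", x$manifest$seed, ")\n\n")
  cat("Top screened candidates:\n")
  print(utils::head(as.data.frame(x$candidates)[,
    c("gene", "rho_pdbs", "gradient", "candidate", "strong")], 3))
  cat("\nIsland correlations (PRAMEF2):\n")
  print(x$islands["PRAMEF2", ])
  cat("\n")
  print(x$model)
  cat(sprintf("\nAt score = %g: %.1f PD-BS (lower bound %.1f)\n",
              x$prediction$score, x$prediction$pd_bs, x$prediction$pd_bs_lower))
  cat(sprintf("Telomere shift on differentiation: median %.0f bp (p = %.3g)\n",
              x$telomere$median_shift, x$telomere$p))
  invisible(x)
}

write_bundle <- function(res, out_dir) {
  ok <- FALSE
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  written <- character()
  on.exit(if (!ok) unlink(written), add = TRUE)   # no partial bundles
  wcsv <- function(d, name) {
    p <- file.path(out_dir, name)
    utils::write.csv(d, p, row.names = FALSE)
    written <<- c(written, p)
  }
  wcsv(res$culture, "annotated_culture.csv")
  wcsv(res$expression, "expression.csv")
  wcsv(res$islands, "island_report.csv")
  wcsv(data.frame(sample_id = names(res$ppn), ppn = unname(res$ppn)),
       "ppn.csv")
  wcsv(as.data.frame(res$candidates), "candidates.csv")
  wcsv(res$induction, "induction.csv")
  wcsv(res$folds, "presenescence_folds.csv")
  wcsv(res$scores, "scores.csv")
  wcsv(res$prediction, "prediction.csv")
  p <- file.path(out_dir, "calibration.json")
  jsonlite::write_json(list(
    slope = res$model$slope, intercept = res$model$intercept,
    cfuo_slope = res$model$cfuo_slope,
    cfuo_intercept = res$model$cfuo_intercept,
    n = res$model$n, band = res$model$band, level = res$model$level,
    rho_pdbs = res$model$rho_pdbs$rho,
    telomere_median_shift_bp = res$telomere$median_shift,
    telomere_p = res$telomere$p,
    manifest = res$manifest
  ), p, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  written <- c(written, p)
  ok <- TRUE
  invisible(written)
}
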