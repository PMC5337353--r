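#' Screen transcripts for association with culture ageing and potency
#'
#' For every gene, Spearman correlations of basal relative expression
#' against four measures -- remaining lifespan (PD-BS), accrued PD, CFU-O
#' and calcium deposition -- plus the expression gradient (OLS slope of
#' relative expression on PD-BS) and the observed expression range.
#' A gene is a `candidate` when it associates with all four measures at
#' `p < p_cut`; it is `strong` when additionally `|rho_pdbs| > rho_strong`.
#' Genes are ranked by (`strong`, |gradient|) descending, so the steepest
#' strong candidate heads the table. Undetected values are excluded
#' pairwise; genes with fewer than `min_pairs` points for any measure are
#' dropped with a message.
#'
#' @param expr Expression table: columns `sample_id`, `gene`, `rel_expr`
#'   (basal condition only).
#' @param measures Data frame with columns `sample_id`, `pd`, `pd_bs`,
#'   `cfuo`, `ca` (one row per sample).
#' @param p_cut Candidature p-value threshold (default 0.05).
#' @param rho_strong Threshold on |rho| against PD-BS for the strong flag
#'   (default 0.6).
#' @param min_pairs Minimum paired points per gene-measure pair (default 5).
#' @return Data frame of class `"candidate_table"`, one row per gene,
#'   ranked; columns `rho_pdbs`, `p_pdbs`, `rho_pd`, `p_pd`, `rho_cfuo`,
#'   `p_cfuo`, `rho_ca`, `p_ca`, `gradient`, `range_min`, `range_max`,
#'   `n`, `candidate`, `strong`.
#' @export
screen_markers <- function(expr, measures, p_cut = 0.05, rho_strong = 0.6,
                           min_pairs = 5L) {
  needed <- c("sample_id", "pd", "pd_bs", "cfuo", "ca")
  if (!all(needed %in% names(measures)))
    stop("measures needs columns: ", paste(needed, collapse = ", "))
  if (anyDuplicated(measures$sample_id)) stop("duplicate sample_id in measures")
  mm <- measures[match(expr$sample_id, measures$sample_id), ]
  genes <- unique(expr$gene)
  rows <- lapply(genes, function(g) {
    sel <- expr$gene == g
    v <- expr$rel_expr[sel]
    meas <- mm[sel, ]
    cors <- lapply(c(pd_bs = "pd_bs", pd = "pd", cfuo = "cfuo", ca = "ca"),
                   function(col) {
                     ok <- is.finite(v) & is.finite(meas[[col]])
                     if (sum(ok) < min_pairs) return(NULL)
                     spearman_cor(v[ok], meas[[col]][ok])
                   })
    if (any(vapply(cors, is.null, logical(1)))) {
      message("gene ", g, " excluded: fewer than ", min_pairs,
              " paired points for some measure")
      return(NULL)
    }
    ok <- is.finite(v) & is.finite(meas$pd_bs)
    grad <- ols_line(meas$pd_bs[ok], v[ok])
    data.frame(
      gene = g,
      rho_pdbs = cors$pd_bs$rho, p_pdbs = cors$pd_bs$p,
      rho_pd = cors$pd$rho, p_pd = cors$pd$p,
      rho_cfuo = cors$cfuo$rho, p_cfuo = cors$cfuo$p,
      rho_ca = cors$ca$rho, p_ca = cors$ca$p,
      gradient = grad$slope,
      range_min = min(v, na.rm = TRUE), range_max = max(v, na.rm = TRUE),
      n = sum(ok)
    )
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no gene had enough paired points to screen")
  ps <- out[, c("p_pdbs", "p_pd", "p_cfuo", "p_ca")]
  out$candidate <- apply(ps < p_cut, 1L, all)
  out$strong <- out$candidate & abs(out$rho_pdbs) > rho_strong
  out <- out[order(-out$strong, -abs(out$gradient)), ]
  rownames(out) <- out$gene
  class(out) <- c("candidate_table", "data.frame")
  out
}

#' Fold changes between passage 0 and the presenescent passage
#'
#' Per-gene mean fold change across donors between the first (p0) and last
#' usable (presenescent) expression samples, with a paired Wilcoxon
#' signed-rank test. Calls follow the reporting convention of expansion
#' studies: `no-change` when `p > p_cut` or the mean fold is within
#' [0.5, 2); otherwise `up`/`down` by direction; `undetectable` when the
#' gene is undetected in more than half of the presenescent samples.
#'
#' @param expr Expression table with columns `donor_id`, `gene`,
#'   `rel_expr`, `detected` (optional; `NA` rel_expr counts as undetected)
#'   and `stage` in `{"p0", "presenescent"}`; one row per donor, gene and
#'   stage.
#' @param p_cut Significance threshold (default 0.05).
#' @param min_pairs Minimum donor pairs (default 5).
#' @return Data frame, one row per gene: `mean_fold` (mean of per-donor
#'   presenescent/p0 ratios), `mean_down_fold` (mean of per-donor p0/
#'   presenescent ratios, the magnitude reported for declining genes),
#'   `p`, `n_pairs`, `call`.
#' @export
presenescence_fold <- function(expr, p_cut = 0.05, min_pairs = 5L) {
  needed <- c("donor_id", "gene", "rel_expr", "stage")
  if (!all(needed %in% names(expr)))
    stop("expr needs columns: ", paste(needed, collapse = ", "))
  if (!all(expr$stage %in% c("p0", "presenescent")))
    stop("stage must be 'p0' or 'presenescent'")
  genes <- unique(expr$gene)
  rows <- lapply(genes, function(g) {
    sub <- expr[expr$gene == g, ]
    p0 <- sub[sub$stage == "p0", ]
    pre <- sub[sub$stage == "presenescent", ]
    donors <- union(p0$donor_id, pre$donor_id)
    if (!setequal(p0$donor_id, pre$donor_id) ||
        anyDuplicated(p0$donor_id) || anyDuplicated(pre$donor_id))
      stop("unpaired donors for gene ", g)
    a <- p0$rel_expr[match(donors, p0$donor_id)]
    b <- pre$rel_expr[match(donors, pre$donor_id)]
    undet_pre <- mean(!is.finite(b))
    if (undet_pre > 0.5) {
      return(data.frame(gene = g, mean_fold = NA_real_,
                        mean_down_fold = NA_real_, p = NA_real_,
                        n_pairs = sum(is.finite(a) & is.finite(b)),
                        call = "undetectable"))
    }
    ok <- is.finite(a) & is.finite(b) & a > 0 & b > 0
    if (sum(ok) < min_pairs)
      stop("fewer than ", min_pairs, " complete donor pairs for gene ", g)
    folds <- fold_induction(b[ok], a[ok])
    mean_fold <- mean(folds)
    p <- wilcoxon_signed_rank(b[ok], a[ok])$p
    call <- if (p > p_cut || (mean_fold >= 0.5 && mean_fold < 2)) "no-change"
            else if (mean_fold >= 2) "up" else "down"
    data.frame(gene = g, mean_fold = mean_fold,
               mean_down_fold = mean(1 / folds), p = p,
               n_pairs = sum(ok), call = call)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- out$gene
  out
}

#' Classify a gene's osteoinduction response over culture expansion
#'
#' Longitudinal induction behaviour falls into four categories. With
#' per-timepoint folds (induced/basal): `upregulated` when the fold
#' is 2 or more at at least `frac` (default 75%) of timepoints,
#' `downregulated` when 0.5 or less at at least `frac`, `noninducible`
#' when every fold lies in
#' (0.5, 2), and `variable` otherwise (e.g. genes whose induction decays
#' towards 1 as the basal level catches up near senescence).
#'
#' @param fold Numeric vector of per-timepoint fold inductions, ordered by
#'   timepoint.
#' @param frac Fraction of timepoints required (default 0.75).
#' @param min_timepoints Minimum timepoints to assess (default 4).
#' @return One of `"upregulated"`, `"downregulated"`, `"noninducible"`,
#'   `"variable"`.
#' @examples
#' classify_induction(c(4, 4, 4, 4))   # upregulated
#' @export
classify_induction <- function(fold, frac = 0.75, min_timepoints = 4L) {
  fold <- fold[is.finite(fold)]
  if (length(fold) < min_timepoints)
    stop("category unassessable: fewer than ", min_timepoints, " timepoints")
  if (mean(fold >= 2) >= frac) return("upregulated")
  if (mean(fold <= 0.5) >= frac) return("downregulated")
  if (all(fold > 0.5 & fold < 2)) return("noninducible")
  "variable"
}

#' Osteogenic induction summary table
#'
#' Per-gene mean fold induction across all basal/induced sample pairs with
#' a paired Wilcoxon signed-rank test. Only genes with a significant
#' (p < `p_cut`) more-than-2-fold change (fold > 2 or < 0.5) are included,
#' with significance stars at 0.05 / 0.01 / 0.001 / 0.0001.
#'
#' @param expr Expression table: columns `sample_id`, `gene`, `condition`
#'   in `{"basal", "osteoinduced"}`, `rel_expr`.
#' @param p_cut Inclusion threshold (default 0.05).
#' @return Data frame sorted by decreasing fold: `gene`, `mean_fold`, `p`,
#'   `stars`, `n_pairs`. Zero rows when nothing qualifies.
#' @export
induction_table <- function(expr, p_cut = 0.05) {
  needed <- c("sample_id", "gene", "condition", "rel_expr")
  if (!all(needed %in% names(expr)))
    stop("expr needs columns: ", paste(needed, collapse = ", "))
  genes <- unique(expr$gene)
  rows <- lapply(genes, function(g) {
    sub <- expr[expr$gene == g, ]
    bas <- sub[sub$condition == "basal", ]
    ind <- sub[sub$condition == "osteoinduced", ]
    ids <- intersect(bas$sample_id, ind$sample_id)
    a <- bas$rel_expr[match(ids, bas$sample_id)]
    b <- ind$rel_expr[match(ids, ind$sample_id)]
    ok <- is.finite(a) & is.finite(b) & a > 0 & b > 0
    if (sum(ok) < 5L) return(NULL)
    mean_fold <- mean(fold_induction(b[ok], a[ok]))
    p <- wilcoxon_signed_rank(b[ok], a[ok])$p
    if (p < p_cut && (mean_fold > 2 || mean_fold < 0.5)) {
      data.frame(gene = g, mean_fold = mean_fold, p = p,
                 stars = as.character(significance_stars(p)),
                 n_pairs = sum(ok))
    } else NULL
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(gene = character(), mean_fold = numeric(),
                      p = numeric(), stars = character(),
                      n_pairs = integer())
  out <- out[order(-out$mean_fold), , drop = FALSE]
  rownames(out) <- NULL
  out
}
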