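#' Relative expression by the 2^(-dCt) method
#'
#' Expression of a gene relative to the reference (housekeeping) gene
#' HPRT: `2^-(ct_gene - ct_hprt)`.
#'
#' @param ct_gene,ct_hprt Ct values (cycles) of the gene of interest and
#'   the reference gene, both detected.
#' @return Relative expression (dimensionless, > 0).
#' @examples
#' relative_expression(24, 27)   # 8
#' @export
relative_expression <- function(ct_gene, ct_hprt) {
  if (any(!is.finite(ct_gene)) || any(!is.finite(ct_hprt)))
    stop("Ct values must be finite (undetected wells cannot be quantified)")
  2^(-(ct_gene - ct_hprt))
}

#' Fold induction by the 2^(-ddCt) method
#'
#' Ratio of induced to basal relative expression, algebraically identical
#' to `2^(-ddCt)`.
#'
#' @param rel_induced,rel_basal Relative expressions (> 0).
#' @return Fold change (dimensionless).
#' @examples
#' fold_induction(8, 2)   # 4
#' @export
fold_induction <- function(rel_induced, rel_basal) {
  if (any(!is.finite(rel_basal)) || any(rel_basal <= 0))
    stop("basal expression undetected or nonpositive; fold undefined")
  if (any(!is.finite(rel_induced)) || any(rel_induced <= 0))
    stop("induced expression undetected or nonpositive; fold undefined")
  rel_induced / rel_basal
}

#' Quantify a Ct panel into relative expressions
#'
#' Converts a long Ct table (one row per sample x gene x condition) into
#' relative expressions normalised to each sample's HPRT Ct within the
#' same condition. Wells with `ct >= ct_cutoff` (or missing Ct) are
#' flagged undetected and carry `rel_expr = NA` -- undetected is never
#' imputed as zero. Samples without a detected HPRT well are dropped with
#' a warning.
#'
#' @param ct_table Data frame with columns `sample_id`, `gene`, `ct` and
#'   optionally `condition` (default `"basal"`); extra columns are carried
#'   through.
#' @param reference Reference gene symbol (default `"HPRT"`).
#' @param ct_cutoff Detection cutoff in cycles (default 40); `ct >=
#'   ct_cutoff` is undetected.
#' @return Data frame of expression records: the non-reference rows of the
#'   input with columns `detected` and `rel_expr` added.
#' @export
panel_quantify <- function(ct_table, reference = "HPRT", ct_cutoff = 40) {
  needed <- c("sample_id", "gene", "ct")
  if (!all(needed %in% names(ct_table)))
    stop("ct_table needs columns: ", paste(needed, collapse = ", "))
  if (!"condition" %in% names(ct_table)) ct_table$condition <- "basal"
  key <- paste(ct_table$sample_id, ct_table$gene, ct_table$condition)
  if (anyDuplicated(key))
    stop("duplicate (sample_id, gene, condition) rows in ct_table")
  ct_table$detected <- is.finite(ct_table$ct) & ct_table$ct < ct_cutoff

  ref <- ct_table[ct_table$gene == reference & ct_table$detected, ]
  ref_key <- paste(ref$sample_id, ref$condition)
  gene_rows <- ct_table[ct_table$gene != reference, , drop = FALSE]
  grp_key <- paste(gene_rows$sample_id, gene_rows$condition)
  has_ref <- grp_key %in% ref_key
  if (any(!has_ref)) {
    warning(sum(!has_ref), " record(s) dropped: no detected ", reference,
            " well for their sample/condition")
    gene_rows <- gene_rows[has_ref, , drop = FALSE]
    grp_key <- grp_key[has_ref]
  }
  ref_ct <- ref$ct[match(grp_key, ref_key)]
  gene_rows$rel_expr <- ifelse(gene_rows$detected,
                               relative_expression(ifelse(gene_rows$detected, gene_rows$ct, ref_ct), ref_ct),
                               NA_real_)
  rownames(gene_rows) <- NULL
  gene_rows
}
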