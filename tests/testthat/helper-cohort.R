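# Shared fixtures: the default synthetic cohort (sealed seed) and its
# derived pipeline tables, computed once per test run.

.shared <- new.env(parent = emptyenv())

shared_cohort <- function() {
  if (is.null(.shared$cohort)) .shared$cohort <- generate_cohort(default_config())
  .shared$cohort
}

# annotated culture + quantified expression + per-sample measures
shared_pipeline <- function() {
  if (!is.null(.shared$pipe)) return(.shared$pipe)
  co <- shared_cohort()
  culture <- annotate_culture(co$culture)
  key <- culture[!is.na(culture$pd_bs), ]
  expr <- panel_quantify(co$expression_ct)
  basal <- expr[expr$condition == "basal", ]
  measures <- merge(
    data.frame(sample_id = key$sample_id, pd = key$accrued_pd,
               pd_bs = key$pd_bs),
    data.frame(sample_id = co$clonal$sample_id, cfuo = co$clonal$cfu_o,
               ca = co$clonal$ca),
    by = "sample_id")
  ms <- unique(co$methylation$sample_id)
  mi <- match(ms, key$sample_id)
  .shared$pipe <- list(
    cohort = co, culture = culture, key = key, expr = expr, basal = basal,
    measures = measures,
    m_pd = stats::setNames(key$accrued_pd[mi], ms),
    m_pdbs = stats::setNames(key$pd_bs[mi], ms),
    m_passage = stats::setNames(key$passage[mi], ms),
    m_donor = stats::setNames(key$donor_id[mi], ms))
  .shared$pipe
}

# composite scores (SPARC x 1/PRAMEF2) on samples with both measurements
shared_scores <- function() {
  if (!is.null(.shared$scores)) return(.shared$scores)
  p <- shared_pipeline()
  sparc <- p$basal[p$basal$gene == "SPARC" & is.finite(p$basal$rel_expr), ]
  mw <- msclong:::meth_wide(p$cohort$methylation)
  common <- intersect(sparc$sample_id, rownames(mw))
  .shared$scores <- list(
    sample_id = common,
    sparc = sparc$rel_expr[match(common, sparc$sample_id)],
    meth = mw[common, , drop = FALSE],
    score = composite_score(sparc$rel_expr[match(common, sparc$sample_id)],
                            mw[common, "PRAMEF2"], -1),
    pd = p$key$accrued_pd[match(common, p$key$sample_id)],
    pd_bs = p$key$pd_bs[match(common, p$key$sample_id)],
    cfuo = p$measures$cfuo[match(common, p$measures$sample_id)])
  .shared$scores
}

# a fully noiseless configuration (every stochastic knob at zero)
noiseless_config <- function(seed = 7L) {
  cohort_config(seed = seed, lifespan_sd = 0, p0_pd_sd = 0,
                expression_noise_cv = 0, methylation_noise_sd = 0,
                cfuo_sd = 0, ca_sd = 0, telomere_bp_sd = 0,
                telomere_shift_sdlog = 0, ct_hprt_sd = 0)
}

# deterministic half split of the methylation samples, stratified within
# donor by passage order (train = 1st, 3rd, ... sample of each donor)
clock_split <- function(p) {
  ms <- names(p$m_pd)
  ord <- order(p$m_donor, p$m_passage)
  train <- unlist(lapply(split(ord, p$m_donor[ord]), function(ix)
    ix[seq(1, length(ix), by = 2)]), use.names = FALSE)
  list(train = ms[sort(train)], test = ms[sort(setdiff(seq_along(ms), train))])
}
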