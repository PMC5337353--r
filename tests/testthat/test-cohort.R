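test_that("default configuration is the frozen study design", {
  cfg <- default_config()
  expect_equal(sort(cfg$donor_ages), c(2, 19, 20, 22, 22, 35, 72))
  expect_equal(cfg$n_donors, 7L)
  expect_equal(cfg$p0_pd_mean, 14.8)
  expect_equal(cfg$n_expression_samples, 36L)
  expect_equal(cfg$n_methylation_samples, 24L)
  expect_equal(cfg$n_telomere_pairs, 23L)
  expect_lt(cfg$lifespan_slope, 0)
})

test_that("invalid configurations are rejected", {
  expect_error(cohort_config(donor_ages = c(20, 130)), "ages")
  expect_error(cohort_config(lifespan_slope = 0.1), "negative")
  expect_error(cohort_config(n_expression_samples = 0L), "counts")
  expect_error(cohort_config(expression_noise_cv = -1), "noise")
  expect_error(cohort_config(donor_effects = 1:3), "donor_effects")
  expect_error(cohort_config(lifespan_intercept = Inf), "finite")
  expect_error(cohort_config(passage_decay = 1.5), "passage_decay")
})

test_that("identical config and seed reproduce identical output", {
  a <- generate_cohort(default_config(seed = 123))
  b <- generate_cohort(default_config(seed = 123))
  expect_identical(a[setdiff(names(a), "config")],
                   b[setdiff(names(b), "config")])
  c <- generate_cohort(default_config(seed = 124))
  expect_false(identical(a$expression_ct$ct, c$expression_ct$ct))
})

test_that("the cohort has the study's sampling structure", {
  co <- shared_cohort()
  expect_equal(nrow(co$donors), 7L)
  expect_equal(nrow(co$truth), 36L)
  expect_equal(length(unique(co$methylation$sample_id)), 24L)
  expect_equal(length(unique(co$telomere$pair_id)), 23L)
  expect_equal(length(unique(co$telomere$donor_id)), 4L)
  expect_equal(nrow(co$methylation), 24L * 6L)
  # every donor contributes its p0 and presenescent samples
  for (d in split(co$truth, co$truth$donor_id)) {
    expect_true(0 %in% d$passage)
    expect_true(any(d$pd_bs == 0))
  }
  # value ranges
  expect_true(all(co$methylation$percent > 0 & co$methylation$percent < 100))
  expect_true(all(co$truth$pd_bs >= 0))
  expect_true(all(co$clonal$cfu_o >= 0))
  sparc <- co$expression_ct[co$expression_ct$gene == "SPARC" &
                              co$expression_ct$condition == "basal", ]
  hprt <- co$expression_ct[co$expression_ct$gene == "HPRT" &
                             co$expression_ct$condition == "basal", ]
  rel <- 2^-(sparc$ct - hprt$ct[match(sparc$sample_id, hprt$sample_id)])
  expect_true(all(rel >= 33.2 * (1 - 1e-12) & rel <= 545 * (1 + 1e-12)))
})

test_that("lifespan declines with donor age in rank across seeds", {
  for (seed in 1:25) {
    co <- generate_cohort(default_config(seed = seed))
    expect_lt(cor(co$donors$age, co$donors$lifespan, method = "spearman"), 0)
  }
})

test_that("noiseless generation is exactly monotone along each driver", {
  co <- generate_cohort(noiseless_config())
  cul <- annotate_culture(co$culture)
  key <- cul[!is.na(cul$pd_bs), ]
  pd <- key$accrued_pd[match(unique(co$methylation$sample_id), key$sample_id)]
  # islands vs accrued PD: |rho| exactly 1 through the pipeline
  for (isl in CPG_ISLANDS) {
    v <- co$methylation$percent[co$methylation$island == isl]
    expect_equal(abs(spearman_cor(v, pd)$rho), 1)
  }
  expect_equal(spearman_cor(
    co$methylation$percent[co$methylation$island == "PRAMEF2"], pd)$rho, -1)
  # SPARC (and CFU-O, calcium) vs PD-BS
  basal <- panel_quantify(co$expression_ct)
  basal <- basal[basal$condition == "basal" & basal$gene == "SPARC", ]
  pdbs <- key$pd_bs[match(basal$sample_id, key$sample_id)]
  expect_equal(spearman_cor(basal$rel_expr, pdbs)$rho, -1)
  cl_pdbs <- key$pd_bs[match(co$clonal$sample_id, key$sample_id)]
  expect_equal(spearman_cor(co$clonal$cfu_o, cl_pdbs)$rho, 1)
  expect_equal(spearman_cor(co$clonal$ca, cl_pdbs)$rho, 1)
  # exponential genes are monotone within each donor
  nan <- panel_quantify(co$expression_ct)
  nan <- nan[nan$condition == "basal" & nan$gene == "NANOG", ]
  for (d in split(nan, nan$donor_id)) {
    d <- d[order(d$passage), ]
    expect_true(all(diff(d$rel_expr) < 0))
  }
})

test_that("estimated SPARC gradient recovers the configured value (200 seeds)", {
  grads <- vapply(1:200, function(seed) {
    co <- generate_cohort(default_config(seed = seed))
    cul <- annotate_culture(co$culture)
    key <- cul[!is.na(cul$pd_bs), ]
    sp <- co$expression_ct[co$expression_ct$gene == "SPARC" &
                             co$expression_ct$condition == "basal", ]
    h <- co$expression_ct[co$expression_ct$gene == "HPRT" &
                            co$expression_ct$condition == "basal", ]
    rel <- 2^-(sp$ct - h$ct[match(sp$sample_id, h$sample_id)])
    ols_line(key$pd_bs[match(sp$sample_id, key$sample_id)], rel)$slope
  }, numeric(1))
  cfgd <- default_gene_models()
  target <- cfgd$gradient[cfgd$gene == "SPARC"]
  expect_lt(abs(mean(grads) - target) / abs(target), 0.05)
})

test_that("write_cohort emits the five CSVs plus a config sidecar", {
  dir <- withr::local_tempdir()
  paths <- write_cohort(shared_cohort(), dir)
  expect_true(all(file.exists(paths)))
  cul <- read.csv(paths[["culture"]])
  expect_no_error(annotate_culture(cul))
  cfg <- jsonlite::read_json(paths[["config"]])
  expect_equal(cfg$seed, 42L)
  expect_equal(length(cfg$donor_ages), 7L)
})
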