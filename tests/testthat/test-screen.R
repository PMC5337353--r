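hand_screen_data <- function() {
  # 6 samples, one gene tracking PD-BS plus one pure-noise gene
  set.seed(71)
  pd_bs <- c(18, 14, 10, 7, 3, 0)
  expr <- rbind(
    data.frame(sample_id = paste0("s", 1:6), gene = "TRK",
               rel_expr = 500 - 20 * pd_bs + c(3, -8, 5, -2, 7, -4)),
    data.frame(sample_id = paste0("s", 1:6), gene = "NULLG",
               rel_expr = c(5, 9, 2, 8, 3, 7)))
  measures <- data.frame(sample_id = paste0("s", 1:6),
                         pd = 30 - pd_bs, pd_bs = pd_bs,
                         cfuo = 5 + 5 * pd_bs + c(1, -2, 0.5, 2, -1, 0),
                         ca = 0.2 + 0.1 * pd_bs + c(0.02, -0.01, 0, 0.03, -0.02, 0.01))
  list(expr = expr, measures = measures)
}

test_that("screen_markers matches rank and least-squares oracles on hand data", {
  h <- hand_screen_data()
  scr <- screen_markers(h$expr, h$measures, min_pairs = 5)
  trk <- h$expr[h$expr$gene == "TRK", "rel_expr"]
  expect_equal(scr["TRK", "rho_pdbs"],
               oracle_spearman_rho(trk, h$measures$pd_bs))
  expect_equal(scr["TRK", "p_pdbs"],
               oracle_spearman_p(trk, h$measures$pd_bs))
  expect_equal(scr["TRK", "gradient"],
               oracle_ols(h$measures$pd_bs, trk)$slope, tolerance = 1e-12)
  expect_equal(scr["TRK", "range_min"], min(trk))
  expect_equal(scr["TRK", "range_max"], max(trk))
  # the null gene is not a candidate; candidature implies strong is possible
  expect_false(scr["NULLG", "candidate"])
  expect_true(all(!scr$strong | scr$candidate))
})

test_that("screen_markers is invariant under monotone transforms of measures", {
  h <- hand_screen_data()
  a <- screen_markers(h$expr, h$measures, min_pairs = 5)
  h$measures$cfuo <- exp(h$measures$cfuo / 20)
  h$measures$ca <- h$measures$ca^3
  b <- screen_markers(h$expr, h$measures, min_pairs = 5)
  expect_equal(a$rho_cfuo, b$rho_cfuo)
  expect_equal(a$p_ca, b$p_ca)
})

test_that("SPARC heads the default cohort's candidate table", {
  p <- shared_pipeline()
  scr <- screen_markers(p$basal, p$measures)
  expect_equal(rownames(scr)[1], "SPARC")
  expect_true(scr["SPARC", "strong"])
  expect_true(scr["SPARC", "candidate"])
  expect_gt(abs(scr["SPARC", "rho_pdbs"]), 0.6)
  # flat genes with no PD-BS relation are not candidates
  expect_false(scr["FRZB", "candidate"])
  # undetected-heavy genes are excluded with a message, not an error
  expect_message(screen_markers(p$basal, p$measures, min_pairs = 30),
                 "excluded")
})

test_that("presenescence folds: identity, exact p, and the cohort calls", {
  # identical paired tables: fold 1, no-change everywhere
  same <- data.frame(donor_id = rep(paste0("D", 1:6), 2), gene = "G",
                     rel_expr = rep(c(4, 2, 7, 5, 3, 6), 2),
                     stage = rep(c("p0", "presenescent"), each = 6))
  out <- suppressMessages(presenescence_fold(same))
  expect_equal(out$mean_fold, 1)
  expect_equal(out$call, "no-change")
  # 7-pair toy: exact signed-rank p via 2^7 enumeration
  set.seed(72)
  a <- runif(7, 1, 5); b <- a * runif(7, 1.2, 4)
  toy <- data.frame(donor_id = rep(paste0("D", 1:7), 2), gene = "G",
                    rel_expr = c(a, b),
                    stage = rep(c("p0", "presenescent"), each = 7))
  expect_equal(presenescence_fold(toy)$p, oracle_signrank_p(b - a),
               tolerance = 1e-12)
  expect_error(presenescence_fold(toy[-1, ]), "unpaired")

  p <- shared_pipeline()
  fl <- presenescence_fold(msclong:::stage_pairs(p$basal, p$culture))
  expect_equal(fl["NANOG", "call"], "down")
  expect_equal(fl["TNFRSF11B", "call"], "up")
  expect_equal(fl["WIF1", "call"], "undetectable")
  expect_true(all(fl$n_pairs[fl$call != "undetectable"] == 7))
})

test_that("induction categories follow the 75%-of-timepoints rule", {
  expect_equal(classify_induction(c(4, 4, 4, 4)), "upregulated")
  expect_equal(classify_induction(c(1, 1, 1, 1)), "noninducible")
  expect_equal(classify_induction(c(0.3, 0.4, 0.45, 0.2)), "downregulated")
  expect_equal(classify_induction(c(4, 4, 1, 1)), "variable")
  expect_error(classify_induction(c(2, 2, 2)), "unassessable")

  # constant strong induction vs induction decaying towards senescence
  p <- shared_pipeline()
  folds_of <- function(gene) {
    bas <- p$expr[p$expr$gene == gene & p$expr$condition == "basal", ]
    ind <- p$expr[p$expr$gene == gene & p$expr$condition == "osteoinduced", ]
    ord <- order(p$key$pd_bs[match(bas$sample_id, p$key$sample_id)])
    fold_induction(ind$rel_expr[ord], bas$rel_expr[ord])
  }
  expect_equal(classify_induction(folds_of("FRZB")), "upregulated")
  expect_equal(classify_induction(folds_of("TNFRSF11B")), "variable")
})

test_that("induction table keeps significant >2-fold genes, FRZB on top", {
  p <- shared_pipeline()
  tab <- induction_table(p$expr)
  expect_equal(tab$gene[1], "FRZB")
  expect_equal(tab$mean_fold[1], 256.9, tolerance = 0.2)
  expect_true(all(tab$p < 0.05))
  expect_true(all(tab$mean_fold > 2 | tab$mean_fold < 0.5))
  expect_false("NANOG" %in% tab$gene)   # noninducible gene excluded
  # a sub-2-fold gene is excluded regardless of significance
  set.seed(73)
  bas <- abs(rnorm(12, 10, 0.3))
  hand <- data.frame(sample_id = rep(paste0("s", 1:12), 2), gene = "G",
                     condition = rep(c("basal", "osteoinduced"), each = 12),
                     rel_expr = c(bas, bas * 1.9))
  expect_equal(nrow(induction_table(hand)), 0L)
})
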