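#' Default gene models of the synthetic expression panel
#'
#' Per-gene generative models emulating the qPCR panel's behaviour over
#' culture expansion. `model` selects the driver: `"pdbs_linear"` (level
#' linear in remaining lifespan, the SPARC-like candidate genes),
#' `"lifespan_exp"` (log-level linear in the fraction of the post-p0
#' lifespan consumed, the strongly fold-changing genes) or `"flat"`.
#' `anchor` is the deterministic level at PD-BS 0 for linear genes
#' (values are clamped to `[range_min, range_max]` after noise); `k` is
#' the total log-fold change over the post-p0 lifespan for
#' exponential genes (positive = rises towards senescence); `donor_het`
#' scales a fixed donor-level offset: for `"pdbs_linear"` genes a
#' horizontal PD-axis shift tied to the donor's standardized lifespan
#' deviation (PD per lifespan SD per unit noise CV; donors sit on
#' parallel lines), for the others a multiplicative level offset on the
#' fixed donor effects; `induction_fold` and
#' `induction_pattern` drive the osteoinduced condition (`"constant"`,
#' `"decaying"` towards 1 near senescence, or `"none"`).
#'
#' @return Data frame, one row per panel gene.
#' @export
default_gene_models <- function() {
  data.frame(
    gene = c("SPARC", "TNFRSF11B", "NANOG", "TWIST1", "FZD4", "FRZB",
             "OMD", "ALPL", "WIF1", "CEBPA", "SOX2"),
    model = c("pdbs_linear", "lifespan_exp", "lifespan_exp", "lifespan_exp",
              "lifespan_exp", "flat", "flat", "lifespan_exp", "lifespan_exp",
              "lifespan_exp", "lifespan_exp"),
    base = c(NA, 1.8, 2.0, 1.0, 0.5, 0.4, 0.2, 0.3, 0.05, 0.02, 0.1),
    anchor = c(545, rep(NA, 10)),
    gradient = c(-16.614, rep(NA, 10)),
    range_min = c(33.2, rep(NA, 10)),
    range_max = c(545, rep(NA, 10)),
    k = c(NA, log(13), -log(84), -log(5), log(5), NA, NA, log(3), -9,
          -log(3), -log(4)),
    donor_het = c(72, 1.0, 0.8, 0.8, 0.8, 0.6, 0.6, 0.8, 0.8, 0.8, 0.8),
    donor_het_u = c(64, rep(0, 10)),
    induction_fold = c(NA, 4, NA, NA, 2.5, 256.9, 72.4, 4.9, NA, NA, NA),
    induction_pattern = c("none", "decaying", "none", "none", "constant",
                          "constant", "constant", "decaying", "none",
                          "none", "none"),
    stringsAsFactors = FALSE
  )
}

#' Default island models of the synthetic methylation panel
#'
#' Linear drift of methylation percent with accrued PD: `percent =
#' baseline + drift * PD + noise`, clamped to (0, 100). `noise_rel` scales
#' the global `methylation_noise_sd`; `donor_het` scales a fixed additive
#' donor-level offset (in percent per unit global noise), which carries
#' the donor-to-donor heterogeneity that loosens the weakly PD-tracking
#' islands.
#'
#' @return Data frame, one row per panel island.
#' @export
default_island_models <- function() {
  data.frame(
    island = c("GRM7", "CASR", "PRAMEF2", "SELP", "CASP14", "KRTAP13-3"),
    baseline = c(5, 15, 95, 100, 85, 110),
    drift = c(1.6, 1.2, -1.9, -2.2, -1.8, -2.5),
    noise_rel = c(1.6, 1.8, 0.6, 0.45, 0.5, 0.45),
    donor_het = c(0.0, 0.0, 0.0, 0.0, 0.0, 0.0),
    stringsAsFactors = FALSE
  )
}

#' Construct (and validate) a synthetic cohort configuration
#'
#' All knobs of the synthetic donor-cohort generator. See
#' [default_config()] for the frozen calibration that reproduces the
#' reference effect sizes; `cohort_config()` is the constructor for
#' custom settings.
#'
#' @param donor_ages Donor ages in years (length = `n_donors`).
#' @param seed Integer seed; the generator is a pure function of
#'   (config, seed).
#' @param lifespan_intercept,lifespan_slope Expected total lifespan (PD)
#'   as an affine function of donor age; slope must be negative (older
#'   donors senesce after fewer doublings).
#' @param lifespan_sd Donor-level lifespan noise, PD.
#' @param p0_pd_mean,p0_pd_sd Population doublings of the p0 culture.
#' @param passage_decay Geometric decay ratio of per-passage PD gains.
#' @param expression_noise_cv Coefficient of variation of the
#'   multiplicative lognormal expression noise (0 = noiseless).
#' @param methylation_noise_sd Global methylation noise scale, percent
#'   (0 = noiseless).
#' @param telomere_shift_bp Median telomere shortening on osteogenic
#'   differentiation, bp.
#' @param telomere_shift_sdlog Lognormal spread (sdlog) of the shift.
#' @param telomere_bp_mean,telomere_bp_sd Undifferentiated telomere
#'   length distribution, bp.
#' @param ts_slope,ts_intercept T/S-to-bp conversion used when emitting
#'   telomere Cts (see [ts_to_bp()]).
#' @param n_expression_samples,n_methylation_samples,n_telomere_pairs
#'   Cohort sample counts.
#' @param n_telomere_donors Donors contributing telomere pairs.
#' @param cfuo_intercept,cfuo_slope,cfuo_sd CFU-O per 500 MSCs as a linear
#'   function of PD-BS plus noise.
#' @param ca_intercept,ca_slope,ca_sd Calcium deposition likewise.
#' @param donor_effects Fixed donor-level heterogeneity scores (mean ~0,
#'   unit scale); scaled into expression/methylation by the noise
#'   parameters so zero noise is exactly monotone.
#' @param donor_shift_cap Bound (in lifespan SD units) on the
#'   standardized lifespan deviation driving the linear genes' donor
#'   shifts.
#' @param ct_hprt_mean,ct_hprt_sd Reference-gene Ct distribution.
#' @param ct_cutoff Detection cutoff in cycles.
#' @param induction_decay_scale PD-BS below which decaying induction
#'   relaxes towards fold 1.
#' @param gene_models,island_models Panel model tables, see
#'   [default_gene_models()] and [default_island_models()].
#' @return Object of class `"cohort_config"` (a validated list).
#' @export
cohort_config <- function(donor_ages = c(2, 19, 20, 22, 22, 35, 72),
                          seed = 42L,
                          lifespan_intercept = 36.346,
                          lifespan_slope = -0.235,
                          lifespan_sd = 0.5,
                          p0_pd_mean = 14.8,
                          p0_pd_sd = 0.8,
                          passage_decay = 0.7,
                          expression_noise_cv = 0.05,
                          methylation_noise_sd = 3.0,
                          telomere_shift_bp = 94,
                          telomere_shift_sdlog = 0.35,
                          telomere_bp_mean = 6000,
                          telomere_bp_sd = 400,
                          ts_slope = 1540,
                          ts_intercept = 2830,
                          n_expression_samples = 36L,
                          n_methylation_samples = 24L,
                          n_telomere_pairs = 23L,
                          n_telomere_donors = 4L,
                          cfuo_intercept = 4,
                          cfuo_slope = 5.5,
                          cfuo_sd = 8,
                          ca_intercept = 0.2,
                          ca_slope = 0.09,
                          ca_sd = 0.15,
                          donor_effects = c(0.8, -1.1, 0.3, 1.2, -0.4, -1.3, 0.5),
                          donor_shift_cap = 0.9,
                          ct_hprt_mean = 27,
                          ct_hprt_sd = 0.4,
                          ct_cutoff = 40,
                          induction_decay_scale = 20,
                          gene_models = default_gene_models(),
                          island_models = default_island_models()) {
  cfg <- as.list(environment())
  cfg$n_donors <- length(donor_ages)
  validate_config(cfg)
  structure(cfg, class = "cohort_config")
}

validate_config <- function(cfg) {
  num <- unlist(cfg[vapply(cfg, is.numeric, logical(1))])
  if (any(!is.finite(num))) stop("non-finite parameter in cohort config")
  if (any(cfg$donor_ages < 0 | cfg$donor_ages > 120))
    stop("donor ages must lie in [0, 120] years")
  if (cfg$lifespan_slope >= 0) stop("lifespan_slope must be negative")
  counts <- c(cfg$n_donors, cfg$n_expression_samples,
              cfg$n_methylation_samples, cfg$n_telomere_pairs,
              cfg$n_telomere_donors)
  if (any(counts < 1)) stop("all counts must be >= 1")
  if (length(cfg$donor_effects) != cfg$n_donors)
    stop("donor_effects length must equal n_donors")
  noise <- c(cfg$lifespan_sd, cfg$p0_pd_sd, cfg$expression_noise_cv,
             cfg$methylation_noise_sd, cfg$telomere_shift_sdlog,
             cfg$telomere_bp_sd, cfg$cfuo_sd, cfg$ca_sd)
  if (any(noise < 0)) stop("noise parameters must be >= 0")
  if (cfg$passage_decay <= 0 || cfg$passage_decay >= 1)
    stop("passage_decay must lie in (0, 1)")
  invisible(cfg)
}

#' The frozen default cohort configuration
#'
#' Seven donors aged 2-72 years with culture lifespans declining with
#' age, 36 expression samples, 24 methylation samples and 23 paired
#' telomere points. The generative constants were calibrated once against
#' the reference effect sizes (island and transcript rank correlations,
#' the SPARC gradient and range, presenescence fold changes, the paired
#' telomere shift) and then frozen; see the package vignette.
#'
#' @param seed Integer seed (default the sealed seed 42).
#' @return A [cohort_config()].
#' @examples
#' sort(default_config()$donor_ages)
#' @export
default_config <- function(seed = 42L) {
  cohort_config(seed = as.integer(seed))
}

#' Generate a synthetic MSC expansion cohort
#'
#' Simulates the full data bundle of an MSC expansion study: per-donor
#' culture logs expanded to senescence, basal and osteoinduced qPCR Ct
#' tables, six-island CpG methylation, paired telomere Cts and clonal
#' CFU-O / calcium assays. Two generative axes are used: methylation
#' islands track accrued PD, while expression of candidate genes, CFU-O
#' and calcium track remaining lifespan (PD-BS); donor-to-donor lifespan
#' heterogeneity then loosens every PD-linked signal against PD-BS, as in
#' real age-diverse cohorts. Identical config + seed reproduces identical
#' output.
#'
#' @param config A [cohort_config()] (default [default_config()]).
#' @return Object of class `"msc_cohort"`: list with `config`, `donors`,
#'   `culture`, `expression_ct`, `methylation`, `telomere`, `clonal` and
#'   `truth` (per-sample accrued PD, PD-BS and lifespan fraction, for
#'   validation).
#' @export
generate_cohort <- function(config = default_config()) {
  if (!inherits(config, "cohort_config")) validate_config(config)
  set.seed(config$seed)
  donors <- simulate_donors(config)
  culture <- donors$culture
  pts <- allocate_samples(donors$table, culture, config)
  expr <- simulate_expression(pts$expression, donors$table, config)
  meth <- simulate_methylation(pts$methylation, config)
  telo <- simulate_telomere(pts$telomere, config)
  clonal <- simulate_clonal(pts$expression, config)
  structure(list(config = config,
                 donors = donors$table,
                 culture = culture,
                 expression_ct = expr,
                 methylation = meth,
                 telomere = telo,
                 clonal = clonal,
                 truth = pts$expression),
            class = "msc_cohort")
}

#' @export
print.msc_cohort <- function(x, ...) {
  cat("Synthetic MSC cohort:", nrow(x$donors), "donors (ages",
      paste(sort(x$donors$age), collapse = ", "), "years)\n")
  cat("  culture log:", nrow(x$culture), "passages;",
      nrow(x$truth), "expression samples;",
      length(unique(x$methylation$sample_id)), "methylation samples;",
      length(unique(x$telomere$pair_id)), "telomere pairs\n")
  cat("  seed:", x$config$seed, "\n")
  invisible(x)
}

# ---- internals -------------------------------------------------------------

# Per-donor lifespans and passage-by-passage culture logs. Per-passage PD
# gains decay geometrically from a starting gain chosen so the accrued PD
# at the presenescent passage approximates the age-programmed lifespan;
# senescence emerges when the gain drops below 1 PD per 7 days.
simulate_donors <- function(cfg) {
  n <- cfg$n_donors
  ids <- sprintf("D%d", seq_len(n))
  p0 <- stats::rnorm(n, cfg$p0_pd_mean, cfg$p0_pd_sd)
  ltarget <- cfg$lifespan_intercept + cfg$lifespan_slope * cfg$donor_ages +
    stats::rnorm(n, 0, cfg$lifespan_sd)
  ltarget <- pmax(ltarget, p0 + 3)  # at least a few passages past p0
  rows <- vector("list", n)
  tab <- vector("list", n)
  for (i in seq_len(n)) {
    cfu <- sample(30:60, 1L)
    cells <- round(cfu * 2^p0[i])
    p0_true <- log2(cells / cfu)
    gains <- passage_gains(ltarget[i] - p0_true, cfg$passage_decay)
    pd_gain <- c(p0_true, gains$increments, gains$senescent_gain)
    k <- length(pd_gain) - 1L
    rows[[i]] <- data.frame(
      donor_id = ids[i], age = cfg$donor_ages[i],
      passage = 0:k,
      days = c(21, rep(7, k)),
      cell_count = c(cells, rep(NA_real_, k)),
      cfu_f = c(cfu, rep(NA_real_, k)),
      pd_gain = pd_gain
    )
    tab[[i]] <- data.frame(
      donor_id = ids[i], age = cfg$donor_ages[i], p0_pd = p0_true,
      lifespan = p0_true + sum(gains$increments),
      presenescent_passage = k - 1L, n_passages = k + 1L
    )
  }
  list(culture = do.call(rbind, rows), table = do.call(rbind, tab))
}

# Geometric gain schedule: first gain g1 (grid-searched) decaying by
# `decay` until the gain falls below 1 PD/week (that passage is the
# senescent one).
passage_gains <- function(budget, decay) {
  grid <- seq(1.05, 14, by = 0.0025)
  sums <- vapply(grid, function(g1) {
    g <- g1 * decay^(0:30)
    sum(g[g >= 1])
  }, numeric(1))
  g1 <- grid[which.min(abs(sums - budget))]
  g <- g1 * decay^(0:30)
  list(increments = g[g >= 1], senescent_gain = g[g < 1][1L])
}

# Deterministic selection of sampling timepoints. Every donor contributes
# its p0 and presenescent passages; interior passages are thinned from the
# most-sampled donors until the requested totals are met.
allocate_samples <- function(donors, culture, cfg) {
  pts <- lapply(seq_len(nrow(donors)), function(i) {
    pass <- 0:donors$presenescent_passage[i]
    data.frame(donor_id = donors$donor_id[i], passage = pass)
  })
  thin <- function(pts, target) {
    total <- sum(vapply(pts, nrow, integer(1)))
    if (total < target)
      stop("cohort too small: only ", total,
           " candidate timepoints for ", target, " samples")
    while (total > target) {
      sizes <- vapply(pts, nrow, integer(1))
      ord <- order(-sizes)
      removed <- FALSE
      for (j in ord) {
        if (nrow(pts[[j]]) > 2L) {           # keep p0 and presenescent
          interior <- 2:(nrow(pts[[j]]) - 1L)
          drop <- interior[ceiling(length(interior) / 2)]
          pts[[j]] <- pts[[j]][-drop, , drop = FALSE]
          removed <- TRUE
          break
        }
      }
      if (!removed) stop("cannot thin below p0 + presenescent endpoints")
      total <- total - 1L
    }
    pts
  }
  epts <- thin(pts, cfg$n_expression_samples)
  mpts <- thin(epts, cfg$n_methylation_samples)
  expression <- annotate_points(do.call(rbind, epts), donors, culture)
  methylation <- annotate_points(do.call(rbind, mpts), donors, culture)
  # telomere pairs: donors spread over the age range, pairs cycled over
  # that donor's sampled timepoints
  ord <- order(donors$age)
  take <- ord[unique(round(seq(1, length(ord), length.out = cfg$n_telomere_donors)))]
  per <- diff(round(seq(0, cfg$n_telomere_pairs, length.out = cfg$n_telomere_donors + 1L)))
  trows <- do.call(rbind, lapply(seq_along(take), function(j) {
    d <- donors$donor_id[take[j]]
    cand <- expression[expression$donor_id == d, ]
    idx <- rep(seq_len(nrow(cand)), length.out = per[j])
    cand[idx, c("donor_id", "passage", "accrued_pd", "pd_bs")]
  }))
  trows$pair_id <- sprintf("T%02d", seq_len(nrow(trows)))
  list(expression = expression, methylation = methylation, telomere = trows)
}

# attach accrued PD, PD-BS and post-p0 lifespan fraction to sampling points
annotate_points <- function(pts, donors, culture) {
  acc <- accrued_lookup(culture)
  out <- merge(pts, acc, by = c("donor_id", "passage"))
  out <- merge(out, donors[, c("donor_id", "p0_pd", "lifespan")],
               by = "donor_id")
  out <- out[order(out$donor_id, out$passage), ]
  out$pd_bs <- out$lifespan - out$accrued_pd
  out$pd_bs[abs(out$pd_bs) < 1e-9] <- 0     # cumsum vs sum rounding dust
  out$frac <- (out$accrued_pd - out$p0_pd) / (out$lifespan - out$p0_pd)
  out$sample_id <- paste0(out$donor_id, "_p", out$passage)
  rownames(out) <- NULL
  out
}

# accrued PD per (donor, passage) from the culture log
accrued_lookup <- function(culture) {
  parts <- split(culture, culture$donor_id)
  out <- do.call(rbind, lapply(parts, function(d) {
    d <- d[order(d$passage), ]
    data.frame(donor_id = d$donor_id, passage = d$passage,
               accrued_pd = cumsum(d$pd_gain))
  }))
  rownames(out) <- NULL
  out
}

simulate_expression <- function(points, donors, cfg) {
  gm <- cfg$gene_models
  sdl <- sqrt(log(1 + cfg$expression_noise_cv^2))
  u <- cfg$donor_effects[match(points$donor_id,
                               sprintf("D%d", seq_len(cfg$n_donors)))]
  # standardized lifespan deviation of each sample's donor, bounded so a
  # single extreme-aged donor cannot dominate the expression offsets
  lsd <- stats::sd(donors$lifespan)
  zl <- if (nrow(donors) < 2L || lsd == 0) rep(0, nrow(points))
        else (points$lifespan - mean(donors$lifespan)) / lsd
  zl <- pmax(pmin(zl, cfg$donor_shift_cap), -cfg$donor_shift_cap)
  het <- function(lambda) {
    a <- cfg$expression_noise_cv * lambda
    f <- exp(a * cfg$donor_effects)
    (exp(a * u)) / mean(f)
  }
  noise <- function(n) stats::rlnorm(n, -sdl^2 / 2, sdl)
  ns <- nrow(points)
  ct_h_bas <- stats::rnorm(ns, cfg$ct_hprt_mean, cfg$ct_hprt_sd)
  ct_h_ind <- stats::rnorm(ns, cfg$ct_hprt_mean, cfg$ct_hprt_sd)
  rows <- vector("list", nrow(gm) + 1L)
  for (g in seq_len(nrow(gm))) {
    if (gm$model[g] == "pdbs_linear") {
      # donor heterogeneity as a horizontal (PD-axis) offset: one part is
      # tied to the donor's lifespan deviation (the donor-ageing axis that
      # also spreads the PD-tracking methylation islands against PD-BS),
      # one part to the neutral fixed donor effects; donors sit on
      # parallel lines of the configured gradient
      shift <- cfg$expression_noise_cv *
        (gm$donor_het[g] * zl + gm$donor_het_u[g] * u)
      mu <- gm$anchor[g] + gm$gradient[g] * (points$pd_bs + shift)
      basal <- pmin(pmax(mu * noise(ns), gm$range_min[g]), gm$range_max[g])
      mu <- pmin(pmax(mu, gm$range_min[g]), gm$range_max[g])
    } else {
      mu <- switch(gm$model[g],
        lifespan_exp = gm$base[g] * exp(gm$k[g] * points$frac),
        flat = rep(gm$base[g], ns)
      )
      mu <- mu * het(gm$donor_het[g])
      basal <- mu * noise(ns)
    }
    indfold <- switch(gm$induction_pattern[g],
      none = rep(1, ns),
      constant = rep(gm$induction_fold[g] * exp(-sdl^2), ns),
      decaying = 1 + (gm$induction_fold[g] * exp(-sdl^2) - 1) *
        pmin(1, points$pd_bs / cfg$induction_decay_scale)
    )
    induced <- mu * indfold * noise(ns)
    rows[[g]] <- data.frame(
      sample_id = rep(points$sample_id, 2L),
      donor_id = rep(points$donor_id, 2L),
      passage = rep(points$passage, 2L),
      gene = gm$gene[g],
      condition = rep(c("basal", "osteoinduced"), each = ns),
      ct = c(ct_h_bas - log2(basal), ct_h_ind - log2(induced))
    )
  }
  rows[[nrow(gm) + 1L]] <- data.frame(
    sample_id = rep(points$sample_id, 2L),
    donor_id = rep(points$donor_id, 2L),
    passage = rep(points$passage, 2L),
    gene = "HPRT",
    condition = rep(c("basal", "osteoinduced"), each = ns),
    ct = c(ct_h_bas, ct_h_ind)
  )
  out <- do.call(rbind, rows)
  # undetected wells (Ct at/over cutoff) are reported without a Ct
  out$ct[out$ct >= cfg$ct_cutoff] <- NA_real_
  rownames(out) <- NULL
  out
}

simulate_methylation <- function(points, cfg) {
  im <- cfg$island_models
  u <- cfg$donor_effects[match(points$donor_id,
                               sprintf("D%d", seq_len(cfg$n_donors)))]
  ns <- nrow(points)
  rows <- lapply(seq_len(nrow(im)), function(i) {
    mu <- im$baseline[i] + im$drift[i] * points$accrued_pd +
      cfg$methylation_noise_sd *
      (im$donor_het[i] * u + im$noise_rel[i] * stats::rnorm(ns))
    data.frame(sample_id = points$sample_id, donor_id = points$donor_id,
               passage = points$passage, island = im$island[i],
               percent = pmin(pmax(mu, 0.3), 99.7))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

simulate_telomere <- function(points, cfg) {
  n <- nrow(points)
  undiff <- stats::rnorm(n, cfg$telomere_bp_mean, cfg$telomere_bp_sd)
  shift <- cfg$telomere_shift_bp *
    stats::rlnorm(n, 0, cfg$telomere_shift_sdlog)
  osteo <- undiff - shift
  to_ct <- function(bp) {
    ts <- (bp - cfg$ts_intercept) / cfg$ts_slope
    ct_s <- stats::rnorm(n, 19, 0.3)
    data.frame(ct_t = ct_s - log2(ts), ct_s = ct_s)
  }
  a <- to_ct(undiff); b <- to_ct(osteo)
  out <- rbind(
    data.frame(pair_id = points$pair_id, donor_id = points$donor_id,
               passage = points$passage, state = "undifferentiated", a),
    data.frame(pair_id = points$pair_id, donor_id = points$donor_id,
               passage = points$passage, state = "osteoinduced", b)
  )
  out <- out[order(out$pair_id, out$state), ]
  rownames(out) <- NULL
  out
}

simulate_clonal <- function(points, cfg) {
  n <- nrow(points)
  data.frame(
    sample_id = points$sample_id,
    donor_id = points$donor_id,
    passage = points$passage,
    cfu_o = pmax(0, cfg$cfuo_intercept + cfg$cfuo_slope * points$pd_bs +
                   stats::rnorm(n, 0, cfg$cfuo_sd)),
    ca = pmax(0, cfg$ca_intercept + cfg$ca_slope * points$pd_bs +
                stats::rnorm(n, 0, cfg$ca_sd))
  )
}

#' Write a synthetic cohort to CSV files
#'
#' Emits the five input tables of the analysis pipeline (culture log,
#' expression Cts, methylation, telomere Cts, clonal assays) plus a JSON
#' sidecar recording the generating configuration and seed.
#'
#' @param cohort An [generate_cohort()] result.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "msc_cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    culture = file.path(dir, "culture.csv"),
    expression = file.path(dir, "expression_ct.csv"),
    methylation = file.path(dir, "methylation.csv"),
    telomere = file.path(dir, "telomere_ct.csv"),
    clonal = file.path(dir, "clonal.csv"),
    config = file.path(dir, "cohort_config.json")
  )
  utils::write.csv(cohort$culture, paths["culture"], row.names = FALSE)
  utils::write.csv(cohort$expression_ct, paths["expression"], row.names = FALSE)
  utils::write.csv(cohort$methylation, paths["methylation"], row.names = FALSE)
  utils::write.csv(cohort$telomere, paths["telomere"], row.names = FALSE)
  utils::write.csv(cohort$clonal, paths["clonal"], row.names = FALSE)
  cfg <- cohort$config
  cfg$gene_models <- NULL; cfg$island_models <- NULL
  jsonlite::write_json(c(unclass(cfg),
                         list(gene_models = cohort$config$gene_models,
                              island_models = cohort$config$island_models)),
                       paths["config"], auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(paths)
}
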