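test_that("the measurement filter skips below 40% and fits at 40%", {
  sim <- sim_experiment(n_snps = 2, seed = 71)
  expr <- sim$expr
  # 240 possible cells per SNP here; unmask exactly 95 then 96 for snp0001
  bc1 <- sim$design$barcode_map$barcode[
    sim$design$barcode_map$snp_id == "snp0001"]
  cells <- which(rownames(expr$values) %in% bc1)
  expr$mask[cells, ] <- FALSE
  flat <- which(rownames(expr$values) %in% bc1)  # 20 barcodes x 12 samples
  idx <- cbind(rep(flat, 12), rep(1:12, each = length(flat)))
  # spread the unmasked cells over all samples so both conditions appear
  pick96 <- round(seq(1, nrow(idx), length.out = 96))
  expr95 <- expr; expr95$mask[idx[pick96[-1], ]] <- TRUE
  expect_true(fit_lmm(expr95, sim$design, "snp0001")$skipped)
  expr96 <- expr; expr96$mask[idx[pick96, ]] <- TRUE
  fit96 <- fit_lmm(expr96, sim$design, "snp0001")
  expect_false(fit96$skipped)
  expect_equal(fit96$n_measurements, 96L)
})

test_that("with no replicate variance the LMM fixed effects equal OLS", {
  sim <- sim_experiment(n_snps = 3, beta_allele = 0.4, beta_drug = 0.3,
                        beta_inter = 0.5, sigma_rep = 0, seed = 72)
  for (sid in sim$design$snps$snp_id) {
    fit <- fit_lmm(sim$expr, sim$design, sid)
    d <- mprastat:::.snp_lmm_data(sim$expr, sim$design, sid)
    ols <- coef(lm(value ~ allele * drug, data = d))
    expect_equal(fit$beta_allele, unname(ols[2]), tolerance = 1e-6)
    expect_equal(fit$beta_drug, unname(ols[3]), tolerance = 1e-6)
    expect_equal(fit$beta_inter, unname(ols[4]), tolerance = 1e-6)
  }
})

test_that("empirical F p-values follow the one-sided add-one rule", {
  sim <- sim_experiment(n_snps = 2, beta_inter = 1.0, seed = 73)
  fit <- fit_lmm(sim$expr, sim$design, "snp0001")
  mknull <- function(v) structure(list(null_stats = v, n_sims = length(v),
                                       subset_size = 10L, statistic = "lmm_F",
                                       seed = 1L), class = "mpra_basal_null")
  nulls <- list(allele = mknull(c(1, 2, 3, 4)), drug = mknull(c(1, 2, 3, 4)),
                inter = mknull(c(1, 2, 3, 4)))
  fake <- fit
  fake$F_allele <- 2.5; fake$F_drug <- 0; fake$F_inter <- 100
  pe <- lmm_empirical_p(fake, nulls)
  expect_equal(pe$p_emp_allele, 0.6)  # (1 + 2) / 5
  expect_equal(pe$p_emp_drug, 1)
  expect_equal(pe$p_emp_inter, 1 / 5)
})

test_that("basal F-null is deterministic and near the parametric F at the tail", {
  # a large basal pool keeps the realized barcode-mean variance close to
  # its expectation, so the conditional null tail approaches F(1, df);
  # with the study's 110 basal barcodes the null is deliberately
  # conditional on the realized pool and need not match the parametric F
  sim <- sim_experiment(n_snps = 2, sigma_rep = 0, sigma_bc = 0,
                        n_basal = 500, depth = 1e7, seed = 74)
  n1 <- basal_F_null(sim$expr, sim$design, n_sims = 400, seed = 9)
  n2 <- basal_F_null(sim$expr, sim$design, n_sims = 400, seed = 9)
  expect_identical(n1$allele$null_stats, n2$allele$null_stats)
  q95 <- quantile(n1$allele$null_stats, 0.95)
  expect_equal(unname(q95), qf(0.95, 1, 236), tolerance = 0.2)
  expect_true(all(n1$inter$null_stats >= 0))
  expect_error(basal_F_null(sim$expr, sim$design, n_sims = 0), "n_sims")
})

test_that("the interaction LRT is calibrated and powered", {
  # degenerate: interaction column constant (single condition) -> LR = 0
  sim <- sim_experiment(n_snps = 2, seed = 75)
  veh <- subset_samples(sim$expr, "vehicle")
  lr0 <- lrt_interaction(veh, sim$design, "snp0001")
  expect_equal(lr0$lrt_stat, 0)
  expect_equal(lr0$lrt_p, 1)

  # planted interaction: decisive LRT
  sim2 <- sim_experiment(n_snps = 2, beta_inter = 1.0, seed = 76)
  expect_lt(lrt_interaction(sim2$expr, sim2$design, "snp0001")$lrt_p, 1e-6)

  # null interaction: LRT p roughly uniform across simulated SNPs
  sim3 <- sim_experiment(n_snps = 40, beta_inter = 0, seed = 77)
  ps <- vapply(sim3$design$snps$snp_id, function(s)
    lrt_interaction(sim3$expr, sim3$design, s)$lrt_p, 1)
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)
})

test_that("effect classification reproduces the decision rules exactly", {
  th <- list(inter = 0.05, allele = 0.05, vehicle_pemp = 0.1, atra_fdr = 0.1)
  # exhaustive grid straddling every threshold
  grid <- expand.grid(pi = c(0.01, 0.049, 0.05, 0.2),
                      pa = c(0.01, 0.049, 0.05, 0.2),
                      vp = c(0.05, 0.099, 0.1, 0.5),
                      af = c(0.05, 0.099, 0.1, 0.5),
                      vd = c(-1, 1), ad = c(-1, 1))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    got <- classify_effects(g$pi, g$pa, g$vp, g$vd, g$af, g$ad, thresholds = th)
    inter <- g$pi < 0.05
    allele <- g$pa < 0.05
    if (inter && allele)
      allele <- g$vp < 0.1 && g$af < 0.1 && g$vd == g$ad
    want <- if (inter && allele) "both" else if (inter) "interaction_only"
    else if (allele) "allele_only" else "none"
    expect_identical(got, want)
  }
  # same inputs always give the same category (pure function)
  expect_identical(
    classify_effects(0.01, 0.01, 0.05, 1, 0.05, 1),
    classify_effects(0.01, 0.01, 0.05, 1, 0.05, 1))
  # missing single-condition results only matter when both coefficients hit
  expect_error(classify_effects(0.01, 0.01), "single-condition")
  expect_identical(classify_effects(0.01, 0.2), "interaction_only")
  expect_identical(classify_effects(0.2, 0.01), "allele_only")
  expect_identical(classify_effects(0.9, 0.9), "none")
  # zero direction never counts as agreement
  expect_identical(classify_effects(0.01, 0.01, 0.05, 0, 0.05, 0),
                   "interaction_only")
})

test_that("variance homogeneity summarises per-condition barcode SDs", {
  des <- generate_library(1, barcodes_per_allele = 2, n_basal = 0, seed = 78)
  bcs <- design_barcodes(des)
  v <- matrix(1, 4, 4, dimnames = list(bcs, paste0("s", 1:4)))
  ex <- manual_expression(v, des, conditions = rep(c("vehicle", "ATRA"), each = 2),
                          replicates = c(1, 2, 1, 2))
  vh <- variance_homogeneity(ex)
  expect_true(all(vh$quantiles == 0))

  ex1 <- manual_expression(v[, 1:3], des, conditions = c("vehicle", "vehicle", "ATRA"),
                           replicates = c(1, 2, 1))
  expect_error(variance_homogeneity(ex1), ">= 2 replicates")

  # matched noise in both conditions -> matched median SDs (close to sigma_e)
  sim <- sim_experiment(n_snps = 60, sigma_e = 0.12, sigma_rep = 0,
                        depth = 1e7, seed = 79)
  vh2 <- variance_homogeneity(sim$expr)
  expect_lt(vh2$diff[["median"]], 0.005)
  # median sample SD of 6 normal draws: sigma * sqrt(median(chi2_5) / 5)
  med_ref <- 0.12 * sqrt(qchisq(0.5, 5) / 5)
  expect_equal(unname(vh2$quantiles[, "median"]), rep(med_ref, 2),
               tolerance = 0.03)
})

test_that("interaction analysis recovers planted interactions end to end", {
  sim <- sim_experiment(n_snps = 12, beta_inter = rep(c(0, 0.8), 6), seed = 80)
  nulls <- basal_F_null(sim$expr, sim$design, n_sims = 1000, seed = 10)
  res <- run_interaction_analysis(sim$expr, sim$design, nulls = nulls)
  planted <- rep(c(FALSE, TRUE), 6)
  expect_true(all(res$p_emp_inter[planted] < 0.05))
  expect_true(all(res$lrt_p[planted] < 0.051))
  expect_gt(mean(res$beta_inter[planted]), 0.6)
  expect_lt(mean(abs(res$beta_inter[!planted])), 0.15)
})
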