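.lmer_ctrl <- function() {
  lme4::lmerControl(calc.derivs = FALSE,
                    check.conv.singular = "ignore",
                    check.conv.grad = "ignore",
                    check.conv.hess = "ignore")
}

# Long-format barcode-level data for one SNP: unmasked cells only, with
# allele / drug / replicate covariates. Condition reference level is the
# first condition in sample_meta order (vehicle in the standard design).
.snp_lmm_data <- function(expr, design, snp_id) {
  bm <- design$barcode_map[design$barcode_map$snp_id == snp_id, , drop = FALSE]
  if (nrow(bm) == 0L) stop("unknown SNP: ", snp_id)
  ridx <- match(bm$barcode, rownames(expr$values))
  ok <- !is.na(ridx)
  bm <- bm[ok, , drop = FALSE]; ridx <- ridx[ok]
  meta <- expr$sample_meta
  cidx <- match(meta$sample_id, colnames(expr$values))
  v <- expr$values[ridx, cidx, drop = FALSE]
  msk <- expr$mask[ridx, cidx, drop = FALSE]
  cond_lev <- unique(meta$condition)
  d <- data.frame(
    value = as.vector(v),
    allele = factor(rep(bm$allele, ncol(v)), levels = c("ref", "alt")),
    drug = factor(rep(meta$condition, each = nrow(v)), levels = cond_lev),
    replicate = factor(rep(meta$replicate, each = nrow(v))),
    barcode = rep(bm$barcode, ncol(v)))
  d[as.vector(msk), , drop = FALSE]
}

# lmer with fixed-start restarts before flagging non-convergence.
.lmer_restart <- function(formula, data, reml) {
  ctrl <- .lmer_ctrl()
  fit <- tryCatch(
    suppressMessages(lme4::lmer(formula, data = data, REML = reml,
                                control = ctrl)),
    warning = function(w) w, error = function(e) e)
  if (inherits(fit, "merMod")) return(list(fit = fit, converged = TRUE))
  for (th in c(0.1, 1, 2)) {
    fit2 <- tryCatch(
      suppressMessages(lme4::lmer(formula, data = data, REML = reml,
                                  control = ctrl, start = list(theta = th))),
      warning = function(w) w, error = function(e) e)
    if (inherits(fit2, "merMod")) return(list(fit = fit2, converged = TRUE))
  }
  # last resort: refit ignoring the convergence warning so estimates exist
  fit3 <- tryCatch(
    suppressWarnings(suppressMessages(
      lme4::lmer(formula, data = data, REML = reml, control = ctrl))),
    error = function(e) NULL)
  list(fit = fit3, converged = FALSE)
}

#' Fit the allele-by-drug linear mixed model for one SNP
#'
#' Barcode-level expression is modeled as
#' `value ~ allele + drug + allele:drug + (1 | replicate)`,
#' with allele coded ref = 0 / alt = 1, drug coded by condition (reference
#' condition = first level of the sample metadata), and a random intercept
#' for the replicate pair spanning both conditions (well-specific effects).
#' Wald F statistics (squared t) are reported per fixed coefficient from
#' the REML fit. SNPs with fewer than `min_prop` of their possible
#' barcode-by-sample measurements unmasked are skipped.
#'
#' @param expr An `mpra_expression` (both conditions).
#' @param design The `mpra_design`.
#' @param snp_id SNP identifier.
#' @param min_prop Minimum fraction of possible measurements (default 0.4,
#'   i.e. 96 of the 240 cells of a 2 allele x 10 barcode x 12 sample SNP).
#' @param reml Use REML for the coefficient fit (default TRUE).
#' @return List of class `mpra_lmm`: coefficients (`beta_allele`,
#'   `beta_drug`, `beta_inter`), Wald `F_allele`/`F_drug`/`F_inter`,
#'   variance components `sigma_rep`/`sigma_resid`, `n_measurements`,
#'   `singular`, `converged`; or a skip record (`skipped = TRUE`, `reason`)
#'   when the measurement filter fails.
#' @export
fit_lmm <- function(expr, design, snp_id, min_prop = 0.4, reml = TRUE) {
  d <- .snp_lmm_data(expr, design, snp_id)
  n_possible <- 2L * design$barcodes_per_allele * nrow(expr$sample_meta)
  n_min <- ceiling(min_prop * n_possible)
  if (nrow(d) < n_min) {
    return(structure(list(snp_id = snp_id, skipped = TRUE,
                          reason = sprintf("%d of %d measurements (< %d)",
                                           nrow(d), n_possible, n_min),
                          n_measurements = nrow(d)),
                     class = "mpra_lmm"))
  }
  r <- .lmer_restart(value ~ allele * drug + (1 | replicate), d, reml)
  if (is.null(r$fit)) stop("mixed-model fit failed for ", snp_id)
  fit <- r$fit
  b <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(stats::vcov(fit))))
  Fs <- (b / se)^2
  vc <- as.data.frame(lme4::VarCorr(fit))
  structure(list(
    snp_id = snp_id, skipped = FALSE,
    beta_allele = unname(b[2L]), beta_drug = unname(b[3L]),
    beta_inter = unname(b[4L]),
    F_allele = unname(Fs[2L]), F_drug = unname(Fs[3L]),
    F_inter = unname(Fs[4L]),
    sigma_rep = vc$sdcor[vc$grp == "replicate"],
    sigma_resid = vc$sdcor[vc$grp == "Residual"],
    n_measurements = nrow(d),
    singular = lme4::isSingular(fit), converged = r$converged),
    class = "mpra_lmm")
}

#' Basal-barcode empirical null of mixed-model F statistics
#'
#' Each of `n_sims` simulations draws two disjoint random subsets of
#' complete basal barcodes as pseudo-alleles, keeps the true drug and
#' replicate labels of every sample, fits the identical allele-by-drug
#' mixed model, and records the Wald F statistic of each fixed
#' coefficient. Because every draw shares the same balanced pseudo-design,
#' the model is fitted once and refitted with each draw's response.
#'
#' @inheritParams build_basal_null
#' @param reml Use REML, matching [fit_lmm()] (default TRUE).
#' @return List of three `mpra_basal_null` objects (`allele`, `drug`,
#'   `inter`), each holding `n_sims` F statistics.
#' @export
basal_F_null <- function(expr, design,
                         subset_size = design$barcodes_per_allele,
                         n_sims = 20000L, reml = TRUE, seed = 1L) {
  stopifnot(inherits(expr, "mpra_expression"), inherits(design, "mpra_design"))
  if (n_sims < 1L) stop("n_sims must be >= 1")
  meta <- expr$sample_meta
  B <- .basal_matrix(expr, design, meta$sample_id)
  m <- subset_size
  if (nrow(B) < 2L * m)
    stop("need >= ", 2L * m, " complete basal barcodes, have ", nrow(B))
  set.seed(seed)
  ns <- nrow(meta)
  cond_lev <- unique(meta$condition)
  template <- data.frame(
    allele = factor(rep(c("ref", "alt"), each = m * ns),
                    levels = c("ref", "alt")),
    drug = factor(rep(meta$condition, times = 2L * m), levels = cond_lev),
    replicate = factor(rep(meta$replicate, times = 2L * m)))

  draw_y <- function() {
    pick <- sample.int(nrow(B), 2L * m)
    as.vector(t(B[pick, , drop = FALSE]))  # barcode-major, sample within
  }
  ctrl <- .lmer_ctrl()
  template$value <- draw_y()
  fit0 <- suppressMessages(
    lme4::lmer(value ~ allele * drug + (1 | replicate), data = template,
               REML = reml, control = ctrl))
  Fmat <- matrix(NA_real_, n_sims, 3L,
                 dimnames = list(NULL, c("allele", "drug", "inter")))
  extractF <- function(f) {
    b <- lme4::fixef(f)
    se <- sqrt(diag(as.matrix(stats::vcov(f))))
    ((b / se)^2)[2:4]
  }
  Fmat[1L, ] <- extractF(fit0)
  if (n_sims > 1L) {
    for (i in 2:n_sims) {
      f <- suppressMessages(suppressWarnings(
        lme4::refit(fit0, draw_y(), control = ctrl)))
      Fmat[i, ] <- extractF(f)
    }
  }
  mk <- function(col) structure(
    list(null_stats = Fmat[, col], n_sims = n_sims, subset_size = m,
         statistic = "lmm_F", seed = seed),
    class = "mpra_basal_null")
  list(allele = mk("allele"), drug = mk("drug"), inter = mk("inter"))
}

#' Per-coefficient empirical p-values for a mixed-model fit
#'
#' Ranks each observed F statistic within its basal-null F vector
#' (one-sided, with the add-one convention).
#'
#' @param lmm An `mpra_lmm` from [fit_lmm()].
#' @param nulls The list returned by [basal_F_null()].
#' @return List with `p_emp_allele`, `p_emp_drug`, `p_emp_inter`.
#' @export
lmm_empirical_p <- function(lmm, nulls) {
  stopifnot(inherits(lmm, "mpra_lmm"), !isTRUE(lmm$skipped))
  list(p_emp_allele = empirical_p(lmm$F_allele, nulls$allele, "one_sided"),
       p_emp_drug = empirical_p(lmm$F_drug, nulls$drug, "one_sided"),
       p_emp_inter = empirical_p(lmm$F_inter, nulls$inter, "one_sided"))
}

#' Likelihood-ratio test of the interaction term
#'
#' Compares the maximum-likelihood allele-by-drug interaction model to the
#' maximum-likelihood additive model; the LR statistic is referred to
#' chi-squared with 1 df. A rank-deficient interaction column (e.g. only
#' one condition observed) yields LR = 0, p = 1.
#'
#' @inheritParams fit_lmm
#' @return List with `lrt_stat`, `lrt_p`, `converged`.
#' @export
lrt_interaction <- function(expr, design, snp_id, min_prop = 0.4) {
  d <- .snp_lmm_data(expr, design, snp_id)
  n_possible <- 2L * design$barcodes_per_allele * nrow(expr$sample_meta)
  if (nrow(d) < ceiling(min_prop * n_possible))
    stop("SNP ", snp_id, " fails the measurement filter")
  if (nlevels(droplevels(d$drug)) < 2L || nlevels(droplevels(d$allele)) < 2L)
    return(list(lrt_stat = 0, lrt_p = 1, converged = TRUE))
  X <- stats::model.matrix(~ allele * drug, d)
  if (qr(X)$rank < ncol(X))
    return(list(lrt_stat = 0, lrt_p = 1, converged = TRUE))
  full <- .lmer_restart(value ~ allele * drug + (1 | replicate), d, reml = FALSE)
  add <- .lmer_restart(value ~ allele + drug + (1 | replicate), d, reml = FALSE)
  if (is.null(full$fit) || is.null(add$fit))
    return(list(lrt_stat = NA_real_, lrt_p = NA_real_, converged = FALSE))
  stat <- max(0, 2 * (as.numeric(stats::logLik(full$fit)) -
                        as.numeric(stats::logLik(add$fit))))
  list(lrt_stat = stat, lrt_p = stats::pchisq(stat, 1L, lower.tail = FALSE),
       converged = full$converged && add$converged)
}

#' Mixed-model analysis of every SNP
#'
#' Fits [fit_lmm()] per SNP, attaches empirical per-coefficient p-values
#' when F nulls are supplied, and (optionally) the interaction LRT.
#'
#' @inheritParams fit_lmm
#' @param nulls Optional list from [basal_F_null()].
#' @param lrt Also run [lrt_interaction()] per SNP (default TRUE).
#' @return Data.frame, one row per fitted SNP, plus an attribute
#'   `"skipped"` (data.frame of skipped SNPs and reasons).
#' @export
run_interaction_analysis <- function(expr, design, nulls = NULL,
                                     min_prop = 0.4, reml = TRUE,
                                     lrt = TRUE) {
  snps <- design$snps$snp_id
  rows <- vector("list", length(snps))
  skipped <- list()
  for (i in seq_along(snps)) {
    fitres <- fit_lmm(expr, design, snps[i], min_prop = min_prop, reml = reml)
    if (isTRUE(fitres$skipped)) {
      skipped[[length(skipped) + 1L]] <-
        data.frame(snp_id = snps[i], reason = fitres$reason)
      next
    }
    row <- data.frame(
      snp_id = snps[i], beta_allele = fitres$beta_allele,
      beta_drug = fitres$beta_drug, beta_inter = fitres$beta_inter,
      F_allele = fitres$F_allele, F_drug = fitres$F_drug,
      F_inter = fitres$F_inter, sigma_rep = fitres$sigma_rep,
      sigma_resid = fitres$sigma_resid,
      n_measurements = fitres$n_measurements,
      singular = fitres$singular, stringsAsFactors = FALSE)
    if (!is.null(nulls)) {
      pe <- lmm_empirical_p(fitres, nulls)
      row$p_emp_allele <- pe$p_emp_allele
      row$p_emp_drug <- pe$p_emp_drug
      row$p_emp_inter <- pe$p_emp_inter
    }
    if (lrt) {
      lr <- lrt_interaction(expr, design, snps[i], min_prop = min_prop)
      row$lrt_p <- lr$lrt_p
    }
    rows[[i]] <- row
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  attr(res, "skipped") <- if (length(skipped)) do.call(rbind, skipped) else
    data.frame(snp_id = character(0), reason = character(0))
  res
}

#' Classify a SNP's effect category
#'
#' Applies the decision rules combining the mixed model with the
#' single-condition analyses: an interaction is present iff the
#' interaction empirical p is below `thresholds$inter`; an allele main
#' effect is present iff the allele empirical p is below
#' `thresholds$allele` and — when an interaction is also present — the
#' vehicle single-condition empirical p < `thresholds$vehicle_pemp`, the
#' ATRA single-condition FDR q < `thresholds$atra_fdr`, and the two
#' single-condition effect directions agree.
#'
#' @param p_emp_inter,p_emp_allele Mixed-model empirical p-values.
#' @param vehicle_pemp,vehicle_direction Vehicle single-condition
#'   empirical p and effect direction (sign of composite log2FC).
#' @param atra_fdr,atra_direction ATRA single-condition BH q and direction.
#' @param thresholds List of thresholds (defaults: inter 0.05, allele
#'   0.05, vehicle_pemp 0.1, atra_fdr 0.1).
#' @return One of `"both"`, `"interaction_only"`, `"allele_only"`, `"none"`.
#' @export
classify_effects <- function(p_emp_inter, p_emp_allele,
                             vehicle_pemp = NA_real_,
                             vehicle_direction = NA_real_,
                             atra_fdr = NA_real_, atra_direction = NA_real_,
                             thresholds = list(inter = 0.05, allele = 0.05,
                                               vehicle_pemp = 0.1,
                                               atra_fdr = 0.1)) {
  stopifnot(is.finite(p_emp_inter), is.finite(p_emp_allele))
  inter_present <- p_emp_inter < thresholds$inter
  allele_candidate <- p_emp_allele < thresholds$allele
  if (inter_present && allele_candidate) {
    if (any(is.na(c(vehicle_pemp, vehicle_direction, atra_fdr,
                    atra_direction))))
      stop("single-condition results required to classify a SNP with both ",
           "significant allele and interaction coefficients")
    ok <- vehicle_pemp < thresholds$vehicle_pemp &&
      atra_fdr < thresholds$atra_fdr &&
      vehicle_direction != 0 && vehicle_direction == atra_direction
    return(if (ok) "both" else "interaction_only")
  }
  if (inter_present) return("interaction_only")
  if (allele_candidate) return("allele_only")
  "none"
}

#' Barcode expression variability per condition
#'
#' Per barcode and condition, the SD of its unmasked expression values
#' across that condition's replicates; summarized as the 25th/50th/75th
#' percentile SD per condition, with between-condition differences — the
#' variance-homogeneity check backing the pooled mixed-model analysis.
#'
#' @param expr An `mpra_expression`.
#' @return List with `quantiles` (matrix conditions x 3) and `diff`
#'   (absolute between-condition differences; only for 2 conditions).
#' @export
variance_homogeneity <- function(expr) {
  meta <- expr$sample_meta
  conds <- unique(meta$condition)
  qs <- matrix(NA_real_, length(conds), 3L,
               dimnames = list(conds, c("q25", "median", "q75")))
  for (cn in conds) {
    cols <- match(meta$sample_id[meta$condition == cn], colnames(expr$values))
    if (length(cols) < 2L)
      stop("need >= 2 replicates per condition, condition ", cn, " has ",
           length(cols))
    v <- expr$values[, cols, drop = FALSE]
    m <- expr$mask[, cols, drop = FALSE]
    v[!m] <- NA
    n_ok <- rowSums(m)
    sds <- apply(v, 1L, stats::sd, na.rm = TRUE)[n_ok >= 2L]
    qs[cn, ] <- stats::quantile(sds, c(0.25, 0.5, 0.75), na.rm = TRUE)
  }
  out <- list(quantiles = qs)
  if (length(conds) == 2L) out$diff <- abs(qs[1L, ] - qs[2L, ])
  out
}
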