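#' Composite allelic log2 fold change for one SNP
#'
#' Mean over samples of (alt element value - ref element value), pairing
#' alt and ref within each sample; samples missing either allele are
#' dropped pairwise. Positive values mean the alternate allele drives
#' higher expression.
#'
#' @param elem An `mpra_elements` table.
#' @param snp_id SNP identifier.
#' @return The composite log2 fold change (alt vs ref), a single number.
#' @export
composite_log2fc <- function(elem, snp_id) {
  e <- elem[elem$snp_id == snp_id, , drop = FALSE]
  ref <- e[e$allele == "ref", ]
  alt <- e[e$allele == "alt", ]
  if (nrow(ref) == 0L || nrow(alt) == 0L)
    stop("allele entirely missing for ", snp_id)
  common <- intersect(ref$sample_id, alt$sample_id)
  if (length(common) == 0L)
    stop("no sample carries both alleles of ", snp_id)
  mean(alt$value[match(common, alt$sample_id)] -
         ref$value[match(common, ref$sample_id)])
}

# Two-sample t statistic; Welch by default. Degenerate inputs (zero
# variance in both groups with equal means) yield t = 0, p = 1, flagged.
.t2 <- function(x, y, var_equal = FALSE) {
  nx <- length(x); ny <- length(y)
  vx <- stats::var(x); vy <- stats::var(y)
  d <- mean(x) - mean(y)
  if (vx == 0 && vy == 0) {
    if (d == 0) return(list(t = 0, df = nx + ny - 2L, p = 1, degenerate = TRUE))
    return(list(t = sign(d) * Inf, df = nx + ny - 2L, p = 0, degenerate = TRUE))
  }
  if (var_equal) {
    sp2 <- ((nx - 1) * vx + (ny - 1) * vy) / (nx + ny - 2)
    se <- sqrt(sp2 * (1 / nx + 1 / ny))
    df <- nx + ny - 2
  } else {
    se <- sqrt(vx / nx + vy / ny)
    df <- (vx / nx + vy / ny)^2 /
      ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  }
  t <- d / se
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df), degenerate = FALSE)
}

#' Allelic t-test on per-sample element values
#'
#' Two-sided two-sample t-test of the alternate allele's element values
#' against the reference allele's, across samples.
#'
#' @param elem An `mpra_elements` table.
#' @param snp_id SNP identifier.
#' @param variant `"welch"` (default) or `"pooled"`.
#' @return List with `t_stat`, `t_pvalue`, `df` and `degenerate` flag.
#' @export
allelic_ttest <- function(elem, snp_id, variant = c("welch", "pooled")) {
  variant <- match.arg(variant)
  e <- elem[elem$snp_id == snp_id, , drop = FALSE]
  x <- e$value[e$allele == "alt"]
  y <- e$value[e$allele == "ref"]
  if (length(x) < 2L || length(y) < 2L)
    stop("need >= 2 samples per allele for ", snp_id)
  r <- .t2(x, y, var_equal = variant == "pooled")
  list(t_stat = r$t, t_pvalue = r$p, df = r$df, degenerate = r$degenerate)
}

#' Empirical null from basal-barcode pseudo-allelic comparisons
#'
#' Each simulation draws two disjoint random subsets of basal (negative
#' control) barcodes, treats them as the two alleles of a pseudo-SNP,
#' forms per-sample pseudo-element means and computes the allelic t
#' statistic exactly as for a real SNP. The resulting statistic vector is
#' the empirical null against which observed statistics are ranked.
#' Only basal barcodes with complete unmasked rows over the chosen samples
#' are used, so every draw sees the same sample structure.
#'
#' @param expr An `mpra_expression`.
#' @param design The `mpra_design` (provides the basal barcode registry).
#' @param samples Sample ids to use (default: all columns).
#' @param subset_size Barcodes per pseudo-allele (default:
#'   `design$barcodes_per_allele`, matching a real allele's variance).
#' @param n_sims Number of simulated comparisons (>= 1000; default 20000).
#' @param variant t-test flavour, as [allelic_ttest()].
#' @param seed Integer seed; the null is deterministic given the seed.
#' @return An object of class `mpra_basal_null`: list with `null_stats`,
#'   `n_sims`, `subset_size`, `statistic`, `seed`.
#' @export
build_basal_null <- function(expr, design, samples = NULL,
                             subset_size = design$barcodes_per_allele,
                             n_sims = 20000L, variant = c("welch", "pooled"),
                             seed = 1L) {
  stopifnot(inherits(expr, "mpra_expression"), inherits(design, "mpra_design"),
            n_sims >= 1L)
  variant <- match.arg(variant)
  if (is.null(samples)) samples <- colnames(expr$values)
  B <- .basal_matrix(expr, design, samples)
  if (nrow(B) < 2L * subset_size)
    stop("need >= ", 2L * subset_size, " complete basal barcodes, have ",
         nrow(B))
  set.seed(seed)
  pooled <- variant == "pooled"
  stats_out <- numeric(n_sims)
  n_basal <- nrow(B)
  m <- subset_size
  for (i in seq_len(n_sims)) {
    pick <- sample.int(n_basal, 2L * m)
    x <- colMeans(B[pick[1:m], , drop = FALSE])
    y <- colMeans(B[pick[(m + 1L):(2L * m)], , drop = FALSE])
    stats_out[i] <- .t2(x, y, var_equal = pooled)$t
  }
  structure(list(null_stats = stats_out, n_sims = n_sims,
                 subset_size = m, statistic = "t", seed = seed),
            class = "mpra_basal_null")
}

# Basal expression submatrix with complete unmasked rows.
.basal_matrix <- function(expr, design, samples) {
  bas <- intersect(design$basal_barcodes, rownames(expr$values))
  v <- expr$values[bas, samples, drop = FALSE]
  m <- expr$mask[bas, samples, drop = FALSE]
  v[rowSums(m) == ncol(m), , drop = FALSE]
}

#' Empirical p-value of an observed statistic against a basal null
#'
#' `p = (1 + #[null >= obs]) / (1 + n_sims)` with the add-one convention,
#' so p is never exactly zero. Two-sided comparisons rank `|obs|` within
#' `|null|`; one-sided comparisons (F statistics) rank raw values.
#'
#' @param obs_stat Observed statistic.
#' @param null An `mpra_basal_null`, or a bare numeric null vector.
#' @param sidedness `"two_sided"` (default, for t) or `"one_sided"` (for F).
#' @return Empirical p-value in (0, 1].
#' @export
empirical_p <- function(obs_stat, null,
                        sidedness = c("two_sided", "one_sided")) {
  sidedness <- match.arg(sidedness)
  ns <- if (inherits(null, "mpra_basal_null")) null$null_stats else null
  if (length(ns) == 0L) stop("empty null vector")
  if (sidedness == "two_sided") {
    k <- sum(abs(ns) >= abs(obs_stat))
  } else {
    k <- sum(ns >= obs_stat)
  }
  (1 + k) / (1 + length(ns))
}

#' Normality gate for per-SNP element values
#'
#' Shapiro-Wilk test on the pooled per-allele-centered element values of
#' one SNP; SNPs failing the gate (p <= 0.05) have their significant
#' t-test results double-checked with a Mann-Whitney U test downstream.
#'
#' @param ref_values,alt_values Per-sample element values of each allele.
#' @param center Center each allele's values on its own mean before
#'   pooling (default TRUE).
#' @return List with `shapiro_p` (NA when values are constant) and
#'   `needs_fallback`.
#' @export
normality_gate <- function(ref_values, alt_values, center = TRUE) {
  if (length(ref_values) + length(alt_values) < 3L)
    stop("need >= 3 values for the normality gate")
  if (center) {
    ref_values <- ref_values - mean(ref_values)
    alt_values <- alt_values - mean(alt_values)
  }
  pooled <- c(ref_values, alt_values)
  if (stats::var(pooled) == 0)
    return(list(shapiro_p = NA_real_, needs_fallback = FALSE, constant = TRUE))
  p <- stats::shapiro.test(pooled)$p.value
  list(shapiro_p = p, needs_fallback = p <= 0.05, constant = FALSE)
}

#' Mann-Whitney U fallback test
#'
#' Two-sided Mann-Whitney (Wilcoxon rank-sum) test of alt vs ref element
#' values, used to verify t-test-significant SNPs that fail the normality
#' gate. The result is recorded, never used to exclude SNPs.
#'
#' @param ref_values,alt_values Per-sample element values of each allele.
#' @return List with `mwu_p` and a `ties` flag.
#' @export
mwu_fallback <- function(ref_values, alt_values) {
  pooled <- c(ref_values, alt_values)
  ties <- anyDuplicated(pooled) > 0L
  if (stats::var(pooled) == 0)  # all values identical: no evidence at all
    return(list(mwu_p = 1, ties = TRUE))
  p <- suppressWarnings(
    stats::wilcox.test(alt_values, ref_values, exact = !ties)$p.value)
  list(mwu_p = p, ties = ties)
}

#' Benjamini-Hochberg q-values
#'
#' Standard step-up FDR adjustment.
#'
#' @param pvalues Vector of p-values in `[0, 1]`.
#' @return q-values, same length and order as the input.
#' @export
bh_fdr <- function(pvalues) {
  stopifnot(all(pvalues >= 0 & pvalues <= 1, na.rm = TRUE))
  stats::p.adjust(pvalues, method = "BH")
}

#' Run the allelic test battery over every SNP
#'
#' For each SNP with both alleles present: composite log2 fold change,
#' allelic t-test, empirical p against a basal null (when supplied), BH
#' q-value across SNPs, Shapiro-Wilk normality gate, and a Mann-Whitney
#' fallback recorded for significant SNPs failing the gate.
#'
#' @param elem An `mpra_elements` table (typically one condition's samples).
#' @param null Optional `mpra_basal_null` of t statistics.
#' @param variant t-test flavour.
#' @param sig_threshold Significance threshold used only to decide which
#'   non-normal SNPs get the recorded fallback test (default 0.05).
#' @return Data.frame (one row per SNP): `snp_id`, `composite_log2fc`,
#'   `t_stat`, `t_pvalue`, `p_emp`, `fdr_q`, `shapiro_p`, `mwu_p`,
#'   `direction`, `n_ref`, `n_alt`.
#' @export
run_allelic_tests <- function(elem, null = NULL,
                              variant = c("welch", "pooled"),
                              sig_threshold = 0.05) {
  variant <- match.arg(variant)
  snps <- sort(unique(elem$snp_id))
  out <- vector("list", length(snps))
  for (i in seq_along(snps)) {
    sid <- snps[i]
    e <- elem[elem$snp_id == sid, , drop = FALSE]
    x <- e$value[e$allele == "alt"]
    y <- e$value[e$allele == "ref"]
    if (length(x) < 2L || length(y) < 2L) next
    lfc <- composite_log2fc(elem, sid)
    tt <- .t2(x, y, var_equal = variant == "pooled")
    ng <- normality_gate(y, x)
    pe <- if (!is.null(null)) empirical_p(tt$t, null) else NA_real_
    primary_p <- if (!is.null(null)) pe else tt$p
    mwu <- if (isTRUE(ng$needs_fallback) && primary_p < sig_threshold)
      mwu_fallback(y, x)$mwu_p else NA_real_
    out[[i]] <- data.frame(
      snp_id = sid, composite_log2fc = lfc, t_stat = tt$t,
      t_pvalue = tt$p, p_emp = pe, shapiro_p = ng$shapiro_p,
      mwu_p = mwu, direction = sign(lfc),
      n_ref = length(y), n_alt = length(x), stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res$fdr_q <- bh_fdr(res$t_pvalue)
  res
}

#' Monte-Carlo power of the allelic t-test under the assay design
#'
#' Simulates the full barcode-to-element pipeline: per allele,
#' `barcodes_per_allele` barcode tracks across `n_replicates` samples with
#' Normal(0, `barcode_sd`) log2 noise, the alternate allele shifted by
#' `effect_log2fc`; barcodes are averaged to per-replicate element means
#' and alleles compared by a two-sided t-test. Power is the fraction of
#' simulated SNPs significant at the Bonferroni-corrected level
#' `alpha / n_tests_bonferroni`.
#'
#' @param barcode_sd Barcode-level log2 expression SD (default 0.12).
#' @param n_replicates Replicate samples per allele (default 6).
#' @param barcodes_per_allele Barcodes averaged per element (default 10).
#' @param effect_log2fc True allelic effect in log2 units.
#' @param alpha Family-wise significance level before correction
#'   (default 0.1).
#' @param n_tests_bonferroni Number of tests corrected for (default 1013).
#' @param n_sims Simulated SNPs (default 2000).
#' @param variant t-test flavour.
#' @param seed Integer seed.
#' @return List with `power` (fraction significant), `alpha_corrected`,
#'   `n_sims`.
#' @export
power_analysis <- function(barcode_sd = 0.12, n_replicates = 6L,
                           barcodes_per_allele = 10L, effect_log2fc = 1.1,
                           alpha = 0.1, n_tests_bonferroni = 1013L,
                           n_sims = 2000L, variant = c("welch", "pooled"),
                           seed = 1L) {
  stopifnot(barcode_sd > 0, n_replicates >= 2L, barcodes_per_allele >= 1L,
            alpha > 0, n_tests_bonferroni >= 1L, n_sims >= 1L)
  variant <- match.arg(variant)
  set.seed(seed)
  a_corr <- alpha / n_tests_bonferroni
  pooled <- variant == "pooled"
  m <- barcodes_per_allele
  hits <- logical(n_sims)
  for (i in seq_len(n_sims)) {
    ref_bc <- matrix(stats::rnorm(m * n_replicates, 0, barcode_sd), m)
    alt_bc <- matrix(stats::rnorm(m * n_replicates, effect_log2fc, barcode_sd), m)
    hits[i] <- .t2(colMeans(alt_bc), colMeans(ref_bc),
                   var_equal = pooled)$p < a_corr
  }
  list(power = mean(hits), alpha_corrected = a_corr, n_sims = n_sims)
}
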