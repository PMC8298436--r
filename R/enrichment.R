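# Per-TF hit sets (SNP ids with a record at/above the required strength).
.tf_hits <- function(records, min_strength = c("strong", "weak")) {
  min_strength <- match.arg(min_strength)
  keep <- if (min_strength == "strong") records$strength == "strong"
  else records$strength %in% c("strong", "weak")
  r <- records[keep, , drop = FALSE]
  split(r$snp_id, r$tf_name)
}

#' Resampling enrichment of motif perturbations among functional SNPs
#'
#' For each TF, the observed count of functional SNPs carrying a motif
#' perturbation is compared to the counts obtained in `n_draws` random
#' subsets of size `|functional|` drawn without replacement from the
#' analyzed SNPs; `p = (1 + #[null >= obs]) / (1 + n_draws)`, BH-adjusted
#' across TFs.
#'
#' @param functional_ids Functional SNP ids (subset of `analyzed_ids`).
#' @param analyzed_ids All analyzed SNP ids.
#' @param records Perturbation records from [scan_all()].
#' @param n_draws Random draws (>= 1000; default 10000).
#' @param min_strength Count a SNP as a hit when it has a `"strong"`
#'   record (default) or any (`"weak"`) perturbation.
#' @param seed Integer seed.
#' @return Data.frame per TF: `tf_name`, `n_functional_hit`,
#'   `n_background_hit`, `null_mean`, `null_sd`, `p_emp_enrich`, `fdr_q`.
#' @export
motif_enrichment <- function(functional_ids, analyzed_ids, records,
                             n_draws = 10000L,
                             min_strength = c("strong", "weak"), seed = 1L) {
  min_strength <- match.arg(min_strength)
  functional_ids <- unique(functional_ids)
  analyzed_ids <- unique(analyzed_ids)
  if (length(functional_ids) == 0L) stop("functional SNP set is empty")
  if (!all(functional_ids %in% analyzed_ids))
    stop("functional SNPs must be a subset of analyzed SNPs")
  if (n_draws < 1L) stop("n_draws must be >= 1")
  hits <- .tf_hits(records, min_strength)
  hits <- lapply(hits, intersect, analyzed_ids)
  hits <- hits[lengths(hits) > 0L]
  if (!length(hits))
    return(data.frame(tf_name = character(0), n_functional_hit = integer(0),
                      n_background_hit = integer(0), null_mean = numeric(0),
                      null_sd = numeric(0), p_emp_enrich = numeric(0),
                      fdr_q = numeric(0)))
  set.seed(seed)
  N <- length(analyzed_ids)
  n <- length(functional_ids)
  H <- vapply(hits, function(h) analyzed_ids %in% h,
              logical(N))  # N x TF indicator
  obs <- colSums(H[match(functional_ids, analyzed_ids), , drop = FALSE])
  null_ge <- matrix(0L, 1L, ncol(H))
  null_sum <- numeric(ncol(H)); null_sq <- numeric(ncol(H))
  ge <- integer(ncol(H))
  for (d in seq_len(n_draws)) {
    cnt <- colSums(H[sample.int(N, n), , drop = FALSE])
    ge <- ge + (cnt >= obs)
    null_sum <- null_sum + cnt
    null_sq <- null_sq + cnt^2
  }
  mu <- null_sum / n_draws
  sdv <- sqrt(pmax(0, null_sq / n_draws - mu^2))
  p <- (1 + ge) / (1 + n_draws)
  data.frame(tf_name = names(hits),
             n_functional_hit = as.integer(obs),
             n_background_hit = vapply(hits, function(h)
               length(setdiff(h, functional_ids)), 1L),
             null_mean = mu, null_sd = sdv,
             p_emp_enrich = p, fdr_q = bh_fdr(p),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Resampling enrichment of motif-expression concordance
#'
#' A (SNP, TF) pair is concordant when the allele better matching the
#' motif is also the allele driving higher reporter expression (the
#' expected behaviour of a strictly activating TF). Per TF, the observed
#' number of concordant functional SNPs is compared to the concordant
#' counts in random draws of `|functional|` SNPs from the analyzed set.
#'
#' @inheritParams motif_enrichment
#' @param allelic_results Data.frame with `snp_id` and `composite_log2fc`
#'   (or `direction`) giving each SNP's expression direction.
#' @return Data.frame per TF: `tf_name`, `n_concordant`, `null_mean`,
#'   `null_sd`, `p_emp_concord`, `fdr_q`, `n_ties_excluded`.
#' @export
concordance_enrichment <- function(functional_ids, analyzed_ids, records,
                                   allelic_results, n_draws = 10000L,
                                   min_strength = c("strong", "weak"),
                                   seed = 1L) {
  min_strength <- match.arg(min_strength)
  functional_ids <- unique(functional_ids)
  analyzed_ids <- unique(analyzed_ids)
  if (length(functional_ids) == 0L) stop("functional SNP set is empty")
  dirv <- if ("direction" %in% names(allelic_results)) allelic_results$direction
  else sign(allelic_results$composite_log2fc)
  names(dirv) <- allelic_results$snp_id
  if (!all(functional_ids %in% allelic_results$snp_id))
    stop("every functional SNP needs an expression direction")
  keep <- if (min_strength == "strong") records$strength == "strong"
  else records$strength %in% c("strong", "weak")
  r <- records[keep & records$snp_id %in% analyzed_ids, , drop = FALSE]
  r$dir <- dirv[r$snp_id]
  ties <- is.na(r$dir) | r$dir == 0 | r$better_allele == "tie"
  n_ties <- sum(ties)
  r <- r[!ties, , drop = FALSE]
  # concordant: motif-better allele is the higher-expressing allele
  r$concordant <- (r$better_allele == "alt") == (r$dir > 0)
  set.seed(seed)
  N <- length(analyzed_ids)
  n <- length(functional_ids)
  tfs <- sort(unique(r$tf_name))
  if (!length(tfs))
    return(data.frame(tf_name = character(0), n_concordant = integer(0),
                      null_mean = numeric(0), null_sd = numeric(0),
                      p_emp_concord = numeric(0), fdr_q = numeric(0),
                      n_ties_excluded = integer(0)))
  C <- vapply(tfs, function(tf) {
    conc <- r$snp_id[r$tf_name == tf & r$concordant]
    analyzed_ids %in% conc
  }, logical(N))
  obs <- colSums(C[match(functional_ids, analyzed_ids), , drop = FALSE])
  ge <- integer(length(tfs))
  null_sum <- numeric(length(tfs)); null_sq <- numeric(length(tfs))
  for (d in seq_len(n_draws)) {
    cnt <- colSums(C[sample.int(N, n), , drop = FALSE])
    ge <- ge + (cnt >= obs)
    null_sum <- null_sum + cnt
    null_sq <- null_sq + cnt^2
  }
  mu <- null_sum / n_draws
  p <- (1 + ge) / (1 + n_draws)
  data.frame(tf_name = tfs, n_concordant = as.integer(obs),
             null_mean = mu,
             null_sd = sqrt(pmax(0, null_sq / n_draws - mu^2)),
             p_emp_concord = p, fdr_q = bh_fdr(p),
             n_ties_excluded = n_ties,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Materialize functional / analyzed SNP sets for enrichment
#'
#' Three comparison modes: `"first_assay"` — functional = allelic
#' empirical p < 0.05 among all tested SNPs; `"allele_vs_null"` —
#' allele-main-effect SNPs (mixed-model allele empirical p < 0.1) vs SNPs
#' with p > 0.1 for allele, drug and interaction; and
#' `"interaction_vs_allele"` — interaction SNPs (interaction empirical
#' p < 0.05) vs SNPs with an allele main effect (p < 0.1) but no
#' interaction (p > 0.1).
#'
#' @param allelic Data.frame from [run_allelic_tests()] (first-assay mode).
#' @param lmm Data.frame from [run_interaction_analysis()] with
#'   `p_emp_allele`, `p_emp_drug`, `p_emp_inter` (the two LMM modes).
#' @param mode Comparison mode.
#' @return List with `functional_ids` and `analyzed_ids`.
#' @export
compare_sets <- function(mode = c("first_assay", "allele_vs_null",
                                  "interaction_vs_allele"),
                         allelic = NULL, lmm = NULL) {
  mode <- match.arg(mode)
  if (mode == "first_assay") {
    stopifnot(!is.null(allelic))
    fun <- allelic$snp_id[allelic$p_emp < 0.05]
    analyzed <- allelic$snp_id
  } else if (mode == "allele_vs_null") {
    stopifnot(!is.null(lmm))
    fun <- lmm$snp_id[lmm$p_emp_allele < 0.1]
    bg <- lmm$snp_id[lmm$p_emp_allele > 0.1 & lmm$p_emp_drug > 0.1 &
                       lmm$p_emp_inter > 0.1]
    analyzed <- union(fun, bg)
  } else {
    stopifnot(!is.null(lmm))
    fun <- lmm$snp_id[lmm$p_emp_inter < 0.05]
    bg <- lmm$snp_id[lmm$p_emp_allele < 0.1 & lmm$p_emp_inter > 0.1]
    analyzed <- union(fun, bg)
  }
  if (length(fun) == 0L) stop("functional SNP set is empty in mode ", mode)
  list(functional_ids = fun, analyzed_ids = analyzed)
}

#' Read a BED file of peak intervals
#'
#' Minimal three-plus-column BED (0-based, half-open); malformed lines
#' fail with their line number.
#'
#' @param path BED file path.
#' @param label Track label (default: file name).
#' @return An `mpra_intervals` object wrapping a sorted `GRanges`.
#' @export
read_bed <- function(path, label = basename(path)) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  for (i in seq_along(parts)) {
    p <- parts[[i]]
    if (length(p) < 3L)
      stop("malformed BED line ", i, ": fewer than 3 fields")
    s <- suppressWarnings(as.numeric(p[2L]))
    e <- suppressWarnings(as.numeric(p[3L]))
    if (is.na(s) || is.na(e) || s < 0 || e <= s)
      stop("malformed BED line ", i, ": need 0 <= start < end")
  }
  chrom <- vapply(parts, `[`, "", 1L)
  start0 <- as.numeric(vapply(parts, `[`, "", 2L))
  end0 <- as.numeric(vapply(parts, `[`, "", 3L))
  gr <- GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = start0 + 1, end = end0))
  gr <- GenomicRanges::sort(gr)
  structure(list(granges = gr, label = label), class = "mpra_intervals")
}

#' Overlap SNP positions with peak intervals
#'
#' SNP positions are 1-based; BED intervals are 0-based half-open, so a
#' SNP at 0-based position p overlaps `[start, end)` iff
#' `start <= p < end`.
#'
#' @param snp_positions Data.frame with `snp_id`, `chrom`, `pos`
#'   (1-based).
#' @param peaks An `mpra_intervals` (or list of them, one per track).
#' @return List with `flags` (data.frame snp_id x track logicals),
#'   `per_track_counts` (named integer vector) and `fraction_any`
#'   (fraction of SNPs overlapping >= 1 track).
#' @export
chip_overlap <- function(snp_positions, peaks) {
  stopifnot(all(c("snp_id", "chrom", "pos") %in% names(snp_positions)))
  if (inherits(peaks, "mpra_intervals")) peaks <- list(peaks)
  snp_gr <- GenomicRanges::GRanges(
    seqnames = snp_positions$chrom,
    ranges = IRanges::IRanges(start = snp_positions$pos, width = 1L))
  flags <- data.frame(snp_id = snp_positions$snp_id,
                      stringsAsFactors = FALSE)
  for (pk in peaks) {
    ov <- GenomicRanges::countOverlaps(snp_gr, pk$granges) > 0L
    flags[[pk$label]] <- ov
  }
  counts <- vapply(flags[-1L], sum, 1L)
  any_hit <- if (ncol(flags) > 1L)
    rowSums(as.matrix(flags[-1L])) > 0L else rep(FALSE, nrow(flags))
  list(flags = flags, per_track_counts = counts,
       fraction_any = mean(any_hit))
}
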