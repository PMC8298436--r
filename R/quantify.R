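#' Compute barcode-level log2 activity from counts
#'
#' Activity of barcode k in sample s is the log2 ratio of its depth-
#' normalized RNA abundance to its depth-normalized input-DNA abundance:
#' `log2((rna + pc) / libsize_rna) - log2((dna + pc) / libsize_dna)`,
#' with library sizes taken as raw column totals (total-count
#' normalization) and a pseudocount applied to the raw counts.
#'
#' @param counts An `mpra_counts` object.
#' @param pseudocount Positive pseudocount added to raw counts (default 1).
#' @param normalization Normalization scheme; only `"total-count"`.
#' @return An `mpra_expression` object: list with `values` (numeric matrix,
#'   barcodes x samples), `mask` (logical matrix, TRUE = cell usable),
#'   `libsize_rna`, `libsize_dna`, `pseudocount`, `sample_meta` and
#'   `dna` (the DNA counts used).
#' @export
compute_expression <- function(counts, pseudocount = 1,
                               normalization = c("total-count")) {
  stopifnot(inherits(counts, "mpra_counts"), pseudocount > 0 ||
              (pseudocount == 0 && all(counts$rna > 0) && all(counts$dna > 0)))
  normalization <- match.arg(normalization)
  lib_rna <- colSums(counts$rna)
  zero <- lib_rna == 0
  if (any(zero))
    stop("sample(s) with zero total RNA counts: ",
         paste(colnames(counts$rna)[zero], collapse = ", "))
  lib_dna <- sum(counts$dna)
  vals <- log2(sweep(counts$rna + pseudocount, 2L, lib_rna, "/")) -
    log2((counts$dna + pseudocount) / lib_dna)
  mask <- matrix(TRUE, nrow(vals), ncol(vals), dimnames = dimnames(vals))
  structure(list(values = vals, mask = mask, libsize_rna = lib_rna,
                 libsize_dna = lib_dna, pseudocount = pseudocount,
                 sample_meta = counts$sample_meta, dna = counts$dna),
            class = "mpra_expression")
}

#' @export
print.mpra_expression <- function(x, ...) {
  cat("MPRA expression table:", nrow(x$values), "barcodes x",
      ncol(x$values), "samples;", sum(!x$mask), "masked cells\n")
  invisible(x)
}

#' Filter an expression table for depth and barcode representation
#'
#' Applies, in order: (1) mask all cells of barcodes whose DNA count is
#' below `min_dna_count`; (2) optionally mask individual cells with zero
#' RNA counts; (3) mask barcodes unmasked in fewer than
#' `min_samples_per_barcode` samples; (4) mask every cell of alleles with
#' fewer than `min_barcodes_per_allele` surviving barcodes. Filtering is
#' idempotent and raising a threshold can only mask additional cells.
#'
#' @param expr An `mpra_expression`.
#' @param design The `mpra_design` the barcodes belong to.
#' @param min_dna_count Minimum input DNA count per barcode (default 10).
#' @param min_barcodes_per_allele Minimum surviving barcodes per allele
#'   (default 3); alleles below this are dropped entirely.
#' @param min_samples_per_barcode Minimum unmasked samples per barcode
#'   (default 0 = off).
#' @param rna_counts Optional raw RNA count matrix; when supplied,
#'   zero-count cells are masked.
#' @return List with `expr` (filtered copy) and `report` (list of removal
#'   counts per step).
#' @export
filter_table <- function(expr, design, min_dna_count = 10L,
                         min_barcodes_per_allele = 3L,
                         min_samples_per_barcode = 0L, rna_counts = NULL) {
  stopifnot(inherits(expr, "mpra_expression"), inherits(design, "mpra_design"),
            min_dna_count >= 0L, min_barcodes_per_allele >= 0L,
            min_samples_per_barcode >= 0L)
  mask <- expr$mask
  bcs <- rownames(expr$values)
  n0 <- sum(mask)

  low_dna <- expr$dna[bcs] < min_dna_count
  mask[low_dna, ] <- FALSE
  n1 <- sum(mask)

  if (!is.null(rna_counts)) mask[rna_counts[bcs, , drop = FALSE] == 0] <- FALSE
  n2 <- sum(mask)

  if (min_samples_per_barcode > 0L) {
    thin <- rowSums(mask) < min_samples_per_barcode
    mask[thin, ] <- FALSE
  }
  n3 <- sum(mask)

  bm <- design$barcode_map
  ridx <- match(bm$barcode, bcs)
  present <- !is.na(ridx)
  surviving <- rowSums(mask[ridx[present], , drop = FALSE]) > 0
  key <- paste(bm$snp_id[present], bm$allele[present])
  n_surv <- tapply(surviving, key, sum)
  bad_alleles <- names(n_surv)[n_surv < min_barcodes_per_allele]
  drop_bc <- bm$barcode[present][key %in% bad_alleles]
  mask[match(drop_bc, bcs), ] <- FALSE
  n4 <- sum(mask)

  expr$mask <- mask
  report <- list(
    cells_initial = n0,
    cells_removed_low_dna = n0 - n1,
    cells_removed_zero_rna = n1 - n2,
    cells_removed_thin_barcode = n2 - n3,
    cells_removed_allele_dropout = n3 - n4,
    cells_remaining = n4,
    barcodes_fully_masked = sum(rowSums(mask) == 0),
    alleles_dropped = length(bad_alleles))
  list(expr = expr, report = report)
}

#' Per-sample element expression (mean over an allele's barcodes)
#'
#' An element is the set of barcodes tagging one allele of one SNP; its
#' expression in a sample is the mean of its unmasked barcode values.
#'
#' @param expr An (optionally filtered) `mpra_expression`.
#' @param design The corresponding `mpra_design`.
#' @return A data.frame of class `mpra_elements` with columns `snp_id`,
#'   `allele`, `sample_id`, `value`, `n_barcodes`; rows where no barcode
#'   survives are omitted.
#' @export
element_means <- function(expr, design) {
  stopifnot(inherits(expr, "mpra_expression"), inherits(design, "mpra_design"))
  bm <- design$barcode_map
  ridx <- match(bm$barcode, rownames(expr$values))
  ok <- !is.na(ridx)
  bm <- bm[ok, , drop = FALSE]
  ridx <- ridx[ok]
  v <- expr$values[ridx, , drop = FALSE]
  m <- expr$mask[ridx, , drop = FALSE]
  v[!m] <- 0
  grp <- paste(bm$snp_id, bm$allele, sep = "\r")
  sums <- rowsum(v, grp)
  ns <- rowsum(m + 0L, grp)
  keys <- do.call(rbind, strsplit(rownames(sums), "\r", fixed = TRUE))
  out <- data.frame(
    snp_id = rep(keys[, 1L], ncol(sums)),
    allele = rep(keys[, 2L], ncol(sums)),
    sample_id = rep(colnames(sums), each = nrow(sums)),
    value = as.vector(sums / ns),
    n_barcodes = as.integer(ns),
    stringsAsFactors = FALSE)
  out <- out[out$n_barcodes > 0L, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("mpra_elements", "data.frame")
  out
}

#' Restrict an expression table to a subset of samples
#'
#' Convenience for single-condition analyses (e.g. vehicle-only or
#' ATRA-only testing of a two-condition experiment).
#'
#' @param expr An `mpra_expression`.
#' @param sample_ids Sample ids (or a condition name) to keep.
#' @return An `mpra_expression` with only those columns.
#' @export
subset_samples <- function(expr, sample_ids) {
  stopifnot(inherits(expr, "mpra_expression"))
  if (length(sample_ids) == 1L && sample_ids %in% expr$sample_meta$condition)
    sample_ids <- expr$sample_meta$sample_id[
      expr$sample_meta$condition == sample_ids]
  stopifnot(all(sample_ids %in% colnames(expr$values)))
  expr$values <- expr$values[, sample_ids, drop = FALSE]
  expr$mask <- expr$mask[, sample_ids, drop = FALSE]
  expr$libsize_rna <- expr$libsize_rna[sample_ids]
  expr$sample_meta <- expr$sample_meta[
    match(sample_ids, expr$sample_meta$sample_id), , drop = FALSE]
  expr
}

# Wide (snp x sample) matrices of element values for one allele;
# internal helper shared by the allelic tests.
.element_matrix <- function(elem, allele) {
  e <- elem[elem$allele == allele, , drop = FALSE]
  samples <- sort(unique(elem$sample_id))
  snps <- sort(unique(elem$snp_id))
  m <- matrix(NA_real_, length(snps), length(samples),
              dimnames = list(snps, samples))
  m[cbind(match(e$snp_id, snps), match(e$sample_id, samples))] <- e$value
  m
}
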