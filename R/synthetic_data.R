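#' Generate an MPRA library design
#'
#' Builds the skeleton of a barcode-tagged reporter library: `n_snps`
#' biallelic SNPs, each represented by two element sequences (reference and
#' alternate allele) that differ at exactly one position (the SNP, placed at
#' the centre of the element), with `barcodes_per_allele` unique 10-nt
#' barcodes per allele, plus a pool of promoter-only "basal" barcodes used
#' downstream to build empirical null distributions.
#'
#' @param n_snps Number of SNPs (each contributes two elements).
#' @param barcodes_per_allele Barcodes tagging each allele (default 10).
#' @param n_basal Number of basal (negative-control) barcodes (default 110).
#' @param element_length Element sequence length in nt; must be odd so the
#'   SNP sits exactly at the centre position (default 125).
#' @param barcode_length Barcode length in nt (default 10).
#' @param snps_per_locus SNPs grouped per synthetic GWAS locus (default 25).
#' @param seed Integer seed; the design is deterministic given the seed.
#' @return An object of class `mpra_design`: a list with elements `snps`
#'   (data.frame: `snp_id`, `locus_id`, `ref_allele`, `alt_allele`,
#'   `ref_seq`, `alt_seq`), `barcode_map` (data.frame: `barcode`, `snp_id`,
#'   `allele`), `basal_barcodes` (character), and the design constants.
#' @export
generate_library <- function(n_snps, barcodes_per_allele = 10L,
                             n_basal = 110L, element_length = 125L,
                             barcode_length = 10L, snps_per_locus = 25L,
                             seed = 1L) {
  stopifnot(n_snps >= 1L, barcodes_per_allele >= 1L, n_basal >= 0L,
            barcode_length >= 1L)
  if (element_length %% 2L == 0L)
    stop("element_length must be odd so the SNP sits at the centre")
  n_bc <- n_snps * 2L * barcodes_per_allele + n_basal
  if (n_bc > 0.5 * 4^barcode_length)
    stop("barcode space exhausted: ", n_bc, " barcodes requested from a ",
         barcode_length, "-nt alphabet")
  set.seed(seed)
  bases <- c("A", "C", "G", "T")

  barcodes <- .draw_unique_seqs(n_bc, barcode_length)

  centre <- (element_length + 1L) %/% 2L
  snp_id <- sprintf("snp%04d", seq_len(n_snps))
  locus_id <- sprintf("locus%03d", (seq_len(n_snps) - 1L) %/% snps_per_locus + 1L)
  ref_seq <- character(n_snps)
  alt_seq <- character(n_snps)
  ref_allele <- character(n_snps)
  alt_allele <- character(n_snps)
  for (i in seq_len(n_snps)) {
    s <- sample(bases, element_length, replace = TRUE)
    ref_allele[i] <- s[centre]
    alt_allele[i] <- sample(setdiff(bases, s[centre]), 1L)
    ref_seq[i] <- paste(s, collapse = "")
    s[centre] <- alt_allele[i]
    alt_seq[i] <- paste(s, collapse = "")
  }
  snps <- data.frame(snp_id = snp_id, locus_id = locus_id,
                     ref_allele = ref_allele, alt_allele = alt_allele,
                     ref_seq = ref_seq, alt_seq = alt_seq,
                     stringsAsFactors = FALSE)

  n_elem_bc <- n_snps * 2L * barcodes_per_allele
  barcode_map <- data.frame(
    barcode = barcodes[seq_len(n_elem_bc)],
    snp_id = rep(snp_id, each = 2L * barcodes_per_allele),
    allele = rep(rep(c("ref", "alt"), each = barcodes_per_allele), n_snps),
    stringsAsFactors = FALSE)
  basal <- if (n_basal > 0L) barcodes[(n_elem_bc + 1L):n_bc] else character(0)

  structure(list(snps = snps, barcode_map = barcode_map,
                 basal_barcodes = basal,
                 barcodes_per_allele = as.integer(barcodes_per_allele),
                 n_basal = as.integer(n_basal),
                 element_length = as.integer(element_length),
                 snp_position = centre),
            class = "mpra_design")
}

# Rejection-sample unique fixed-length DNA strings.
.draw_unique_seqs <- function(n, len) {
  bases <- c("A", "C", "G", "T")
  out <- character(0)
  for (attempt in 1:50) {
    need <- n - length(out)
    if (need <= 0L) break
    new <- vapply(seq_len(ceiling(need * 1.2) + 8L), function(i)
      paste(sample(bases, len, replace = TRUE), collapse = ""), "")
    out <- unique(c(out, new))
  }
  if (length(out) < n) stop("could not draw ", n, " unique ", len, "-nt barcodes")
  out[seq_len(n)]
}

#' @export
print.mpra_design <- function(x, ...) {
  cat("MPRA library design:", nrow(x$snps), "SNPs x 2 alleles x",
      x$barcodes_per_allele, "barcodes;", x$n_basal, "basal barcodes;",
      "elements", x$element_length, "nt (SNP at position", x$snp_position, ")\n")
  invisible(x)
}

#' All barcodes of a design (element barcodes then basal barcodes)
#' @param design An `mpra_design`.
#' @return Character vector of barcode strings.
#' @export
design_barcodes <- function(design) {
  c(design$barcode_map$barcode, design$basal_barcodes)
}

#' Define generative ground truth for a library design
#'
#' Encodes the latent linear model from which synthetic counts are drawn:
#' per-SNP fixed effects (allelic, drug, allele-by-drug interaction, log2
#' units), barcode-specific offsets, per-replicate random offsets shared
#' across conditions, and the residual barcode-level noise SD. Basal
#' barcodes receive a barcode offset but no allele/drug/interaction terms.
#'
#' @param design An `mpra_design`.
#' @param beta_allele,beta_drug,beta_inter True effects in log2 units;
#'   length 1 (recycled) or one value per SNP.
#' @param mu0 Baseline log2 activity shared by element and basal barcodes.
#' @param basal_offset Additive shift of basal barcodes relative to `mu0`
#'   (default 0: basal barcodes share the element baseline).
#' @param sigma_bc SD of barcode-specific offsets (default 0.05).
#' @param sigma_rep SD of per-replicate random offsets (default 0.05).
#' @param sigma_e Residual barcode-level log2 noise SD (default 0.12, the
#'   scale of barcode expression variability this generator emulates).
#' @param n_replicates Replicates per condition for which replicate offsets
#'   are drawn (default 6).
#' @param seed Integer seed.
#' @return An object of class `mpra_truth`.
#' @export
make_ground_truth <- function(design, beta_allele = 0, beta_drug = 0,
                              beta_inter = 0, mu0 = 0, basal_offset = 0,
                              sigma_bc = 0.05, sigma_rep = 0.05,
                              sigma_e = 0.12, n_replicates = 6L, seed = 1L) {
  stopifnot(inherits(design, "mpra_design"), sigma_bc >= 0, sigma_rep >= 0,
            sigma_e >= 0, n_replicates >= 1L)
  n <- nrow(design$snps)
  eff <- data.frame(snp_id = design$snps$snp_id,
                    beta_allele = rep_len(beta_allele, n),
                    beta_drug = rep_len(beta_drug, n),
                    beta_inter = rep_len(beta_inter, n),
                    stringsAsFactors = FALSE)
  stopifnot(all(is.finite(eff$beta_allele)), all(is.finite(eff$beta_drug)),
            all(is.finite(eff$beta_inter)))
  set.seed(seed)
  bcs <- design_barcodes(design)
  b_k <- stats::rnorm(length(bcs), 0, sigma_bc)
  names(b_k) <- bcs
  u_r <- stats::rnorm(n_replicates, 0, sigma_rep)
  structure(list(effects = eff, barcode_offsets = b_k,
                 replicate_offsets = u_r, mu0 = mu0,
                 basal_offset = basal_offset, sigma_bc = sigma_bc,
                 sigma_rep = sigma_rep, sigma_e = sigma_e,
                 n_replicates = as.integer(n_replicates)),
            class = "mpra_truth")
}

#' Simulate DNA and RNA barcode count tables
#'
#' Draws an input-plasmid (DNA) count per barcode and per-sample RNA counts
#' for a two-condition (vehicle / ATRA) design with paired replicates.
#' The latent log2 activity of barcode k in sample s is
#' `mu0 + b_k + [alt]*beta_allele + [ATRA]*beta_drug + [alt & ATRA]*beta_inter
#'  + u_r(s) + e`, with `e ~ Normal(0, sigma_e)`; RNA counts are
#' Poisson-lognormal: `Poisson(depth * w / sum(w))` with
#' `w = dna_k * 2^latent`. DNA counts are lognormal around
#' `dna_depth / n_barcodes`.
#'
#' @param design An `mpra_design`.
#' @param truth An `mpra_truth` covering every SNP in `design`.
#' @param n_replicates_per_condition Replicates per condition (default 6).
#' @param depth Total RNA read depth per sample.
#' @param dna_depth Total DNA read depth (default `depth`).
#' @param dna_sdlog Lognormal SD (log scale) of DNA counts (default 0.25).
#' @param conditions Condition labels, reference level first.
#' @param seed Integer seed.
#' @return An object of class `mpra_counts`: list with `dna` (named integer
#'   vector), `rna` (integer matrix, barcodes x samples) and `sample_meta`
#'   (data.frame: `sample_id`, `condition`, `replicate`).
#' @export
simulate_counts <- function(design, truth, n_replicates_per_condition = 6L,
                            depth = 2e6, dna_depth = depth, dna_sdlog = 0.25,
                            conditions = c("vehicle", "ATRA"), seed = 1L) {
  stopifnot(inherits(design, "mpra_design"), inherits(truth, "mpra_truth"))
  if (depth <= 0 || dna_depth <= 0) stop("depth must be > 0")
  n_rep <- as.integer(n_replicates_per_condition)
  if (n_rep != truth$n_replicates)
    stop("truth holds replicate offsets for ", truth$n_replicates,
         " replicates but ", n_rep, " were requested")
  missing_snp <- setdiff(design$snps$snp_id, truth$effects$snp_id)
  if (length(missing_snp))
    stop("ground truth missing for SNP(s): ",
         paste(utils::head(missing_snp, 5L), collapse = ", "))

  set.seed(seed)
  bcs <- design_barcodes(design)
  n_bc <- length(bcs)

  mlog <- log(dna_depth / n_bc) - dna_sdlog^2 / 2
  dna <- as.integer(round(stats::rlnorm(n_bc, mlog, dna_sdlog)))
  names(dna) <- bcs

  sample_meta <- data.frame(
    sample_id = paste0(rep(conditions, each = n_rep), "_rep", 1:n_rep),
    condition = rep(conditions, each = n_rep),
    replicate = rep(seq_len(n_rep), 2L),
    stringsAsFactors = FALSE)

  idx <- match(design$barcode_map$snp_id, truth$effects$snp_id)
  is_alt <- design$barcode_map$allele == "alt"
  bA <- truth$effects$beta_allele[idx]
  bD <- truth$effects$beta_drug[idx]
  bI <- truth$effects$beta_inter[idx]
  b_k <- truth$barcode_offsets[bcs]
  n_elem <- nrow(design$barcode_map)
  basal_shift <- rep(c(0, truth$basal_offset), c(n_elem, n_bc - n_elem))

  rna <- matrix(0L, n_bc, nrow(sample_meta),
                dimnames = list(bcs, sample_meta$sample_id))
  for (s in seq_len(nrow(sample_meta))) {
    drugged <- sample_meta$condition[s] != conditions[1L]
    lat <- truth$mu0 + b_k + basal_shift +
      c(is_alt * bA + drugged * bD + (is_alt & drugged) * bI,
        numeric(n_bc - n_elem)) +
      truth$replicate_offsets[sample_meta$replicate[s]] +
      stats::rnorm(n_bc, 0, truth$sigma_e)
    w <- dna * 2^lat
    rna[, s] <- stats::rpois(n_bc, depth * w / sum(w))
  }
  structure(list(dna = dna, rna = rna, sample_meta = sample_meta),
            class = "mpra_counts")
}

#' @export
print.mpra_counts <- function(x, ...) {
  cat("MPRA count tables:", length(x$dna), "barcodes,",
      ncol(x$rna), "RNA samples (",
      paste(unique(x$sample_meta$condition), collapse = "/"), ")\n")
  invisible(x)
}

#' Generate PWM fixtures and plant allelic motif matches
#'
#' Emits `n_tfs` random position weight matrices (motif lengths 6-12) and
#' rewrites a fraction of SNP elements so that one allele carries the
#' consensus of one PWM spanning the SNP position while the other allele
#' carries the worst-scoring base at that position. Each PWM has one highly
#' informative position (the one aligned to the SNP when planted) and
#' moderately informative flanks, so a planted mismatch produces a strong
#' relative-score drop. Planting records are returned for oracle tests.
#'
#' @param design An `mpra_design`.
#' @param n_tfs Number of PWMs to generate.
#' @param plant_fraction Fraction of SNPs whose elements are rewritten to
#'   carry a planted allelic motif disruption (0-1).
#' @param seed Integer seed.
#' @return List with `pwms` (an `mpra_pwm_set`), `design` (updated copy) and
#'   `plantings` (data.frame: `snp_id`, `tf_name`, `offset`, `better_allele`).
#' @export
generate_motif_fixtures <- function(design, n_tfs, plant_fraction = 0,
                                    seed = 1L) {
  stopifnot(inherits(design, "mpra_design"), n_tfs >= 1L,
            plant_fraction >= 0, plant_fraction <= 1)
  set.seed(seed)
  bases <- c("A", "C", "G", "T")

  lens <- sample(6:12, n_tfs, replace = TRUE)
  sharp_pos <- vapply(lens, function(L) sample.int(L, 1L), 1L)
  pwms <- vector("list", n_tfs)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  for (t in seq_len(n_tfs)) {
    L <- lens[t]
    m <- matrix(0, 4L, L, dimnames = list(bases, NULL))
    sharp_base <- sample(bases, 1L)
    # keep the sharp consensus base (and its complement, for the reverse
    # strand) out of the flanking consensus so that no shifted window over
    # a planted consensus run can re-match the informative position
    flank_bases <- setdiff(bases, c(sharp_base, comp[sharp_base]))
    for (j in seq_len(L)) {
      if (j == sharp_pos[t]) {
        p <- rep(0.01, 4L); p[match(sharp_base, bases)] <- 0.97
      } else {
        p <- rep(0.2, 4L)
        p[match(sample(flank_bases, 1L), bases)] <- 0.4
      }
      m[, j] <- p
    }
    pwms[[t]] <- new_pwm(sprintf("TF%03d", t), m)
  }
  names(pwms) <- vapply(pwms, function(p) p$tf_name, "")
  pwm_set <- structure(pwms, class = "mpra_pwm_set")

  n_snps <- nrow(design$snps)
  n_plant <- round(plant_fraction * n_snps)
  plantings <- data.frame(snp_id = character(0), tf_name = character(0),
                          offset = integer(0), better_allele = character(0),
                          stringsAsFactors = FALSE)
  if (n_plant > 0L) {
    centre <- design$snp_position
    planted <- sort(sample.int(n_snps, n_plant))
    for (i in planted) {
      t <- sample.int(n_tfs, 1L)
      L <- lens[t]
      if (L > design$element_length)
        stop("element too short for motif of length ", L)
      start <- centre - sharp_pos[t] + 1L
      if (start < 1L || start + L - 1L > design$element_length)
        stop("motif of length ", L, " cannot overlap the SNP inside the element")
      cons <- consensus_seq(pwm_set[[t]])
      cons_sharp <- substr(cons, sharp_pos[t], sharp_pos[t])
      # the breaking base must not be the complement of the consensus base
      # either, or the reverse strand re-matches through the SNP itself
      cand <- setdiff(bases, c(cons_sharp, comp[cons_sharp]))
      worst <- cand[which.min(pwm_set[[t]]$matrix[cand, sharp_pos[t]])]
      better <- sample(c("ref", "alt"), 1L)

      # A window elsewhere on the random flanks can happen to score well
      # on the broken allele and dilute the planted delta; redraw the
      # flanks until the planting satisfies the strong-perturbation
      # contract at the default thresholds.
      for (attempt in 1:50) {
        seqv <- sample(bases, design$element_length, replace = TRUE)
        seqv[start:(start + L - 1L)] <- strsplit(cons, "")[[1]]
        good <- seqv; good[centre] <- strsplit(cons, "")[[1]][sharp_pos[t]]
        bad <- seqv; bad[centre] <- worst
        if (better == "ref") {
          design$snps$ref_seq[i] <- paste(good, collapse = "")
          design$snps$alt_seq[i] <- paste(bad, collapse = "")
          design$snps$ref_allele[i] <- good[centre]
          design$snps$alt_allele[i] <- bad[centre]
        } else {
          design$snps$alt_seq[i] <- paste(good, collapse = "")
          design$snps$ref_seq[i] <- paste(bad, collapse = "")
          design$snps$alt_allele[i] <- good[centre]
          design$snps$ref_allele[i] <- bad[centre]
        }
        rec <- allelic_perturbation(design, design$snps$snp_id[i],
                                    pwm_set[[t]])
        if (rec$strength == "strong" && rec$better_allele == better) break
        if (attempt == 50L)
          stop("could not plant a strong motif disruption at ",
               design$snps$snp_id[i])
      }
      plantings <- rbind(plantings, data.frame(
        snp_id = design$snps$snp_id[i], tf_name = pwm_set[[t]]$tf_name,
        offset = start, better_allele = better, stringsAsFactors = FALSE))
    }
  }
  list(pwms = pwm_set, design = design, plantings = plantings)
}
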