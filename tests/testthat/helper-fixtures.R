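# Shared fixture builders: every fixture is generated in code at test time.

# Simulate a full two-condition experiment and quantify it.
sim_experiment <- function(n_snps = 20, beta_allele = 0, beta_drug = 0,
                           beta_inter = 0, sigma_rep = 0.05,
                           sigma_bc = 0.05, sigma_e = 0.12,
                           n_basal = 110, barcodes_per_allele = 10,
                           n_replicates = 6, depth = 2e6, seed = 1) {
  design <- generate_library(n_snps, barcodes_per_allele = barcodes_per_allele,
                             n_basal = n_basal, seed = seed)
  truth <- make_ground_truth(design, beta_allele = beta_allele,
                             beta_drug = beta_drug, beta_inter = beta_inter,
                             sigma_rep = sigma_rep, sigma_bc = sigma_bc,
                             sigma_e = sigma_e, n_replicates = n_replicates,
                             seed = seed + 1)
  counts <- simulate_counts(design, truth,
                            n_replicates_per_condition = n_replicates,
                            depth = depth, seed = seed + 2)
  expr <- filter_table(compute_expression(counts), design,
                       rna_counts = counts$rna)$expr
  list(design = design, truth = truth, counts = counts, expr = expr,
       elem = element_means(expr, design))
}

# Independent brute-force PWM scanner oracle: enumerate every window on
# both strands with an explicit per-position log-odds sum.
brute_scan <- function(seq, pwm, windows = NULL) {
  L <- ncol(pwm$matrix)
  n <- nchar(seq)
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  sc_one <- function(chars) {
    s <- 0
    for (j in seq_len(L)) {
      b <- chars[j]
      s <- s + if (b == "N") 0 else log2(pwm$matrix[b, j] / pwm$background[
        match(b, c("A", "C", "G", "T"))])
    }
    s
  }
  best <- -Inf; bpos <- NA; bstr <- NA
  starts <- if (is.null(windows)) seq_len(n - L + 1) else windows
  for (strand in c("+", "-")) {
    for (i in starts) {
      chars <- strsplit(substr(seq, i, i + L - 1), "")[[1]]
      if (strand == "-") chars <- rev(unname(comp[chars]))
      s <- unname(sc_one(chars))
      if (s > best + 1e-12) { best <- s; bpos <- i; bstr <- strand }
    }
  }
  lo <- log2(sweep(pwm$matrix, 1, pwm$background, "/"))
  lims <- c(sum(apply(lo, 2, min)), sum(apply(lo, 2, max)))
  list(score = best, rel_score = (best - lims[1]) / (lims[2] - lims[1]),
       position = bpos, strand = bstr)
}

# Hand-built expression table: values matrix (barcodes x samples) plus a
# design whose barcode map matches the rownames.
manual_expression <- function(values, design,
                              conditions = rep("vehicle", ncol(values)),
                              replicates = seq_len(ncol(values))) {
  mask <- matrix(TRUE, nrow(values), ncol(values), dimnames = dimnames(values))
  dna <- rep(100L, nrow(values))
  names(dna) <- rownames(values)
  structure(list(values = values, mask = mask,
                 libsize_rna = rep(1, ncol(values)), libsize_dna = 1,
                 pseudocount = 1,
                 sample_meta = data.frame(sample_id = colnames(values),
                                          condition = conditions,
                                          replicate = replicates,
                                          stringsAsFactors = FALSE),
                 dna = dna),
            class = "mpra_expression")
}
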