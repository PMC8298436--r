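fake_records <- function(snp_ids, tf = "TF001", strength = "strong",
                         better = "alt") {
  data.frame(snp_id = snp_ids, tf_name = tf, strength = strength,
             better_allele = better, stringsAsFactors = FALSE)
}

test_that("enrichment p matches the exact hypergeometric tail", {
  analyzed <- sprintf("s%02d", 1:8)
  functional <- analyzed[1:3]
  recs <- fake_records(analyzed[1:2])  # 2 hits, both functional
  res <- motif_enrichment(functional, analyzed, recs, n_draws = 10000,
                          seed = 3)
  exact <- phyper(1, 2, 6, 3, lower.tail = FALSE)  # 3/28
  se <- sqrt(exact * (1 - exact) / 10000)
  expect_equal(res$n_functional_hit, 2L)
  expect_lt(abs(res$p_emp_enrich - exact), 3 * se + 2e-4)

  # a larger case against the hypergeometric as well
  analyzed2 <- sprintf("t%03d", 1:40)
  functional2 <- analyzed2[1:10]
  recs2 <- fake_records(analyzed2[c(1:6, 15:18)])  # 10 hits, 6 functional
  res2 <- motif_enrichment(functional2, analyzed2, recs2, n_draws = 10000,
                           seed = 4)
  exact2 <- phyper(5, 10, 30, 10, lower.tail = FALSE)
  se2 <- sqrt(exact2 * (1 - exact2) / 10000)
  expect_lt(abs(res2$p_emp_enrich - exact2), 3 * se2 + 2e-4)
})

test_that("perfectly enriched sets reach the add-one floor", {
  analyzed <- sprintf("s%02d", 1:30)
  functional <- analyzed[1:5]
  recs <- fake_records(functional)  # every hit functional, none elsewhere
  res <- motif_enrichment(functional, analyzed, recs, n_draws = 2000, seed = 5)
  expect_equal(res$p_emp_enrich, 1 / 2001)
  expect_error(motif_enrichment(character(0), analyzed, recs), "empty")
  expect_error(motif_enrichment("zzz", analyzed, recs), "subset")
})

test_that("random functional labels give calibrated enrichment p-values", {
  set.seed(6)
  analyzed <- sprintf("s%03d", 1:120)
  # 120 TFs, each hitting a random quarter of the SNPs
  recs <- do.call(rbind, lapply(1:120, function(t)
    fake_records(sample(analyzed, 30), tf = sprintf("TF%03d", t))))
  functional <- sample(analyzed, 25)
  res <- motif_enrichment(functional, analyzed, recs, n_draws = 800, seed = 7)
  # hit counts are discrete, so the resampling p-value is valid but
  # conservative: the rejection rate must not exceed its nominal level,
  # and p must spread over the unit interval rather than pile up anywhere
  se05 <- sqrt(0.05 * 0.95 / nrow(res))
  expect_lte(mean(res$p_emp_enrich < 0.05), 0.05 + 3 * se05)
  expect_gt(mean(res$p_emp_enrich), 0.45)
  expect_lt(mean(res$p_emp_enrich), 0.7)
  expect_gt(mean(res$p_emp_enrich < 0.4), 0.15)
})

test_that("adding a motif-hit SNP to the functional set never raises its p", {
  analyzed <- sprintf("s%02d", 1:30)
  recs <- fake_records(analyzed[1:12])
  base_fun <- analyzed[c(1:4, 20:23)]
  p1 <- motif_enrichment(base_fun, analyzed, recs, n_draws = 4000,
                         seed = 8)$p_emp_enrich
  p2 <- motif_enrichment(c(base_fun, analyzed[5]), analyzed, recs,
                         n_draws = 4000, seed = 8)$p_emp_enrich
  expect_lte(p2, p1)
})

test_that("concordance counts motif-expression agreement and excludes ties", {
  analyzed <- sprintf("s%02d", 1:12)
  functional <- analyzed[1:4]
  recs <- rbind(fake_records(analyzed[1:4], better = "alt"),
                fake_records(analyzed[5:6], better = "ref"))
  allelic <- data.frame(snp_id = analyzed,
                        composite_log2fc = c(rep(1, 4), rep(-1, 8)))
  res <- concordance_enrichment(functional, analyzed, recs, allelic,
                                n_draws = 3000, seed = 9)
  # all 4 functional records concordant (alt better, alt higher), and the
  # 2 background records also concordant (ref better, ref higher):
  # observed = 4 of a possible 4 -> strong enrichment
  expect_equal(res$n_concordant, 4L)
  expect_lt(res$p_emp_concord, 0.05)

  # direction tie: excluded and reported
  allelic$composite_log2fc[1] <- 0
  res2 <- concordance_enrichment(functional, analyzed, recs, allelic,
                                 n_draws = 500, seed = 10)
  expect_equal(res2$n_ties_excluded, 1L)
  expect_equal(res2$n_concordant, 3L)
})

test_that("planted motif-expression coupling is detected as concordant", {
  sim <- sim_experiment(n_snps = 24, beta_allele = 0.8, n_basal = 30,
                        seed = 91)
  mf <- generate_motif_fixtures(sim$design, n_tfs = 2, plant_fraction = 1,
                                seed = 92)
  # force the motif's better allele to be alt, matching beta_allele > 0
  recs <- scan_all(mf$design, mf$pwms)
  recs <- recs[recs$better_allele == "alt", ]
  expect_gte(nrow(recs), 5)
  veh <- element_means(subset_samples(sim$expr, "vehicle"), sim$design)
  allelic <- run_allelic_tests(veh)
  functional <- allelic$snp_id[allelic$t_pvalue < 0.05]
  res <- concordance_enrichment(functional, allelic$snp_id, recs, allelic,
                                n_draws = 2000, seed = 93)
  # every functional SNP with a record is concordant by construction
  expect_true(all(res$n_concordant > 0))
})

test_that("compare_sets applies the threshold predicates exactly", {
  lmm <- expand.grid(p_emp_allele = c(0.05, 0.15),
                     p_emp_drug = c(0.05, 0.15),
                     p_emp_inter = c(0.01, 0.08, 0.15))
  lmm$snp_id <- sprintf("s%02d", seq_len(nrow(lmm)))
  s1 <- compare_sets("allele_vs_null", lmm = lmm)
  expect_setequal(s1$functional_ids, lmm$snp_id[lmm$p_emp_allele < 0.1])
  bg <- lmm$snp_id[lmm$p_emp_allele > 0.1 & lmm$p_emp_drug > 0.1 &
                     lmm$p_emp_inter > 0.1]
  expect_setequal(s1$analyzed_ids, union(s1$functional_ids, bg))

  s2 <- compare_sets("interaction_vs_allele", lmm = lmm)
  expect_setequal(s2$functional_ids, lmm$snp_id[lmm$p_emp_inter < 0.05])
  expect_setequal(
    setdiff(s2$analyzed_ids, s2$functional_ids),
    setdiff(lmm$snp_id[lmm$p_emp_allele < 0.1 & lmm$p_emp_inter > 0.1],
            s2$functional_ids))

  allelic <- data.frame(snp_id = c("a", "b", "c"),
                        p_emp = c(0.01, 0.05, 0.2))
  s3 <- compare_sets("first_assay", allelic = allelic)
  expect_identical(s3$functional_ids, "a")
  expect_identical(s3$analyzed_ids, c("a", "b", "c"))

  allelic$p_emp <- rep(1, 3)
  expect_error(compare_sets("first_assay", allelic = allelic), "empty")
})

test_that("ChIP overlap respects half-open BED semantics", {
  bed <- tempfile(fileext = ".bed")
  writeLines(c("chr1\t100\t200", "chr1\t500\t600", "chr2\t0\t50"), bed)
  peaks <- read_bed(bed, label = "trackA")
  snps <- data.frame(snp_id = sprintf("v%d", 1:5),
                     chrom = c("chr1", "chr1", "chr1", "chr2", "chr3"),
                     # 1-based positions: 101 is 0-based 100 (= start, in),
                     # 201 is 0-based 200 (= end, out)
                     pos = c(101, 201, 550, 1, 10))
  ov <- chip_overlap(snps, peaks)
  expect_equal(unname(ov$flags$trackA), c(TRUE, FALSE, TRUE, TRUE, FALSE))
  expect_equal(unname(ov$per_track_counts), 3L)
  expect_equal(ov$fraction_any, 3 / 5)

  # brute-force all-pairs oracle
  ints <- data.frame(chrom = c("chr1", "chr1", "chr2"),
                     s = c(100, 500, 0), e = c(200, 600, 50))
  brute <- vapply(seq_len(nrow(snps)), function(i) {
    p0 <- snps$pos[i] - 1  # 0-based
    any(ints$chrom == snps$chrom[i] & ints$s <= p0 & p0 < ints$e)
  }, TRUE)
  expect_equal(unname(ov$flags$trackA), brute)

  # empty interval set and malformed input
  empty <- tempfile(fileext = ".bed")
  writeLines(character(0), empty)
  ov0 <- chip_overlap(snps, read_bed(empty, label = "none"))
  expect_equal(unname(ov0$per_track_counts), 0L)
  writeLines("chr1\t10", bed)
  expect_error(read_bed(bed), "line 1")
  writeLines(c("chr1\t100\t200", "chr1\t50\tx"), bed)
  expect_error(read_bed(bed), "line 2")
})

test_that("overlap counting is order-independent and idempotent", {
  bed <- tempfile(fileext = ".bed")
  writeLines(c("chr1\t10\t20", "chr1\t5\t8"), bed)
  peaks <- read_bed(bed)
  snps <- data.frame(snp_id = c("a", "b", "c"), chrom = "chr1",
                     pos = c(6, 15, 30))
  o1 <- chip_overlap(snps, peaks)
  o2 <- chip_overlap(snps[c(3, 1, 2), ], peaks)
  expect_setequal(paste(o1$flags$snp_id, o1$flags[[2]]),
                  paste(o2$flags$snp_id, o2$flags[[2]]))
  expect_equal(chip_overlap(snps, peaks)$per_track_counts,
               o1$per_track_counts)
})
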