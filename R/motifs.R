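#' Construct a position weight matrix object
#'
#' @param tf_name Transcription factor name.
#' @param matrix Numeric matrix, 4 rows (A, C, G, T) x motif positions;
#'   each column must sum to 1 (within 1e-9).
#' @param background Base background frequencies (default uniform 0.25).
#' @return An object of class `mpra_pwm`.
#' @export
new_pwm <- function(tf_name, matrix, background = rep(0.25, 4L)) {
  stopifnot(is.matrix(matrix), nrow(matrix) == 4L, ncol(matrix) >= 1L,
            all(matrix >= 0), length(background) == 4L,
            abs(sum(background) - 1) < 1e-9)
  if (any(abs(colSums(matrix) - 1) > 1e-9))
    stop("PWM columns must each sum to 1")
  rownames(matrix) <- c("A", "C", "G", "T")
  structure(list(tf_name = tf_name, matrix = matrix,
                 background = background), class = "mpra_pwm")
}

#' @export
print.mpra_pwm <- function(x, ...) {
  cat("PWM", x$tf_name, "(", ncol(x$matrix), "positions )\n")
  invisible(x)
}

#' Consensus sequence of a PWM (highest-probability base per position)
#' @param pwm An `mpra_pwm`.
#' @return Consensus string.
#' @export
consensus_seq <- function(pwm) {
  paste(rownames(pwm$matrix)[apply(pwm$matrix, 2L, which.max)], collapse = "")
}

.revcomp <- function(seq) {
  chartr("ACGTN", "TGCAN", paste(rev(strsplit(seq, "")[[1]]), collapse = ""))
}

# Per-position log2 odds lookup with a 5th row (N) scoring 0 (background).
.lo_matrix <- function(pwm) {
  lo <- log2(pwm$matrix / pwm$background)
  rbind(lo, N = 0)
}

.seq_codes <- function(seq) {
  codes <- match(strsplit(toupper(seq), "")[[1]], c("A", "C", "G", "T", "N"))
  if (anyNA(codes)) stop("sequence contains bases outside {A,C,G,T,N}")
  codes
}

# Log-odds of every window start (forward orientation of the given codes).
.window_scores <- function(codes, lo) {
  L <- ncol(lo)
  n_win <- length(codes) - L + 1L
  out <- numeric(n_win)
  for (j in seq_len(L)) out <- out + lo[codes[j:(j + n_win - 1L)], j]
  out
}

#' Scan a sequence with a PWM
#'
#' Scores every window on both strands with the log2-odds score
#' `sum(log2(p_base / background))`; `N` bases contribute 0. The relative
#' score rescales the log-odds to `[0, 1]` between the PWM's attainable
#' extremes. Ties are broken toward the leftmost position and forward
#' strand.
#'
#' @param seq Nucleotide string (A/C/G/T/N).
#' @param pwm An `mpra_pwm`.
#' @param windows Optional integer vector of window start positions
#'   (1-based) to restrict the scan to.
#' @param both_strands Scan the reverse strand as well (default TRUE).
#' @return List with `score` (best log-odds), `rel_score`, `position`
#'   (1-based window start on the given sequence), `strand` (`"+"`/`"-"`).
#' @export
score_sequence <- function(seq, pwm, windows = NULL, both_strands = TRUE) {
  stopifnot(inherits(pwm, "mpra_pwm"))
  L <- ncol(pwm$matrix)
  if (!nzchar(seq) || nchar(seq) < L)
    stop("sequence shorter than the motif (", nchar(seq), " < ", L, ")")
  lo <- .lo_matrix(pwm)
  codes <- .seq_codes(seq)
  n <- length(codes)
  fwd <- .window_scores(codes, lo)
  # reverse strand: score the reverse complement of each window; window i
  # on the reverse complement of the full sequence corresponds to forward
  # window (n - L + 2 - i).
  if (!is.null(windows)) {
    keep <- windows
    stopifnot(all(keep >= 1L), all(keep <= n - L + 1L))
  } else keep <- seq_len(n - L + 1L)
  if (both_strands) {
    rc <- .seq_codes(.revcomp(seq))
    rev_all <- .window_scores(rc, lo)
    rev <- rev_all[(n - L + 1L):1L]  # indexed by forward window start
    sc <- c(fwd[keep], rev[keep])
  } else sc <- fwd[keep]
  best <- which.max(sc)  # which.max takes the first (leftmost fwd) maximum
  strand <- if (best <= length(keep)) "+" else "-"
  pos <- keep[(best - 1L) %% length(keep) + 1L]
  score <- unname(sc[best])
  lims <- c(sum(apply(lo[1:4, , drop = FALSE], 2L, min)),
            sum(apply(lo[1:4, , drop = FALSE], 2L, max)))
  list(score = score,
       rel_score = (score - lims[1L]) / (lims[2L] - lims[1L]),
       position = pos, strand = strand)
}

#' Allelic motif perturbation at one SNP
#'
#' Scans only the windows overlapping the SNP position in each allele's
#' element sequence, and compares the alleles' best relative scores.
#' `delta = alt_rel - ref_rel`; the perturbation is `"strong"` when the
#' better allele matches the motif at `match_threshold` or above and
#' `|delta| >= strong_delta`; `"weak"` when `|delta| >= weak_delta`;
#' otherwise `"none"`.
#'
#' @param design An `mpra_design` with element sequences.
#' @param snp_id SNP identifier.
#' @param pwm An `mpra_pwm`.
#' @param match_threshold Minimum best relative score for a "strong" call
#'   (default 0.85).
#' @param strong_delta,weak_delta Relative-score change thresholds
#'   (defaults 0.3 and 0.1).
#' @param tie_tol Absolute delta below which alleles tie (default 1e-9).
#' @return Data.frame (one row): `snp_id`, `tf_name`, `ref_score`,
#'   `alt_score`, `ref_rel`, `alt_rel`, `delta`, `strength`,
#'   `better_allele`, best position/strand per allele.
#' @export
allelic_perturbation <- function(design, snp_id, pwm, match_threshold = 0.85,
                                 strong_delta = 0.3, weak_delta = 0.1,
                                 tie_tol = 1e-9) {
  stopifnot(inherits(design, "mpra_design"), inherits(pwm, "mpra_pwm"))
  i <- match(snp_id, design$snps$snp_id)
  if (is.na(i)) stop("unknown SNP: ", snp_id)
  ref <- design$snps$ref_seq[i]
  alt <- design$snps$alt_seq[i]
  centre <- design$snp_position
  if (substr(ref, centre, centre) != design$snps$ref_allele[i] ||
      substr(alt, centre, centre) != design$snps$alt_allele[i])
    stop("SNP ", snp_id, " is not at the expected centre position")
  L <- ncol(pwm$matrix)
  n <- nchar(ref)
  if (L > n) stop("element shorter than the motif for ", snp_id)
  windows <- max(1L, centre - L + 1L):min(n - L + 1L, centre)
  r <- score_sequence(ref, pwm, windows = windows)
  a <- score_sequence(alt, pwm, windows = windows)
  delta <- a$rel_score - r$rel_score
  strength <- if (max(r$rel_score, a$rel_score) >= match_threshold &&
                  abs(delta) >= strong_delta) "strong"
  else if (abs(delta) >= weak_delta) "weak" else "none"
  better <- if (abs(delta) <= tie_tol) "tie"
  else if (delta > 0) "alt" else "ref"
  data.frame(snp_id = snp_id, tf_name = pwm$tf_name,
             ref_score = r$score, alt_score = a$score,
             ref_rel = r$rel_score, alt_rel = a$rel_score,
             delta = delta, strength = strength, better_allele = better,
             ref_position = r$position, ref_strand = r$strand,
             alt_position = a$position, alt_strand = a$strand,
             stringsAsFactors = FALSE)
}

#' Scan every SNP against every PWM
#'
#' Cartesian product of the design's SNPs and the PWM set; records with
#' `strength != "none"` are retained, ordered by (`snp_id`, `tf_name`).
#'
#' @param design An `mpra_design`.
#' @param pwmset An `mpra_pwm_set` (named list of `mpra_pwm`).
#' @param ... Thresholds passed to [allelic_perturbation()].
#' @return Data.frame of perturbation records (possibly empty).
#' @export
scan_all <- function(design, pwmset, ...) {
  rows <- list()
  for (sid in sort(design$snps$snp_id)) {
    for (tf in sort(names(pwmset))) {
      rec <- allelic_perturbation(design, sid, pwmset[[tf]], ...)
      if (rec$strength != "none") rows[[length(rows) + 1L]] <- rec
    }
  }
  if (!length(rows)) {
    return(data.frame(snp_id = character(0), tf_name = character(0),
                      ref_score = numeric(0), alt_score = numeric(0),
                      ref_rel = numeric(0), alt_rel = numeric(0),
                      delta = numeric(0), strength = character(0),
                      better_allele = character(0),
                      ref_position = integer(0), ref_strand = character(0),
                      alt_position = integer(0), alt_strand = character(0),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
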