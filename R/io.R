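#' Write a library design to plain-text files
#'
#' Writes the barcode map as TSV (`barcode`, `snp_id`, `allele`; basal
#' barcodes carry `snp_id = ""` and `allele = "basal"`) and, optionally,
#' the element sequences as FASTA with record ids `snp_id|allele`.
#'
#' @param design An `mpra_design`.
#' @param map_path Path for the design map TSV.
#' @param fasta_path Optional path for the element FASTA.
#' @return Invisibly, the design.
#' @export
write_design <- function(design, map_path, fasta_path = NULL) {
  bm <- design$barcode_map
  tab <- rbind(bm, data.frame(barcode = design$basal_barcodes,
                              snp_id = "", allele = "basal",
                              stringsAsFactors = FALSE))
  utils::write.table(tab, map_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(fasta_path)) {
    seqs <- c(design$snps$ref_seq, design$snps$alt_seq)
    names(seqs) <- c(paste0(design$snps$snp_id, "|ref"),
                     paste0(design$snps$snp_id, "|alt"))
    Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), fasta_path)
  }
  invisible(design)
}

#' Write simulated counts to TSV files
#'
#' @param counts An `mpra_counts`.
#' @param dna_path TSV path for DNA counts (`barcode`, `count`).
#' @param rna_path TSV path for RNA counts (first column `barcode`, one
#'   column per sample).
#' @param meta_path TSV path for sample metadata.
#' @return Invisibly, the counts.
#' @export
write_counts <- function(counts, dna_path, rna_path, meta_path) {
  utils::write.table(
    data.frame(barcode = names(counts$dna), count = counts$dna),
    dna_path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(barcode = rownames(counts$rna), counts$rna,
               check.names = FALSE),
    rna_path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(counts$sample_meta, meta_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(counts)
}

#' Read count tables written by [write_counts()]
#'
#' @param dna_path,rna_path,meta_path TSV paths in the dialect written by
#'   [write_counts()].
#' @return An `mpra_counts`.
#' @export
read_counts <- function(dna_path, rna_path, meta_path) {
  dna_df <- utils::read.delim(dna_path, stringsAsFactors = FALSE)
  dna <- as.integer(dna_df$count)
  names(dna) <- dna_df$barcode
  rna_df <- utils::read.delim(rna_path, check.names = FALSE,
                              stringsAsFactors = FALSE)
  rna <- as.matrix(rna_df[, -1L, drop = FALSE])
  storage.mode(rna) <- "integer"
  rownames(rna) <- rna_df[[1L]]
  meta <- utils::read.delim(meta_path, stringsAsFactors = FALSE)
  structure(list(dna = dna, rna = rna, sample_meta = meta),
            class = "mpra_counts")
}

#' Write PWMs as JASPAR-style plain text
#'
#' One record per PWM: a `>name` header followed by four rows
#' `A [ ... ]` etc. of per-position probabilities.
#'
#' @param pwmset An `mpra_pwm_set` (named list of `mpra_pwm`).
#' @param path Output path.
#' @export
write_jaspar <- function(pwmset, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (p in pwmset) {
    writeLines(paste0(">", p$tf_name), con)
    for (b in c("A", "C", "G", "T")) {
      writeLines(sprintf("%s [ %s ]", b,
                         paste(format(p$matrix[b, ], digits = 10),
                               collapse = " ")), con)
    }
  }
  invisible(pwmset)
}

#' Read JASPAR-style PWM text
#'
#' Accepts probability or count matrices; count matrices are converted to
#' probabilities with a pseudocount split by the background frequencies.
#'
#' @param path Input path.
#' @param pseudocount Pseudocount for count matrices (default 0.8).
#' @param background Base background frequencies (default uniform).
#' @return An `mpra_pwm_set`.
#' @export
read_jaspar <- function(path, pseudocount = 0.8,
                        background = rep(0.25, 4L)) {
  lines <- readLines(path)
  lines <- trimws(lines[nzchar(trimws(lines))])
  heads <- grep("^>", lines)
  if (!length(heads)) stop("no PWM records found in ", path)
  out <- list()
  for (h in seq_along(heads)) {
    i <- heads[h]
    name <- sub("^>\\s*", "", lines[i])
    name <- strsplit(name, "\\s+")[[1]]
    name <- name[length(name)]  # JASPAR headers: ">MA0001.1 NAME"
    rows <- lines[(i + 1L):(i + 4L)]
    vals <- lapply(rows, function(r) {
      r <- sub("^[ACGTacgt]\\s*", "", r)
      r <- gsub("\\[|\\]", " ", r)
      as.numeric(strsplit(trimws(r), "\\s+")[[1]])
    })
    m <- do.call(rbind, vals)
    rownames(m) <- c("A", "C", "G", "T")
    if (any(abs(colSums(m) - 1) > 1e-6)) {  # counts, not probabilities
      m <- sweep(m + pseudocount * background,
                 2L, colSums(m) + pseudocount, "/")
    }
    out[[name]] <- new_pwm(name, m, background = background)
  }
  structure(out, class = "mpra_pwm_set")
}
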