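#' Default coding variant classifications
#'
#' MAF `Variant_Classification` values counted as coding-sequence
#' mutations by [read_maf_counts()]. Configurable per call.
#' @export
default_coding_classes <- function() {
  c("Missense_Mutation", "Nonsense_Mutation", "Silent",
    "Frame_Shift_Del", "Frame_Shift_Ins", "In_Frame_Del", "In_Frame_Ins",
    "Splice_Site", "Translation_Start_Site", "Nonstop_Mutation")
}

#' Count coding mutations per gene from a MAF-lite table
#'
#' Reads a tab-separated file with a header containing at least
#' `Hugo_Symbol` and `Variant_Classification` (a subset of the standard
#' MAF columns) and tallies, per gene, the rows whose classification is in
#' `coding_classes`, pooling all samples.
#'
#' @param path MAF-lite TSV path.
#' @param coding_classes Classifications counted as CDS mutations.
#' @return `data.frame` with `gene_id` and `count`; attribute `n_samples`
#'   holds the number of distinct `Tumor_Sample_Barcode` values when that
#'   column is present.
#' @export
read_maf_counts <- function(path, coding_classes = default_coding_classes()) {
  d <- utils::read.table(path, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE, quote = "",
                         comment.char = "#", check.names = FALSE)
  for (col in c("Hugo_Symbol", "Variant_Classification")) {
    if (!col %in% names(d)) stop("MAF input is missing required column ", col)
  }
  keep <- d$Variant_Classification %in% coding_classes
  tab <- table(d$Hugo_Symbol[keep])
  out <- data.frame(gene_id = names(tab), count = as.integer(tab),
                    stringsAsFactors = FALSE)
  out <- out[order(out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  if ("Tumor_Sample_Barcode" %in% names(d)) {
    attr(out, "n_samples") <- length(unique(d$Tumor_Sample_Barcode))
  }
  out
}

#' First quartile of gene lengths
#'
#' 25th percentile with linear interpolation between order statistics
#' (type-7 quantile, the mainstream default). Q1 sets the scale of the
#' burden adjustment, so the convention is fixed and recorded in run
#' provenance.
#'
#' @param lengths Positive lengths in bp.
#' @return Scalar Q1.
#' @export
first_quartile <- function(lengths) {
  if (length(lengths) == 0L) stop("empty length vector")
  stats::quantile(lengths, 0.25, type = 7, names = FALSE)
}

#' Length-adjusted mutation count
#'
#' \deqn{\mathrm{adjusted} = \frac{m}{L + Q_1 \log_2 L}}
#' where `m` is the gene's total coding mutation count, `L` its CDS length
#' in bp and `Q1` the first quartile of CDS lengths. The denominator grows
#' slower than `L`, so for a fixed per-bp mutation rate the adjusted count
#' increases with length — gene-size bias is mitigated while relative
#' burden in long genes is emphasized.
#'
#' @param m Total mutation count (vectorized).
#' @param cds_length CDS length in bp, at least 2.
#' @param q1 First quartile of CDS lengths (positive).
#' @return Adjusted count(s).
#' @export
adjusted_mutation_count <- function(m, cds_length, q1) {
  if (any(cds_length < 2)) stop("cds_length must be >= 2 (log2 term degenerate)")
  if (q1 <= 0) stop("Q1 must be positive")
  if (any(m < 0)) stop("mutation counts must be non-negative")
  m / (cds_length + q1 * log2(cds_length))
}

#' Classify high-mutation genes
#'
#' Flags genes whose adjusted mutation count is strictly greater than the
#' median over all genes with mutation data; at most half the genes can be
#' flagged, and a constant vector flags none.
#'
#' @param adjusted Named numeric vector of adjusted counts.
#' @return Named logical vector.
#' @export
classify_high_mutation <- function(adjusted) {
  if (length(adjusted) == 0L) stop("no adjusted counts supplied")
  adjusted > stats::median(adjusted)
}

#' Per-band mutation-burden tests
#'
#' For each band of interest, runs (a) a hypergeometric upper-tail test of
#' high-mutation genes in the band against the universe of all genes with
#' mutation data (shared implementation: [hypergeometric_upper()]) and
#' (b) a two-sample t-test comparing the band genes' adjusted counts with
#' all other genes (Welch by default). BH adjustment is applied separately
#' within each test family. Bands with fewer than 2 genes skip the t-test
#' (reported as `NA`); the hypergeometric test still runs.
#'
#' @param genes `data.frame` with `gene_id`, `band_id`, `adjusted`
#'   (numeric) and `high_mut` (logical) columns.
#' @param bands_of_interest Band ids to test.
#' @param welch Use Welch's unequal-variance t-test (default) or the
#'   pooled-variance variant.
#' @return `data.frame` with `band_id, n_genes, n_high_mut, mean_adjusted,
#'   p_hyper_raw, p_hyper_adj, p_ttest_raw, p_ttest_adj`.
#' @export
band_burden_tests <- function(genes, bands_of_interest, welch = TRUE) {
  stopifnot(all(c("band_id", "adjusted", "high_mut") %in% names(genes)))
  if (any(is.na(genes$band_id))) stop("every gene needs a band assignment")
  N <- nrow(genes)
  K <- sum(genes$high_mut)
  rows <- lapply(bands_of_interest, function(b) {
    inb <- genes$band_id == b
    n <- sum(inb)
    k <- sum(genes$high_mut[inb])
    p_h <- hypergeometric_upper(k, K, n, N)
    p_t <- if (n >= 2L && (N - n) >= 2L) {
      stats::t.test(genes$adjusted[inb], genes$adjusted[!inb],
                    var.equal = !welch)$p.value
    } else NA_real_
    data.frame(band_id = b, n_genes = n, n_high_mut = k,
               mean_adjusted = if (n > 0L) mean(genes$adjusted[inb]) else NA_real_,
               p_hyper_raw = p_h, p_ttest_raw = p_t,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$p_hyper_adj <- benjamini_hochberg(res$p_hyper_raw)
  res$p_ttest_adj <- NA_real_
  ok <- !is.na(res$p_ttest_raw)
  if (any(ok)) res$p_ttest_adj[ok] <- benjamini_hochberg(res$p_ttest_raw[ok])
  res <- res[, c("band_id", "n_genes", "n_high_mut", "mean_adjusted",
                 "p_hyper_raw", "p_hyper_adj", "p_ttest_raw", "p_ttest_adj")]
  rownames(res) <- NULL
  attr(res, "bh_family_sizes") <- c(hyper = nrow(res), ttest = sum(ok))
  res
}
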