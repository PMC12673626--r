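#' Exact Poisson rate-ratio F test for one band
#'
#' Tests whether a band's variant density exceeds the genome-wide
#' background. With `k` of `N` variants in a band of length `L_b` inside a
#' genome of length `L_tot`, the enrichment rate ratio is
#' \deqn{F = \frac{k / L_b}{(N - k + 1) / (L_{tot} - L_b)}}
#' which under the null of uniform placement is referred to an F
#' distribution with `df1 = 2(N - k + 1)` and `df2 = 2k` degrees of
#' freedom; the one-sided (enrichment) p-value is the upper tail at `F`.
#' This is the exact conditional test: the p-value equals the binomial
#' tail `P(X >= k | n = N, pi = L_b/L_tot)` (beta-F identity), so the `+1`
#' term is a continuity device, not an approximation.
#'
#' `k = 0` is degenerate (`df2` would be 0) and returns `F = 0`,
#' `p_raw = 1`, `df2 = 0`.
#'
#' @param k Variant count in the band (vectorized).
#' @param N Total variant count genome-wide.
#' @param length_bp Band length in bp (vectorized with `k`).
#' @param total_length_bp Genome length in bp.
#' @return `data.frame` with columns `F`, `df1`, `df2`, `p_raw`.
#' @export
poisson_rate_f_test <- function(k, N, length_bp, total_length_bp) {
  if (any(k < 0) || any(k > N)) stop("k must satisfy 0 <= k <= N")
  if (N < 1) stop("N must be >= 1")
  if (any(length_bp <= 0) || any(length_bp >= total_length_bp)) {
    stop("band length must satisfy 0 < length_bp < total_length_bp")
  }
  n <- max(length(k), length(length_bp))
  k <- rep_len(k, n); length_bp <- rep_len(length_bp, n)
  F_stat <- (k / length_bp) / ((N - k + 1) / (total_length_bp - length_bp))
  df1 <- 2 * (N - k + 1)
  df2 <- 2 * k
  p <- ifelse(k == 0, 1,
              stats::pf(F_stat, df1, df2, lower.tail = FALSE))
  F_stat[k == 0] <- 0
  data.frame(F = F_stat, df1 = df1, df2 = df2, p_raw = p)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Computes BH-adjusted p-values: with order statistics `p_(1) <= ... <=
#' p_(m)`, `adj_(i) = min_{j >= i} min(1, p_(j) m / j)`. Adjustment is
#' order-preserving, never below the raw value, and ties share one
#' adjusted value.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, same order as the input.
#' @export
benjamini_hochberg <- function(p) {
  if (length(p) == 0L) return(numeric(0))
  if (any(is.na(p)) || any(p < 0) || any(p > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  m <- length(p)
  desc <- order(p, decreasing = TRUE)
  back <- order(desc)
  pmin(1, cummin(p[desc] * m / seq.int(m, 1)))[back]
}

#' Genome-wide band scan for variant clustering
#'
#' Applies [poisson_rate_f_test()] to every band with at least one variant
#' and controls the FDR with [benjamini_hochberg()] across all tested
#' bands (bands with `k = 0` are excluded from the family: their `df2` is
#' undefined and they cannot be enriched).
#'
#' @param counts `data.frame` `band_id`, `count` covering every band of
#'   the annotation (zeros allowed), as produced by [assign_variants()].
#' @param annotation A `genome_annotation`.
#' @param N Total variant count (must be at least `sum(counts$count)`;
#'   variants left unassigned still contribute to the background).
#' @param alpha FDR threshold for the `significant` flag.
#' @return `data.frame` of class `band_scan_result` with columns
#'   `band_id, k, length_bp, F, df1, df2, p_raw, p_adj, significant`,
#'   sorted by `p_adj` (ties by `band_id`).
#' @export
scan_bands <- function(counts, annotation, N, alpha = 0.05) {
  stopifnot(all(annotation$band_id %in% counts$band_id))
  counts <- counts[match(annotation$band_id, counts$band_id), , drop = FALSE]
  if (sum(counts$count) > N) stop("sum of band counts exceeds N")
  keep <- counts$count >= 1L
  k <- counts$count[keep]
  len <- annotation$length_bp[keep]
  ft <- poisson_rate_f_test(k, N, len, total_length(annotation))
  res <- data.frame(band_id = annotation$band_id[keep],
                    k = k, length_bp = len,
                    F = ft$F, df1 = ft$df1, df2 = ft$df2,
                    p_raw = ft$p_raw,
                    stringsAsFactors = FALSE)
  res$p_adj <- benjamini_hochberg(res$p_raw)
  res$significant <- res$p_adj < alpha
  res <- res[order(res$p_adj, res$band_id), , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "bh_family_size") <- nrow(res)
  attr(res, "alpha") <- alpha
  class(res) <- c("band_scan_result", "data.frame")
  res
}

#' Write a band-scan report TSV
#'
#' Fixed column order `band_id, k, length_bp, F, df1, df2, p_raw, p_adj,
#' significant`; `F` and p-values are formatted to 4 significant digits.
#'
#' @param results A `band_scan_result`.
#' @param path Output path.
#' @param sort_by `"p_adj"` (default) or `"band_id"`.
#' @export
write_scan_report <- function(results, path, sort_by = c("p_adj", "band_id")) {
  sort_by <- match.arg(sort_by)
  r <- as.data.frame(results)
  if (sort_by == "band_id") r <- r[order(r$band_id), , drop = FALSE]
  r$F <- signif(r$F, 4)
  r$p_raw <- signif(r$p_raw, 4)
  r$p_adj <- signif(r$p_adj, 4)
  utils::write.table(r[, c("band_id", "k", "length_bp", "F", "df1", "df2",
                           "p_raw", "p_adj", "significant")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
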