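#' Hypergeometric upper-tail probability
#'
#' `P(X >= k)` where `X` counts query members in a size-`n` draw from a
#' universe of `N` genes of which `K` are query members — the standard
#' over-representation test. The roles of query and target are symmetric
#' (`K` and `n` can be swapped without changing the result).
#'
#' @param k Observed overlap (vectorized).
#' @param K Query size in the universe.
#' @param n Target size in the universe.
#' @param N Universe size.
#' @return Upper-tail probability in `(0, 1]`.
#' @export
hypergeometric_upper <- function(k, K, n, N) {
  len <- max(length(k), length(K), length(n), length(N))
  k <- rep_len(k, len); K <- rep_len(K, len)
  n <- rep_len(n, len); N <- rep_len(N, len)
  if (any(k < 0) || any(K > N) || any(n > N) || any(k > pmin(K, n))) {
    stop("inconsistent hypergeometric counts: need 0 <= k <= min(K, n) <= N")
  }
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Read gene sets from a GMT file
#'
#' Tab-separated lines `set_id<TAB>description<TAB>member1<TAB>member2...`.
#' Duplicate members within a set are dropped.
#'
#' @param path GMT file path.
#' @return A named list of unique member vectors, with a parallel
#'   `description` attribute (named character vector).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3L)
  if (length(bad)) stop("GMT line ", bad[1L], ": fewer than 3 fields")
  ids <- vapply(fields, `[[`, "", 1L)
  if (anyDuplicated(ids)) stop("duplicate set id in GMT: ", ids[duplicated(ids)][1L])
  sets <- lapply(fields, function(f) unique(f[-c(1L, 2L)]))
  names(sets) <- ids
  desc <- vapply(fields, `[[`, "", 2L)
  names(desc) <- ids
  attr(sets, "description") <- desc
  sets
}

#' Write gene sets to a GMT file
#' @param sets Named list of member vectors (optional `description`
#'   attribute; defaults to the set id).
#' @param path Output path.
#' @export
write_gmt <- function(sets, path) {
  desc <- attr(sets, "description")
  if (is.null(desc)) desc <- stats::setNames(names(sets), names(sets))
  lines <- vapply(names(sets), function(id) {
    paste(c(id, desc[[id]], sets[[id]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Reciprocal enrichment of gene sets within chromosomal bands
#'
#' For every (gene set, band) pair, tests whether the set's members are
#' over-represented among the band's genes by a hypergeometric upper-tail
#' test; BH adjustment is applied across all pairs in the run. Members
#' outside the universe are dropped (counted in a message); sets smaller
#' than `min_set_size` after intersection are skipped.
#'
#' @param sets Named list of gene-id vectors (as from [read_gmt()]).
#' @param genes `data.frame` with `gene_id` and `band_id` (see
#'   [assign_genes_to_bands()]).
#' @param bands_of_interest Character vector of band ids to test.
#' @param universe Gene-id vector; default all `genes$gene_id`.
#' @param min_set_size Minimum query size after universe intersection.
#' @return `data.frame` with columns `query_id, target_id, n_target,
#'   k_overlap, K_query, N_universe, p_raw, p_adj`, ordered by
#'   `(query_id, target_id)`.
#' @export
enrich_sets_in_bands <- function(sets, genes, bands_of_interest,
                                 universe = NULL, min_set_size = 2L) {
  if (is.null(universe)) universe <- genes$gene_id
  universe <- unique(universe)
  if (length(universe) == 0L) stop("empty gene universe")
  missing_bands <- setdiff(bands_of_interest, genes$band_id)
  if (length(missing_bands)) {
    stop("band(s) absent from gene table: ",
         paste(missing_bands, collapse = ", "))
  }
  band_members <- lapply(bands_of_interest, function(b) {
    intersect(genes$gene_id[!is.na(genes$band_id) & genes$band_id == b],
              universe)
  })
  names(band_members) <- bands_of_interest
  N <- length(universe)
  rows <- list()
  for (sid in sort(names(sets))) {
    members <- unique(sets[[sid]])
    inside <- intersect(members, universe)
    if (length(inside) < length(members)) {
      message("set ", sid, ": ", length(members) - length(inside),
              " member(s) outside universe dropped")
    }
    if (length(inside) < min_set_size) {
      message("set ", sid, " skipped (", length(inside),
              " members after universe intersection)")
      next
    }
    for (b in sort(bands_of_interest)) {
      tgt <- band_members[[b]]
      rows[[length(rows) + 1L]] <- data.frame(
        query_id = sid, target_id = b,
        n_target = length(tgt),
        k_overlap = length(intersect(inside, tgt)),
        K_query = length(inside), N_universe = N,
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) stop("no testable sets")
  res <- do.call(rbind, rows)
  res$p_raw <- hypergeometric_upper(res$k_overlap, res$K_query,
                                    res$n_target, res$N_universe)
  res$p_adj <- benjamini_hochberg(res$p_raw)
  res <- res[order(res$query_id, res$target_id), , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "bh_family_size") <- nrow(res)
  res
}

#' Term over-representation analysis for a query gene list
#'
#' Standard ORA: one hypergeometric test per annotation term, BH across
#' terms. Terms with zero overlap are reported with `p = 1` by default or
#' skipped when `include_zero_overlap = FALSE`.
#'
#' @param query_genes Character vector of gene ids.
#' @param annotation_sets Named list of term member vectors.
#' @param universe Gene-id vector.
#' @param min_set_size Minimum term size after universe intersection.
#' @param include_zero_overlap Report zero-overlap terms (`p = 1`)?
#' @return `data.frame` as in [enrich_sets_in_bands()] with `query_id` the
#'   literal `"query"` and `target_id` the term id.
#' @export
term_overrepresentation <- function(query_genes, annotation_sets, universe,
                                    min_set_size = 2L,
                                    include_zero_overlap = TRUE) {
  universe <- unique(universe)
  if (length(universe) == 0L) stop("empty gene universe")
  query <- intersect(unique(query_genes), universe)
  if (length(query) == 0L) stop("query gene list empty after universe intersection")
  N <- length(universe)
  rows <- list()
  for (tid in sort(names(annotation_sets))) {
    term <- intersect(unique(annotation_sets[[tid]]), universe)
    if (length(term) < min_set_size) {
      message("term ", tid, " skipped (", length(term), " members in universe)")
      next
    }
    k <- length(intersect(query, term))
    if (k == 0L && !include_zero_overlap) next
    rows[[length(rows) + 1L]] <- data.frame(
      query_id = "query", target_id = tid,
      n_target = length(term), k_overlap = k,
      K_query = length(query), N_universe = N,
      stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L) stop("no testable terms")
  res <- do.call(rbind, rows)
  res$p_raw <- hypergeometric_upper(res$k_overlap, res$K_query,
                                    res$n_target, res$N_universe)
  res$p_adj <- benjamini_hochberg(res$p_raw)
  rownames(res) <- NULL
  attr(res, "bh_family_size") <- nrow(res)
  res
}

#' Write an enrichment result TSV
#' @param res Result `data.frame` from [enrich_sets_in_bands()] or
#'   [term_overrepresentation()].
#' @param path Output path.
#' @export
write_enrichment <- function(res, path) {
  r <- as.data.frame(res)
  r$p_raw <- signif(r$p_raw, 4)
  r$p_adj <- signif(r$p_adj, 4)
  utils::write.table(r[, c("query_id", "target_id", "n_target", "k_overlap",
                           "K_query", "N_universe", "p_raw", "p_adj")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
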