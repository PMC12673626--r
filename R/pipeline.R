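#' Step 1: deduplicate, assign and scan variants across bands
#'
#' Reads the cytoband and variant inputs, removes duplicate variants,
#' assigns the unique sites to major bands and runs the genome-wide rate
#' scan. Writes `step1_band_scan.tsv` (band, k, length, F, df pair, raw
#' and adjusted p, significance) sorted by band id.
#'
#' @param cytoband Path to a UCSC-style cytoBand TSV.
#' @param variants Path to a variant TSV (or a pre-read `data.frame`).
#' @param out_dir Output directory (created if needed); `NULL` skips
#'   writing.
#' @param alpha FDR threshold.
#' @return List with `annotation`, `variants` (deduplicated), `counts`,
#'   `scan` (the `band_scan_result`), `significant_bands`, `n_unassigned`.
#' @export
run_step1 <- function(cytoband, variants, out_dir = NULL, alpha = 0.05) {
  if (!file.exists(cytoband)) stop("cytoband input not found: ", cytoband)
  ann <- collapse_to_major_bands(parse_cytoband(cytoband))
  v <- if (is.character(variants)) {
    if (!file.exists(variants)) stop("variant input not found: ", variants)
    read_variants(variants)
  } else variants
  v <- dedup_variants(v)
  if (nrow(v) == 0L) stop("no variants after deduplication")
  asg <- assign_variants(v, ann)
  scan <- scan_bands(asg$counts, ann, N = nrow(v), alpha = alpha)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_scan_report(scan, file.path(out_dir, "step1_band_scan.tsv"),
                      sort_by = "band_id")
  }
  list(annotation = ann, variants = v, counts = asg$counts, scan = scan,
       significant_bands = scan$band_id[scan$significant],
       n_unassigned = nrow(asg$unassigned))
}

#' Step 2: functional enrichment and reciprocal band enrichment
#'
#' First direction: ORA of the genes located in the significant bands
#' against the supplied term sets. Second (reciprocal) direction: each
#' term's full gene set tested for concentration within the significant
#' bands. Writes `step2_term_ora.tsv` and `step2_reciprocal.tsv`.
#'
#' @param genes Gene table (path or `data.frame`) with band assignments
#'   added against `annotation` when missing.
#' @param gene_sets GMT path or a named list of member vectors.
#' @param significant_bands Band ids (deduplicated; empty is an error).
#' @param annotation A `genome_annotation` (needed if `genes` lacks
#'   `band_id`).
#' @param out_dir Output directory or `NULL`.
#' @param universe Optional gene-id universe (default: whole gene table).
#' @return List with `ora` and `reciprocal` result tables.
#' @export
run_step2 <- function(genes, gene_sets, significant_bands, annotation = NULL,
                      out_dir = NULL, universe = NULL) {
  if (length(significant_bands) == 0L) stop("empty band list")
  if (anyDuplicated(significant_bands)) {
    warning("duplicate band ids in list; deduplicated")
    significant_bands <- unique(significant_bands)
  }
  genes <- .load_genes(genes, annotation)
  sets <- if (is.character(gene_sets)) read_gmt(gene_sets) else gene_sets
  if (is.null(universe)) universe <- genes$gene_id
  query <- genes$gene_id[!is.na(genes$band_id) &
                           genes$band_id %in% significant_bands]
  ora <- term_overrepresentation(query, sets, universe)
  reciprocal <- enrich_sets_in_bands(sets, genes, significant_bands, universe)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_enrichment(ora, file.path(out_dir, "step2_term_ora.tsv"))
    write_enrichment(reciprocal, file.path(out_dir, "step2_reciprocal.tsv"))
  }
  list(ora = ora, reciprocal = reciprocal)
}

#' Step 4: enrichment of a DEG list within bands
#'
#' Hypergeometric test of the differentially-expressed-gene list within
#' each band of interest, reporting every band including non-significant
#' (`p_adj = 1`) rows. Writes `step4_deg_bands.tsv` with columns
#' `band_id, n_genes, n_DEGs, p_raw, p_adj`.
#'
#' @param genes Gene table (path or `data.frame`, see [run_step2()]).
#' @param deg DEG list: path to a one-id-per-line file or a character
#'   vector. Ids absent from the gene table are dropped (count logged).
#' @param significant_bands Band ids to test.
#' @param annotation Optional `genome_annotation`.
#' @param out_dir Output directory or `NULL`.
#' @param universe Optional universe (default: whole gene table).
#' @return The per-band result `data.frame`.
#' @export
run_step4 <- function(genes, deg, significant_bands, annotation = NULL,
                      out_dir = NULL, universe = NULL) {
  genes <- .load_genes(genes, annotation)
  deg_ids <- if (is.character(deg) && length(deg) == 1L && file.exists(deg)) {
    readLines(deg)
  } else as.character(deg)
  deg_ids <- unique(deg_ids[nzchar(trimws(deg_ids))])
  n_dropped <- sum(!deg_ids %in% genes$gene_id)
  if (n_dropped > 0L) {
    message(n_dropped, " DEG id(s) absent from gene table dropped")
  }
  res <- enrich_sets_in_bands(list(DEG = deg_ids), genes, significant_bands,
                              universe)
  out <- data.frame(band_id = res$target_id, n_genes = res$n_target,
                    n_DEGs = res$k_overlap, p_raw = res$p_raw,
                    p_adj = res$p_adj, stringsAsFactors = FALSE)
  out <- out[order(out$band_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "bh_family_size") <- attr(res, "bh_family_size")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    w <- out
    w$p_raw <- signif(w$p_raw, 4); w$p_adj <- signif(w$p_adj, 4)
    utils::write.table(w, file.path(out_dir, "step4_deg_bands.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  out
}

#' Step 5: length-adjusted mutation burden per band
#'
#' Computes adjusted mutation counts `m / (L + Q1 log2 L)` from a MAF-lite
#' file or a pre-aggregated per-gene count table, classifies high-mutation
#' genes by the strict median rule, and runs the per-band hypergeometric
#' and t-test families. Genes absent from the mutation input count as
#' `m = 0` by default. Writes `step5_burden.tsv`.
#'
#' @param genes Gene table (path or `data.frame`; needs `cds_length`).
#' @param mutations MAF-lite path, counts `data.frame(gene_id, count)`, or
#'   a 2-column counts TSV.
#' @param significant_bands Band ids to test.
#' @param annotation Optional `genome_annotation`.
#' @param out_dir Output directory or `NULL`.
#' @param coding_classes Variant classifications counted as coding.
#' @param welch Welch t-test (default) vs pooled variance.
#' @param drop_unmutated Drop genes absent from the mutation table instead
#'   of treating them as zero-count.
#' @return List with `burden` (the per-band table), `genes` (per-gene
#'   adjusted counts and flags), `q1`, `median_adjusted`.
#' @export
run_step5 <- function(genes, mutations, significant_bands, annotation = NULL,
                      out_dir = NULL,
                      coding_classes = default_coding_classes(),
                      welch = TRUE, drop_unmutated = FALSE) {
  genes <- .load_genes(genes, annotation)
  counts <- if (is.data.frame(mutations)) {
    mutations
  } else if (is.character(mutations) && file.exists(mutations)) {
    first <- readLines(mutations, n = 1L)
    if (grepl("Hugo_Symbol", first)) {
      read_maf_counts(mutations, coding_classes)
    } else {
      d <- utils::read.table(mutations, sep = "\t", header = FALSE,
                             stringsAsFactors = FALSE)
      data.frame(gene_id = as.character(d[[1L]]), count = as.numeric(d[[2L]]),
                 stringsAsFactors = FALSE)
    }
  } else stop("mutation input not found: ", mutations)
  g <- genes[!is.na(genes$band_id), , drop = FALSE]
  g$mutation_count <- counts$count[match(g$gene_id, counts$gene_id)]
  if (drop_unmutated) {
    g <- g[!is.na(g$mutation_count), , drop = FALSE]
  } else {
    g$mutation_count[is.na(g$mutation_count)] <- 0
  }
  if (nrow(g) == 0L) stop("no genes with mutation data")
  q1 <- first_quartile(g$cds_length)
  g$adjusted <- adjusted_mutation_count(g$mutation_count, g$cds_length, q1)
  g$high_mut <- classify_high_mutation(g$adjusted)
  burden <- band_burden_tests(g, significant_bands, welch = welch)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    w <- burden
    for (col in c("mean_adjusted", "p_hyper_raw", "p_hyper_adj",
                  "p_ttest_raw", "p_ttest_adj")) w[[col]] <- signif(w[[col]], 4)
    utils::write.table(w, file.path(out_dir, "step5_burden.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  list(burden = burden, genes = g, q1 = q1,
       median_adjusted = stats::median(g$adjusted))
}

.load_genes <- function(genes, annotation) {
  if (is.character(genes)) {
    if (!file.exists(genes)) stop("gene input not found: ", genes)
    genes <- read_genes(genes)
  }
  if (!"band_id" %in% names(genes)) {
    if (is.null(annotation)) {
      stop("gene table lacks band_id and no annotation was supplied")
    }
    genes <- assign_genes_to_bands(genes, annotation)
  }
  genes
}

#' Run the full band-enrichment pipeline
#'
#' Orchestrates Steps 1, 2, 4 and 5 from a configuration list. Steps 2, 4
#' and 5 default to the band list produced by Step 1 but accept an
#' explicit `bands` entry; stages whose inputs are missing are skipped
#' with a notice. A machine-readable run manifest (JSON) with input
#' checksums, the configuration echo, every BH family size and the
#' package version is written beside the TSVs.
#'
#' @param config List with paths `cytoband`, `variants`, `genes` and
#'   optionally `gene_sets` (GMT), `deg` (one id per line), `mutations`
#'   (MAF-lite or counts TSV), plus `bands` (explicit band list),
#'   `alpha` (default 0.05), `universe`, `welch`, `coding_classes`.
#' @param out_dir Output directory.
#' @return List with the per-step results and the manifest, invisibly.
#' @export
run_pipeline <- function(config, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  alpha <- if (is.null(config$alpha)) 0.05 else config$alpha
  if (!is.null(config$alpha) && (alpha <= 0 || alpha >= 1)) {
    stop("alpha must lie in (0, 1)")
  }
  s1 <- run_step1(config$cytoband, config$variants, out_dir, alpha)
  bands <- if (!is.null(config$bands)) unique(config$bands) else
    s1$significant_bands
  families <- c(step1_scan = attr(s1$scan, "bh_family_size"))
  genes <- if (!is.null(config$genes)) {
    .load_genes(config$genes, s1$annotation)
  } else NULL
  s2 <- s4 <- s5 <- NULL
  if (!is.null(genes) && !is.null(config$gene_sets) && length(bands)) {
    s2 <- run_step2(genes, config$gene_sets, bands, s1$annotation, out_dir,
                    config$universe)
    families <- c(families,
                  step2_ora = attr(s2$ora, "bh_family_size"),
                  step2_reciprocal = attr(s2$reciprocal, "bh_family_size"))
  } else message("step 2 skipped (gene sets or genes not supplied)")
  if (!is.null(genes) && !is.null(config$deg) && length(bands)) {
    s4 <- run_step4(genes, config$deg, bands, s1$annotation, out_dir,
                    config$universe)
    families <- c(families, step4_deg = attr(s4, "bh_family_size"))
  } else message("step 4 skipped (DEG list or genes not supplied)")
  if (!is.null(genes) && !is.null(config$mutations) && length(bands)) {
    s5 <- run_step5(genes, config$mutations, bands, s1$annotation, out_dir,
                    welch = if (is.null(config$welch)) TRUE else config$welch)
    fam5 <- attr(s5$burden, "bh_family_sizes")
    families <- c(families, step5_hyper = fam5[["hyper"]],
                  step5_ttest = fam5[["ttest"]])
  } else message("step 5 skipped (mutation input or genes not supplied)")
  inputs <- unlist(config[c("cytoband", "variants", "genes", "gene_sets",
                            "deg", "mutations")])
  inputs <- inputs[!is.na(inputs) & vapply(inputs, is.character, TRUE)]
  inputs <- inputs[file.exists(inputs)]
  manifest <- list(
    package = "bandscan",
    version = as.character(utils::packageVersion("bandscan")),
    alpha = alpha,
    bands_tested = bands,
    bh_family_sizes = as.list(families),
    input_md5 = as.list(tools::md5sum(inputs)),
    config = config[setdiff(names(config), "universe")],
    q1 = if (!is.null(s5)) s5$q1 else NULL)
  jsonlite::write_json(manifest, file.path(out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")
  invisible(list(step1 = s1, step2 = s2, step4 = s4, step5 = s5,
                 manifest = manifest))
}
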