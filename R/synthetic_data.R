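#' Simulation configuration
#'
#' Bundles the parameters of the synthetic-data generators. Defaults
#' emulate the analysis' stated world: a human-scale genome (23
#' chromosomes x 14 major bands, log-normal band lengths with ~8 Mb
#' median, ~3 Gb total), N = 1,346 variant sites, and per-gene coding
#' mutation counts that are Poisson in CDS length.
#'
#' @param seed Integer seed fixing every downstream draw.
#' @param n_chromosomes,bands_per_chromosome Genome shape (major bands).
#' @param band_length_meanlog,band_length_sdlog Log-normal band lengths (bp).
#' @param n_variants Number of variant sites to place.
#' @param enriched_bands `data.frame(band_id, multiplier)` of bands with
#'   elevated variant rate (multipliers >= 1), or `NULL`.
#' @param n_duplicate_variants Duplicate records appended for
#'   deduplication tests.
#' @param n_genes Number of genes.
#' @param cds_meanlog,cds_sdlog Log-normal CDS lengths (bp).
#' @param mutation_rate Coding mutations per CDS bp (pooled over samples).
#' @param burden_multiplier_bands `data.frame(band_id, multiplier)` of
#'   bands with elevated mutation burden, or `NULL`.
#' @param n_gene_sets Number of gene sets to simulate.
#' @param set_size_range Inclusive range of set sizes.
#' @param planted_sets `data.frame(band_id, concentration)` — one planted
#'   set per row drawing `concentration` of its members from the target
#'   band; remaining sets are uniform (null).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_chromosomes = 23L, bands_per_chromosome = 14L,
                       band_length_meanlog = log(8e6),
                       band_length_sdlog = 0.5,
                       n_variants = 1346L, enriched_bands = NULL,
                       n_duplicate_variants = 0L,
                       n_genes = 20000L,
                       cds_meanlog = log(1500), cds_sdlog = 0.6,
                       mutation_rate = 2e-3,
                       burden_multiplier_bands = NULL,
                       n_gene_sets = 20L, set_size_range = c(10L, 100L),
                       planted_sets = NULL) {
  for (tab in list(enriched_bands, burden_multiplier_bands)) {
    if (!is.null(tab) && any(tab$multiplier < 1)) {
      stop("rate multipliers must be >= 1")
    }
  }
  if (!is.null(planted_sets) &&
      any(planted_sets$concentration < 0 | planted_sets$concentration > 1)) {
    stop("band concentrations must lie in [0, 1]")
  }
  if (n_chromosomes < 1L || bands_per_chromosome < 1L) {
    stop("genome must have at least one band")
  }
  structure(list(seed = as.integer(seed),
                 n_chromosomes = n_chromosomes,
                 bands_per_chromosome = bands_per_chromosome,
                 band_length_meanlog = band_length_meanlog,
                 band_length_sdlog = band_length_sdlog,
                 n_variants = n_variants, enriched_bands = enriched_bands,
                 n_duplicate_variants = n_duplicate_variants,
                 n_genes = n_genes,
                 cds_meanlog = cds_meanlog, cds_sdlog = cds_sdlog,
                 mutation_rate = mutation_rate,
                 burden_multiplier_bands = burden_multiplier_bands,
                 n_gene_sets = n_gene_sets,
                 set_size_range = set_size_range,
                 planted_sets = planted_sets),
            class = "sim_config")
}

.sim_chrom_labels <- function(n) {
  labs <- c(as.character(1:22), "X", "Y")
  if (n > length(labs)) labs <- c(labs, paste0("S", seq_len(n - length(labs))))
  labs[seq_len(n)]
}

#' Simulate a genome annotation and its cytoBand fixture
#'
#' Draws major-band lengths from a log-normal, splits each major band into
#' 1-3 contiguous dotted sub-bands, writes a UCSC-style cytoBand TSV and
#' returns the annotation obtained by running that file through the real
#' [parse_cytoband()] / [collapse_to_major_bands()] readers, so the
#' fixture path is exercised end to end. Deterministic under
#' `config$seed`.
#'
#' @param config A [sim_config()].
#' @param path Where to write the cytoBand TSV (default: tempfile).
#' @return A `genome_annotation` with attribute `cytoband_path`.
#' @export
make_genome <- function(config, path = tempfile(fileext = ".cytoband.tsv")) {
  set.seed(config$seed)
  chroms <- .sim_chrom_labels(config$n_chromosomes)
  stains <- c("gneg", "gpos25", "gpos50", "gpos75", "gpos100")
  lines <- character(0)
  for (ch in chroms) {
    m <- config$bands_per_chromosome
    lens <- round(stats::rlnorm(m, config$band_length_meanlog,
                                config$band_length_sdlog))
    lens <- pmax(lens, 1e5)
    n_p <- m %/% 2
    arms <- c(if (n_p > 0) paste0("p", rev(seq_len(n_p))),
              paste0("q", seq_len(m - n_p)))
    pos <- 0
    for (i in seq_len(m)) {
      nsub <- sample.int(3L, 1L)
      cuts <- if (nsub == 1L) c(0, lens[i]) else {
        round(c(0, sort(stats::runif(nsub - 1L, 0.2, 0.8)), 1) * lens[i])
      }
      for (s in seq_len(nsub)) {
        nm <- if (nsub == 1L) arms[i] else paste0(arms[i], ".", s)
        lines <- c(lines, sprintf("chr%s\t%d\t%d\t%s\t%s", ch,
                                  as.integer(pos + cuts[s]),
                                  as.integer(pos + cuts[s + 1L]),
                                  nm, sample(stains, 1L)))
      }
      pos <- pos + lens[i]
    }
  }
  writeLines(lines, path)
  ann <- collapse_to_major_bands(parse_cytoband(path))
  attr(ann, "cytoband_path") <- path
  ann
}

#' Simulate variant sites over a genome
#'
#' Positions are drawn from a piecewise-uniform density: each band's
#' weight is its length times its rate multiplier (1 for unlisted bands),
#' and the position within the chosen band is uniform. Optionally appends
#' duplicate records (copies of already-drawn variants) for
#' deduplication tests, shuffled into the output.
#'
#' @param annotation A `genome_annotation`.
#' @param n_variants Number of distinct variant sites.
#' @param enriched_bands `data.frame(band_id, multiplier)` or `NULL`.
#' @param seed Integer seed.
#' @param n_duplicates Duplicate records to append.
#' @return `data.frame` with `chrom`, `pos` (1-based), `variant_id`.
#' @export
simulate_variants <- function(annotation, n_variants, enriched_bands = NULL,
                              seed = 1L, n_duplicates = 0L) {
  set.seed(seed)
  w <- annotation$length_bp
  if (!is.null(enriched_bands)) {
    idx <- match(enriched_bands$band_id, annotation$band_id)
    if (anyNA(idx)) {
      stop("unknown enriched band id: ",
           enriched_bands$band_id[which(is.na(idx))[1L]])
    }
    w[idx] <- w[idx] * enriched_bands$multiplier
  }
  band <- sample.int(nrow(annotation), n_variants, replace = TRUE, prob = w)
  len <- annotation$length_bp[band]
  pos <- annotation$start[band] + floor(stats::runif(n_variants) * len) + 1
  out <- data.frame(chrom = annotation$chrom[band], pos = pos,
                    variant_id = sprintf("rs%07d", seq_len(n_variants)),
                    stringsAsFactors = FALSE)
  if (n_duplicates > 0L) {
    dup <- out[sample.int(n_variants, n_duplicates, replace = TRUE), ,
               drop = FALSE]
    out <- rbind(out, dup)
    out <- out[sample.int(nrow(out)), , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

#' Simulate genes with CDS lengths and somatic mutation counts
#'
#' Genes are placed in bands with probability proportional to band length
#' and uniformly within the band; CDS lengths are log-normal; per-gene
#' coding mutation counts are Poisson with mean
#' `mutation_rate * cds_length * band multiplier`. Writes a 6-column gene
#' TSV and a MAF-lite fixture (one row per mutation, coding
#' classifications sampled uniformly, plus ~10% non-coding decoy rows that
#' the reader must filter out), both consumed only through the public
#' readers.
#'
#' @param annotation A `genome_annotation`.
#' @param config A [sim_config()].
#' @param seed Integer seed (default `config$seed`).
#' @param genes_path,maf_path Fixture paths (default: tempfiles).
#' @param write_fixtures Write the TSV fixtures? Replicate loops that only
#'   need the in-memory tables can skip the file IO.
#' @return List with `genes` (gene table incl. `band_id` and
#'   `mutation_count`), `counts` (per-gene coding counts, the generator's
#'   bookkeeping), `genes_path`, `maf_path`.
#' @export
simulate_genes_and_mutations <- function(annotation, config,
                                         seed = config$seed,
                                         genes_path = tempfile(fileext = ".genes.tsv"),
                                         maf_path = tempfile(fileext = ".maf.tsv"),
                                         write_fixtures = TRUE) {
  set.seed(seed)
  n <- config$n_genes
  band <- sample.int(nrow(annotation), n, replace = TRUE,
                     prob = annotation$length_bp)
  cds <- pmax(2, round(stats::rlnorm(n, config$cds_meanlog, config$cds_sdlog)))
  blen <- annotation$length_bp[band]
  span <- pmin(cds, blen - 1)
  start <- annotation$start[band] +
    floor(stats::runif(n) * (blen - span))
  genes <- data.frame(gene_id = sprintf("G%05d", seq_len(n)),
                      chrom = annotation$chrom[band],
                      start = start, end = start + span,
                      strand = sample(c("+", "-"), n, replace = TRUE),
                      cds_length = cds,
                      stringsAsFactors = FALSE)
  mult <- rep(1, n)
  if (!is.null(config$burden_multiplier_bands)) {
    idx <- match(config$burden_multiplier_bands$band_id, annotation$band_id)
    if (anyNA(idx)) stop("unknown burden band id")
    for (j in seq_along(idx)) {
      mult[band == idx[j]] <- config$burden_multiplier_bands$multiplier[j]
    }
  }
  counts <- stats::rpois(n, config$mutation_rate * cds * mult)
  genes$mutation_count <- counts
  if (write_fixtures) {
    write_genes(genes, genes_path)
    # MAF-lite fixture: one row per coding mutation + non-coding decoys
    gene_rows <- rep(genes$gene_id, counts)
    classes <- sample(default_coding_classes(), length(gene_rows),
                      replace = TRUE)
    n_decoy <- max(1L, round(0.1 * length(gene_rows)))
    decoy_genes <- sample(genes$gene_id, n_decoy, replace = TRUE)
    decoy_classes <- sample(c("3'UTR", "5'UTR", "Intron", "IGR", "RNA"),
                            n_decoy, replace = TRUE)
    maf <- data.frame(
      Hugo_Symbol = c(gene_rows, decoy_genes),
      Variant_Classification = c(classes, decoy_classes),
      Tumor_Sample_Barcode = sample(sprintf("TCGA-SYN-%03d", 1:60),
                                    length(gene_rows) + n_decoy,
                                    replace = TRUE),
      stringsAsFactors = FALSE)
    maf <- maf[sample.int(nrow(maf)), , drop = FALSE]
    utils::write.table(maf, maf_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    genes_path <- maf_path <- NULL
  }
  genes <- assign_genes_to_bands(genes, annotation)
  list(genes = genes,
       counts = data.frame(gene_id = genes$gene_id, count = counts,
                           stringsAsFactors = FALSE),
       genes_path = genes_path, maf_path = maf_path)
}

#' Simulate gene sets with optional band-planted concentration
#'
#' Planted sets draw `concentration` of their members uniformly from the
#' target band's genes and the rest uniformly from other genes; null sets
#' are fully uniform. Optionally writes a GMT fixture.
#'
#' @param genes Gene table with `gene_id` and `band_id`.
#' @param config A [sim_config()] (`n_gene_sets`, `set_size_range`,
#'   `planted_sets` are used).
#' @param seed Integer seed (default `config$seed`).
#' @param path GMT output path, or `NULL` to skip writing.
#' @return Named list of member vectors (attribute `description` carries
#'   the target band for planted sets, `"null"` otherwise; attribute
#'   `gmt_path` if written).
#' @export
simulate_gene_sets <- function(genes, config, seed = config$seed,
                               path = tempfile(fileext = ".gmt")) {
  set.seed(seed)
  universe <- genes$gene_id
  planted <- config$planted_sets
  n_planted <- if (is.null(planted)) 0L else nrow(planted)
  if (config$n_gene_sets < n_planted) stop("more planted sets than n_gene_sets")
  sizes <- sample(seq(config$set_size_range[1L], config$set_size_range[2L]),
                  config$n_gene_sets, replace = TRUE)
  if (any(sizes > length(universe))) stop("set size exceeds gene universe")
  sets <- vector("list", config$n_gene_sets)
  desc <- character(config$n_gene_sets)
  ids <- character(config$n_gene_sets)
  for (i in seq_len(config$n_gene_sets)) {
    if (i <= n_planted) {
      b <- planted$band_id[i]
      in_band <- universe[!is.na(genes$band_id) & genes$band_id == b]
      n_in <- round(planted$concentration[i] * sizes[i])
      if (n_in > length(in_band)) {
        stop("band ", b, " has too few genes for the planted concentration")
      }
      members <- c(sample(in_band, n_in),
                   sample(setdiff(universe, in_band), sizes[i] - n_in))
      ids[i] <- sprintf("SET_P%02d", i)
      desc[i] <- b
    } else {
      members <- sample(universe, sizes[i])
      ids[i] <- sprintf("SET_N%02d", i - n_planted)
      desc[i] <- "null"
    }
    sets[[i]] <- members
  }
  names(sets) <- ids
  names(desc) <- ids
  attr(sets, "description") <- desc
  if (!is.null(path)) {
    write_gmt(sets, path)
    attr(sets, "gmt_path") <- path
  }
  sets
}
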