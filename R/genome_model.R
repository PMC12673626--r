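#' Parse a UCSC-style cytoBand table
#'
#' Reads cytogenetic band definitions in the UCSC `cytoBand.txt` dialect:
#' tab-separated `chrom, start, end, name[, stain]` with 0-based half-open
#' coordinates. Chromosome labels are normalized by stripping a leading
#' `"chr"` prefix, so `"chr8"` and `"8"` are equivalent on input.
#'
#' @param path Path to a cytoBand TSV file, or a character vector of lines
#'   (anything with more than one element, or a single element containing a
#'   newline, is treated as file content rather than a path).
#' @return A `data.frame` with columns `chrom` (character, no `"chr"`
#'   prefix), `start` (0-based inclusive), `end` (0-based exclusive),
#'   `name` (sub-band label such as `"q24.21"`) and `stain`.
#' @export
parse_cytoband <- function(path) {
  lines <- .read_lines_or_path(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    stop("cytoband input is empty")
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 4L)) {
    stop("cytoband line ", which(nf < 4L)[1L],
         ": fewer than 4 tab-separated fields")
  }
  chrom <- sub("^chr", "", vapply(fields, `[[`, "", 1L))
  start <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L)))
  end   <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3L)))
  name  <- vapply(fields, `[[`, "", 4L)
  stain <- ifelse(nf >= 5L, vapply(fields, function(f) f[min(5L, length(f))], ""), "")
  bad <- which(is.na(start) | is.na(end))
  if (length(bad)) {
    stop("cytoband line ", bad[1L], ": non-numeric coordinates")
  }
  bad <- which(start >= end)
  if (length(bad)) {
    stop("cytoband line ", bad[1L], ": start >= end (",
         start[bad[1L]], " >= ", end[bad[1L]], ")")
  }
  bad <- which(!grepl("^[pq][0-9]+(\\.[0-9]+)?$", name))
  if (length(bad)) {
    stop("cytoband line ", bad[1L], ": band name '", name[bad[1L]],
         "' does not match the arm pattern p/q<number>[.<number>]")
  }
  data.frame(chrom = chrom, start = start, end = end,
             name = name, stain = stain, stringsAsFactors = FALSE)
}

.read_lines_or_path <- function(x) {
  if (is.character(x) && length(x) == 1L && !grepl("[\n\t]", x)) {
    if (!file.exists(x)) stop("input file not found: ", x)
    return(readLines(x))
  }
  if (is.character(x)) return(unlist(strsplit(x, "\n", fixed = TRUE)))
  stop("expected a file path or character vector of lines")
}

#' Collapse sub-bands to major cytogenetic bands
#'
#' Truncates each sub-band name at the first `"."` (`"q24.1"`, `"q24.2"` ->
#' `"q24"`; names without a dot pass through) and merges the constituent
#' sub-bands of each major band into a single interval spanning their
#' extent. Constituents of one major band must be contiguous; a gap means
#' the annotation is corrupt and is an error.
#'
#' @param records A `data.frame` as returned by [parse_cytoband()].
#' @return A `genome_annotation`: a `data.frame` with columns `band_id`
#'   (e.g. `"8q24"`), `chrom`, `start`, `end`, `length_bp`, carrying the
#'   total genome length in attribute `total_length_bp`.
#' @export
collapse_to_major_bands <- function(records) {
  stopifnot(is.data.frame(records), nrow(records) > 0L)
  major <- sub("\\..*$", "", records$name)
  band_id <- paste0(records$chrom, major)
  ord <- order(records$chrom, records$start)
  records <- records[ord, , drop = FALSE]
  band_id <- band_id[ord]
  pieces <- split(records, factor(band_id, levels = unique(band_id)))
  out <- lapply(names(pieces), function(id) {
    b <- pieces[[id]]
    b <- b[order(b$start), , drop = FALSE]
    if (nrow(b) > 1L && any(b$end[-nrow(b)] != b$start[-1L])) {
      stop("major band ", id, ": constituent sub-bands are not contiguous")
    }
    data.frame(band_id = id, chrom = b$chrom[1L],
               start = b$start[1L], end = b$end[nrow(b)],
               length_bp = b$end[nrow(b)] - b$start[1L],
               stringsAsFactors = FALSE)
  })
  ann <- do.call(rbind, out)
  ann <- ann[order(ann$chrom, ann$start), , drop = FALSE]
  rownames(ann) <- NULL
  # disjointness within chromosome
  for (ch in unique(ann$chrom)) {
    a <- ann[ann$chrom == ch, , drop = FALSE]
    if (nrow(a) > 1L && any(a$start[-1L] < a$end[-nrow(a)])) {
      stop("overlapping major bands on chromosome ", ch)
    }
  }
  if (anyDuplicated(ann$band_id)) {
    stop("duplicate major band ids after collapsing")
  }
  attr(ann, "total_length_bp") <- sum(ann$length_bp)
  class(ann) <- c("genome_annotation", "data.frame")
  ann
}

#' @export
print.genome_annotation <- function(x, ...) {
  cat("genome_annotation:", nrow(x), "major bands on",
      length(unique(x$chrom)), "chromosomes,",
      format(attr(x, "total_length_bp"), big.mark = ","), "bp total\n")
  print.data.frame(utils::head(as.data.frame(x)), ...)
  if (nrow(x) > 6L) cat("...\n")
  invisible(x)
}

#' Total genome length of an annotation
#' @param annotation A `genome_annotation`.
#' @return Total length in bp (the exposure denominator of the rate test).
#' @export
total_length <- function(annotation) {
  attr(annotation, "total_length_bp")
}

#' Remove duplicate variant records
#'
#' One record is kept per distinct `variant_id` (first occurrence wins).
#' Records with a missing or empty id are deduplicated by `(chrom, pos)`
#' instead.
#'
#' @param variants A `data.frame` with columns `chrom`, `pos` (1-based) and
#'   `variant_id`.
#' @return The deduplicated `data.frame`, input order preserved.
#' @export
dedup_variants <- function(variants) {
  if (nrow(variants) == 0L) return(variants)
  id <- as.character(variants$variant_id)
  noid <- is.na(id) | !nzchar(id)
  key <- ifelse(noid, paste0("@pos:", variants$chrom, ":", variants$pos), id)
  out <- variants[!duplicated(key), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Assign variant sites to major bands
#'
#' A 1-based position `p` falls in the band `[start, end)` (0-based
#' half-open) iff `start < p <= end`; each variant lands in at most one
#' band because bands are disjoint. Variants on chromosomes absent from the
#' annotation, or in gaps, are returned as unassigned.
#'
#' @param variants `data.frame` with `chrom`, `pos`, `variant_id`.
#' @param annotation A `genome_annotation`.
#' @return A list with `counts` (a `data.frame` `band_id`, `count`, one row
#'   per annotation band, zeros included), `assignment` (per-variant band id
#'   or `NA`), and `unassigned` (the subset of variants with no band).
#' @export
assign_variants <- function(variants, annotation) {
  stopifnot(nrow(annotation) > 0L)
  band <- rep(NA_character_, nrow(variants))
  for (ch in unique(variants$chrom)) {
    vi <- which(variants$chrom == ch)
    a <- annotation[annotation$chrom == ch, , drop = FALSE]
    if (nrow(a) == 0L) next
    a <- a[order(a$start), , drop = FALSE]
    p0 <- variants$pos[vi] - 1               # 0-based point coordinate
    idx <- findInterval(p0, a$start)
    hit <- idx >= 1L & p0 < a$end[pmax(idx, 1L)]
    band[vi[hit]] <- a$band_id[idx[hit]]
  }
  tab <- table(factor(band, levels = annotation$band_id))
  counts <- data.frame(band_id = annotation$band_id,
                       count = as.integer(tab),
                       stringsAsFactors = FALSE)
  unassigned <- variants[is.na(band), , drop = FALSE]
  if (nrow(unassigned)) {
    message(nrow(unassigned), " variant(s) not assigned to any band")
  }
  list(counts = counts, assignment = band, unassigned = unassigned)
}

# Merge a set of possibly-overlapping [start, end) intervals on one
# chromosome into disjoint sorted intervals.
.reduce_intervals <- function(start, end) {
  if (length(start) == 0L) return(list(start = numeric(0), end = numeric(0)))
  o <- order(start, end)
  start <- start[o]; end <- end[o]
  ks <- numeric(0); ke <- numeric(0)
  cs <- start[1L]; ce <- end[1L]
  for (i in seq_along(start)[-1L]) {
    if (start[i] <= ce) {
      ce <- max(ce, end[i])
    } else {
      ks <- c(ks, cs); ke <- c(ke, ce)
      cs <- start[i]; ce <- end[i]
    }
  }
  list(start = c(ks, cs), end = c(ke, ce))
}

# TRUE for each 0-based point p0 lying inside any reduced interval.
.point_in_any <- function(p0, red) {
  if (length(red$start) == 0L) return(rep(FALSE, length(p0)))
  idx <- findInterval(p0, red$start)
  idx >= 1L & p0 < red$end[pmax(idx, 1L)]
}

#' Classify variant genomic context
#'
#' Labels each variant `genic_exonic`, `genic_intronic` or `intergenic`.
#' A variant is genic iff it lies inside any gene span, exonic iff it is
#' genic and inside any exon span; overlapping genes never double-count.
#'
#' @param variants `data.frame` with `chrom`, `pos` (1-based).
#' @param gene_spans `data.frame` with `chrom`, `start`, `end`
#'   (0-based half-open).
#' @param exon_spans Same shape; exons must be nested inside gene spans.
#' @return A list with `labels` (character per variant) and `summary`
#'   (named counts over the three classes).
#' @export
classify_variant_context <- function(variants, gene_spans, exon_spans) {
  for (ch in unique(exon_spans$chrom)) {
    g <- gene_spans[gene_spans$chrom == ch, , drop = FALSE]
    e <- exon_spans[exon_spans$chrom == ch, , drop = FALSE]
    red <- .reduce_intervals(g$start, g$end)
    inside <- .point_in_any(e$start, red) &
      .point_in_any(pmax(e$end - 1, e$start), red)
    if (!all(inside)) stop("exon spans not nested within gene spans on chromosome ", ch)
  }
  labels <- rep("intergenic", nrow(variants))
  for (ch in unique(variants$chrom)) {
    vi <- which(variants$chrom == ch)
    p0 <- variants$pos[vi] - 1
    g <- gene_spans[gene_spans$chrom == ch, , drop = FALSE]
    e <- exon_spans[exon_spans$chrom == ch, , drop = FALSE]
    genic <- .point_in_any(p0, .reduce_intervals(g$start, g$end))
    exonic <- .point_in_any(p0, .reduce_intervals(e$start, e$end))
    labels[vi[genic & exonic]] <- "genic_exonic"
    labels[vi[genic & !exonic]] <- "genic_intronic"
  }
  lev <- c("genic_exonic", "genic_intronic", "intergenic")
  list(labels = labels,
       summary = c(table(factor(labels, levels = lev))))
}

#' Read a variant table
#'
#' Accepts 3-column TSV `chrom, pos (1-based), variant_id`, or BED3+name
#' (`chrom, start, end, name`, 0-based half-open; the 1-based position is
#' `start + 1`).
#'
#' @param path File path.
#' @param format `"tsv"` (default) or `"bed"`.
#' @return `data.frame` with `chrom`, `pos`, `variant_id`.
#' @export
read_variants <- function(path, format = c("tsv", "bed")) {
  format <- match.arg(format)
  d <- utils::read.table(path, sep = "\t", header = FALSE,
                         stringsAsFactors = FALSE, quote = "",
                         comment.char = "")
  if (format == "tsv") {
    if (ncol(d) < 3L) stop("variant TSV needs 3 columns (chrom, pos, id)")
    out <- data.frame(chrom = sub("^chr", "", as.character(d[[1L]])),
                      pos = as.numeric(d[[2L]]),
                      variant_id = as.character(d[[3L]]),
                      stringsAsFactors = FALSE)
  } else {
    if (ncol(d) < 4L) stop("variant BED needs 4 columns (chrom, start, end, name)")
    out <- data.frame(chrom = sub("^chr", "", as.character(d[[1L]])),
                      pos = as.numeric(d[[2L]]) + 1,
                      variant_id = as.character(d[[4L]]),
                      stringsAsFactors = FALSE)
  }
  if (any(out$pos < 1)) stop("variant position < 1 after conversion")
  out
}

#' Write variants as 3-column TSV
#' @param variants `data.frame` with `chrom`, `pos`, `variant_id`.
#' @param path Output path.
#' @export
write_variants <- function(variants, path) {
  utils::write.table(variants[, c("chrom", "pos", "variant_id")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Read a gene table
#'
#' 6-column TSV: `gene_id, chrom, start, end, strand, cds_length`
#' (0-based half-open span).
#'
#' @param path File path.
#' @return `data.frame` with those columns.
#' @export
read_genes <- function(path) {
  d <- utils::read.table(path, sep = "\t", header = FALSE,
                         stringsAsFactors = FALSE, quote = "",
                         comment.char = "")
  if (ncol(d) < 6L) stop("gene TSV needs 6 columns (gene_id, chrom, start, end, strand, cds_length)")
  data.frame(gene_id = as.character(d[[1L]]),
             chrom = sub("^chr", "", as.character(d[[2L]])),
             start = as.numeric(d[[3L]]), end = as.numeric(d[[4L]]),
             strand = as.character(d[[5L]]),
             cds_length = as.numeric(d[[6L]]),
             stringsAsFactors = FALSE)
}

#' Write a gene table
#' @param genes `data.frame` as from [read_genes()].
#' @param path Output path.
#' @export
write_genes <- function(genes, path) {
  utils::write.table(genes[, c("gene_id", "chrom", "start", "end", "strand",
                               "cds_length")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Assign genes to major bands by midpoint
#'
#' Each gene is assigned to the band containing its span midpoint, so a
#' gene straddling a band boundary gets exactly one band and per-band gene
#' universes form a partition.
#'
#' @param genes `data.frame` with `gene_id`, `chrom`, `start`, `end`.
#' @param annotation A `genome_annotation`.
#' @return `genes` with a `band_id` column added (`NA` if the midpoint
#'   falls outside every band).
#' @export
assign_genes_to_bands <- function(genes, annotation) {
  mid <- floor((genes$start + genes$end) / 2)   # 0-based midpoint
  fake <- data.frame(chrom = genes$chrom, pos = mid + 1,
                     variant_id = genes$gene_id, stringsAsFactors = FALSE)
  genes$band_id <- suppressMessages(assign_variants(fake, annotation))$assignment
  genes
}

#' Write major bands as BED4
#'
#' `chr`-prefixed BED with columns chrom, start, end, band_id.
#' @param annotation A `genome_annotation`.
#' @param path Output path.
#' @export
write_major_bands_bed <- function(annotation, path) {
  utils::write.table(
    data.frame(paste0("chr", annotation$chrom), annotation$start,
               annotation$end, annotation$band_id),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read major bands from BED4
#' @param path BED file written by [write_major_bands_bed()].
#' @return A `genome_annotation`.
#' @export
read_major_bands_bed <- function(path) {
  d <- utils::read.table(path, sep = "\t", header = FALSE,
                         stringsAsFactors = FALSE)
  ann <- data.frame(band_id = as.character(d[[4L]]),
                    chrom = sub("^chr", "", as.character(d[[1L]])),
                    start = as.numeric(d[[2L]]), end = as.numeric(d[[3L]]),
                    stringsAsFactors = FALSE)
  ann$length_bp <- ann$end - ann$start
  ann <- ann[order(ann$chrom, ann$start), , drop = FALSE]
  rownames(ann) <- NULL
  attr(ann, "total_length_bp") <- sum(ann$length_bp)
  class(ann) <- c("genome_annotation", "data.frame")
  ann
}
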