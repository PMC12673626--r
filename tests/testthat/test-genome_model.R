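test_that("parse_cytoband maps fields and strips chr prefixes", {
  rec <- parse_cytoband("chr8\t117700000\t127300000\tq24.1\tgneg")
  expect_equal(rec$chrom, "8")
  expect_equal(rec$start, 117700000)
  expect_equal(rec$end, 127300000)
  expect_equal(rec$name, "q24.1")

  rec <- parse_cytoband("chrX\t0\t4400000\tp22.33\tgneg")
  expect_equal(rec$chrom, "X")
})

test_that("parse_cytoband rejects malformed input with line numbers", {
  expect_error(parse_cytoband(character(0)), "empty")
  expect_error(parse_cytoband("chr1\t100\t50\tp11\tgneg"), "line 1.*start >= end")
  expect_error(parse_cytoband(c("chr1\t0\t10\tp11\tgneg", "chr1\t10\t20")),
               "line 2")
  expect_error(parse_cytoband("chr1\t0\t10\tcen\tacen"), "arm pattern")
})

test_that("a generated full-size fixture parses without rejects", {
  path <- tempfile()
  make_genome(sim_config(seed = 42), path)
  records <- parse_cytoband(path)
  expect_equal(nrow(records), length(readLines(path)))
})

test_that("collapse_to_major_bands merges dotted sub-bands", {
  ann <- toy_annotation()
  expect_setequal(ann$band_id, c("8p11", "8q23", "8q24", "9p11", "9q34"))
  q24 <- ann[ann$band_id == "8q24", ]
  expect_equal(c(q24$start, q24$end), c(100, 200))
  # names without a dot pass through unchanged
  expect_true("9p11" %in% ann$band_id)
  # total length conserved
  rec <- parse_cytoband(toy_cytoband_lines())
  expect_equal(total_length(ann), sum(rec$end - rec$start))
})

test_that("collapse_to_major_bands rejects non-contiguous constituents", {
  bad <- c("chr1\t0\t10\tq11.1\tgneg", "chr1\t20\t30\tq11.2\tgneg")
  expect_error(collapse_to_major_bands(parse_cytoband(bad)), "contiguous")
})

test_that("major-band lengths equal the sum of their constituents", {
  path <- tempfile()
  make_genome(sim_config(seed = 3), path)
  rec <- parse_cytoband(path)
  ann <- collapse_to_major_bands(rec)
  by_major <- tapply(rec$end - rec$start,
                     paste0(rec$chrom, sub("\\..*$", "", rec$name)), sum)
  expect_equal(as.numeric(by_major[ann$band_id]), ann$length_bp)
  expect_equal(total_length(ann), sum(rec$end - rec$start))
})

test_that("dedup_variants keeps first occurrence per id", {
  v <- data.frame(chrom = "1", pos = c(100, 100, 200),
                  variant_id = c("rs1", "rs1", "rs2"))
  expect_equal(nrow(dedup_variants(v)), 2L)
  expect_equal(dedup_variants(v)$variant_id, c("rs1", "rs2"))

  # missing ids fall back to (chrom, pos)
  v2 <- data.frame(chrom = c("1", "1", "1"), pos = c(5, 5, 6),
                   variant_id = c(NA, NA, NA))
  expect_equal(dedup_variants(v2)$pos, c(5, 6))

  empty <- v[0, ]
  expect_equal(nrow(dedup_variants(empty)), 0L)
})

test_that("assign_variants follows the half-open membership rule", {
  ann <- two_band_annotation()   # 1p11 [0,1000), 1q11 [1000,3000)
  v <- data.frame(chrom = "1", pos = c(1, 1000, 1001, 3000, 3001),
                  variant_id = paste0("v", 1:5))
  asg <- assign_variants(v, ann)
  # pos = start + 1 is the first base of a band; pos = end belongs to the
  # earlier band under start < p <= end
  expect_equal(asg$assignment,
               c("1p11", "1p11", "1q11", "1q11", NA))
  expect_equal(nrow(asg$unassigned), 1L)
})

test_that("assign_variants conserves variants and flags foreign chromosomes", {
  ann <- two_band_annotation()
  set.seed(11)
  v <- data.frame(chrom = "1", pos = sample(3000, 100, replace = TRUE),
                  variant_id = sprintf("v%03d", 1:100))
  asg <- assign_variants(v, ann)
  expect_equal(sum(asg$counts$count), 100L)
  expect_equal(nrow(asg$unassigned), 0L)

  v$chrom[1:7] <- "17"
  expect_message(asg <- assign_variants(v, ann), "7 variant")
  expect_equal(sum(asg$counts$count) + nrow(asg$unassigned), 100L)
})

test_that("classify_variant_context matches the brute-force oracle", {
  genes <- data.frame(chrom = "1", start = c(100, 150, 400),
                      end = c(200, 260, 500))
  exons <- data.frame(chrom = "1", start = c(100, 180, 410, 450),
                      end = c(120, 200, 430, 460))
  v <- data.frame(chrom = "1", pos = c(105, 130, 190, 255, 300, 415, 440, 500, 1, 460),
                  variant_id = paste0("v", 1:10))
  res <- classify_variant_context(v, genes, exons)
  expect_equal(res$labels, brute_force_context(v, genes, exons))
  expect_equal(sum(res$summary), nrow(v))

  # randomized instances, overlapping genes included
  set.seed(99)
  for (rep in 1:10) {
    g <- data.frame(chrom = "1", start = sort(sample(1000, 8)))
    g$end <- g$start + sample(50:150, 8, replace = TRUE)
    e <- data.frame(chrom = "1",
                    start = g$start + sample(0:20, 8, replace = TRUE))
    e$end <- pmin(e$start + sample(5:30, 8, replace = TRUE), g$end)
    vv <- data.frame(chrom = "1", pos = sample(1200, 50),
                     variant_id = sprintf("r%02d", 1:50))
    res <- classify_variant_context(vv, g, e)
    expect_equal(res$labels, brute_force_context(vv, g, e))
  }
})

test_that("classify_variant_context rejects exons outside genes", {
  genes <- data.frame(chrom = "1", start = 100, end = 200)
  exons <- data.frame(chrom = "1", start = 150, end = 250)
  v <- data.frame(chrom = "1", pos = 10, variant_id = "v1")
  expect_error(classify_variant_context(v, genes, exons), "nested")
})

test_that("major bands round-trip through BED", {
  ann <- make_genome(sim_config(seed = 5))
  path <- tempfile(fileext = ".bed")
  write_major_bands_bed(ann, path)
  back <- read_major_bands_bed(path)
  expect_equal(back$band_id, ann$band_id)
  expect_equal(back$start, ann$start)
  expect_equal(back$end, ann$end)
  expect_equal(total_length(back), total_length(ann))
})

test_that("variant readers handle TSV and BED coordinate dialects", {
  tsv <- tempfile(); bed <- tempfile()
  writeLines(c("chr1\t101\trs1", "2\t202\trs2"), tsv)
  writeLines(c("chr1\t100\t101\trs1", "chr2\t201\t202\trs2"), bed)
  a <- read_variants(tsv, "tsv")
  b <- read_variants(bed, "bed")
  expect_equal(a, b)
  expect_equal(a$pos, c(101, 202))
})

test_that("gene-band assignment uses the span midpoint", {
  ann <- two_band_annotation()
  genes <- data.frame(gene_id = c("gA", "gB", "gC"), chrom = "1",
                      start = c(0, 900, 2900), end = c(100, 1300, 3400))
  g <- assign_genes_to_bands(genes, ann)
  # gB straddles the boundary; midpoint 1100 -> 1q11 only
  expect_equal(g$band_id, c("1p11", "1q11", NA))
})
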