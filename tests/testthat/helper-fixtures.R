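# Tiny hand-written fixtures shared across test files.

toy_cytoband_lines <- function() {
  c("chr8\t0\t50\tp11\tgneg",
    "chr8\t50\t100\tq23\tgpos50",
    "chr8\t100\t140\tq24.1\tgneg",
    "chr8\t140\t170\tq24.2\tgpos25",
    "chr8\t170\t200\tq24.3\tgneg",
    "chr9\t0\t60\tp11\tacen",
    "chr9\t60\t200\tq34.1\tgneg")
}

toy_annotation <- function() {
  collapse_to_major_bands(parse_cytoband(toy_cytoband_lines()))
}

# Two-band single-chromosome genome for conservation checks.
two_band_annotation <- function() {
  collapse_to_major_bands(parse_cytoband(
    c("chr1\t0\t1000\tp11\tgneg", "chr1\t1000\t3000\tq11\tgneg")))
}

# Brute-force point-in-interval oracle: label each 1-based position
# against every gene/exon span by direct O(n*m) lookup.
brute_force_context <- function(variants, gene_spans, exon_spans) {
  vapply(seq_len(nrow(variants)), function(i) {
    p0 <- variants$pos[i] - 1
    ch <- variants$chrom[i]
    in_span <- function(sp) {
      any(sp$chrom == ch & sp$start <= p0 & p0 < sp$end)
    }
    if (!in_span(gene_spans)) "intergenic"
    else if (in_span(exon_spans)) "genic_exonic"
    else "genic_intronic"
  }, "")
}

# Full-enumeration hypergeometric oracle: probability that a uniform
# size-n draw from N labelled items (K of them "query") overlaps the
# query in at least k items.
enumerate_hyper_upper <- function(k, K, n, N) {
  if (n == 0) return(as.numeric(k <= 0))
  draws <- utils::combn(N, n)
  mean(colSums(draws <= K) >= k)   # items 1..K are the query members
}
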