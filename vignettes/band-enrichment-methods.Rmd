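---
title: "Methods: band-level clustering, reciprocal enrichment and mutation burden"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: band-level clustering, reciprocal enrichment and mutation burden}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bandscan)
```

# The scientific problem

GWAS catalogs report disease-associated polymorphisms as isolated loci,
but their spatial arrangement carries information of its own: if
variants cluster in particular cytogenetic bands far beyond what their
lengths explain, those bands are candidates for harboring regulatory
hotspots, oncogenes or tumor suppressors. `bandscan` treats the variant
catalog as a point process over the genome and asks three questions at
major-band resolution (the band label truncated before the first
decimal, `8q24` rather than `8q24.21`): which bands are over-dense in
variants; whether functionally coherent gene sets concentrate in those
bands; and whether the bands' genes carry an unusual somatic mutation
burden.

# The band-scan model

## Null model and test statistic

Under the null, the `N` unique variants fall uniformly on the genome,
so the count `k` in a band of length $L_b$ is binomial with success
probability $L_b / L_{tot}$ — equivalently, two Poisson processes with
exposures $L_b$ and $L_{tot} - L_b$ are compared. The implemented
statistic is the enrichment rate ratio

$$F = \frac{k / L_b}{(N - k + 1)/(L_{tot} - L_b)}$$

referred, one-sided for enrichment, to an F distribution with
$(2(N-k+1),\, 2k)$ degrees of freedom. The `+1` in the background count
is the classical continuity device of the exact Poisson rate-ratio
test. By the beta–F identity this upper tail *equals* the conditional
binomial tail $P(X \ge k \mid N, L_b/L_{tot})$, a fact the test suite
asserts to machine precision over a grid of `k`, `N` and band
fractions: the F formulation is an exact test, and because the
statistic is discrete it is conservative, which the null-calibration
tests confirm (empirical type-I error at $\alpha = 0.05$ sits below
the nominal level).

Orientation matters: with the band rate in the numerator, df1 is the
large background df $2(N-k+1)$ and df2 the small band df $2k$, and
enriched bands have $F > 1$. A band with $k = 0$ cannot be enriched and
has no defined df2; it is excluded from testing and reported nowhere in
the scan output.

## Multiplicity

The Benjamini–Hochberg step-up is applied across *all* bands with
$k \ge 1$ genome-wide — the scan tests the whole genome, so the most
defensible family is every tested band, and the family size is recorded
in the run manifest. Significance is declared at adjusted $p < 0.05$.
The BH implementation is the package's own (it is a shared operation of
the pipeline contract); the test suite verifies it against the
independent reference implementation in `stats::p.adjust` on 1,000
random vectors.

## Coordinate conventions

Bands are stored 0-based half-open (the UCSC cytoBand dialect); variant
positions are 1-based (the GWAS-catalog dialect). A 1-based position
`p` is inside `[start, end)` iff `start < p <= end`, which is the same
rule expressed in either dialect and leaves no off-by-one ambiguity;
boundary cases are unit-tested explicitly. Major-band collapsing
truncates the sub-band name at the first `"."`; names without a dot
pass through. All Giemsa stain classes, including `acen`/`gvar`/`stalk`,
are retained — no exclusion rule is applied. No liftover or remote
annotation retrieval is performed; all inputs are files.

# Reciprocal enrichment

Both directions reduce to the hypergeometric upper tail
$P(X \ge k)$ for an overlap of `k` between a size-`K` query and a
size-`n` target in a universe of `N` genes, computed by
`stats::phyper` and verified in the tests against a full-enumeration
oracle for every configuration with $N \le 12$. Design choices where
the analysis convention is genuinely open:

- **Universe**: configurable; the default is all genes in the supplied
  gene table. Reported p-values depend on it (monotonically decreasing
  in `N` at fixed overlap — a property the tests assert), which is why
  the universe size is part of every result row.
- **Gene→band assignment** uses the gene's span midpoint, so genes
  straddling a band boundary get exactly one band and the per-band
  universes partition the gene table — hypergeometric counts are then
  well-defined.
- **Multiplicity family** for the reciprocal analysis is all
  (set, band) pairs in one run; for ORA, all terms in one run.
- **Zero-overlap results** are reported with $p = 1$ by default so that
  all-bands tables keep their full shape; a flag skips them instead.
- **Minimum set size** is 2 after universe intersection; singletons are
  skipped with a log message.

# Mutation burden

Per-gene coding mutation counts come from a MAF-lite table filtered to
a configurable set of coding `Variant_Classification` values (missense,
nonsense, silent, frame-shifts, in-frame indels, splice site,
translation start, nonstop). The adjusted count is

$$\text{adjusted}(m, L) = \frac{m}{L + Q_1 \log_2 L}$$

with `L` the CDS length and `Q1` the first quartile of CDS lengths.
The denominator grows sub-linearly relative to the correction term, so
at a fixed per-bp rate the adjusted count still increases with length:
size bias is damped while relative burden in long genes is emphasized
(a property the tests assert across $L \in [10^2, 10^6]$). The fraction
could in principle be read as $m/L + Q_1\log_2 L$; that reading is
rejected because it does not normalize counts and is unbounded in `L`.
Conventions:

- `Q1` uses the type-7 quantile (linear interpolation between order
  statistics), the mainstream numerical default; since `Q1` rescales
  every adjusted count, the value is recorded in run provenance.
- "Gene length" means CDS length throughout; CDS lengths below 2 bp are
  rejected (the log term would be degenerate).
- High-mutation genes are those *strictly* above the median adjusted
  count, so at most half the genes are flagged and a constant vector
  flags none. Genes absent from the mutation input count as zero
  mutations by default (droppable via a flag).
- The per-band location test is Welch's two-sided t-test by default
  (the safer choice under unequal variances; pooled-variance available
  via a flag); the per-band composition test is the same
  hypergeometric core used everywhere else. BH is applied separately
  within the t-test and hypergeometric families. Bands with fewer than
  two genes report `NA` for the t-test and keep the hypergeometric
  result.

# What the synthetic generators emulate

The generators state a world and keep it fixed:

- **Genome**: 23 chromosomes x 14 major bands (322 bands), log-normal
  band lengths with median 8 Mb and $\sigma_{\log} = 0.5$, giving a
  ~3 Gb genome — the size spread of human major bands at hg38-like
  scale. Each major band is emitted as 1–3 contiguous dotted sub-bands
  so the collapsing path is genuinely exercised, and every fixture is
  consumed through the public file readers only.
- **Variants**: `N = 1346` sites by default (the catalog size after
  deduplication that the analysis design assumes), piecewise-uniform
  with per-band rate multipliers; planted scenarios use 13 bands at 4x,
  which lands the planted F statistics in the 2–8 range typical of a
  genuinely clustered catalog. Duplicate injection (450 duplicates on
  top of 1,346 uniques by default geometry) exercises deduplication.
- **Genes and mutations**: 20,000 genes (the human protein-coding
  count, and the universe size at which the DEG-list geometry of the
  reference tables is reproduced), placed proportional to band length;
  log-normal CDS lengths (median 1.5 kb, $\sigma_{\log} = 0.6$);
  counts Poisson with mean `rate x CDS x band multiplier` at a default
  pooled rate of $2\times10^{-3}$ per CDS bp (~3 coding mutations per
  gene, a plausible pooled-cohort scale).
- **Gene sets**: planted sets draw a stated concentration of members
  from one target band, null sets are uniform.

What the generators do **not** emulate: linkage disequilibrium among
variants (real GWAS hits arrive in LD blocks, so real counts are
over-dispersed relative to uniform placement), GWAS effect sizes,
gene-length correlation with band identity, hypermutated-sample
structure in the mutation data, and survival outcomes. A green
calibration or power test therefore establishes correctness of the
statistical machinery under the stated model, not robustness to those
real-data features.

# Numerical and testing choices

- The scan's p-values are computed with `stats::pf` on the F scale (no
  underflow issues at these df); ties in adjusted p-values are ordered
  by band id for deterministic output.
- Reports format `F` and p-values to 4 significant digits; underlying
  tables keep full precision.
- Null calibration of the scan uses 200 seeded replicates and the
  burden pipeline 100 replicates over the 13 bands of interest; the
  planted-recovery runs use 100 seeds, matching the stated acceptance
  protocol. Unit-level versions of the same checks run scaled-down
  replicate counts to keep the default suite fast.
- Every generator is a pure function of its (config, seed) arguments;
  rerunning with the same seed reproduces fixtures byte-for-byte, which
  the determinism tests assert.

# Known limitations

- Reported F values and adjusted p-values for a real catalog depend on
  the genome assembly's band lengths and on the multiplicity family; a
  published table can be matched in its df structure exactly (df
  depends only on `k` and `N`) but not bit-for-bit in F or adjusted p
  without the original assembly and family.
- Hypergeometric results depend on the unstated gene universe of any
  published analysis; this package exposes the universe rather than
  guessing one.
- The scan is one-sided (enrichment only); depletion testing is out of
  scope, as is survival analysis, GO-graph propagation and any remote
  database access.
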