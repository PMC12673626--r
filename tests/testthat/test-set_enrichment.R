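test_that("hypergeometric_upper equals the enumeration oracle for N <= 12", {
  for (N in c(4, 7, 10, 12)) {
    for (K in 0:N) {
      for (n in c(0, 1, N %/% 2, N)) {
        for (k in max(0, K + n - N):min(K, n)) {
          expect_equal(hypergeometric_upper(k, K, n, N),
                       enumerate_hyper_upper(k, K, n, N),
                       tolerance = 1e-12,
                       info = sprintf("k=%d K=%d n=%d N=%d", k, K, n, N))
        }
      }
    }
  }
})

test_that("hypergeometric_upper boundary and symmetry properties", {
  expect_equal(hypergeometric_upper(0, 5, 4, 10), 1)
  # enumeration of C(10,4)=210 draws with >= 4 of the 5 query members
  expect_equal(hypergeometric_upper(4, 5, 4, 10),
               enumerate_hyper_upper(4, 5, 4, 10))
  # K <-> n symmetry
  set.seed(10)
  for (i in 1:50) {
    N <- sample(20:200, 1); K <- sample(1:N, 1); n <- sample(1:N, 1)
    k <- sample(0:min(K, n), 1)
    expect_equal(hypergeometric_upper(k, K, n, N),
                 hypergeometric_upper(k, n, K, N))
  }
  expect_error(hypergeometric_upper(6, 5, 4, 10), "inconsistent")
})

test_that("enrichment p decreases in the universe size at fixed overlap", {
  # DEG-in-band geometry: k=11 of K=500 in an n=170 band
  p <- vapply(c(5000, 10000, 20000, 60000),
              function(N) hypergeometric_upper(11, 500, 170, N), 0)
  expect_true(all(diff(p) < 0))
})

test_that("GMT round-trips and deduplicates members", {
  sets <- list(A = c("g1", "g2", "g3"), B = c("g2", "g4"))
  attr(sets, "description") <- c(A = "first", B = "second")
  path <- tempfile(fileext = ".gmt")
  write_gmt(sets, path)
  back <- read_gmt(path)
  expect_equal(back[["A"]], sets[["A"]])
  expect_equal(attr(back, "description")[["B"]], "second")

  writeLines("S1\tdesc\tg1\tg2\tg1", path)
  expect_equal(read_gmt(path)[["S1"]], c("g1", "g2"))
  writeLines("S1\tdesc", path)
  expect_error(read_gmt(path), "line 1")
})

test_that("enrich_sets_in_bands: concentration and disjointness extremes", {
  genes <- data.frame(gene_id = sprintf("g%03d", 1:300),
                      band_id = rep(paste0("1q", 1:10), each = 30))
  full_band <- genes$gene_id[genes$band_id == "1q3"]
  sets <- list(hit = full_band, miss = genes$gene_id[genes$band_id == "1q7"])
  res <- enrich_sets_in_bands(sets, genes, paste0("1q", 1:10))
  hit <- res[res$query_id == "hit", ]
  expect_equal(hit$target_id[which.min(hit$p_raw)], "1q3")
  expect_equal(res$p_raw[res$query_id == "miss" & res$target_id == "1q3"], 1)
  expect_true(all(res$p_adj >= res$p_raw - 1e-15))
  # deterministic (query, target) ordering
  expect_equal(res[, c("query_id", "target_id")],
               res[order(res$query_id, res$target_id),
                   c("query_id", "target_id")])
})

test_that("planted sets rank first in the reciprocal analysis", {
  cfg <- sim_config(seed = 21, n_genes = 6000, n_gene_sets = 20,
                    set_size_range = c(40L, 60L))
  ann <- make_genome(cfg)
  gm <- simulate_genes_and_mutations(ann, cfg, write_fixtures = FALSE)
  big <- names(sort(table(gm$genes$band_id), decreasing = TRUE))[1:5]
  cfg$planted_sets <- data.frame(band_id = big, concentration = 0.5)
  sets <- simulate_gene_sets(gm$genes, cfg, path = NULL)
  res <- enrich_sets_in_bands(sets, gm$genes, big)
  planted_pairs <- paste0("SET_P0", 1:5, ":", big)
  got <- paste0(res$query_id, ":", res$target_id)
  top5 <- got[order(res$p_adj)][1:5]
  expect_setequal(top5, planted_pairs)
})

test_that("enrichment-list significance is stable under input permutation", {
  set.seed(31)
  genes <- data.frame(gene_id = sprintf("g%04d", 1:1000),
                      band_id = sample(paste0("2p", 1:20), 1000, TRUE))
  sets <- lapply(1:8, function(i) sample(genes$gene_id, 40))
  names(sets) <- paste0("S", 1:8)
  res1 <- enrich_sets_in_bands(sets, genes, paste0("2p", 1:20))
  perm <- sets[sample(names(sets))]
  res2 <- enrich_sets_in_bands(perm, genes[sample(1000), ], paste0("2p", 20:1))
  expect_equal(res1, res2, ignore_attr = TRUE)
})

test_that("term_overrepresentation recovers a fully contained query", {
  universe <- sprintf("g%03d", 1:200)
  terms <- list(T1 = universe[1:50], T2 = universe[51:100])
  res <- term_overrepresentation(universe[1:50], terms, universe)
  expect_equal(res$target_id[which.min(res$p_raw)], "T1")
  expect_error(term_overrepresentation(character(0), terms, universe),
               "empty")
  skip_res <- term_overrepresentation(universe[1:50], terms, universe,
                                      include_zero_overlap = FALSE)
  expect_false("T2" %in% skip_res$target_id)
})

test_that("null calibration of ORA: ~5% of term tests at p < 0.05", {
  set.seed(77)
  universe <- sprintf("g%04d", 1:1000)
  hits <- 0; total <- 0
  for (rep in 1:30) {
    terms <- lapply(1:50, function(i) sample(universe, sample(20:60, 1)))
    names(terms) <- paste0("T", 1:50)
    query <- sample(universe, 10)
    res <- term_overrepresentation(query, terms, universe)
    hits <- hits + sum(res$p_raw < 0.05)
    total <- total + nrow(res)
  }
  # discrete test: rejection rate at or below nominal, not far under
  expect_lt(hits / total, 0.08)
  expect_gt(hits / total, 0.005)
})

test_that("universe handling: dropped members, singleton skip, empty error", {
  genes <- data.frame(gene_id = sprintf("g%02d", 1:50),
                      band_id = rep(c("1p1", "1q1"), each = 25))
  expect_error(enrich_sets_in_bands(list(A = "g01"), genes, "1p1",
                                    universe = character(0)), "empty")
  expect_message(
    expect_error(enrich_sets_in_bands(list(A = c("g01", "zzz")), genes, "1p1",
                                      min_set_size = 2L), "no testable"),
    "skipped")
  expect_message(
    res <- enrich_sets_in_bands(list(A = c("g01", "g02", "zzz")), genes, "1p1"),
    "outside universe")
  expect_equal(res$K_query, 2L)
})
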