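test_that("ladder counts encompassed TSS and tests enrichment on a toy genome", {
  genes <- toy_gene_table()
  peak <- data.frame(chrom = "chr1", start = 49000, end = 51000)
  res <- ladder_enrichment(peak, genes, "up", distances = c(5000, 25000),
                           sizes = toy_sizes)
  # d = 5 kb: union [44k, 56k) holds only the TSS at 50k (an 'up' gene)
  expect_equal(res$encompassed_tss[1], 1)
  expect_equal(res$deg_hits[1], 1)
  expect_equal(res$p_value[1], enum_hypergeom_tail(1, 2, 3, 1))
  expect_equal(res$p_value[1], 2 / 5)
  # d = 25 kb: union [24k, 76k) holds 30k, 50k, 70k; two are 'up'
  expect_equal(res$encompassed_tss[2], 3)
  expect_equal(res$deg_hits[2], 2)
  expect_equal(res$p_value[2], enum_hypergeom_tail(2, 2, 3, 3))
  expect_equal(res$p_value[2], 3 / 10)
})

test_that("ladder handles labels with zero genes and rejects empty inputs", {
  genes <- toy_gene_table()
  genes$de_label[genes$de_label == "up"] <- "unchanged"
  peak <- data.frame(chrom = "chr1", start = 49000, end = 51000)
  res <- ladder_enrichment(peak, genes, "up", distances = c(5000, 25000),
                           sizes = toy_sizes)
  expect_equal(res$p_value, c(1, 1))
  expect_error(ladder_enrichment(peak[0, ], genes, "up", sizes = toy_sizes),
               "empty")
  expect_error(ladder_enrichment(peak, genes[0, ], "up", sizes = toy_sizes),
               "empty")
})

test_that("encompassed TSS are non-decreasing and saturate at the chromosome span", {
  set.seed(17)
  sizes <- c(chr1 = 200000, chr2 = 200000)
  genes <- data.frame(gene_id = sprintf("g%02d", 1:40),
                      chrom = rep(c("chr1", "chr2"), each = 20),
                      strand = "+",
                      tss = rep(seq(5000, 195000, by = 10000), 2),
                      de_label = sample(c("up", "unchanged"), 40, TRUE))
  peaks <- data.frame(chrom = "chr1", start = c(20000, 150000),
                      end = c(20400, 150500))
  res <- ladder_enrichment(peaks, genes, "up",
                           distances = c(1e3, 1e4, 5e4, 2e5, 4e5),
                           sizes = sizes)
  expect_true(all(diff(res$encompassed_tss) >= 0))
  # beyond the chromosome span all chr1 genes (and no chr2 genes) are inside
  expect_equal(res$encompassed_tss[5], 20)
})

test_that("union-then-count counts a gene once even under many peaks", {
  genes <- toy_gene_table()
  peaks <- data.frame(chrom = "chr1", start = c(49000, 49500, 50200),
                      end = c(51000, 50100, 50800))
  res <- ladder_enrichment(peaks, genes, "up", distances = 5000,
                           sizes = toy_sizes)
  expect_equal(res$encompassed_tss, 1)
  expect_equal(res$deg_hits, 1)
})

test_that("matched random sets reproduce the target width profile", {
  set.seed(23)
  universe <- rand_intervals(1000, chroms = c("chr1", "chr2"), len = 100000,
                             max_w = 800)
  target <- universe[sample.int(1000, 100), ]
  sets <- sample_matched_peak_sets(universe, target, 50, seed = 99)
  expect_length(sets, 50)
  wt <- target$end - target$start
  breaks <- unique(quantile(wt, 0:10 / 10, type = 7))
  inner <- breaks[-c(1, length(breaks))]
  want <- tabulate(findInterval(wt, inner) + 1L, length(inner) + 1L)
  for (s in sets[c(1, 25, 50)]) {
    expect_equal(nrow(s), 100)
    ws <- s$end - s$start
    expect_equal(tabulate(findInterval(ws, inner) + 1L, length(inner) + 1L),
                 want)
  }
})

test_that("matched sampling is exhaustive, seed-reproducible and validated", {
  set.seed(24)
  universe <- rand_intervals(40)
  # target = universe: every draw is forced to return the whole universe
  sets <- sample_matched_peak_sets(universe, universe, 5, seed = 1)
  for (s in sets) {
    expect_equal(s[order(s$chrom, s$start), c("chrom", "start", "end")],
                 universe[order(universe$chrom, universe$start), ],
                 ignore_attr = TRUE)
  }
  expect_equal(sample_matched_peak_sets(universe, universe[1:5, ], 0, 1),
               list())
  expect_error(sample_matched_peak_sets(universe[1:3, ], universe, 2, 1),
               "fewer peaks")
  a <- sample_matched_peak_sets(universe, universe[1:10, ], 3, seed = 5)
  b <- sample_matched_peak_sets(universe, universe[1:10, ], 3, seed = 5)
  c_ <- sample_matched_peak_sets(universe, universe[1:10, ], 3, seed = 6)
  expect_identical(a, b)
  expect_false(identical(a, c_))
  # global RNG stream is untouched
  set.seed(77); before <- runif(3)
  set.seed(77); invisible(sample_matched_peak_sets(universe, universe[1:10, ],
                                                   2, seed = 5))
  expect_identical(runif(3), before)
})

test_that("null envelope applies type-7 quantiles on the -log10 scale", {
  d <- c(1e4, 2e4)
  same <- matrix(0.01, nrow = 5, ncol = 2)
  env <- null_envelope(same, d)
  expect_equal(env$null_q05, c(2, 2))
  expect_equal(env$null_median, env$null_q95)
  three <- matrix(10^-c(1, 2, 3), nrow = 3, ncol = 2)
  expect_equal(null_envelope(three, d)$null_median, c(2, 2))
  # arithmetic grid of 101 values: closed-form type-7 quantiles
  grid <- matrix(10^-seq(0, 1, by = 0.01), ncol = 1)
  env101 <- null_envelope(grid, 1e4)
  expect_equal(env101$null_q05, 0.05)
  expect_equal(env101$null_q95, 0.95)
  expect_error(null_envelope(grid, c(1e4, 2e4)), "ragged|columns")
})

test_that("observed-plus-envelope wrapper joins consistent columns", {
  set.seed(30)
  genes <- toy_gene_table()
  universe <- rand_intervals(60, chroms = "chr1", len = 99000, max_w = 400)
  target <- universe[1:8, ]
  res <- ladder_with_null(target, universe, genes, "up",
                          distances = c(5000, 20000), sizes = toy_sizes,
                          n_random = 25, seed = 3)
  expect_equal(nrow(res), 2)
  expect_true(all(c("neg_log10_p", "null_q05", "null_median", "null_q95")
                  %in% names(res)))
  expect_equal(res$neg_log10_p, -log10(res$p_value))
  expect_true(all(res$null_q05 <= res$null_median + 1e-12))
  expect_true(all(res$null_median <= res$null_q95 + 1e-12))
})
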