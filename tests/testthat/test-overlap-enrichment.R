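test_that("region-overlap enrichment reproduces closed-form toy cases", {
  universe <- data.frame(chrom = "chr1", start = 0:9 * 1000,
                         end = 0:9 * 1000 + 500)
  features <- data.frame(chrom = "chr1", start = 0:3 * 1000 + 100,
                         end = 0:3 * 1000 + 200)
  # diff set = exactly the four feature-overlapping peaks
  res <- region_overlap_enrichment(universe[1:4, ], features, universe)
  expect_equal(c(res$q, res$m, res$n, res$k), c(4, 4, 6, 4))
  expect_equal(res$p_value, 1 / choose(10, 4))
  # no diff peak overlaps any feature
  res0 <- region_overlap_enrichment(universe[5:7, ], features, universe)
  expect_equal(res0$q, 0)
  expect_equal(res0$p_value, 1)
  # feature-centric reporting counts features hit
  resf <- region_overlap_enrichment(universe[1:4, ], features, universe,
                                    counting_mode = "feature_centric")
  expect_equal(resf$features_hit, 4)
  expect_equal(resf$n_features, 4)
  # universe mismatch is an error, not a silent bias
  rogue <- data.frame(chrom = "chr1", start = 777, end = 888)
  expect_error(region_overlap_enrichment(rogue, features, universe),
               "absent from the universe")
})

test_that("overlap p-values equal subset enumeration on random instances", {
  set.seed(13)
  for (rep in 1:5) {
    universe <- rand_intervals(18, chroms = "chr1", len = 50000, max_w = 900)
    universe <- universe[!duplicated(universe[, c("start", "end")]), ]
    n_u <- nrow(universe)
    features <- rand_intervals(6, chroms = "chr1", len = 50000, max_w = 2000)
    k <- sample(3:5, 1)
    diff_idx <- sample.int(n_u, k)
    res <- region_overlap_enrichment(universe[diff_idx, ], features, universe)
    # oracle: enumerate every k-subset of the universe and count those with
    # at least q feature-overlapping peaks
    hit <- vapply(seq_len(n_u), function(i) {
      brute_count_hits(universe[i, , drop = FALSE], features,
                       "query_centric") > 0
    }, logical(1))
    draws <- utils::combn(n_u, k)
    tail_mass <- mean(colSums(matrix(hit[draws], nrow = k)) >= res$q)
    expect_equal(res$p_value, tail_mass, tolerance = 1e-12)
  }
})

test_that("TSS-window enrichment matches a per-gene brute-force scan", {
  # degenerate cases first
  genes <- toy_gene_table()
  empty <- data.frame(chrom = character(), start = numeric(),
                      end = numeric())
  res0 <- tss_window_enrichment(empty, genes, "up")
  expect_equal(c(res0$q, res0$m), c(0, 0))
  expect_equal(res0$p_value, 1)
  whole <- data.frame(chrom = "chr1", start = 0, end = 100000)
  res1 <- tss_window_enrichment(whole, genes, "up")
  expect_equal(res1$q, res1$k)
  expect_equal(res1$p_value, 1)

  set.seed(19)
  genes20 <- data.frame(gene_id = sprintf("g%02d", 1:20), chrom = "chr1",
                        strand = sample(c("+", "-"), 20, TRUE),
                        tss = sort(sample.int(200000, 20)),
                        de_label = sample(c("up", "down", "unchanged"), 20,
                                          TRUE, prob = c(.3, .2, .5)))
  features <- rand_intervals(15, chroms = "chr1", len = 200000, max_w = 3000)
  res <- tss_window_enrichment(features, genes20, "up", window = 2500)
  win <- data.frame(chrom = "chr1", start = pmax(0, genes20$tss - 2500),
                    end = genes20$tss + 2501)
  hit <- vapply(seq_len(20), function(i) {
    brute_count_hits(win[i, , drop = FALSE], features, "query_centric") > 0
  }, logical(1))
  lab <- genes20$de_label == "up"
  expect_equal(c(res$q, res$m, res$n, res$k),
               c(sum(hit & lab), sum(hit), sum(!hit), sum(lab)))
  expect_equal(res$p_value,
               lchoose_hypergeom_tail(res$q, res$m, res$n, res$k),
               tolerance = 1e-12)
})

test_that("composition tallies every class and deduplicates closest genes", {
  genes <- data.frame(gene_id = sprintf("g%d", 1:8), chrom = "chr1",
                      strand = "+", tss = 1:8 * 10000,
                      de_label = "unchanged",
                      chromatin_class = c(rep("bivalent", 4), "k4_only",
                                          "k4_only", "k27_only", "neither"))
  comp <- geneset_composition(sprintf("g%d", 1:4), genes)
  expect_equal(comp$fraction[comp$chromatin_class == "bivalent"], 1)
  expect_equal(sum(comp$fraction), 1)
  # empty classes stay in the output with fraction 0
  expect_setequal(comp$chromatin_class,
                  c("bivalent", "k4_only", "k27_only", "neither"))
  expect_error(geneset_composition("nope", genes), "nope")

  # 200-gene table vs independent tally
  set.seed(25)
  big <- data.frame(gene_id = sprintf("g%03d", 1:200), chrom = "chr1",
                    strand = "+", tss = 1:200 * 100,
                    de_label = "unchanged",
                    chromatin_class = sample(c("bivalent", "k4_only",
                                               "k27_only", "neither"),
                                             200, TRUE))
  pick <- sample(big$gene_id, 70)
  comp_big <- geneset_composition(pick, big)
  tally <- table(big$chromatin_class[match(pick, big$gene_id)])
  for (cl in names(tally)) {
    expect_equal(comp_big$count[comp_big$chromatin_class == cl],
                 as.integer(tally[[cl]]))
  }
  expect_equal(sum(comp_big$fraction), 1)

  # two peaks nearest the same gene count it once
  peaks <- data.frame(chrom = "chr1", start = c(9900, 10100, 39000),
                      end = c(10000, 10200, 39500))
  cc <- closest_gene_composition(peaks, genes)
  expect_equal(attr(cc, "gene_ids"), c("g1", "g4"))
  expect_equal(sum(cc$count), 2)
  # 30-peak instance vs brute-force nearest + tally oracle
  pk30 <- rand_intervals(30, chroms = "chr1", len = 80000, max_w = 400)
  nearest <- vapply(seq_len(30), function(i) {
    d <- vapply(seq_len(8), function(j) {
      if (pk30$start[i] <= genes$tss[j] && genes$tss[j] < pk30$end[i]) 0 else
        min(abs(genes$tss[j] - pk30$start[i]),
            abs(genes$tss[j] - (pk30$end[i] - 1)))
    }, numeric(1))
    sort(genes$gene_id[d == min(d)])[1]
  }, character(1))
  cc30 <- closest_gene_composition(pk30, genes)
  want <- table(genes$chromatin_class[match(unique(nearest), genes$gene_id)])
  for (cl in names(want)) {
    expect_equal(cc30$count[cc30$chromatin_class == cl],
                 as.integer(want[[cl]]))
  }
})
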