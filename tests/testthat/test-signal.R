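toy_track <- function() {
  data.frame(chrom = "chr1",
             start = c(0, 100, 300, 600),
             end = c(100, 300, 500, 1000),
             value = c(2, 1, 4, 0.5))
}

test_that("median-equalization factors follow the four documented steps", {
  set.seed(33)
  a <- rlnorm(20, 3, 1)
  mat <- cbind(A = a, B = 2 * a)
  f <- median_equalization_factors(mat)
  expect_equal(as.numeric(f["B"] / f["A"]), 0.5, tolerance = 1e-12)
  same <- cbind(A = a, B = a, C = a)
  expect_equal(as.numeric(median_equalization_factors(same)),
               rep(1, 3), tolerance = 1e-12)

  # independent step-by-step oracle on a 20 x 3 table
  mat3 <- cbind(A = a, B = 1.7 * a * runif(20, 0.9, 1.1),
                C = 0.6 * a * runif(20, 0.9, 1.1))
  f3 <- median_equalization_factors(mat3)
  rmean <- rowMeans(mat3)
  keep <- rmean > median(rmean)
  med <- apply(mat3[keep, ], 2, median)
  ref <- prod(med)^(1 / 3)
  expect_equal(as.numeric(f3), as.numeric(ref / med), tolerance = 1e-12)
  expect_equal(sum(attr(f3, "retained")), sum(keep))

  # applying the factors equalizes the per-condition medians exactly
  scaled <- sweep(mat3[keep, ], 2, f3, "*")
  meds <- apply(scaled, 2, median)
  expect_lt(max(abs(meds / meds[1] - 1)), 1e-9)

  expect_error(median_equalization_factors(mat3[, 1, drop = FALSE]),
               "2 conditions")
  expect_error(median_equalization_factors(mat3[1:3, ]), "4 regions")
  zero <- mat3; zero[, "B"] <- 0
  expect_error(median_equalization_factors(zero), "zero median")
})

test_that("region read counts sum value times covered bases", {
  track <- data.frame(chrom = "chr1", start = 0, end = 1000, value = 3)
  region <- data.frame(chrom = "chr1", start = 200, end = 700)
  expect_equal(region_read_counts(track, region, factor = 2), 3 * 500 * 2)
  # missing coverage is zero with a warning on absent chromosomes
  far <- data.frame(chrom = "chr2", start = 0, end = 100)
  expect_warning(v <- region_read_counts(track, far), "chr2")
  expect_equal(v, 0)
  # additivity over a partition of a region
  parts <- data.frame(chrom = "chr1", start = c(0, 250, 640),
                      end = c(250, 640, 1000))
  whole <- data.frame(chrom = "chr1", start = 0, end = 1000)
  expect_equal(sum(region_read_counts(toy_track(), parts)),
               region_read_counts(toy_track(), whole))
  # 10-region instance vs per-base summation oracle
  set.seed(35)
  regions <- rand_intervals(10, chroms = "chr1", len = 1000, max_w = 300)
  tr <- toy_track()
  oracle <- vapply(seq_len(10), function(i) {
    v <- numeric(1000)
    for (j in seq_len(nrow(tr))) v[(tr$start[j] + 1):tr$end[j]] <- tr$value[j]
    sum(v[(regions$start[i] + 1):regions$end[i]])
  }, numeric(1))
  expect_equal(region_read_counts(tr, regions), oracle)
})

test_that("metaplots bin regions with leftmost remainders and honour strand", {
  flat <- data.frame(chrom = "chr1", start = 0, end = 1000, value = 7)
  regions <- data.frame(chrom = "chr1", start = c(10, 500), end = c(110, 800))
  mp <- metaplot(flat, regions, n_bins = 10, factor = 0.5)
  expect_equal(mp$values, rep(3.5, 10))
  expect_equal(mp$n_regions, 2)
  # identity binning: n_bins = region length reproduces the per-base signal
  tr <- toy_track()
  one <- data.frame(chrom = "chr1", start = 95, end = 105)
  mp1 <- metaplot(tr, one, n_bins = 10)
  expect_equal(mp1$values, c(rep(2, 5), rep(1, 5)))
  # remainder bases go to the leftmost bins: width 7 over 3 bins = 3,2,2
  seg <- data.frame(chrom = "chr1", start = 97, end = 104, strand = "+")
  mp2 <- metaplot(tr, seg, n_bins = 3)
  expect_equal(mp2$values, c(mean(c(2, 2, 2)), mean(c(1, 1)), mean(c(1, 1))))
  # minus-strand regions are reversed
  seg_m <- seg; seg_m$strand <- "-"
  mp3 <- metaplot(tr, seg_m, n_bins = 3)
  expect_equal(mp3$values, rev(mp2$values))
  # strand-symmetric signal is invariant under flipping all strands
  sym <- data.frame(chrom = "chr1", start = 0, end = 400, value = 5)
  reg <- data.frame(chrom = "chr1", start = c(0, 100), end = c(100, 200),
                    strand = c("+", "+"))
  reg_f <- reg; reg_f$strand <- c("-", "-")
  expect_equal(metaplot(sym, reg, 10)$values, metaplot(sym, reg_f, 10)$values)
  # 5-region oracle against per-base binning
  set.seed(36)
  regs <- rand_intervals(5, chroms = "chr1", len = 900, max_w = 120)
  regs$strand <- sample(c("+", "-"), 5, TRUE)
  got <- metaplot(tr, regs, n_bins = 4)$values
  v_full <- numeric(1000)
  for (j in seq_len(nrow(tr))) v_full[(tr$start[j] + 1):tr$end[j]] <- tr$value[j]
  prof <- sapply(seq_len(5), function(i) {
    v <- v_full[(regs$start[i] + 1):regs$end[i]]
    W <- length(v)
    sizes <- rep(W %/% 4, 4) + (1:4 <= W %% 4)
    means <- as.numeric(tapply(v, rep(1:4, times = sizes), mean))
    if (regs$strand[i] == "-") rev(means) else means
  })
  expect_equal(got, rowMeans(prof))
})

test_that("region matrices agree with per-condition read counts", {
  tr_a <- toy_track()
  tr_b <- toy_track(); tr_b$value <- tr_b$value * 3
  regions <- data.frame(chrom = "chr1", start = c(50, 400), end = c(150, 700))
  m <- region_matrix(list(a = tr_a, b = tr_b), regions,
                     factors = c(a = 1, b = 0.5))
  expect_equal(dim(m), c(2, 2))
  expect_equal(m[, "a"], region_read_counts(tr_a, regions))
  expect_equal(m[, "b"], region_read_counts(tr_b, regions, factor = 0.5))
  # permuting region order permutes rows identically
  m_rev <- region_matrix(list(a = tr_a, b = tr_b), regions[2:1, ],
                         factors = c(a = 1, b = 0.5))
  expect_equal(m_rev, m[2:1, ])
  expect_error(region_matrix(list(a = tr_a, b = tr_b), regions,
                             factors = c(a = 1)), "b")
})
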