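# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's own machinery (GenomicRanges, phyper) so each check is
# a genuine dual route.

# all-pairs O(n*m) overlap scan on 0-based half-open intervals
brute_pair_overlap <- function(c1, s1, e1, c2, s2, e2) {
  c1 == c2 && s1 < e2 && s2 < e1
}

brute_count_hits <- function(queries, features, mode) {
  hit_q <- logical(nrow(queries))
  hit_f <- logical(nrow(features))
  for (i in seq_len(nrow(queries))) {
    for (j in seq_len(nrow(features))) {
      if (brute_pair_overlap(queries$chrom[i], queries$start[i],
                             queries$end[i], features$chrom[j],
                             features$start[j], features$end[j])) {
        hit_q[i] <- TRUE
        hit_f[j] <- TRUE
      }
    }
  }
  if (mode == "query_centric") sum(hit_q) else sum(hit_f)
}

# per-base occupancy union: total covered bases and the merged intervals
brute_union_bases <- function(df, chrom_len) {
  total <- 0
  for (ch in unique(df$chrom)) {
    occ <- logical(chrom_len)
    sub <- df[df$chrom == ch, ]
    for (i in seq_len(nrow(sub))) {
      occ[(sub$start[i] + 1):sub$end[i]] <- TRUE
    }
    total <- total + sum(occ)
  }
  total
}

# exhaustive hypergeometric tail by enumerating every C(m+n, k) draw
enum_hypergeom_tail <- function(q, m, n, k, inclusive = TRUE) {
  if (k == 0) return(if (q == 0 && inclusive) 1 else 0)
  draws <- utils::combn(m + n, k)
  marked_per_draw <- colSums(draws <= m)
  if (inclusive) mean(marked_per_draw >= q) else mean(marked_per_draw > q)
}

# log-factorial closed form, independent of phyper
lchoose_hypergeom_tail <- function(q, m, n, k, inclusive = TRUE) {
  lo <- if (inclusive) q else q + 1
  hi <- min(m, k)
  if (lo > hi) return(0)
  i <- lo:hi
  sum(exp(lchoose(m, i) + lchoose(n, k - i) - lchoose(m + n, k)))
}

# random interval set on a toy genome
rand_intervals <- function(n, chroms = c("chrA", "chrB"), len = 10000,
                           max_w = 500) {
  ch <- sample(chroms, n, replace = TRUE)
  st <- sample.int(len - max_w, n, replace = TRUE) - 1
  w <- sample.int(max_w, n, replace = TRUE)
  data.frame(chrom = ch, start = st, end = st + w, stringsAsFactors = FALSE)
}

# tiny fixed gene table on one 100 kb chromosome: TSS every 20 kb, two of
# five genes upregulated
toy_gene_table <- function() {
  data.frame(
    gene_id = sprintf("g%d", 1:5),
    chrom = "chr1",
    strand = c("+", "-", "+", "-", "+"),
    tss = c(10000, 30000, 50000, 70000, 90000),
    de_label = c("unchanged", "up", "up", "unchanged", "unchanged"),
    stringsAsFactors = FALSE
  )
}

toy_sizes <- c(chr1 = 100000)

run_cli <- function(args) {
  script <- system.file("cli", "peakladder.R", package = "peakladder")
  out <- tempfile()
  err <- tempfile()
  status <- system2("Rscript", c(script, args), stdout = out, stderr = err,
                    env = paste0("R_LIBS=", paste(.libPaths(), collapse = ":")))
  list(status = status, stdout = readLines(out, warn = FALSE),
       stderr = readLines(err, warn = FALSE))
}
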