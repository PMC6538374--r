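#' Default distance ladder
#'
#' The grid of expansion distances used when none is given: 5 kb steps to
#' 100 kb, 25 kb steps to 500 kb, then 100 kb steps to 2 Mb — preserving the
#' documented 5 kb start and 2 Mb endpoint while keeping the grid small
#' enough for repeated resampling.
#'
#' @return Numeric vector of distances (bp), sorted ascending.
#' @export
ladder_distances <- function() {
  c(seq(5e3, 1e5, by = 5e3),
    seq(1.25e5, 5e5, by = 2.5e4),
    seq(6e5, 2e6, by = 1e5))
}

# --- fast sweep machinery -------------------------------------------------
# The ladder evaluates thousands of (peak set, distance) pairs during
# resampling, so the union/membership step runs on flat numeric vectors:
# each chromosome is mapped onto a disjoint segment of one axis (offsets),
# expansions are clipped per chromosome first so segments cannot bleed into
# one another, the union comes from a sort + cumulative-max sweep, and TSS
# membership is a findInterval parity lookup on the union boundaries.

chrom_offsets <- function(sizes) {
  off <- c(0, cumsum(as.numeric(sizes)))[seq_along(sizes)]
  stats::setNames(off, names(sizes))
}

# union of [s, e) intervals (already offset); returns boundary vector
# b = c(s1, e1, s2, e2, ...) with adjacent/overlapping runs coalesced
sweep_union_bounds <- function(s, e) {
  o <- order(s)
  s <- s[o]
  ce <- cummax(e[o])
  new_run <- c(TRUE, s[-1] > ce[-length(ce)])
  us <- s[new_run]
  ue <- ce[c(which(new_run)[-1] - 1L, length(ce))]
  as.vector(rbind(us, ue))
}

# count points inside the half-open union: parity of findInterval
points_in_union <- function(pts, bounds) {
  findInterval(pts, bounds) %% 2L == 1L
}

ladder_eval <- function(s, e, lim, off, radius, tss_flat, is_label, m, n,
                        tail) {
  bounds <- sweep_union_bounds(pmax(0, s - radius) + off,
                               pmin(lim, e + radius) + off)
  inside <- points_in_union(tss_flat, bounds)
  k <- sum(inside)
  q <- sum(inside & is_label)
  p <- hypergeom_upper_tail(q, m, n, k, tail = tail)
  c(k = k, q = q, p = p)
}

#' Distance-ladder enrichment of differential genes around peaks
#'
#' For each distance `d`, every peak is expanded by `d`, the expanded ranges
#' are unioned, the distinct genes whose TSS falls in the union are counted
#' (`encompassed_tss = k`), the subset carrying the target differential
#' label is counted (`deg_hits = q`), and an upper-tail hypergeometric
#' probability is computed against the whole gene table
#' (`m` = genes with the label, `n` = the rest). Genes covered by several
#' expanded peaks are counted once: the test models sampling without
#' replacement from distinct genes.
#'
#' @param peaks Interval data.frame (e.g. the HA or LA peak set).
#' @param genes Gene table with `de_label` (see [read_gene_table()]).
#' @param label Target label, `"up"` or `"down"`.
#' @param distances Ascending distances in bp; default [ladder_distances()].
#' @param sizes Chromosome sizes (expansion is clipped to bounds).
#' @param tail Tail convention, see [hypergeom_upper_tail()].
#' @param range_mode `"radius"` (a distance-`d` range reaches `d` bp beyond
#'   each peak edge; default) or `"total_width"` (each edge extends `d/2`).
#' @return Data.frame with one row per distance: `d_bp`,
#'   `encompassed_tss`, `deg_hits`, `m`, `n`, `k`, `q`, `p_value`.
#' @export
ladder_enrichment <- function(peaks, genes, label = c("up", "down"),
                              distances = ladder_distances(), sizes,
                              tail = c("inclusive", "exclusive"),
                              range_mode = c("radius", "total_width")) {
  label <- match.arg(label)
  tail <- match.arg(tail)
  range_mode <- match.arg(range_mode)
  if (nrow(peaks) == 0) stop("peak set is empty")
  if (nrow(genes) == 0) stop("gene table is empty")
  if (is.unsorted(distances)) stop("distances must be sorted ascending")
  peaks <- as_intervals(peaks, sizes)
  check_chrom_bounds(genes$chrom, genes$tss, genes$tss + 1, sizes)
  m <- sum(genes$de_label == label)
  n <- nrow(genes) - m
  off <- chrom_offsets(sizes)
  tss_flat <- genes$tss + off[genes$chrom]
  is_label <- genes$de_label == label
  lim <- unname(sizes[peaks$chrom])
  poff <- unname(off[peaks$chrom])
  res <- lapply(distances, function(d) {
    radius <- if (range_mode == "radius") d else d / 2
    ev <- ladder_eval(peaks$start, peaks$end, lim, poff, radius,
                      tss_flat, is_label, m, n, tail)
    data.frame(d_bp = d, encompassed_tss = ev[["k"]], deg_hits = ev[["q"]],
               m = m, n = n, k = ev[["k"]], q = ev[["q"]],
               p_value = ev[["p"]])
  })
  do.call(rbind, res)
}

# Run fn() with the RNG seeded locally, restoring global RNG state after.
with_local_seed <- function(seed, fn) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed, kind = "Mersenne-Twister", sample.kind = "Rejection")
  fn()
}

#' Random peak sets matched in number and width to a target set
#'
#' Draws `n_sets` subsets of the observed peak universe, each with exactly
#' as many peaks as `target` and the same width profile: target widths are
#' binned into deciles (bin edges from the target's own width quantiles),
#' and each random set draws the target's per-bin counts from the universe
#' peaks falling in that width bin, without replacement within a set. If a
#' bin holds too few universe peaks the deficit is borrowed from the nearest
#' adjacent bins, and the total borrowed count is attached as
#' `attr(, "borrowed")`.
#'
#' @param universe Interval data.frame of all observed peaks.
#' @param target Interval data.frame of the differential set being matched.
#' @param n_sets Number of random sets (>= 0).
#' @param seed Integer seed; the draw is fully reproducible.
#' @return A list of `n_sets` interval data.frames (rows of `universe`).
#' @export
sample_matched_peak_sets <- function(universe, target, n_sets, seed) {
  universe <- as_intervals(universe)
  target <- as_intervals(target)
  if (n_sets < 0) stop("n_sets must be >= 0")
  if (nrow(universe) < nrow(target)) {
    stop("universe has fewer peaks (", nrow(universe),
         ") than the target set (", nrow(target), ")")
  }
  if (n_sets == 0) return(list())
  wt <- target$end - target$start
  wu <- universe$end - universe$start
  breaks <- unique(stats::quantile(wt, probs = 0:10 / 10, type = 7))
  # findInterval on interior breakpoints: bins cover the whole real line so
  # every universe width lands in some bin (extremes join the end bins)
  inner <- breaks[-c(1, length(breaks))]
  bin_t <- findInterval(wt, inner) + 1L
  bin_u <- findInterval(wu, inner) + 1L
  n_bins <- length(inner) + 1L
  need <- tabulate(bin_t, nbins = n_bins)
  pool <- split(seq_len(nrow(universe)), factor(bin_u, levels = seq_len(n_bins)))
  borrowed_total <- 0L
  sets <- with_local_seed(seed, function() {
    lapply(seq_len(n_sets), function(i) {
      taken <- integer(0)
      for (b in seq_len(n_bins)) {
        nb <- need[b]
        if (nb == 0) next
        avail <- setdiff(pool[[b]], taken)
        if (length(avail) >= nb) {
          pick <- sample_int(avail, nb)
        } else {
          pick <- avail
          deficit <- nb - length(avail)
          borrowed_total <<- borrowed_total + deficit
          for (off in seq_len(n_bins)) {
            if (deficit == 0) break
            for (nb2 in c(b - off, b + off)) {
              if (deficit == 0 || nb2 < 1 || nb2 > n_bins) next
              extra <- setdiff(pool[[nb2]], c(taken, pick))
              take <- min(deficit, length(extra))
              if (take > 0) {
                pick <- c(pick, sample_int(extra, take))
                deficit <- deficit - take
              }
            }
          }
          if (deficit > 0) stop("cannot fill width bin ", b,
                                ": universe exhausted")
        }
        taken <- c(taken, pick)
      }
      out <- universe[sort(taken), , drop = FALSE]
      attr(out, "universe_rows") <- sort(taken)
      out
    })
  })
  attr(sets, "borrowed") <- borrowed_total
  sets
}

# sample() without its length-1 surprise
sample_int <- function(x, size) x[sample.int(length(x), size)]

#' Quantile envelope of the resampling null
#'
#' Collapses per-distance p-values from the random peak sets into the
#' plotted band: the requested quantiles of `-log10 p` (type-7,
#' linear-interpolation definition) at every distance.
#'
#' @param p_matrix Matrix of p-values, one row per random set, one column
#'   per distance (all sets must share the distance grid).
#' @param distances The distance grid (bp).
#' @param quantiles Three probabilities, default `c(0.05, 0.5, 0.95)`.
#' @return Data.frame `d_bp`, `null_q05`, `null_median`, `null_q95` (on the
#'   `-log10 p` scale).
#' @export
null_envelope <- function(p_matrix, distances,
                          quantiles = c(0.05, 0.5, 0.95)) {
  p_matrix <- as.matrix(p_matrix)
  if (nrow(p_matrix) < 1) stop("at least one random result is required")
  if (ncol(p_matrix) != length(distances)) {
    stop("p-value matrix has ", ncol(p_matrix), " columns but ",
         length(distances), " distances (ragged grids are not allowed)")
  }
  nl <- neg_log10(p_matrix)
  qs <- apply(nl, 2, stats::quantile, probs = quantiles, type = 7)
  data.frame(d_bp = distances, null_q05 = qs[1, ], null_median = qs[2, ],
             null_q95 = qs[3, ], row.names = NULL)
}

#' Observed ladder with its matched-random null envelope
#'
#' Convenience wrapper running [ladder_enrichment()] on the differential
#' peaks and on `n_random` width/number-matched random subsets of the peak
#' universe, then joining the observed curve with the 5/50/95 percent
#' envelope of the random curves.
#'
#' @inheritParams ladder_enrichment
#' @param universe Interval data.frame of all observed peaks the random
#'   sets are drawn from.
#' @param n_random Number of random sets (1000 mirrors the published
#'   analysis; smaller values are useful for testing).
#' @param seed Integer seed driving the resampling.
#' @return The [ladder_enrichment()] data.frame with `neg_log10_p`,
#'   `null_q05`, `null_median`, `null_q95` columns appended.
#' @export
ladder_with_null <- function(peaks, universe, genes, label = c("up", "down"),
                             distances = ladder_distances(), sizes,
                             n_random = 1000, seed = 1,
                             tail = c("inclusive", "exclusive"),
                             range_mode = c("radius", "total_width")) {
  label <- match.arg(label)
  tail <- match.arg(tail)
  range_mode <- match.arg(range_mode)
  obs <- ladder_enrichment(peaks, genes, label, distances, sizes,
                           tail = tail, range_mode = range_mode)
  universe <- as_intervals(universe, sizes)
  rand_sets <- sample_matched_peak_sets(universe, peaks, n_random, seed)
  off <- chrom_offsets(sizes)
  tss_flat <- genes$tss + off[genes$chrom]
  is_label <- genes$de_label == label
  m <- sum(is_label)
  n <- nrow(genes) - m
  u_lim <- unname(sizes[universe$chrom])
  u_off <- unname(off[universe$chrom])
  radii <- if (range_mode == "radius") distances else distances / 2
  praw <- vapply(rand_sets, function(rs) {
    idx <- attr(rs, "universe_rows")
    vapply(radii, function(r) {
      ladder_eval(universe$start[idx], universe$end[idx], u_lim[idx],
                  u_off[idx], r, tss_flat, is_label, m, n, tail)[["p"]]
    }, numeric(1))
  }, numeric(length(distances)))
  pmat <- t(matrix(praw, nrow = length(distances)))
  env <- null_envelope(pmat, distances)
  obs$neg_log10_p <- neg_log10(obs$p_value)
  cbind(obs, env[, c("null_q05", "null_median", "null_q95")])
}
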