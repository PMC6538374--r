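#' Median-equalization scale factors across conditions
#'
#' Normalization used to compare signal between conditions: scale each
#' condition so the median read count over a high-signal subset of the
#' considered regions is the same everywhere. Regions whose signal cannot
#' be distinguished from noise are excluded first. Concretely:
#' (1) compute each region's cross-condition mean; (2) retain regions whose
#' mean strictly exceeds the median of those means (ties at the median are
#' excluded); (3) the reference value is the geometric mean of the
#' per-condition medians over retained regions, so the result does not
#' depend on condition order; (4) `factor_c = reference / median_c`.
#' Applying the factors makes every per-condition median over the retained
#' regions equal to the reference.
#'
#' @param mat Numeric matrix of raw read counts, regions in rows,
#'   conditions in columns (>= 4 regions, >= 2 named columns).
#' @return Named numeric vector of multiplicative factors, with attributes
#'   `reference` (the equalized median), `medians` (raw per-condition
#'   medians) and `retained` (logical row filter).
#' @export
median_equalization_factors <- function(mat) {
  mat <- as.matrix(mat)
  if (ncol(mat) < 2) stop("at least 2 conditions are required")
  if (nrow(mat) < 4) stop("at least 4 regions are required")
  if (any(mat < 0)) stop("read counts must be non-negative")
  if (is.null(colnames(mat))) colnames(mat) <- paste0("cond", seq_len(ncol(mat)))
  rmean <- rowMeans(mat)
  retained <- rmean > stats::median(rmean)
  if (!any(retained)) stop("no region exceeds the median signal")
  med <- apply(mat[retained, , drop = FALSE], 2, stats::median)
  if (any(med == 0)) {
    stop("condition(s) with zero median over retained regions: ",
         paste(colnames(mat)[med == 0], collapse = ", "))
  }
  reference <- exp(mean(log(med)))
  factors <- reference / med
  attr(factors, "reference") <- reference
  attr(factors, "medians") <- med
  attr(factors, "retained") <- retained
  factors
}

# Per-base signal vector over [start, end) of one chromosome of a track.
track_region_vector <- function(track, chrom, start, end) {
  v <- numeric(end - start)
  rows <- which(track$chrom == chrom & track$start < end & track$end > start)
  for (i in rows) {
    a <- max(track$start[i], start) - start + 1
    b <- min(track$end[i], end) - start
    v[a:b] <- v[a:b] + track$value[i]
  }
  v
}

#' Normalized read counts over regions from a bedGraph track
#'
#' For each region, the sum of `value * covered bases` over all overlapping
#' track intervals, multiplied by the condition's scale factor. Regions on
#' chromosomes absent from the track get 0 with a warning (not an error),
#' since missing coverage is a legitimate empty signal.
#'
#' @param track bedGraph data.frame (see [read_bedgraph()]).
#' @param regions Interval data.frame.
#' @param factor Multiplicative normalization factor (default 1).
#' @return Numeric vector of normalized per-region values.
#' @export
region_read_counts <- function(track, regions, factor = 1) {
  regions <- as_intervals(regions)
  if (nrow(regions) == 0) stop("regions are empty")
  absent <- setdiff(unique(regions$chrom), unique(track$chrom))
  if (length(absent)) {
    warning("region chromosome(s) absent from track (counted as 0): ",
            paste(absent, collapse = ", "))
  }
  out <- numeric(nrow(regions))
  if (nrow(track) > 0) {
    lv <- union(unique(regions$chrom), unique(track$chrom))
    mk <- function(d) GenomicRanges::GRanges(
      factor(d$chrom, levels = lv),
      IRanges::IRanges(start = d$start + 1L, end = d$end))
    tg <- mk(track)
    rg <- mk(regions)
    ov <- GenomicRanges::findOverlaps(rg, tg, ignore.strand = TRUE)
    if (length(ov) > 0) {
      ri <- S4Vectors::queryHits(ov)
      ti <- S4Vectors::subjectHits(ov)
      covered <- pmin(regions$end[ri], track$end[ti]) -
        pmax(regions$start[ri], track$start[ti])
      contrib <- covered * track$value[ti]
      agg <- tapply(contrib, ri, sum)
      out[as.integer(names(agg))] <- as.numeric(agg)
    }
  }
  out * factor
}

#' Average signal metaprofile over a region set
#'
#' Each region is split into `n_bins` equal sub-intervals (remainder bases
#' go to the leftmost bins, so profiles are bit-reproducible), the mean
#' per-base signal in every bin is scaled by `factor`, minus-strand regions
#' are reversed so all profiles run 5' to 3', and the profile is the
#' unweighted mean across regions — the metaplot drawn over
#' super-enhancers or binding-site catalogues.
#'
#' @param track bedGraph data.frame.
#' @param regions Interval data.frame (all widths >= 1; strand honoured
#'   when present).
#' @param n_bins Number of bins (>= 1).
#' @param factor Normalization factor applied to the signal.
#' @return A `metaprofile` list: `values` (length `n_bins`), `n_bins`,
#'   `n_regions`.
#' @export
metaplot <- function(track, regions, n_bins = 100, factor = 1) {
  stopifnot(n_bins >= 1)
  regions <- as_intervals(regions)
  if (nrow(regions) == 0) stop("regions are empty")
  widths <- regions$end - regions$start
  if (any(widths < n_bins)) {
    # still defined: bins of width >= 0 would break the mean; require 1 bp
    if (any(widths < 1)) stop("all regions must have length >= 1")
  }
  profiles <- matrix(0, nrow(regions), n_bins)
  for (r in seq_len(nrow(regions))) {
    v <- track_region_vector(track, regions$chrom[r], regions$start[r],
                             regions$end[r])
    W <- length(v)
    base_size <- W %/% n_bins
    sizes <- rep(base_size, n_bins) + (seq_len(n_bins) <= W %% n_bins)
    if (any(sizes == 0)) {
      stop("region of width ", W, " cannot be split into ", n_bins, " bins")
    }
    idx <- rep(seq_len(n_bins), times = sizes)
    means <- as.numeric(tapply(v, idx, mean))
    if (regions$strand[r] == "-") means <- rev(means)
    profiles[r, ] <- means * factor
  }
  structure(list(values = colMeans(profiles), n_bins = n_bins,
                 n_regions = nrow(regions)),
            class = "metaprofile")
}

#' @export
print.metaprofile <- function(x, ...) {
  cat("Metaprofile over", x$n_regions, "regions,", x$n_bins, "bins\n")
  cat("  mean signal range: [", format(min(x$values), digits = 4), ", ",
      format(max(x$values), digits = 4), "]\n", sep = "")
  invisible(x)
}

#' Region-by-condition matrix of normalized signal
#'
#' One [region_read_counts()] column per condition, row order preserved —
#' the export shape consumed by external heatmap renderers.
#'
#' @param tracks Named list of bedGraph data.frames, one per condition.
#' @param regions Interval data.frame.
#' @param factors Named factor vector (default all 1); names must cover the
#'   track names.
#' @return Numeric matrix, regions x conditions.
#' @export
region_matrix <- function(tracks, regions, factors = NULL) {
  stopifnot(is.list(tracks), length(tracks) >= 1, !is.null(names(tracks)))
  if (is.null(factors)) {
    factors <- stats::setNames(rep(1, length(tracks)), names(tracks))
  }
  miss <- setdiff(names(tracks), names(factors))
  if (length(miss)) stop("no factor for condition(s): ",
                         paste(miss, collapse = ", "))
  out <- vapply(names(tracks), function(cn) {
    region_read_counts(tracks[[cn]], regions, factor = factors[[cn]])
  }, numeric(nrow(regions)))
  out <- matrix(out, nrow = nrow(regions),
                dimnames = list(NULL, names(tracks)))
  out
}
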