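#' Enrichment of differential peaks in a genomic feature set
#'
#' The peak-level overlap test: with the merged considered peaks as the
#' universe, `q` = differential peaks intersecting at least one feature,
#' `m` = universe peaks intersecting the features, `n` = universe peaks not
#' intersecting them, `k` = number of differential peaks, and the p-value is
#' the upper-tail hypergeometric probability. Differential peaks must be a
#' coordinate subset of the universe — a mismatch usually means the two
#' tables came from different peak-processing runs, and is an error rather
#' than a silent bias.
#'
#' @param diff_peaks Interval data.frame of the differential set.
#' @param features Interval data.frame of the feature catalogue
#'   (enhancers, super-enhancers, TF binding sites, ...).
#' @param universe_peaks Interval data.frame of all considered peaks.
#' @param counting_mode `"query_centric"` (the test above) or
#'   `"feature_centric"`, which additionally reports how many features are
#'   hit (for statements like "present in 127/684 of these regions").
#' @param tail See [hypergeom_upper_tail()].
#' @return An `enrichment_result` list: `q`, `m`, `n`, `k`, `p_value`,
#'   `counting_mode`, `tail`, and (feature-centric) `features_hit`,
#'   `n_features`.
#' @export
region_overlap_enrichment <- function(diff_peaks, features, universe_peaks,
                                      counting_mode = c("query_centric",
                                                        "feature_centric"),
                                      tail = c("inclusive", "exclusive")) {
  counting_mode <- match.arg(counting_mode)
  tail <- match.arg(tail)
  diff_peaks <- as_intervals(diff_peaks)
  universe_peaks <- as_intervals(universe_peaks)
  features <- as_intervals(features)
  key <- function(x) paste(x$chrom, x$start, x$end, sep = ":")
  missing_ <- setdiff(key(diff_peaks), key(universe_peaks))
  if (length(missing_)) {
    stop("differential peak(s) absent from the universe (first: ",
         missing_[1], "); diff_peaks must be a subset of universe_peaks")
  }
  q <- count_region_hits(diff_peaks, features, "query_centric")
  m <- count_region_hits(universe_peaks, features, "query_centric")
  n <- nrow(universe_peaks) - m
  k <- nrow(diff_peaks)
  out <- list(q = q, m = m, n = n, k = k,
              p_value = hypergeom_upper_tail(q, m, n, k, tail = tail),
              counting_mode = counting_mode, tail = tail)
  if (counting_mode == "feature_centric") {
    out$features_hit <- count_region_hits(diff_peaks, features,
                                          "feature_centric")
    out$n_features <- nrow(features)
  }
  structure(out, class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat("Region-overlap enrichment (", x$counting_mode, ", ", x$tail,
      " tail)\n", sep = "")
  cat("  q = ", x$q, "  m = ", x$m, "  n = ", x$n, "  k = ", x$k, "\n",
      sep = "")
  if (!is.null(x$features_hit)) {
    cat("  features hit: ", x$features_hit, "/", x$n_features, "\n", sep = "")
  }
  cat("  p = ", format(x$p_value, digits = 4), "\n", sep = "")
  invisible(x)
}

#' @export
as.data.frame.enrichment_result <- function(x, ...) {
  data.frame(q = x$q, m = x$m, n = x$n, k = x$k, p_value = x$p_value,
             counting_mode = x$counting_mode, tail = x$tail,
             features_hit = if (is.null(x$features_hit)) NA else x$features_hit,
             n_features = if (is.null(x$n_features)) NA else x$n_features)
}

#' Enrichment of a feature set near the TSS of differential genes
#'
#' Gene-centric overlap test around TSS windows: each gene contributes the
#' window `[tss - window, tss + window + 1)` (clipped to its chromosome when
#' sizes are given); `m` = genes whose window intersects at least one
#' feature, `k` = genes carrying `de_label`, `q` = labelled genes whose
#' window is hit.
#'
#' @param features Interval data.frame (e.g. ChIP-seq peaks for a factor or
#'   histone mark).
#' @param genes Gene table.
#' @param de_label `"up"` or `"down"`.
#' @param window Half-width in bp (default 2500, i.e. TSS +/- 2.5 kb).
#' @param tail See [hypergeom_upper_tail()].
#' @param sizes Optional chromosome sizes for clipping.
#' @return An `enrichment_result` list.
#' @export
tss_window_enrichment <- function(features, genes, de_label = c("up", "down"),
                                  window = 2500,
                                  tail = c("inclusive", "exclusive"),
                                  sizes = NULL) {
  de_label <- match.arg(de_label)
  tail <- match.arg(tail)
  stopifnot(window > 0)
  features <- as_intervals(features)
  win <- data.frame(chrom = genes$chrom,
                    start = pmax(0, genes$tss - window),
                    end = genes$tss + window + 1)
  if (!is.null(sizes)) {
    check_chrom_bounds(genes$chrom, genes$tss, genes$tss + 1, sizes)
    win$end <- pmin(unname(sizes[win$chrom]), win$end)
  }
  hit <- if (nrow(features) == 0) rep(FALSE, nrow(genes)) else
    IRanges::overlapsAny(intervals_to_granges(win),
                         intervals_to_granges(features), ignore.strand = TRUE)
  is_label <- genes$de_label == de_label
  m <- sum(hit)
  n <- nrow(genes) - m
  k <- sum(is_label)
  q <- sum(hit & is_label)
  structure(list(q = q, m = m, n = n, k = k,
                 p_value = hypergeom_upper_tail(q, m, n, k, tail = tail),
                 counting_mode = "gene_centric", tail = tail),
            class = "enrichment_result")
}
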