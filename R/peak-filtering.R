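#' Remove the top fraction of exceptionally high-depth regions
#'
#' Removes exactly `floor(fraction * n)` peaks of highest `depth` from a
#' per-condition peak table, mirroring the exclusion of regions of
#' exceptionally high depth of aligned short reads before peaks are merged
#' across conditions. With the default 0.001 nothing is removed until the
#' set holds at least 1000 peaks. Depth ties break by chromosome then start,
#' with later-sorted peaks removed first, so the result is deterministic.
#'
#' @param peaks Data.frame with interval columns and a `depth` column.
#' @param fraction Fraction in `[0, 1)` of peaks to drop (default 0.001,
#'   i.e. the top 0.1 percent).
#' @return The retained peaks; the removed rows are attached as
#'   `attr(, "removed")` for audit logging.
#' @export
exclude_high_depth <- function(peaks, fraction = 0.001) {
  stopifnot(is.data.frame(peaks))
  if (!"depth" %in% names(peaks)) stop("peak table has no depth column")
  if (any(is.na(peaks$depth))) stop("depth contains missing values")
  if (fraction < 0 || fraction >= 1) stop("fraction must be in [0, 1)")
  n_drop <- floor(fraction * nrow(peaks))
  if (n_drop == 0) {
    out <- peaks
    attr(out, "removed") <- peaks[0, , drop = FALSE]
    return(out)
  }
  # later-sorted (by chrom, start) removed first among equal depths
  ord <- order(-peaks$depth, -xtfrm(peaks$chrom), -peaks$start)
  drop <- ord[seq_len(n_drop)]
  out <- peaks[-drop, , drop = FALSE]
  attr(out, "removed") <- peaks[drop, , drop = FALSE]
  out
}

#' Merge peak sets from several conditions into considered regions
#'
#' The union of all per-condition peak calls, with overlapping intervals
#' coalesced, defines the considered regions that serve as the statistical
#' universe for all downstream tests. Bookended intervals stay separate at
#' the default `merge_gap = 0`.
#'
#' @param peak_sets A list of interval data.frames (one per condition), or a
#'   single data.frame.
#' @param merge_gap See [reduce_intervals()].
#' @return Sorted interval data.frame of merged regions.
#' @export
merge_considered_regions <- function(peak_sets, merge_gap = 0) {
  if (is.data.frame(peak_sets)) peak_sets <- list(peak_sets)
  if (length(peak_sets) == 0) stop("at least one peak set is required")
  core <- lapply(peak_sets, function(p) as_intervals(p)[, c("chrom", "start", "end")])
  reduce_intervals(do.call(rbind, core), merge_gap = merge_gap)
}

#' Filter peaks on the maximum per-condition group mean
#'
#' Retains peaks whose largest `group_mean_<condition>` strictly exceeds
#' `mgm_min`; regions too shallow in every condition are excluded from
#' differential testing.
#'
#' @param peaks Stats table with `group_mean_*` columns.
#' @param mgm_min Threshold in reads (strict `>`).
#' @return The retained rows.
#' @export
mgm_filter <- function(peaks, mgm_min) {
  gm_cols <- grep("^group_mean_", names(peaks), value = TRUE)
  if (length(gm_cols) == 0) stop("no group_mean_<condition> columns present")
  gm <- as.matrix(peaks[, gm_cols, drop = FALSE])
  if (any(is.na(gm))) stop("group means contain missing values")
  peaks[apply(gm, 1, max) > mgm_min, , drop = FALSE]
}

#' Differential-call thresholds
#'
#' Bundles the q-value ceiling, the linear fold-change floor and the
#' max-group-mean floor applied when labelling peaks as higher accessibility
#' (HA), lower accessibility (LA) or unchanged. Two presets encode the two
#' analysis regimes used for steady-state (q < 0.05, FC > 1.5, mgm > 8) and
#' neural-induction (q < 0.01, FC > 2, mgm > 32) comparisons; the
#' steady-state/neural fold-change discrepancy between a linear and a log2
#' reading is deliberately left as an explicit knob.
#'
#' @param q_max Adjusted-significance ceiling in `(0, 1]`.
#' @param fc_min Linear fold-change floor (> 1).
#' @param mgm_min Max-group-mean floor (>= 0 reads).
#' @return A `diff_call_config` list.
#' @export
diff_call_config <- function(q_max, fc_min, mgm_min) {
  stopifnot(q_max > 0, q_max <= 1, fc_min > 1, mgm_min >= 0)
  structure(list(q_max = q_max, fc_min = fc_min, mgm_min = mgm_min),
            class = "diff_call_config")
}

#' @rdname diff_call_config
#' @param preset `"steady_state"` or `"neural"`.
#' @export
preset_config <- function(preset = c("steady_state", "neural")) {
  switch(match.arg(preset),
         steady_state = diff_call_config(0.05, 1.5, 8),
         neural = diff_call_config(0.01, 2.0, 32))
}

#' Label peaks as higher/lower accessibility or unchanged
#'
#' Fold changes are signed linear ratios: `+3` means three-fold higher in
#' the treatment, `-3` three-fold lower. HA requires `q < q_max` and
#' `fold_change >= fc_min`; LA requires `q < q_max` and
#' `fold_change <= -fc_min`; everything else is unchanged. The three sets
#' partition the input.
#'
#' @param peaks Stats table with `q_value` and `fold_change` columns
#'   (typically after [mgm_filter()]).
#' @param config A [diff_call_config()].
#' @return `peaks` with a `call` column in `{HA, LA, unchanged}`.
#' @export
call_differential <- function(peaks, config) {
  stopifnot(inherits(config, "diff_call_config"))
  if (!all(c("q_value", "fold_change") %in% names(peaks))) {
    stop("stats table must contain q_value and fold_change columns")
  }
  if (any(is.na(peaks$q_value)) || any(is.na(peaks$fold_change))) {
    stop("q_value/fold_change contain missing values")
  }
  fc <- peaks$fold_change
  if (any(abs(fc) < 1 & fc != 0)) {
    stop("fold_change values in (-1, 1) found; expected signed linear ",
         "fold changes (use -x, not 1/x, for the inverse contrast)")
  }
  sig <- peaks$q_value < config$q_max
  call <- rep("unchanged", nrow(peaks))
  call[sig & fc >= config$fc_min] <- "HA"
  call[sig & fc <= -config$fc_min] <- "LA"
  peaks$call <- call
  peaks
}

#' @rdname call_differential
#' @return `split_differential()`: a list with elements `ha`, `la`,
#'   `unchanged`.
#' @export
split_differential <- function(peaks, config) {
  called <- call_differential(peaks, config)
  list(ha = called[called$call == "HA", , drop = FALSE],
       la = called[called$call == "LA", , drop = FALSE],
       unchanged = called[called$call == "unchanged", , drop = FALSE])
}
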