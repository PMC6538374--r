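#' Validated hypergeometric counts
#'
#' The `(q, m, n, k)` quadruple of an overlap test: `q` observed hits, `m`
#' marked items in the universe, `n` unmarked items, `k` items drawn.
#'
#' @param q,m,n,k Non-negative integers with `q <= min(m, k)` and
#'   `k <= m + n`.
#' @return A named list of the validated counts.
#' @export
hypergeom_counts <- function(q, m, n, k) {
  vals <- c(q = q, m = m, n = n, k = k)
  if (any(is.na(vals)) || any(vals < 0) || any(vals != floor(vals))) {
    stop("hypergeometric counts must be non-negative integers; got q=", q,
         " m=", m, " n=", n, " k=", k)
  }
  if (q > min(m, k) || k > m + n) {
    stop("invalid hypergeometric counts (need q <= min(m, k) and ",
         "k <= m + n): q=", q, " m=", m, " n=", n, " k=", k)
  }
  list(q = q, m = m, n = n, k = k)
}

#' Upper-tail hypergeometric probability
#'
#' Probability of observing at least (`inclusive`, the default enrichment
#' convention) or strictly more than (`exclusive`, the literal
#' `phyper(q, m, n, k, lower.tail = FALSE)` convention) `q` marked items in
#' a without-replacement sample of `k` items from a universe holding `m`
#' marked and `n` unmarked items. Evaluated through the distribution
#' function in log space, so extreme tails do not underflow prematurely.
#'
#' @inheritParams hypergeom_counts
#' @param tail `"inclusive"` for `P(X >= q)` or `"exclusive"` for
#'   `P(X > q)`.
#' @return The tail probability in `(0, 1]` (exactly 1 when `q = 0`
#'   inclusive).
#' @examples
#' hypergeom_upper_tail(2, 2, 2, 2) # 1/6
#' @export
hypergeom_upper_tail <- function(q, m, n, k, tail = c("inclusive", "exclusive")) {
  tail <- match.arg(tail)
  cnt <- hypergeom_counts(q, m, n, k)
  cut <- if (tail == "inclusive") cnt$q - 1 else cnt$q
  lp <- stats::phyper(cut, cnt$m, cnt$n, cnt$k, lower.tail = FALSE, log.p = TRUE)
  min(exp(lp), 1)
}

#' Clamp p-values away from zero on the -log10 scale
#'
#' Probabilities below `1e-300` saturate at `1e-300` before taking
#' `-log10`, matching how vanishingly small overlap p-values are reported.
#'
#' @param p Numeric vector of probabilities.
#' @return `-log10(pmax(p, 1e-300))`.
#' @export
neg_log10 <- function(p) -log10(pmax(p, 1e-300))
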