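#' Validate and canonicalize a genomic-interval table
#'
#' Intervals are plain data frames in BED convention: 0-based, half-open
#' `[start, end)`. Zero-length intervals are rejected, and when a
#' chromosome-sizes vector is supplied every interval must lie within its
#' chromosome.
#'
#' @param x A data.frame with at least columns `chrom`, `start`, `end`.
#'   Optional columns `strand` (`+`, `-`, `*`), `name`, `score` are kept;
#'   `strand` defaults to `*` (unstranded).
#' @param sizes Optional named vector of chromosome lengths (bp), as read by
#'   [read_chrom_sizes()].
#' @return The validated data.frame with `strand` filled in.
#' @examples
#' as_intervals(data.frame(chrom = "chr1", start = 100, end = 200))
#' @export
as_intervals <- function(x, sizes = NULL) {
  stopifnot(is.data.frame(x))
  need <- c("chrom", "start", "end")
  miss <- setdiff(need, names(x))
  if (length(miss)) {
    stop("interval table is missing column(s): ", paste(miss, collapse = ", "))
  }
  x$chrom <- as.character(x$chrom)
  x$start <- as.numeric(x$start)
  x$end <- as.numeric(x$end)
  if (any(is.na(x$start)) || any(is.na(x$end)) || any(is.na(x$chrom))) {
    stop("interval table contains missing chrom/start/end values")
  }
  if (any(x$start < 0)) stop("interval start positions must be >= 0")
  bad <- which(x$start >= x$end)
  if (length(bad)) {
    stop("zero- or negative-length interval(s) at row(s): ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  if (!"strand" %in% names(x)) {
    x$strand <- rep("*", nrow(x))
  } else {
    x$strand <- as.character(x$strand)
    x$strand[is.na(x$strand) | x$strand == "."] <- "*"
    ok <- x$strand %in% c("+", "-", "*")
    if (!all(ok)) stop("invalid strand value(s): ",
                       paste(unique(x$strand[!ok]), collapse = ", "))
  }
  if (!is.null(sizes)) check_chrom_bounds(x$chrom, x$start, x$end, sizes)
  x
}

check_chrom_bounds <- function(chrom, start, end, sizes) {
  unknown <- setdiff(unique(chrom), names(sizes))
  if (length(unknown)) {
    stop("chromosome(s) absent from sizes table: ",
         paste(unknown, collapse = ", "))
  }
  lim <- unname(sizes[chrom])
  bad <- which(end > lim | start < 0)
  if (length(bad)) {
    stop("interval(s) outside chromosome bounds at row(s): ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  invisible(TRUE)
}

#' Convert a BED-convention interval table to a GRanges object
#'
#' Shifts 0-based half-open `[start, end)` to the 1-based closed coordinates
#' GRanges uses. The inverse is [granges_to_intervals()].
#'
#' @param x Interval data.frame (see [as_intervals()]).
#' @return A [GenomicRanges::GRanges] object.
#' @export
intervals_to_granges <- function(x) {
  x <- as_intervals(x)
  strand <- x$strand
  strand[strand == "*"] <- "*"
  GenomicRanges::GRanges(
    seqnames = x$chrom,
    ranges = IRanges::IRanges(start = x$start + 1L, end = x$end),
    strand = strand
  )
}

#' @rdname intervals_to_granges
#' @param gr A GRanges object.
#' @export
granges_to_intervals <- function(gr) {
  data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    stringsAsFactors = FALSE
  )
}

#' Resolve the transcription start site of a gene body
#'
#' The TSS is the 5' base of the gene in half-open coordinates: `start` for a
#' `+` gene, `end - 1` for a `-` gene.
#'
#' @param start,end Gene body in 0-based half-open coordinates.
#' @param strand `"+"` or `"-"` (vectors recycled as usual).
#' @param gene_id Optional ids used in error messages.
#' @return Integer-valued TSS positions (bp, 0-based).
#' @examples
#' resolve_tss(1000, 5000, "+") # 1000
#' resolve_tss(1000, 5000, "-") # 4999
#' @export
resolve_tss <- function(start, end, strand, gene_id = NULL) {
  bad <- !strand %in% c("+", "-")
  if (any(bad)) {
    who <- if (is.null(gene_id)) paste("row", which(bad)[1]) else gene_id[bad][1]
    stop("unknown strand for gene ", who, " (must be '+' or '-')")
  }
  ifelse(strand == "+", start, end - 1)
}

#' TSS of gene records
#'
#' Returns the stored `tss` column of a gene table (the table stores the
#' already-resolved strand-aware TSS); errors if any record has an unknown
#' strand.
#'
#' @param genes A gene table (see [read_gene_table()]).
#' @return Numeric vector of TSS positions.
#' @export
tss_of <- function(genes) {
  bad <- !genes$strand %in% c("+", "-")
  if (any(bad)) {
    stop("unknown strand for gene ", genes$gene_id[bad][1],
         " (must be '+' or '-')")
  }
  genes$tss
}

#' Expand intervals symmetrically, clipped to chromosome bounds
#'
#' Each interval `[start, end)` becomes
#' `[max(0, start - radius), min(L, end + radius))` where `L` is the
#' chromosome length. Strand is preserved.
#'
#' @param x Interval data.frame.
#' @param radius Expansion radius in bp (>= 0).
#' @param sizes Named chromosome-length vector; every chromosome in `x` must
#'   appear.
#' @return The expanded interval data.frame.
#' @export
expand_intervals <- function(x, radius, sizes) {
  stopifnot(length(radius) == 1, radius >= 0)
  x <- as_intervals(x)
  unknown <- setdiff(unique(x$chrom), names(sizes))
  if (length(unknown)) {
    stop("chromosome(s) absent from sizes table: ",
         paste(unknown, collapse = ", "))
  }
  lim <- unname(sizes[x$chrom])
  x$start <- pmax(0, x$start - radius)
  x$end <- pmin(lim, x$end + radius)
  x
}

#' Do two intervals overlap?
#'
#' Strand-blind single-pair test: TRUE iff both intervals are on the same
#' chromosome and share at least one base. Bookended half-open intervals
#' (`[0,10)` vs `[10,20)`) do not overlap.
#'
#' @param a,b One-row interval data.frames (or rows of one).
#' @return Logical scalar.
#' @export
overlaps <- function(a, b) {
  a <- as_intervals(a); b <- as_intervals(b)
  stopifnot(nrow(a) == 1, nrow(b) == 1)
  a$chrom == b$chrom && a$start < b$end && b$start < a$end
}

#' Count overlap hits between a query set and a feature set
#'
#' `query_centric` counts queries that overlap at least one feature (each
#' query at most once); `feature_centric` counts features overlapped by at
#' least one query. Overlap requires >= 1 shared base; strand is ignored.
#'
#' @param queries,features Interval data.frames.
#' @param mode `"query_centric"` or `"feature_centric"`.
#' @return Integer count.
#' @export
count_region_hits <- function(queries, features,
                              mode = c("query_centric", "feature_centric")) {
  mode <- match.arg(mode)
  if (nrow(queries) == 0 || nrow(features) == 0) return(0L)
  queries <- as_intervals(queries)
  features <- as_intervals(features)
  lv <- union(unique(queries$chrom), unique(features$chrom))
  mk <- function(d) GenomicRanges::GRanges(
    factor(d$chrom, levels = lv),
    IRanges::IRanges(start = d$start + 1L, end = d$end))
  qg <- mk(queries)
  fg <- mk(features)
  if (mode == "query_centric") {
    sum(IRanges::overlapsAny(qg, fg, ignore.strand = TRUE))
  } else {
    sum(IRanges::overlapsAny(fg, qg, ignore.strand = TRUE))
  }
}

#' Distance from an interval to a point (TSS) position
#'
#' Zero if `start <= pos < end`; otherwise the distance to the nearer edge
#' base, `min(|pos - start|, |pos - (end - 1)|)`.
#'
#' @keywords internal
interval_point_distance <- function(start, end, pos) {
  inside <- start <= pos & pos < end
  d <- pmin(abs(pos - start), abs(pos - (end - 1)))
  d[inside] <- 0
  d
}

#' Closest gene to each peak
#'
#' For every peak, finds the gene (on the same chromosome) whose TSS is
#' nearest under [interval_point_distance()]; ties break to the
#' lexicographically smallest `gene_id` so results are deterministic.
#'
#' @param peaks Interval data.frame.
#' @param genes Gene table with `gene_id`, `chrom`, `tss`.
#' @return A data.frame with one row per peak: `gene_id`, `distance`.
#' @export
closest_genes <- function(peaks, genes) {
  peaks <- as_intervals(peaks)
  no_gene <- setdiff(unique(peaks$chrom), unique(genes$chrom))
  if (length(no_gene)) {
    stop("no gene on chromosome(s): ", paste(no_gene, collapse = ", "))
  }
  out <- data.frame(gene_id = character(nrow(peaks)),
                    distance = numeric(nrow(peaks)),
                    stringsAsFactors = FALSE)
  by_chrom <- split(seq_len(nrow(genes)), genes$chrom)
  for (i in seq_len(nrow(peaks))) {
    gi <- by_chrom[[peaks$chrom[i]]]
    d <- interval_point_distance(peaks$start[i], peaks$end[i], genes$tss[gi])
    best <- gi[d == min(d)]
    best <- best[order(genes$gene_id[best])][1]
    out$gene_id[i] <- genes$gene_id[best]
    out$distance[i] <- min(d)
  }
  out
}

#' Coalesce overlapping intervals into a sorted union
#'
#' Strictly overlapping intervals (>= 1 shared base) are merged; bookended
#' intervals stay separate unless `merge_gap` >= 1. Output is sorted by
#' `(chrom, start)` in C-locale order.
#'
#' @param x Interval data.frame.
#' @param merge_gap Merge intervals separated by a gap strictly smaller than
#'   this many bases (default 0: only true overlaps coalesce).
#' @return Interval data.frame of the union (strand dropped to `*`).
#' @export
reduce_intervals <- function(x, merge_gap = 0) {
  if (nrow(x) == 0) return(as_intervals(x[0, c("chrom", "start", "end")]))
  gr <- intervals_to_granges(x)
  red <- GenomicRanges::reduce(gr, min.gapwidth = merge_gap,
                               ignore.strand = TRUE)
  out <- granges_to_intervals(red)
  out[order(out$chrom, out$start, method = "radix"), , drop = FALSE] |>
    `rownames<-`(NULL)
}
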