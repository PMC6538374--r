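#' Chromatin-class composition of a gene list
#'
#' Counts and fractions of each promoter chromatin class (bivalent,
#' H3K4me3-only, H3K27me3-only, neither) over a gene list, e.g. all
#' considered genes vs. the upregulated set vs. the most-upregulated genes.
#' Classes absent from the list are reported with fraction 0, never
#' dropped; genes without a class are tallied as `unclassified`. Fractions
#' sum to 1.
#'
#' @param gene_ids Character vector of gene ids; every id must exist in
#'   `genes`.
#' @param genes Gene table with `gene_id` and `chromatin_class`.
#' @return Data.frame `chromatin_class`, `count`, `fraction`.
#' @export
geneset_composition <- function(gene_ids, genes) {
  unknown <- setdiff(gene_ids, genes$gene_id)
  if (length(unknown)) stop("unknown gene_id: ", unknown[1])
  cls <- genes$chromatin_class[match(gene_ids, genes$gene_id)]
  levels_ <- c("bivalent", "k4_only", "k27_only", "neither")
  if (any(is.na(cls))) {
    cls[is.na(cls)] <- "unclassified"
    levels_ <- c(levels_, "unclassified")
  }
  counts <- table(factor(cls, levels = levels_))
  data.frame(chromatin_class = levels_,
             count = as.integer(counts),
             fraction = if (length(gene_ids) == 0) 0 else
               as.numeric(counts) / length(gene_ids),
             row.names = NULL)
}

#' Chromatin-class composition of the genes closest to a peak set
#'
#' Maps every peak to its closest gene (ties broken deterministically, see
#' [closest_genes()]), deduplicates genes chosen by several peaks, and
#' returns the [geneset_composition()] of that gene set — the analysis used
#' to ask whether the nearest neighbours of differential peaks are enriched
#' in bivalent genes.
#'
#' @param peaks Interval data.frame.
#' @param genes Gene table.
#' @return Data.frame as in [geneset_composition()], with the deduplicated
#'   gene ids attached as `attr(, "gene_ids")`.
#' @export
closest_gene_composition <- function(peaks, genes) {
  hits <- closest_genes(peaks, genes)
  ids <- unique(hits$gene_id)
  out <- geneset_composition(ids, genes)
  attr(out, "gene_ids") <- ids
  out
}
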