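#' Read a two-column chromosome-sizes table
#'
#' @param path TSV with columns chromosome name, length (bp). No header.
#' @return Named numeric vector of lengths.
#' @export
read_chrom_sizes <- function(path) {
  lines <- read_nonempty_lines(path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(parts, length, 1L) < 2)
  if (length(bad)) stop(path, ":", bad[1], ": expected 2 tab-separated fields")
  nm <- vapply(parts, `[[`, "", 1L)
  len <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 2L)))
  if (any(is.na(len)) || any(len <= 0)) {
    stop(path, ":", which(is.na(len) | len <= 0)[1],
         ": chromosome length must be a positive number")
  }
  if (anyDuplicated(nm)) stop(path, ": duplicated chromosome name")
  stats::setNames(len, nm)
}

read_nonempty_lines <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines[nzchar(lines) & !startsWith(lines, "#") &
          !startsWith(lines, "track") & !startsWith(lines, "browser")]
}

parse_bed_fields <- function(path, min_fields, exact = NULL) {
  lines <- read_nonempty_lines(path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- vapply(parts, length, 1L)
  if (!is.null(exact)) {
    bad <- which(nf != exact)
    if (length(bad)) {
      stop(path, ":", bad[1], ": expected ", exact, " fields, found ",
           nf[bad[1]])
    }
  } else {
    bad <- which(nf < min_fields)
    if (length(bad)) {
      stop(path, ":", bad[1], ": expected >= ", min_fields,
           " fields, found ", nf[bad[1]])
    }
  }
  parts
}

bed_core <- function(parts, path) {
  chrom <- vapply(parts, `[[`, "", 1L)
  start <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 2L)))
  end <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 3L)))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad)) stop(path, ":", bad[1], ": non-numeric start/end")
  bad <- which(start < 0 | start >= end)
  if (length(bad)) {
    stop(path, ":", bad[1], ": invalid interval [", start[bad[1]], ", ",
         end[bad[1]], ") (must satisfy 0 <= start < end)")
  }
  data.frame(chrom = chrom, start = start, end = end, stringsAsFactors = FALSE)
}

#' Read a BED3/BED6 file into an interval table
#'
#' Coordinates stay in the file's native 0-based half-open convention.
#' Columns beyond the first six are ignored; missing name/score/strand are
#' filled with `"."`/`NA`/`"*"`.
#'
#' @param path BED file path.
#' @param sizes Optional chromosome sizes; intervals are bounds-checked.
#' @return Interval data.frame with `chrom`, `start`, `end`, `name`,
#'   `score`, `strand`.
#' @export
read_bed <- function(path, sizes = NULL) {
  parts <- parse_bed_fields(path, 3)
  df <- bed_core(parts, path)
  nf <- vapply(parts, length, 1L)
  df$name <- ifelse(nf >= 4, vapply(parts, function(p) p[min(4, length(p))], ""), ".")
  df$name[nf < 4] <- "."
  df$score <- suppressWarnings(
    as.numeric(ifelse(nf >= 5, vapply(parts, function(p) p[min(5, length(p))], ""), NA))
  )
  df$strand <- ifelse(nf >= 6, vapply(parts, function(p) p[min(6, length(p))], ""), "*")
  df$strand[!df$strand %in% c("+", "-")] <- "*"
  as_intervals(df, sizes)
}

#' Read an ENCODE narrowPeak (10-column) file
#'
#' @inheritParams read_bed
#' @return Interval data.frame with BED6 columns plus `signal_value`,
#'   `p_value`, `q_value`, `summit_offset`.
#' @export
read_narrowpeak <- function(path, sizes = NULL) {
  parts <- parse_bed_fields(path, 10, exact = 10)
  df <- bed_core(parts, path)
  df$name <- vapply(parts, `[[`, "", 4L)
  df$score <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 5L)))
  df$strand <- vapply(parts, `[[`, "", 6L)
  df$strand[!df$strand %in% c("+", "-")] <- "*"
  df$signal_value <- as.numeric(vapply(parts, `[[`, "", 7L))
  df$p_value <- as.numeric(vapply(parts, `[[`, "", 8L))
  df$q_value <- as.numeric(vapply(parts, `[[`, "", 9L))
  df$summit_offset <- as.integer(vapply(parts, `[[`, "", 10L))
  as_intervals(df, sizes)
}

#' Read a bedGraph signal track
#'
#' @inheritParams read_bed
#' @return Data.frame with `chrom`, `start`, `end`, `value` (0-based
#'   half-open intervals).
#' @export
read_bedgraph <- function(path, sizes = NULL) {
  parts <- parse_bed_fields(path, 4)
  df <- bed_core(parts, path)
  df$value <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 4L)))
  bad <- which(is.na(df$value))
  if (length(bad)) stop(path, ":", bad[1], ": non-numeric bedGraph value")
  if (!is.null(sizes)) check_chrom_bounds(df$chrom, df$start, df$end, sizes)
  df
}

#' Read a gene table
#'
#' A headered TSV with required columns `gene_id`, `chrom`, `strand`, `tss`,
#' `de_label` and optional `chromatin_class` and `coordinate_system`. When
#' `coordinate_system` is 1 the `tss` column is interpreted as 1-based and
#' shifted to the internal 0-based convention on read.
#'
#' @param path Gene table path.
#' @param sizes Optional chromosome sizes for bounds checking.
#' @return Gene data.frame (`tss` 0-based).
#' @export
read_gene_table <- function(path, sizes = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_id", "chrom", "strand", "tss", "de_label")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop(path, ": gene table missing column(s): ", paste(miss, collapse = ", "))
  }
  if (anyDuplicated(df$gene_id)) {
    stop(path, ": duplicated gene_id: ",
         df$gene_id[duplicated(df$gene_id)][1])
  }
  bad <- !df$strand %in% c("+", "-")
  if (any(bad)) {
    stop(path, ": unknown strand for gene ", df$gene_id[bad][1])
  }
  bad <- !df$de_label %in% c("up", "down", "unchanged")
  if (any(bad)) {
    stop(path, ": invalid de_label for gene ", df$gene_id[bad][1],
         " (must be up/down/unchanged)")
  }
  if ("coordinate_system" %in% names(df)) {
    cs <- unique(df$coordinate_system)
    if (length(cs) != 1 || !cs %in% c(0, 1)) {
      stop(path, ": coordinate_system must be constant 0 or 1")
    }
    if (cs == 1) df$tss <- df$tss - 1
    df$coordinate_system <- NULL
  }
  if (!"chromatin_class" %in% names(df)) {
    df$chromatin_class <- NA_character_
  } else {
    known <- c("bivalent", "k4_only", "k27_only", "neither")
    bad <- !(is.na(df$chromatin_class) | df$chromatin_class %in% known)
    if (any(bad)) {
      stop(path, ": invalid chromatin_class for gene ", df$gene_id[bad][1])
    }
  }
  if (!is.null(sizes)) {
    check_chrom_bounds(df$chrom, df$tss, df$tss + 1, sizes)
  }
  df
}

#' Write intervals as BED
#'
#' Writes BED6 when name/score/strand are present, BED3 otherwise. Scores
#' absent (`NA`) are written as 0, names as `"."`.
#'
#' @param x Interval data.frame.
#' @param path Output path.
#' @export
write_bed <- function(x, path) {
  x <- as_intervals(x)
  has6 <- any(c("name", "score") %in% names(x)) || any(x$strand != "*")
  if (has6) {
    name <- if ("name" %in% names(x)) ifelse(is.na(x$name), ".", x$name) else "."
    score <- if ("score" %in% names(x)) ifelse(is.na(x$score), 0, x$score) else 0
    strand <- ifelse(x$strand == "*", ".", x$strand)
    lines <- paste(x$chrom, format_pos(x$start), format_pos(x$end),
                   name, score, strand, sep = "\t")
  } else {
    lines <- paste(x$chrom, format_pos(x$start), format_pos(x$end), sep = "\t")
  }
  writeLines(lines, path)
  invisible(path)
}

format_pos <- function(p) formatC(p, format = "d")

#' Write a data.frame as a plain TSV
#'
#' Deterministic tab-separated output with a header and no quoting or row
#' names; the writer used for all tabular results.
#'
#' @param x Data.frame.
#' @param path Output path.
#' @export
write_table <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE)
  invisible(path)
}

#' Read a per-peak statistics table
#'
#' A headered TSV keyed by peak coordinates with columns `chrom`, `start`,
#' `end`, `depth`, `q_value`, `fold_change` and one `group_mean_<condition>`
#' column per condition.
#'
#' @inheritParams read_gene_table
#' @return Data.frame validated as intervals with the statistics columns.
#' @export
read_peak_stats <- function(path, sizes = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("chrom", "start", "end", "depth", "q_value", "fold_change")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop(path, ": stats table missing column(s): ", paste(miss, collapse = ", "))
  }
  if (!any(grepl("^group_mean_", names(df)))) {
    stop(path, ": stats table has no group_mean_<condition> columns")
  }
  as_intervals(df, sizes)
}
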