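#' Configuration for the synthetic-data generator
#'
#' Defines the study conditions the generator emulates: a reduced two-
#' chromosome genome carrying strand-aware TSS annotations, an ATAC-like
#' peak universe with log-normal widths and promoter-proximal clustering, a
#' differential peak subset with q/fold-change statistics passing the
#' standard thresholds, a planted peak-gene linkage (each differential peak
#' labels, with probability `linkage_prob`, one gene within
#' `linkage_distance` concordantly: HA peaks pair with upregulated genes,
#' LA with downregulated), background differential labels, enhancer /
#' super-enhancer / TF-site feature catalogues, per-condition negative-
#' binomial read counts with planted global scale differences, and a few
#' injected exceptionally-high-depth artifact regions.
#'
#' @param seed Integer seed; every random choice derives from it.
#' @param chrom_lengths Named chromosome lengths (bp).
#' @param n_genes Number of genes (minimum TSS spacing `min_tss_spacing`).
#' @param min_tss_spacing Minimum distance between adjacent TSS (bp).
#' @param n_peaks Number of peaks in the universe.
#' @param peak_width_meanlog,peak_width_sdlog Log-normal width model
#'   (median 400 bp, log-sd 0.5 by default).
#' @param prox_fraction Fraction of peaks clustered near a random TSS
#'   (s.d. 1 kb); the rest are uniform background.
#' @param n_diff_peaks Differential peaks, split evenly into HA and LA.
#' @param linkage_distance Planted peak-gene linkage distance D (bp).
#' @param linkage_prob Probability pi that a differential peak labels a
#'   gene within D.
#' @param background_de_rate Rate rho at which unlinked genes are labelled
#'   differential (split evenly up/down).
#' @param n_enhancers,enhancer_width Enhancer catalogue (count, width bp).
#' @param n_superenhancers,se_width_range Super-enhancers: count and width
#'   range (bp); placed over gene-bearing neighbourhoods.
#' @param n_tf_sites,tf_site_width TF binding-site catalogue.
#' @param conditions Named per-condition scale factors `s_c`; the first is
#'   the untreated reference, later conditions carry the treatment effect
#'   of differential peaks.
#' @param reads_per_bp Expected reads per peak base at scale 1 (so a
#'   median-width 400 bp peak averages ~40 reads).
#' @param nb_dispersion Negative-binomial dispersion (variance
#'   `mu + dispersion * mu^2`).
#' @param n_artifact_regions Injected high-depth artifacts.
#' @param artifact_depth_mult Depth multiplier for artifacts (100x).
#' @param bivalent_fraction Baseline bivalent fraction among genes.
#' @param bivalent_fraction_de Bivalent fraction among planted-linked
#'   differential genes (enriched over baseline).
#' @param condition_dropout Fraction of universe peaks absent from each
#'   per-condition peak call (exercises the merge step).
#' @param noiseless If TRUE, counts equal their expectations (no
#'   negative-binomial sampling); used for exact factor-recovery checks.
#' @return A validated `simulation_config` list.
#' @export
simulation_config <- function(seed = 1,
                              chrom_lengths = c(chr1 = 2e7, chr2 = 2e7),
                              n_genes = 1000,
                              min_tss_spacing = 5000,
                              n_peaks = 5000,
                              peak_width_meanlog = log(400),
                              peak_width_sdlog = 0.5,
                              prox_fraction = 0.4,
                              n_diff_peaks = 300,
                              linkage_distance = 50000,
                              linkage_prob = 0.6,
                              background_de_rate = 0.02,
                              n_enhancers = 500,
                              enhancer_width = 1000,
                              n_superenhancers = 30,
                              se_width_range = c(1e4, 5e4),
                              n_tf_sites = 2000,
                              tf_site_width = 200,
                              conditions = c(untreated = 1.0, kd_day2 = 1.3,
                                             kd_day3 = 0.7),
                              reads_per_bp = 0.1,
                              nb_dispersion = 0.2,
                              n_artifact_regions = 3,
                              artifact_depth_mult = 100,
                              bivalent_fraction = 0.18,
                              bivalent_fraction_de = 0.35,
                              condition_dropout = 0.03,
                              noiseless = FALSE) {
  cfg <- as.list(environment())
  stopifnot(length(chrom_lengths) >= 1, !is.null(names(chrom_lengths)),
            all(chrom_lengths > 0),
            n_genes >= 1, n_peaks >= 1, n_diff_peaks >= 0,
            n_diff_peaks <= n_peaks,
            linkage_prob >= 0, linkage_prob <= 1,
            background_de_rate >= 0, background_de_rate <= 1,
            prox_fraction >= 0, prox_fraction <= 1,
            linkage_distance < max(chrom_lengths),
            length(conditions) >= 2, !is.null(names(conditions)),
            all(conditions > 0), reads_per_bp > 0, nb_dispersion > 0,
            n_artifact_regions >= 0, artifact_depth_mult > 1,
            bivalent_fraction >= 0, bivalent_fraction <= 1,
            bivalent_fraction_de >= 0, bivalent_fraction_de <= 1,
            condition_dropout >= 0, condition_dropout < 1)
  structure(cfg, class = "simulation_config")
}

place_genes <- function(cfg) {
  lens <- cfg$chrom_lengths
  n_by_chrom <- round(cfg$n_genes * lens / sum(lens))
  # rounding drift goes to the largest chromosome
  n_by_chrom[which.max(lens)] <- n_by_chrom[which.max(lens)] +
    cfg$n_genes - sum(n_by_chrom)
  out <- lapply(names(lens), function(ch) {
    n <- n_by_chrom[[ch]]
    if (n == 0) return(NULL)
    span <- lens[[ch]] - (n - 1) * cfg$min_tss_spacing - 1
    if (span <= 0) {
      stop("infeasible gene placement: ", n, " genes with ",
           cfg$min_tss_spacing, " bp spacing exceed ", ch)
    }
    tss <- floor(sort(stats::runif(n, 0, span))) +
      (seq_len(n) - 1) * cfg$min_tss_spacing
    data.frame(chrom = ch, tss = tss,
               strand = sample(c("+", "-"), n, replace = TRUE),
               stringsAsFactors = FALSE)
  })
  genes <- do.call(rbind, out)
  genes$gene_id <- sprintf("gene_%04d", seq_len(nrow(genes)))
  genes$de_label <- "unchanged"
  genes[, c("gene_id", "chrom", "strand", "tss", "de_label")]
}

place_peaks <- function(cfg, genes) {
  lens <- cfg$chrom_lengths
  n <- cfg$n_peaks
  w <- pmax(50, round(stats::rlnorm(n, cfg$peak_width_meanlog,
                                    cfg$peak_width_sdlog)))
  prox <- stats::runif(n) < cfg$prox_fraction
  chrom <- character(n)
  center <- numeric(n)
  gi <- sample.int(nrow(genes), n, replace = TRUE)
  chrom[prox] <- genes$chrom[gi[prox]]
  center[prox] <- genes$tss[gi[prox]] + round(stats::rnorm(sum(prox), 0, 1000))
  chrom[!prox] <- sample(names(lens), sum(!prox), replace = TRUE,
                         prob = lens / sum(lens))
  center[!prox] <- floor(stats::runif(sum(!prox), 0, lens[chrom[!prox]]))
  start <- pmin(pmax(0, round(center - w / 2)), lens[chrom] - w)
  start <- pmax(0, start)
  peaks <- data.frame(chrom = chrom, start = start, end = start + w,
                      stringsAsFactors = FALSE)
  peaks <- peaks[order(peaks$chrom, peaks$start, method = "radix"), ]
  peaks$name <- sprintf("peak_%05d", seq_len(nrow(peaks)))
  rownames(peaks) <- NULL
  peaks
}

place_features <- function(cfg, genes) {
  lens <- cfg$chrom_lengths
  uniform_set <- function(n, width) {
    ch <- sample(names(lens), n, replace = TRUE, prob = lens / sum(lens))
    st <- floor(stats::runif(n, 0, lens[ch] - width))
    data.frame(chrom = ch, start = st, end = st + width,
               stringsAsFactors = FALSE)
  }
  enh <- uniform_set(cfg$n_enhancers, cfg$enhancer_width)
  enh$name <- sprintf("enh_%04d", seq_len(nrow(enh)))
  sew <- round(stats::runif(cfg$n_superenhancers, cfg$se_width_range[1],
                            cfg$se_width_range[2]))
  anchor <- genes[sample.int(nrow(genes), cfg$n_superenhancers), ]
  se_start <- pmax(0, pmin(anchor$tss - round(sew / 2),
                           lens[anchor$chrom] - sew))
  se <- data.frame(chrom = anchor$chrom, start = se_start,
                   end = se_start + sew,
                   name = sprintf("se_%03d", seq_len(cfg$n_superenhancers)),
                   stringsAsFactors = FALSE)
  tf <- uniform_set(cfg$n_tf_sites, cfg$tf_site_width)
  tf$name <- sprintf("tf_%04d", seq_len(nrow(tf)))
  sort_iv <- function(x) {
    x <- x[order(x$chrom, x$start, method = "radix"), ]
    rownames(x) <- NULL
    x
  }
  list(enhancers = sort_iv(enh), superenhancers = sort_iv(se),
       tf_sites = sort_iv(tf))
}

#' Generate a synthetic analysis bundle in memory
#'
#' Runs the full generator for a [simulation_config()] without touching the
#' file system. All randomness derives from `config$seed`: identical
#' configs give identical bundles.
#'
#' @param config A [simulation_config()].
#' @return A `synthetic_bundle` list: `sizes`, `genes`, `peaks` (universe
#'   intervals with per-peak statistics and a `role` truth column in
#'   `{HA, LA, background}`), `condition_peaks` (per-condition interval
#'   tables), `considered` (merged regions), `features` (enhancers,
#'   superenhancers, tf_sites), `tracks` (per-condition bedGraph tables
#'   over the merged regions), `region_counts` (merged-region x condition
#'   count matrix) and `manifest` (every planted truth).
#' @export
simulate_tables <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  cfg <- config
  with_local_seed(cfg$seed, function() {
    genes <- place_genes(cfg)
    peaks <- place_peaks(cfg, genes)
    n <- nrow(peaks)
    w <- peaks$end - peaks$start

    # differential roles and statistics passing both threshold presets
    role <- rep("background", n)
    diff_idx <- if (cfg$n_diff_peaks > 0) sample.int(n, cfg$n_diff_peaks)
                else integer(0)
    n_ha <- ceiling(cfg$n_diff_peaks / 2)
    role[diff_idx[seq_len(n_ha)]] <- "HA"
    if (cfg$n_diff_peaks > n_ha) {
      role[diff_idx[(n_ha + 1):cfg$n_diff_peaks]] <- "LA"
    }
    q_value <- stats::runif(n, 0.1, 1)
    fc_mag <- exp(stats::runif(n, 0, log(1.3)))
    fold_change <- ifelse(stats::runif(n) < 0.5, 1, -1) * fc_mag
    is_diff <- role != "background"
    q_value[is_diff] <- 10^stats::runif(sum(is_diff), -8, -3)
    mag <- exp(stats::runif(sum(is_diff), log(2.5), log(8)))
    fold_change[is_diff] <- ifelse(role[is_diff] == "HA", mag, -mag)

    # per-condition counts: mean = width * reads_per_bp * s_c, with the
    # treatment effect applied to every non-reference condition
    scales <- cfg$conditions
    counts <- matrix(0, n, length(scales),
                     dimnames = list(NULL, names(scales)))
    for (ci in seq_along(scales)) {
      mu <- w * cfg$reads_per_bp * scales[[ci]]
      if (ci > 1) {
        eff <- rep(1, n)
        eff[role == "HA"] <- abs(fold_change[role == "HA"])
        eff[role == "LA"] <- 1 / abs(fold_change[role == "LA"])
        mu <- mu * eff
      }
      counts[, ci] <- if (cfg$noiseless) mu else
        stats::rnbinom(n, mu = mu, size = 1 / cfg$nb_dispersion)
    }

    # injected exceptionally-high-depth artifacts among background peaks
    bg_idx <- which(role == "background")
    artifact_idx <- if (cfg$n_artifact_regions > 0) {
      sort(sample_int(bg_idx, min(cfg$n_artifact_regions, length(bg_idx))))
    } else integer(0)
    counts[artifact_idx, ] <- counts[artifact_idx, , drop = FALSE] *
      cfg$artifact_depth_mult
    depth <- rowSums(counts)

    # planted peak-gene linkage: HA -> up, LA -> down, within D
    planted <- list()
    gene_label <- genes$de_label
    for (i in diff_idx) {
      if (stats::runif(1) >= cfg$linkage_prob) next
      on_chrom <- which(genes$chrom == peaks$chrom[i])
      d <- interval_point_distance(peaks$start[i], peaks$end[i],
                                   genes$tss[on_chrom])
      cand <- on_chrom[d <= cfg$linkage_distance]
      free <- cand[gene_label[cand] == "unchanged"]
      if (length(free) == 0) next
      g <- sample_int(free, 1)
      gene_label[g] <- if (role[i] == "HA") "up" else "down"
      planted[[length(planted) + 1]] <- data.frame(
        peak = peaks$name[i], gene_id = genes$gene_id[g],
        de_label = gene_label[g], stringsAsFactors = FALSE)
    }
    planted_links <- if (length(planted)) do.call(rbind, planted) else
      data.frame(peak = character(), gene_id = character(),
                 de_label = character())
    # background differential labels at rate rho
    free <- which(gene_label == "unchanged")
    bg_de <- free[stats::runif(length(free)) < cfg$background_de_rate]
    gene_label[bg_de] <- sample(c("up", "down"), length(bg_de),
                                replace = TRUE)
    genes$de_label <- gene_label

    # chromatin classes, bivalency enriched among planted-linked genes
    is_planted <- genes$gene_id %in% planted_links$gene_id
    p_biv <- ifelse(is_planted, cfg$bivalent_fraction_de,
                    cfg$bivalent_fraction)
    cls <- ifelse(stats::runif(nrow(genes)) < p_biv, "bivalent",
                  sample(c("k4_only", "k27_only", "neither"), nrow(genes),
                         replace = TRUE, prob = c(0.55, 0.15, 0.30)))
    genes$chromatin_class <- cls

    features <- place_features(cfg, genes)

    # per-condition peak calls: universe minus a small dropout
    condition_peaks <- lapply(names(scales), function(cn) {
      keep <- stats::runif(n) >= cfg$condition_dropout
      peaks[keep, c("chrom", "start", "end", "name")]
    })
    names(condition_peaks) <- names(scales)

    considered <- reduce_intervals(peaks)
    # per-condition signal over merged regions: member-peak counts pooled,
    # expressed as a per-base rate so tracks are valid bedGraphs
    pk_gr <- intervals_to_granges(peaks)
    cons_gr <- intervals_to_granges(considered)
    ov <- GenomicRanges::findOverlaps(pk_gr, cons_gr, ignore.strand = TRUE)
    region_of <- S4Vectors::subjectHits(ov)[match(seq_len(n),
                                                  S4Vectors::queryHits(ov))]
    region_counts <- matrix(0, nrow(considered), length(scales),
                            dimnames = list(NULL, names(scales)))
    for (ci in seq_along(scales)) {
      agg <- tapply(counts[, ci], region_of, sum)
      region_counts[as.integer(names(agg)), ci] <- as.numeric(agg)
    }
    cons_w <- considered$end - considered$start
    tracks <- lapply(names(scales), function(cn) {
      data.frame(chrom = considered$chrom, start = considered$start,
                 end = considered$end,
                 value = region_counts[, cn] / cons_w,
                 stringsAsFactors = FALSE)
    })
    names(tracks) <- names(scales)

    stats_tab <- peaks
    for (cn in names(scales)) {
      stats_tab[[paste0("group_mean_", cn)]] <- counts[, cn]
    }
    stats_tab$depth <- depth
    stats_tab$q_value <- q_value
    stats_tab$fold_change <- fold_change
    stats_tab$role <- role

    manifest <- list(
      seed = cfg$seed,
      n_genes = nrow(genes),
      n_peaks = n,
      n_considered = nrow(considered),
      conditions = as.list(scales),
      true_scales = as.list(scales),
      n_diff_peaks = cfg$n_diff_peaks,
      diff_peaks = peaks$name[is_diff],
      ha_peaks = peaks$name[role == "HA"],
      la_peaks = peaks$name[role == "LA"],
      artifact_peaks = peaks$name[artifact_idx],
      planted_links = planted_links,
      de_counts = as.list(table(factor(genes$de_label,
                                       levels = c("up", "down", "unchanged")))),
      noiseless = cfg$noiseless
    )
    structure(list(sizes = cfg$chrom_lengths, genes = genes,
                   peaks = stats_tab, condition_peaks = condition_peaks,
                   considered = considered, features = features,
                   tracks = tracks, region_counts = region_counts,
                   manifest = manifest, config = cfg),
              class = "synthetic_bundle")
  })
}

#' Write a synthetic bundle to disk
#'
#' Generates (or takes) a bundle and writes every file the pipeline reads:
#' `chrom.sizes`, `genes.tsv`, per-condition `peaks_<cond>.bed` and
#' `signal_<cond>.bedgraph`, `peaks_all.bed`, `peak_stats.tsv`,
#' `considered_regions.bed`, the three feature BEDs, and `manifest.json`.
#' Identical configs produce byte-identical directories.
#'
#' @param config A [simulation_config()].
#' @param out_dir Output directory (created if needed).
#' @return The `synthetic_bundle`, invisibly, with a `paths` element.
#' @export
simulate <- function(config, out_dir) {
  bundle <- simulate_tables(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(out_dir, f)
  paths <- list(sizes = p("chrom.sizes"), genes = p("genes.tsv"),
                peaks_all = p("peaks_all.bed"),
                peak_stats = p("peak_stats.tsv"),
                considered = p("considered_regions.bed"),
                enhancers = p("enhancers.bed"),
                superenhancers = p("superenhancers.bed"),
                tf_sites = p("tf_sites.bed"),
                manifest = p("manifest.json"))
  writeLines(paste(names(bundle$sizes),
                   format_pos(unname(bundle$sizes)), sep = "\t"),
             paths$sizes)
  write_table(bundle$genes, paths$genes)
  write_bed(bundle$peaks[, c("chrom", "start", "end", "name")],
            paths$peaks_all)
  stats_cols <- setdiff(names(bundle$peaks), "role")
  write_table(bundle$peaks[, stats_cols], paths$peak_stats)
  write_bed(bundle$considered, paths$considered)
  for (f in names(bundle$features)) {
    write_bed(bundle$features[[f]], p(paste0(f, ".bed")))
  }
  for (cn in names(bundle$condition_peaks)) {
    fp <- p(paste0("peaks_", cn, ".bed"))
    write_bed(bundle$condition_peaks[[cn]], fp)
    paths[[paste0("peaks_", cn)]] <- fp
  }
  for (cn in names(bundle$tracks)) {
    tr <- bundle$tracks[[cn]]
    fp <- p(paste0("signal_", cn, ".bedgraph"))
    writeLines(paste(tr$chrom, format_pos(tr$start), format_pos(tr$end),
                     formatC(tr$value, format = "g", digits = 15),
                     sep = "\t"), fp)
    paths[[paste0("signal_", cn)]] <- fp
  }
  man <- bundle$manifest
  man$planted_links <- as.list(man$planted_links)
  jsonlite::write_json(man, paths$manifest, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  bundle$paths <- paths
  invisible(bundle)
}

#' Consistency checks between a bundle and its truth manifest
#'
#' Verifies that the generated tables agree with the planted truth: label
#' counts, differential-peak statistics passing both threshold presets,
#' artifacts being the depth outliers, planted links lying within the
#' linkage distance, cross-file chromosome consistency, and (for a
#' noiseless bundle without differential peaks) exact recovery of the
#' planted scale factors by [median_equalization_factors()].
#'
#' @param bundle A `synthetic_bundle` from [simulate_tables()] or
#'   [simulate()].
#' @return Named logical vector of check results (all TRUE for an
#'   untouched bundle); also printed via its class.
#' @export
truth_check <- function(bundle) {
  stopifnot(inherits(bundle, "synthetic_bundle"))
  man <- bundle$manifest
  peaks <- bundle$peaks
  genes <- bundle$genes
  checks <- c(
    chroms_in_sizes = all(c(peaks$chrom, genes$chrom,
                            bundle$considered$chrom) %in%
                            names(bundle$sizes)),
    de_counts_match = all(
      as.integer(table(factor(genes$de_label,
                              levels = c("up", "down", "unchanged")))) ==
        unlist(man$de_counts)),
    diff_count_match = length(man$diff_peaks) == man$n_diff_peaks,
    diff_in_universe = all(man$diff_peaks %in% peaks$name),
    diff_pass_thresholds = {
      d <- peaks[peaks$name %in% man$diff_peaks, ]
      nrow(d) == 0 || all(d$q_value < 0.01 & abs(d$fold_change) >= 2)
    },
    artifacts_are_depth_outliers = {
      a <- man$artifact_peaks
      length(a) == 0 ||
        min(peaks$depth[peaks$name %in% a]) >
          max(peaks$depth[!peaks$name %in% a])
    },
    links_within_distance = {
      pl <- man$planted_links
      if (NROW(pl) == 0) TRUE else all(vapply(seq_len(NROW(pl)), function(i) {
        pk <- peaks[peaks$name == pl$peak[i], ]
        g <- genes[genes$gene_id == pl$gene_id[i], ]
        pk$chrom == g$chrom &&
          interval_point_distance(pk$start, pk$end, g$tss) <=
            bundle$config$linkage_distance
      }, logical(1)))
    },
    factors_recoverable = {
      if (!isTRUE(man$noiseless) || man$n_diff_peaks > 0) NA else {
        f <- median_equalization_factors(bundle$region_counts)
        s <- unlist(man$true_scales)
        ftrue <- exp(mean(log(s))) / s
        max(abs(f / ftrue - 1)) < 1e-9
      }
    }
  )
  checks
}
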