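#' Carrier frequency per site
#'
#' Carrier frequency is the fraction of carrier individuals among all
#' non-NA individuals at the site.
#'
#' @param states Character matrix sites x individuals (`"C"`, `"N"`, `NA`).
#' @return Named numeric vector in `[0, 1]`; all-NA sites yield `NA` with
#'   a warning (they carry no information).
#' @export
#' @examples
#' m <- rbind(s1 = c("C", "N", "N", NA))
#' colnames(m) <- paste0("i", 1:4)
#' carrier_frequency(m)  # 1/3
carrier_frequency <- function(states) {
  carriers <- rowSums(states == "C", na.rm = TRUE)
  informative <- rowSums(!is.na(states))
  if (any(informative == 0L)) {
    warning(sum(informative == 0L), " site(s) with all states NA excluded")
  }
  out <- ifelse(informative > 0L, carriers / informative, NA_real_)
  names(out) <- rownames(states)
  out
}

#' Low/high-frequency classes from the diploid spectrum
#'
#' Thresholds are the empirical 10th and 90th percentiles (linear
#' interpolation between order statistics) of the diploid carrier-frequency
#' spectrum; the same thresholds are applied unchanged to tetraploid
#' frequencies. A site is `LF` when its frequency is at or below the low
#' threshold, `HF` at or above the high threshold, `mid` otherwise.
#'
#' @param diploid_freqs Carrier frequencies of sites in the diploid cohort
#'   (NA entries dropped); at least 10 values required.
#' @param probs The two percentiles (default `c(0.1, 0.9)`).
#' @return Object of class `freq_classes`: list with `lf_threshold`,
#'   `hf_threshold`.
#' @seealso [frequency_class()]
#' @export
lf_hf_classes <- function(diploid_freqs, probs = c(0.1, 0.9)) {
  f <- diploid_freqs[!is.na(diploid_freqs)]
  if (length(f) < 10L) stop("need at least 10 diploid site frequencies")
  th <- quantile(f, probs, names = FALSE, type = 7)
  if (th[1] >= th[2]) {
    stop("degenerate diploid frequency spectrum: LF threshold (", th[1],
         ") not below HF threshold (", th[2], ")")
  }
  structure(list(lf_threshold = th[1], hf_threshold = th[2]),
            class = "freq_classes")
}

#' @export
print.freq_classes <- function(x, ...) {
  cat(sprintf("freq_classes: LF <= %.4f, HF >= %.4f\n",
              x$lf_threshold, x$hf_threshold))
  invisible(x)
}

#' @rdname lf_hf_classes
#' @param freqs Frequencies to classify.
#' @param classes A `freq_classes` object.
#' @export
frequency_class <- function(freqs, classes) {
  stopifnot(inherits(classes, "freq_classes"))
  out <- rep(NA_character_, length(freqs))
  out[freqs <= classes$lf_threshold] <- "LF"
  out[freqs >= classes$hf_threshold] <- "HF"
  out[is.na(out) & !is.na(freqs)] <- "mid"
  out
}

#' Classify sites into genomic categories
#'
#' Assigns each site (by breakpoint midpoint) to exactly one category
#' using the priority order 3'UTR > 5'UTR > exon > intron >
#' upstream<250 bp > downstream<250 bp; sites overlapping no gene but
#' within 2 kb of one are near-gene, attributed strand-aware to the
#' closest gene; everything else is intergenic. Also reports the nearest
#' gene, the distance to it (0 for genic categories) and whether the site
#' lies on a chromosome arm (further than `arm_threshold` from the
#' centromere).
#'
#' @param sites Site table (`chrom`, `start`, `end`).
#' @param ann A [genome_annotation()].
#' @param near_bp,far_bp Distance tiers (defaults 250 and 2000 bp).
#' @param arm_threshold Arm distance threshold from the centromere
#'   midpoint in bp (default 5 Mb; scale it down on small synthetic
#'   genomes).
#' @return Copy of `sites` with `category`, `nearest_gene`,
#'   `gene_distance`, `arm` columns.
#' @export
classify_sites <- function(sites, ann, near_bp = 250L, far_bp = 2000L,
                           arm_threshold = 5e6) {
  stopifnot(inherits(ann, "genome_annotation"))
  bad <- setdiff(unique(sites$chrom), names(ann$seqlengths))
  if (length(bad) > 0L) {
    stop("site chromosome(s) absent from annotation: ",
         paste(bad, collapse = ", "))
  }
  sites <- copy(as.data.table(sites))
  mid <- floor((sites$start + sites$end) / 2)
  pts <- GRanges(sites$chrom, IRanges(mid, width = 1L))
  part <- category_partition(ann, near_bp = near_bp, far_bp = far_bp)
  iv <- GRanges(sites$chrom, IRanges(sites$start, sites$end))
  sites[, category := classify_intervals(iv, part)]
  if (length(ann$genes) > 0L) {
    dtn <- distanceToNearest(iv, ann$genes)
    sites[, nearest_gene := NA_character_]
    sites[, gene_distance := NA_real_]
    sites$nearest_gene[queryHits(dtn)] <-
      mcols(ann$genes)$gene_id[subjectHits(dtn)]
    sites$gene_distance[queryHits(dtn)] <- mcols(dtn)$distance
  } else {
    sites[, nearest_gene := NA_character_]
    sites[, gene_distance := NA_real_]
  }
  cen <- centromere_midpoints(ann)
  sites[, arm := abs(mid - cen[chrom]) > arm_threshold]
  sites[]
}

#' Fraction of sites on chromosome arms
#'
#' @param sites Site table (uses breakpoint midpoints), or a logical `arm`
#'   column if already classified.
#' @param centromeres Named vector of centromere midpoints (bp) per
#'   chromosome, or a [genome_annotation()].
#' @param arm_threshold Distance threshold in bp (default 5 Mb).
#' @return Proportion of sites further than `arm_threshold` from their
#'   centromere.
#' @export
arm_fraction <- function(sites, centromeres, arm_threshold = 5e6) {
  if (inherits(centromeres, "genome_annotation")) {
    centromeres <- centromere_midpoints(centromeres)
  }
  mid <- floor((sites$start + sites$end) / 2)
  mean(abs(mid - centromeres[sites$chrom]) > arm_threshold)
}

#' Feature density along chromosomes
#'
#' Counts features per non-overlapping window and adds a LOWESS-smoothed
#' curve (tricube weights, `span`, one robustness iteration) per
#' chromosome. The smooth is for plotting; downstream statistics use the
#' raw counts.
#'
#' @param sites Site table (`chrom`, `start`, `end`) or [GRanges].
#' @param seqlengths Named chromosome lengths (bp).
#' @param window Window size in bp (default 100 kb).
#' @param span LOWESS span (default 0.1).
#' @return data.table: chrom, win_start, win_end, count, smooth.
#' @export
density_profile <- function(sites, seqlengths, window = 1e5, span = 0.1) {
  if (is(sites, "GRanges")) {
    gr <- sites
  } else {
    gr <- GRanges(sites$chrom, IRanges(sites$start, sites$end))
  }
  out <- list()
  for (chrom in names(seqlengths)) {
    L <- seqlengths[[chrom]]
    starts <- seq(1, L, by = window)
    wins <- GRanges(chrom, IRanges(starts, pmin(starts + window - 1, L)))
    mids <- floor((start(gr) + end(gr)) / 2)
    sel <- as.character(seqnames(gr)) == chrom
    cnt <- countOverlaps(wins, GRanges(rep(chrom, sum(sel)),
                                       IRanges(mids[sel], width = 1L)))
    sm <- if (length(cnt) >= 3L) {
      lowess(start(wins), cnt, f = span, iter = 1)$y
    } else {
      as.numeric(cnt)
    }
    out[[chrom]] <- data.table(chrom = chrom, win_start = start(wins),
                               win_end = end(wins), count = cnt, smooth = sm)
  }
  rbindlist(out)
}

#' Genomic footprint of each category
#'
#' Computes the bp footprint of every category under the same priority
#' rules as [classify_sites()], optionally weighted by the relative
#' mappable coverage of a companion track (e.g. mean depth of a
#' high-coverage alignment in 10-kb windows), and normalizes to
#' proportions. This is the whole-genome expectation against which
#' insertion category proportions are compared.
#'
#' @param ann A [genome_annotation()].
#' @param coverage Optional [GRanges] with a numeric `score` column
#'   (coverage per window); footprints are weighted by the mean relative
#'   score over each category piece.
#' @param near_bp,far_bp Distance tiers (defaults 250 / 2000 bp).
#' @return data.table: category, bp, weighted_bp, proportion.
#' @export
reference_category_footprint <- function(ann, coverage = NULL,
                                         near_bp = 250L, far_bp = 2000L) {
  part <- category_partition(ann, near_bp = near_bp, far_bp = far_bp)
  w <- as.numeric(width(part))
  weight <- rep(1, length(part))
  if (!is.null(coverage)) {
    mean_score <- sum(as.numeric(width(coverage)) * coverage$score) /
      sum(as.numeric(width(coverage)))
    hits <- findOverlaps(part, coverage)
    ow <- width(pintersect(part[queryHits(hits)], coverage[subjectHits(hits)]))
    sc <- coverage$score[subjectHits(hits)]
    acc <- data.table(piece = queryHits(hits), w = as.numeric(ow), s = sc)
    m <- acc[, .(mw = sum(w * s) / sum(w)), by = piece]
    weight[m$piece] <- m$mw / mean_score
  }
  dt <- data.table(category = mcols(part)$category, bp = w,
                   weighted_bp = w * weight)
  out <- dt[, .(bp = sum(bp), weighted_bp = sum(weighted_bp)),
            by = category]
  # every category appears, even with zero footprint
  out <- out[data.table(category = CATEGORY_LEVELS), on = "category"]
  out[is.na(bp), c("bp", "weighted_bp") := 0]
  out[, proportion := weighted_bp / sum(weighted_bp)]
  out[]
}

#' Bootstrap comparison of distance-to-gene distributions
#'
#' Resamples (with replacement) the median (or mean) distance to the
#' nearest gene within each cohort and compares the two bootstrap
#' distributions with a two-sided t-test.
#'
#' @param dist_a,dist_b Distances (bp) of non-genic sites in the two
#'   cohorts.
#' @param n_boot Number of bootstrap resamples (minimum 100, default
#'   1000).
#' @param stat `"median"` (default) or `"mean"`.
#' @return List: `boot_a`, `boot_b` (bootstrap statistics), `delta`
#'   (mean difference b - a), `p_value`.
#' @export
gene_distance_bootstrap <- function(dist_a, dist_b, n_boot = 1000L,
                                    stat = c("median", "mean")) {
  stat <- match.arg(stat)
  if (length(dist_a) < 2L || length(dist_b) < 2L) {
    stop("each cohort needs at least 2 sites")
  }
  if (n_boot < 100L) stop("n_boot must be at least 100")
  fun <- if (stat == "median") median else mean
  boot_a <- replicate(n_boot, fun(sample(dist_a, replace = TRUE)))
  boot_b <- replicate(n_boot, fun(sample(dist_b, replace = TRUE)))
  tt <- t.test(boot_b, boot_a)
  list(boot_a = boot_a, boot_b = boot_b,
       delta = mean(boot_b) - mean(boot_a), p_value = tt$p.value)
}
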