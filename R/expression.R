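#' Carrier / non-carrier expression ratios
#'
#' For every gene whose nearest insertion falls in the requested distance
#' tier, compares mean expression between carrier populations (at least
#' one member carries the insertion) and non-carrier populations (no
#' member carries it; populations whose members are all NA for the site
#' are excluded). Genes lacking either a carrier or a non-carrier
#' population are excluded and counted.
#'
#' @param expr Numeric matrix genes x individuals (assumed normalized).
#' @param sites Classified site table with `site_id`, `nearest_gene`,
#'   `gene_distance`.
#' @param states State matrix sites x individuals.
#' @param samples Sample sheet mapping individuals to populations.
#' @param tier `"genic"` (insertion within the gene or < `near_bp`) or
#'   `"intergenic"` (nearest insertion >= `far_bp` away).
#' @param near_bp,far_bp Tier bounds in bp (defaults 250 and 2000).
#' @return Object of class `cnc_table`: data.table with gene, insertion,
#'   distance, `c_mean`, `nc_mean`, `ratio`, `log2_ratio`; attribute
#'   `"n_excluded"` counts genes without both population classes.
#' @export
cnc_ratios <- function(expr, sites, states, samples,
                       tier = c("genic", "intergenic"),
                       near_bp = 250L, far_bp = 2000L) {
  tier <- match.arg(tier)
  samples <- as.data.table(samples)
  miss <- setdiff(samples$population, samples$population[samples$id %in%
                                                           colnames(expr)])
  if (length(miss) > 0L) {
    stop("population(s) without expression columns: ",
         paste(unique(miss), collapse = ", "))
  }
  sites <- as.data.table(sites)
  # nearest insertion of each gene
  near <- sites[!is.na(nearest_gene),
                .SD[which.min(gene_distance)], by = nearest_gene]
  keep <- if (tier == "genic") near[gene_distance < near_bp]
  else near[gene_distance >= far_bp]
  keep <- keep[nearest_gene %in% rownames(expr)]
  pops <- split(samples$id, samples$population)
  n_excluded <- 0L
  rows <- list()
  for (r in seq_len(nrow(keep))) {
    g <- keep$nearest_gene[r]
    sid <- keep$site_id[r]
    if (!sid %in% rownames(states)) next
    st <- states[sid, ]
    pop_state <- vapply(pops, function(ids) {
      s <- st[intersect(ids, names(st))]
      if (any(s == "C", na.rm = TRUE)) "C"
      else if (any(s == "N", na.rm = TRUE)) "N"
      else NA_character_
    }, character(1))
    c_pops <- names(pop_state)[pop_state == "C" & !is.na(pop_state)]
    n_pops <- names(pop_state)[pop_state == "N" & !is.na(pop_state)]
    if (length(c_pops) == 0L || length(n_pops) == 0L) {
      n_excluded <- n_excluded + 1L
      next
    }
    c_mean <- mean(expr[g, intersect(unlist(pops[c_pops]), colnames(expr))])
    nc_mean <- mean(expr[g, intersect(unlist(pops[n_pops]), colnames(expr))])
    if (!is.finite(nc_mean) || nc_mean <= 0) {
      n_excluded <- n_excluded + 1L
      next
    }
    rows[[length(rows) + 1L]] <- data.table(
      gene_id = g, site_id = sid, distance = keep$gene_distance[r],
      c_mean = c_mean, nc_mean = nc_mean, ratio = c_mean / nc_mean,
      log2_ratio = log2(c_mean / nc_mean))
  }
  out <- if (length(rows)) rbindlist(rows) else
    data.table(gene_id = character(), site_id = character(),
               distance = numeric(), c_mean = numeric(),
               nc_mean = numeric(), ratio = numeric(),
               log2_ratio = numeric())
  setattr(out, "n_excluded", n_excluded)
  setattr(out, "class", c("cnc_table", class(out)))
  out
}

#' Kolmogorov-Smirnov tests of C/NC ratio distributions
#'
#' Compares the near-genic C/NC log2-ratio distribution to (a) a null of
#' ratios recomputed after randomly relabelling carrier / non-carrier
#' populations, and (b) the intergenic-tier ratio distribution, using
#' two-sample KS tests.
#'
#' @param genic A `cnc_table` for the genic/near-genic tier.
#' @param intergenic A `cnc_table` for the intergenic tier.
#' @param expr,samples As in [cnc_ratios()]; needed for the random null.
#' @param n_null Number of random relabelings pooled into the null
#'   (default 1000; 0 disables the random-null comparison).
#' @param min_records Minimum records per compared distribution.
#' @return List: `ks_random` and `ks_intergenic` (each `NULL` or a list
#'   with `statistic`, `p_value`), `null_ratios`.
#' @export
cnc_tests <- function(genic, intergenic, expr = NULL, samples = NULL,
                      n_null = 1000L, min_records = 20L) {
  if (nrow(genic) < min_records || nrow(intergenic) < min_records) {
    stop("need at least ", min_records, " C/NC records per distribution")
  }
  ks_random <- NULL
  null_ratios <- NULL
  if (n_null > 0L) {
    if (is.null(expr) || is.null(samples)) {
      stop("expr and samples are required for the random-pairing null")
    }
    samples <- as.data.table(samples)
    pops <- split(samples$id, samples$population)
    pop_names <- names(pops)
    pop_means <- vapply(pops, function(ids)
      colMeans(t(expr[genic$gene_id, intersect(ids, colnames(expr)),
                      drop = FALSE])), numeric(nrow(genic)))
    if (is.null(dim(pop_means))) {
      pop_means <- matrix(pop_means, nrow = nrow(genic))
    }
    draws <- ceiling(n_null / nrow(genic))
    acc <- numeric(0)
    for (d in seq_len(max(draws, 1L))) {
      n_c <- pmax(1L, sample(length(pop_names) - 1L, nrow(genic),
                             replace = TRUE))
      for (r in seq_len(nrow(genic))) {
        csel <- sample(length(pop_names), n_c[r])
        cm <- mean(pop_means[r, csel])
        nm <- mean(pop_means[r, -csel])
        if (is.finite(nm) && nm > 0) acc <- c(acc, log2(cm / nm))
      }
    }
    null_ratios <- acc[seq_len(min(length(acc), max(n_null, length(acc))))]
    ks <- suppressWarnings(ks.test(genic$log2_ratio, null_ratios))
    ks_random <- list(statistic = unname(ks$statistic),
                      p_value = ks$p.value)
  }
  ks2 <- suppressWarnings(ks.test(genic$log2_ratio, intergenic$log2_ratio))
  list(ks_random = ks_random,
       ks_intergenic = list(statistic = unname(ks2$statistic),
                            p_value = ks2$p.value),
       null_ratios = null_ratios)
}
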