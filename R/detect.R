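#' Extract split and discordant candidate reads from one alignment
#'
#' Pulls, from a coordinate-sorted indexed BAM, the reads that can support
#' a non-reference TE insertion: soft-clipped reads with at least
#' `min_clip` clipped bases (split candidates, anchored at the clip
#' position) and discordant pairs (mate unmapped, or both mapped but not
#' flagged proper). For mate-unmapped pairs the unmapped mate's sequence is
#' attached so it can be matched against the TE library.
#'
#' @param bam Path to a coordinate-sorted, indexed BAM file.
#' @param min_clip Minimum soft-clip length (bp) for a split candidate.
#' @return data.table with columns `qname, chrom, anchor, side`
#'   (`"up"` = clip at the read's 3' alignment end, supporting the
#'   upstream boundary; `"down"` = clip at the 5' end; `"disc"`),
#'   and `seq` (clipped portion or unmapped mate sequence).
#' @export
extract_candidates <- function(bam, min_clip = 20L) {
  check_bam(bam)
  param <- ScanBamParam(what = c("qname", "flag", "seq"),
                        flag = scanBamFlag(isUnmappedQuery = FALSE))
  aln <- readGAlignments(bam, param = param)
  if (length(aln) == 0L) {
    return(data.table(qname = character(), chrom = character(),
                      anchor = integer(), side = character(),
                      seq = character()))
  }
  cig <- cigar(aln)
  lclip <- rclip <- integer(length(cig))
  has_l <- grepl("^[0-9]+S", cig)
  lclip[has_l] <- as.integer(sub("^([0-9]+)S.*$", "\\1", cig[has_l]))
  has_r <- grepl("[^0-9][0-9]+S$", cig)
  rclip[has_r] <- as.integer(sub("^.*[^0-9]([0-9]+)S$", "\\1", cig[has_r]))
  seqs <- as.character(mcols(aln)$seq)
  qw <- nchar(seqs)
  flag <- mcols(aln)$flag
  chrom <- as.character(seqnames(aln))

  out <- list()
  up <- which(rclip >= min_clip)
  if (length(up) > 0L) {
    out$up <- data.table(qname = mcols(aln)$qname[up], chrom = chrom[up],
                         anchor = end(aln)[up], side = "up",
                         seq = substring(seqs[up], qw[up] - rclip[up] + 1L,
                                         qw[up]))
  }
  dn <- which(lclip >= min_clip)
  if (length(dn) > 0L) {
    out$down <- data.table(qname = mcols(aln)$qname[dn], chrom = chrom[dn],
                           anchor = start(aln)[dn], side = "down",
                           seq = substring(seqs[dn], 1L, lclip[dn]))
  }
  # discordant: paired reads with an unmapped mate, or mapped pairs not
  # flagged proper
  paired <- bitwAnd(flag, 1L) > 0L
  mate_unmapped <- paired & bitwAnd(flag, 8L) > 0L
  improper <- paired & bitwAnd(flag, 2L) == 0L
  disc <- which(mate_unmapped | improper)
  if (length(disc) > 0L) {
    fwd <- bitwAnd(flag[disc], 16L) == 0L
    dd <- data.table(qname = mcols(aln)$qname[disc], chrom = chrom[disc],
                     anchor = ifelse(fwd, end(aln)[disc], start(aln)[disc]),
                     side = "disc", seq = NA_character_)
    # attach unmapped mate sequences for TE assignment
    um <- scanBam(bam, param = ScanBamParam(
      what = c("qname", "seq"),
      flag = scanBamFlag(isUnmappedQuery = TRUE)))[[1]]
    if (length(um$qname) > 0L) {
      mseq <- setNames(as.character(um$seq), um$qname)
      dd[, seq := unname(mseq[qname])]
    }
    out$disc <- dd
  }
  res <- rbindlist(out)
  if (nrow(res) == 0L) {
    return(data.table(qname = character(), chrom = character(),
                      anchor = integer(), side = character(),
                      seq = character()))
  }
  setorder(res, chrom, anchor)
  res[]
}

check_bam <- function(bam) {
  if (!file.exists(bam)) stop("no such BAM file: ", bam)
  if (!file.exists(paste0(bam, ".bai")) &&
      !file.exists(sub("\\.bam$", ".bai", bam))) {
    stop("BAM is not indexed: ", bam)
  }
  hdr <- scanBamHeader(bam)[[1]]$text
  hd <- hdr[names(hdr) == "@HD"]
  sorted <- length(hd) > 0L && any(grepl("SO:coordinate", unlist(hd)))
  if (!sorted) stop("BAM is not coordinate-sorted: ", bam)
  invisible(TRUE)
}

#' Assign candidate reads to TE families
#'
#' Matches each candidate's informative sequence (the soft-clipped portion
#' or the unmapped mate) against the TE library in both orientations,
#' allowing `floor((1 - min_identity) * length)` mismatches. Candidates
#' shorter than `min_match` or without a qualifying hit are dropped;
#' equal-best hits in several families are assigned to the first family in
#' library order and flagged ambiguous.
#'
#' @param candidates data.table from [extract_candidates()].
#' @param te_library [Biostrings::DNAStringSet] of family consensus
#'   sequences (names are family labels), or a FASTA path.
#' @param min_identity Minimum identity of the match (default 0.9).
#' @param min_match Minimum matched length in bp (default 15).
#' @param max_assign_len Longest sequence stretch used for matching; longer
#'   clips are trimmed to their junction-proximal end (default 60 bp).
#' @return The candidate table restricted to assigned reads, with columns
#'   `family`, `identity`, `ambiguous` added.
#' @export
assign_te <- function(candidates, te_library, min_identity = 0.9,
                      min_match = 15L, max_assign_len = 60L) {
  if (is.character(te_library)) te_library <- readDNAStringSet(te_library)
  if (length(te_library) == 0L) stop("TE library is empty")
  cand <- copy(candidates)[!is.na(seq) & nchar(seq) >= min_match]
  if (nrow(cand) == 0L) {
    return(cbind(candidates[0], data.table(family = character(),
                                           identity = numeric(),
                                           ambiguous = logical())))
  }
  # junction-proximal trim: "up" clips start at the TE 5' end, "down"
  # clips end at the TE 3' end
  cand[, probe := ifelse(side == "down" & nchar(seq) > max_assign_len,
                         substring(seq, nchar(seq) - max_assign_len + 1L,
                                   nchar(seq)),
                         substring(seq, 1L, max_assign_len))]
  probes <- unique(cand$probe)
  fam <- character(length(probes))
  idy <- numeric(length(probes))
  amb <- logical(length(probes))
  for (k in seq_along(probes)) {
    hit <- match_library(probes[k], te_library, min_identity)
    fam[k] <- hit$family; idy[k] <- hit$identity; amb[k] <- hit$ambiguous
  }
  lut <- data.table(probe = probes, family = fam, identity = idy,
                    ambiguous = amb)
  cand <- lut[cand, on = "probe"]
  cand <- cand[!is.na(family)]
  cand[, probe := NULL]
  setcolorder(cand, c("qname", "chrom", "anchor", "side", "seq",
                      "family", "identity", "ambiguous"))
  cand[]
}

# best-family match of one probe against the library; NA family if no hit
match_library <- function(probe, te_library, min_identity) {
  pat <- DNAString(probe)
  len <- nchar(probe)
  mm_max <- floor((1 - min_identity) * len)
  for (mm in 0:mm_max) {
    n_f <- vcountPattern(pat, te_library, max.mismatch = mm)
    n_r <- vcountPattern(reverseComplement(pat), te_library,
                         max.mismatch = mm)
    hits <- which(n_f + n_r > 0L)
    if (length(hits) > 0L) {
      return(list(family = names(te_library)[hits[1]],
                  identity = 1 - mm / len,
                  ambiguous = length(hits) > 1L))
    }
  }
  list(family = NA_character_, identity = NA_real_, ambiguous = NA)
}

#' Cluster TE-assigned reads into per-individual candidate sites
#'
#' Anchors of the same family on the same chromosome are chained into one
#' site whenever consecutive anchors are at most `cluster_window` bp
#' apart. The site interval spans the split-read anchors (which bracket
#' the target-site duplication); discordant anchors only contribute
#' support counts.
#'
#' @param te_reads data.table from [assign_te()].
#' @param cluster_window Maximum anchor gap (bp) within one site.
#' @return data.table: chrom, start, end, family, split_up, split_down,
#'   discordant.
#' @export
define_sites <- function(te_reads, cluster_window = 100L) {
  if (nrow(te_reads) == 0L) {
    return(data.table(chrom = character(), start = integer(),
                      end = integer(), family = character(),
                      split_up = integer(), split_down = integer(),
                      discordant = integer()))
  }
  dt <- copy(te_reads)
  setorder(dt, chrom, family, anchor)
  dt[, cluster := cumsum(c(1L, (diff(anchor) > cluster_window) |
                             (head(chrom, -1) != tail(chrom, -1)) |
                             (head(family, -1) != tail(family, -1))))]
  sites <- dt[, {
    split_anchor <- anchor[side != "disc"]
    if (length(split_anchor) == 0L) split_anchor <- anchor
    list(chrom = chrom[1],
         start = min(split_anchor), end = max(split_anchor),
         family = family[1],
         split_up = sum(side == "up"),
         split_down = sum(side == "down"),
         discordant = sum(side == "disc"))
  }, by = cluster][, cluster := NULL]
  setorder(sites, chrom, start)
  sites[]
}

#' Intersect candidate sites across individuals
#'
#' Overlapping per-individual sites of the same family are merged into
#' unified sites. A unified site is retained only if at least one
#' individual supports it with `split_up + split_down + discordant >=
#' min_support` reads including at least one upstream and one downstream
#' junction read.
#'
#' @param site_list Named list (by individual id) of tables from
#'   [define_sites()].
#' @param min_support Minimum total supporting reads in the best
#'   individual (default 3).
#' @return List with `sites` (site_id, chrom, start, end, family,
#'   superfamily, type) and `evidence` (site_id, id, split_up, split_down,
#'   discordant).
#' @export
intersect_sites <- function(site_list, min_support = 3L) {
  all <- rbindlist(site_list, idcol = "id")
  if (nrow(all) == 0L) stop("no candidate sites in any individual")
  all[, merged := NA_integer_]
  nxt <- 0L
  for (f in unique(all$family)) {
    sel <- which(all$family == f)
    gr <- GRanges(all$chrom[sel], IRanges(all$start[sel], all$end[sel]))
    red <- reduce(gr)
    hit <- findOverlaps(gr, red, select = "first")
    all$merged[sel] <- nxt + hit
    nxt <- nxt + length(red)
  }
  ev <- all[, .(split_up = sum(split_up), split_down = sum(split_down),
                discordant = sum(discordant)),
            by = .(merged, id, family)]
  sites <- all[, .(chrom = chrom[1], start = min(start), end = max(end),
                   family = family[1]), by = merged]
  best <- ev[, .(ok = any(split_up + split_down + discordant >= min_support &
                            split_up >= 1L & split_down >= 1L)), by = merged]
  keep <- best[ok == TRUE, merged]
  sites <- sites[merged %in% keep]
  setorder(sites, chrom, start)
  sites[, site_id := sprintf("site%05d", .I)]
  ev <- ev[merged %in% keep]
  ev <- ev[sites[, .(merged, site_id)], on = "merged"]
  fam_sf <- sub("_fam[0-9]+$", "", sites$family)
  sf <- ifelse(fam_sf %in% TE_SUPERFAMILIES, fam_sf, NA_character_)
  sites[, superfamily := sf]
  sites[, type := ifelse(is.na(superfamily), NA_character_,
                         selection_type(superfamily))]
  sites[, merged := NULL]
  ev[, c("merged", "family") := NULL]
  setcolorder(sites, c("site_id", "chrom", "start", "end", "family",
                       "superfamily", "type"))
  list(sites = sites[], evidence = ev[])
}

#' Negative coverage at site boundaries
#'
#' Negative coverage of a site in an individual is the minimum aligned
#' read depth over the two boundary positions of the site interval;
#' soft-clipped bases do not count towards depth.
#'
#' @param bam Indexed BAM path.
#' @param sites Site table with `chrom`, `start`, `end`.
#' @return Integer vector of negative coverages, one per site.
#' @export
negative_coverage <- function(bam, sites) {
  check_bam(bam)
  cov <- GenomicAlignments::coverage(readGAlignments(bam))
  vapply(seq_len(nrow(sites)), function(i) {
    chrom <- sites$chrom[i]
    if (!chrom %in% names(cov)) return(0L)
    r <- cov[[chrom]]
    d1 <- as.integer(r[min(sites$start[i], length(r))])
    d2 <- as.integer(r[min(sites$end[i], length(r))])
    min(d1, d2)
  }, integer(1))
}

#' Assign per-individual carrier states and filter non-informative sites
#'
#' An individual is a carrier of a site when its own evidence meets the
#' support rule (`>= min_support` reads with at least one upstream and one
#' downstream junction read). Otherwise it is a confident non-carrier when
#' its negative coverage lies within `[min_negcov, max_negcov]` (defaults
#' 5 and 100), and `NA` (missing information) otherwise. Sites where the
#' number of NA diploids and the number of NA tetraploids both exceed
#' `na_max` are non-informative and removed (`na_rule = "or"` switches to
#' the disjunctive reading).
#'
#' @param sites Site table from [intersect_sites()].
#' @param evidence Evidence table from [intersect_sites()].
#' @param samples Sample sheet (data.table with `id`, `ploidy`).
#' @param neg_cov Numeric matrix sites x individuals of negative coverage.
#' @param min_support,min_negcov,max_negcov Thresholds (see above).
#' @param na_max Maximum tolerated NA individuals per ploidy group;
#'   default `ceiling(0.1 * group size)`, which reproduces the value 10
#'   at cohort sizes around 100 per ploidy.
#' @param na_rule `"and"` (both ploidy groups must exceed `na_max`) or
#'   `"or"`.
#' @return List: `states` (character matrix sites x individuals with
#'   `"C"`, `"N"`, `NA`), `sites` (informative sites with `carrier_freq`
#'   added), `dropped` (ids of non-informative sites).
#' @export
assign_states <- function(sites, evidence, samples, neg_cov,
                          min_support = 3L, min_negcov = 5L,
                          max_negcov = 100L, na_max = NULL,
                          na_rule = c("and", "or")) {
  na_rule <- match.arg(na_rule)
  ids <- samples$id
  if (is.null(na_max)) {
    na_max <- ceiling(0.1 * c(`2` = sum(samples$ploidy == 2L),
                              `4` = sum(samples$ploidy == 4L)))
  } else {
    na_max <- c(`2` = na_max, `4` = na_max)
  }
  if (!all(dim(neg_cov) == c(nrow(sites), length(ids)))) {
    bad <- setdiff(ids, colnames(neg_cov))
    stop("negative coverage missing for individual(s) ",
         paste(bad, collapse = ", "), " at site ", sites$site_id[1])
  }
  neg_cov <- neg_cov[, ids, drop = FALSE]
  carrier <- matrix(FALSE, nrow(sites), length(ids),
                    dimnames = list(sites$site_id, ids))
  ev <- evidence[split_up + split_down + discordant >= min_support &
                   split_up >= 1L & split_down >= 1L]
  if (nrow(ev) > 0L) {
    missing_id <- setdiff(unique(ev$id), ids)
    if (length(missing_id) > 0L) {
      stop("individual ", missing_id[1], " in evidence for site ",
           ev$site_id[match(missing_id[1], ev$id)],
           " is absent from the sample sheet")
    }
    carrier[cbind(match(ev$site_id, sites$site_id), match(ev$id, ids))] <- TRUE
  }
  states <- matrix(NA_character_, nrow(sites), length(ids),
                   dimnames = list(sites$site_id, ids))
  states[carrier] <- "C"
  confident_n <- !carrier & neg_cov >= min_negcov & neg_cov <= max_negcov
  states[confident_n] <- "N"

  is2 <- samples$ploidy == 2L
  na2 <- rowSums(is.na(states[, is2, drop = FALSE]))
  na4 <- rowSums(is.na(states[, !is2, drop = FALSE]))
  drop <- if (na_rule == "and") {
    na2 > na_max[["2"]] & na4 > na_max[["4"]]
  } else {
    na2 > na_max[["2"]] | na4 > na_max[["4"]]
  }
  dropped <- sites$site_id[drop]
  sites <- sites[!drop]
  states <- states[!drop, , drop = FALSE]
  freq <- carrier_frequency(states)
  sites[, carrier_freq := freq[site_id]]
  list(states = states, sites = sites[], dropped = dropped)
}

#' Name retained sites
#'
#' Sites whose family matches an overlapping record of a known TE
#' annotation inherit its common name; unannotated sites are named
#' `<superfamily>_new-<k>`. Names occurring more than once get `.1`,
#' `.2`, ... suffixes in coordinate order.
#'
#' @param sites Site table.
#' @param known Optional data.table of known TEs: `chrom, start, end,
#'   name, family`.
#' @return The site table with a `name` column.
#' @export
name_sites <- function(sites, known = NULL) {
  sites <- copy(sites)
  setorder(sites, chrom, start)
  nm <- rep(NA_character_, nrow(sites))
  if (!is.null(known) && nrow(known) > 0L) {
    gs <- GRanges(sites$chrom, IRanges(sites$start, sites$end))
    gk <- GRanges(known$chrom, IRanges(known$start, known$end))
    hits <- findOverlaps(gs, gk)
    ok <- sites$family[queryHits(hits)] == known$family[subjectHits(hits)]
    hits <- hits[ok]
    first <- !duplicated(queryHits(hits))
    nm[queryHits(hits)[first]] <- known$name[subjectHits(hits)[first]]
  }
  new <- which(is.na(nm))
  base <- ifelse(is.na(sites$superfamily), "TE", sites$superfamily)
  nm[new] <- paste0(base[new], "_new-", seq_along(new))
  dup <- names(which(table(nm) > 1L))
  for (d in dup) {
    at <- which(nm == d)
    nm[at] <- paste0(d, ".", seq_along(at))
  }
  sites[, name := nm]
  sites[]
}

#' Run the full detection pipeline over a cohort
#'
#' Orchestrates candidate extraction, TE-library assignment, per-individual
#' site definition, cross-individual intersection, negative-coverage
#' computation, state assignment and naming.
#'
#' @param bam_files Named character vector (names = individual ids) of
#'   indexed BAM paths, covering every individual in `samples`.
#' @param te_library DNAStringSet or FASTA path of TE family consensi.
#' @param samples Sample sheet data.table.
#' @param known Optional known TE annotation for naming (see
#'   [name_sites()]).
#' @param min_clip,min_identity,min_match,cluster_window,min_support,min_negcov,max_negcov,na_max,na_rule
#'   Detection thresholds, see the individual stage functions.
#' @return List: `sites` (named, with carrier frequencies), `states`,
#'   `evidence`, `params`.
#' @export
detect_insertions <- function(bam_files, te_library, samples, known = NULL,
                              min_clip = 20L, min_identity = 0.9,
                              min_match = 15L, cluster_window = 100L,
                              min_support = 3L, min_negcov = 5L,
                              max_negcov = 100L, na_max = NULL,
                              na_rule = "and") {
  stopifnot(all(samples$id %in% names(bam_files)))
  if (is.character(te_library)) te_library <- readDNAStringSet(te_library)
  per_ind <- lapply(samples$id, function(i) {
    cand <- extract_candidates(bam_files[[i]], min_clip = min_clip)
    te <- assign_te(cand, te_library, min_identity = min_identity,
                    min_match = min_match)
    define_sites(te, cluster_window = cluster_window)
  })
  names(per_ind) <- samples$id
  uni <- intersect_sites(per_ind, min_support = min_support)
  nc <- vapply(samples$id, function(i)
    negative_coverage(bam_files[[i]], uni$sites), numeric(nrow(uni$sites)))
  nc <- matrix(nc, nrow = nrow(uni$sites),
               dimnames = list(uni$sites$site_id, samples$id))
  st <- assign_states(uni$sites, uni$evidence, samples, nc,
                      min_support = min_support, min_negcov = min_negcov,
                      max_negcov = max_negcov, na_max = na_max,
                      na_rule = na_rule)
  sites <- name_sites(st$sites, known = known)
  params <- list(min_clip = min_clip, min_identity = min_identity,
                 min_match = min_match, cluster_window = cluster_window,
                 min_support = min_support, min_negcov = min_negcov,
                 max_negcov = max_negcov, na_max = na_max, na_rule = na_rule)
  list(sites = sites, states = st$states[sites$site_id, , drop = FALSE],
       evidence = uni$evidence, dropped = st$dropped, params = params)
}
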