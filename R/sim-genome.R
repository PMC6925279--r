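#' Simulate a reference genome with annotation
#'
#' Generates a multi-chromosome random reference sequence with gene models
#' concentrated on the chromosome arms and annotated reference TEs
#' concentrated in the pericentromeres, plus a TE consensus library for the
#' configured superfamilies. The arm/pericentromere density contrasts are
#' allocated deterministically to hit the configured ratios up to rounding.
#'
#' @param cfg A [sim_config()].
#' @return Object of class `sim_genome`: list with `config`, `reference`
#'   (a [Biostrings::DNAStringSet]), `annotation` (a
#'   [genome_annotation()]), `te_library` (DNAStringSet of family
#'   consensus sequences) and `te_families` (data.table: family,
#'   superfamily, length, tsd_len).
#' @export
#' @examples
#' g <- simulate_genome(sim_config(seed = 1, n_genes = 30,
#'                                 chrom_length = 5e5,
#'                                 pericentromere_halfwidth = 1e5))
#' g$annotation
simulate_genome <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  with_stage_seed(cfg, "genome", {
    chroms <- paste0("chr", seq_len(cfg$n_chromosomes))
    seqlens <- setNames(cfg$chrom_length, chroms)
    reference <- DNAStringSet(vapply(cfg$chrom_length, random_dna, character(1)))
    names(reference) <- chroms

    peri <- GRanges(chroms, IRanges(
      pmax(1, cfg$centromere_pos - cfg$pericentromere_halfwidth),
      pmin(cfg$chrom_length, cfg$centromere_pos + cfg$pericentromere_halfwidth)))
    seqlengths(peri) <- seqlens
    arms <- setdiff(GRanges(chroms, IRanges(1, cfg$chrom_length),
                            seqlengths = seqlens), peri)

    gene_tracks <- place_genes(cfg, arms, peri)
    tes <- place_reference_tes(cfg, arms, peri)

    cen <- GRanges(chroms, IRanges(
      round(cfg$centromere_pos - cfg$centromere_width / 2) + 1,
      round(cfg$centromere_pos + cfg$centromere_width / 2)))

    lib <- te_library(cfg)
    ann <- genome_annotation(seqlens, gene_tracks$genes, gene_tracks$exons,
                             gene_tracks$utr5, gene_tracks$utr3, tes, cen)
    structure(list(config = cfg, reference = reference, annotation = ann,
                   te_library = lib$seqs, te_families = lib$families),
              class = "sim_genome")
  })
}

random_dna <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

# deterministic count allocation between two compartments given a per-bp
# density ratio (first compartment denser by `ratio`)
split_counts <- function(n, bp_dense, bp_sparse, ratio) {
  p_dense <- (ratio * bp_dense) / (ratio * bp_dense + bp_sparse)
  n_dense <- round(n * p_dense)
  c(dense = n_dense, sparse = n - n_dense)
}

# lay n non-overlapping intervals of the given widths uniformly inside a
# set of host intervals (stick-breaking within each host); the result is
# returned in the order of `widths`
scatter_intervals <- function(hosts, widths) {
  if (length(widths) == 0L) return(GRanges(seqinfo = seqinfo(hosts)))
  host_w <- as.numeric(width(hosts))
  idx <- sample.int(length(hosts), length(widths), replace = TRUE,
                    prob = host_w)
  res_chrom <- character(length(widths))
  res_start <- numeric(length(widths))
  for (h in unique(idx)) {
    sel <- which(idx == h)
    w <- widths[sel]
    free <- host_w[h] - sum(w) - length(w)
    if (free < 1) stop("features do not fit in compartment; ",
                       "reduce counts or sizes")
    gaps <- diff(c(0, sort(runif(length(w))))) * free + 1
    starts <- round(start(hosts)[h] + cumsum(gaps) +
                      c(0, cumsum(w[-length(w)])) - 1)
    res_chrom[sel] <- as.character(seqnames(hosts))[h]
    res_start[sel] <- starts
  }
  gr <- GRanges(factor(res_chrom, levels = seqlevels(hosts)),
                IRanges(res_start, width = widths), seqinfo = seqinfo(hosts))
  gr
}

place_genes <- function(cfg, arms, peri) {
  gs <- cfg$gene_structure
  n <- cfg$n_genes
  empty <- GRanges(seqinfo = seqinfo(arms))
  if (n == 0L) {
    return(list(genes = empty, exons = empty, utr5 = empty, utr3 = empty))
  }
  # draw gene anatomies first so footprints are known
  n_ex <- sample(seq(gs$n_exons[1], gs$n_exons[2]), n, replace = TRUE)
  anatomy <- lapply(seq_len(n), function(i) {
    k <- n_ex[i]
    list(utr5 = round(runif(1, gs$utr5_len[1], gs$utr5_len[2])),
         utr3 = round(runif(1, gs$utr3_len[1], gs$utr3_len[2])),
         exons = round(runif(k, gs$exon_len[1], gs$exon_len[2])),
         introns = if (k > 1L) round(runif(k - 1L, gs$intron_len[1],
                                           gs$intron_len[2])) else integer(0))
  })
  widths <- vapply(anatomy, function(a)
    a$utr5 + a$utr3 + sum(a$exons) + sum(a$introns), numeric(1))
  alloc <- split_counts(n, sum(width(arms)), sum(width(peri)),
                        cfg$gene_arm_density_ratio)
  which_arm <- sample(c(rep(TRUE, alloc[["dense"]]),
                        rep(FALSE, alloc[["sparse"]])))
  bodies <- GRanges(factor(rep(seqlevels(arms)[1], n),
                           levels = seqlevels(arms)),
                    IRanges(rep(1L, n), width = 1L), seqinfo = seqinfo(arms))
  if (any(which_arm)) {
    bodies[which_arm] <- scatter_intervals(arms, widths[which_arm])
  }
  if (any(!which_arm)) {
    bodies[!which_arm] <- scatter_intervals(peri, widths[!which_arm])
  }
  seqlengths(bodies) <- seqlengths(arms)
  bodies <- resize(bodies, widths, fix = "start")

  strandv <- sample(c("+", "-"), n, replace = TRUE)
  o <- order(as.integer(match(as.character(seqnames(bodies)),
                              seqlevels(bodies))), start(bodies))
  bodies <- bodies[o]; anatomy <- anatomy[o]; strandv <- strandv[o]
  ids <- sprintf("g%04d", seq_len(n))
  genes <- exons <- u5 <- u3 <- vector("list", n)
  for (i in seq_len(n)) {
    a <- anatomy[[i]]
    chrom <- as.character(seqnames(bodies))[i]
    pos <- start(bodies)[i]
    k <- length(a$exons)
    mids <- as.vector(rbind(a$exons, c(a$introns, NA)))[seq_len(2 * k - 1)]
    blocks <- c(a$utr5, mids, a$utr3)
    starts <- pos + c(0, cumsum(blocks[-length(blocks)]))
    ends <- starts + blocks - 1
    lbl <- c("u_left", rep(c("exon", "intron"), length.out = 2 * k - 1),
             "u_right")
    utr5_lbl <- if (strandv[i] == "+") "u_left" else "u_right"
    utr3_lbl <- if (strandv[i] == "+") "u_right" else "u_left"
    chromf <- factor(chrom, levels = seqlevels(arms))
    mk <- function(sel) GRanges(rep(chromf, sum(sel)),
                                IRanges(starts[sel], ends[sel]),
                                strand = strandv[i], gene_id = ids[i],
                                seqinfo = seqinfo(arms))
    genes[[i]] <- GRanges(chromf, IRanges(pos, ends[length(ends)]),
                          strand = strandv[i], gene_id = ids[i],
                          seqinfo = seqinfo(arms))
    exons[[i]] <- mk(lbl == "exon")
    u5[[i]] <- mk(lbl == utr5_lbl)
    u3[[i]] <- mk(lbl == utr3_lbl)
  }
  squash <- function(x) {
    gr <- do.call(c, x)
    seqlengths(gr) <- seqlengths(arms)
    gr
  }
  list(genes = squash(genes), exons = squash(exons),
       utr5 = squash(u5), utr3 = squash(u3))
}

place_reference_tes <- function(cfg, arms, peri) {
  n <- cfg$n_ref_tes
  if (n == 0L) return(GRanges(seqinfo = seqinfo(arms)))
  widths <- round(runif(n, 200, 3000))
  alloc <- split_counts(n, sum(width(peri)), sum(width(arms)),
                        cfg$te_peri_density_ratio)
  in_peri <- sample(c(rep(TRUE, alloc[["dense"]]),
                      rep(FALSE, alloc[["sparse"]])))
  gr <- c(if (any(in_peri)) scatter_intervals(peri, widths[in_peri]),
          if (any(!in_peri)) scatter_intervals(arms, widths[!in_peri]))
  gr <- sort(gr)
  sf <- sample(names(cfg$te_superfamilies), length(gr), replace = TRUE)
  nf <- vapply(cfg$te_superfamilies, `[[`, integer(1), "n_families")
  fam <- vapply(sf, function(s)
    paste0(s, "_fam", sample.int(nf[[s]], 1L)), character(1))
  mcols(gr) <- DataFrame(name = paste0("AL", fam, "_", seq_along(gr)),
                         family = unname(fam), superfamily = sf)
  gr
}

te_library <- function(cfg) {
  fams <- list()
  for (sf in names(cfg$te_superfamilies)) {
    spec <- cfg$te_superfamilies[[sf]]
    for (k in seq_len(spec$n_families)) {
      len <- round(runif(1, spec$te_len_range[1], spec$te_len_range[2]))
      fams[[length(fams) + 1L]] <- data.table(
        family = paste0(sf, "_fam", k), superfamily = sf,
        length = len, tsd_len = spec$tsd_len)
    }
  }
  families <- rbindlist(fams)
  seqs <- DNAStringSet(vapply(families$length, random_dna, character(1)))
  names(seqs) <- families$family
  list(seqs = seqs, families = families)
}

#' Write simulated genome artifacts to disk
#'
#' Emits the reference FASTA, TE-library FASTA, annotation GFF3 (1-based,
#' inclusive) and centromere BED (0-based, half-open).
#'
#' @param genome A `sim_genome` from [simulate_genome()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, a named list of the file paths written.
#' @export
write_genome_files <- function(genome, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(reference = file.path(dir, "reference.fa"),
                te_library = file.path(dir, "te_library.fa"),
                gff3 = file.path(dir, "annotation.gff3"),
                centromeres = file.path(dir, "centromeres.bed"))
  writeXStringSet(genome$reference, paths$reference)
  writeXStringSet(genome$te_library, paths$te_library)
  write_annotation_gff3(genome$annotation, paths$gff3)
  export_bed0(genome$annotation$centromeres, paths$centromeres)
  invisible(paths)
}

write_annotation_gff3 <- function(ann, path) {
  feat <- function(gr, type, id = NULL, parent = NULL) {
    if (length(gr) == 0L) return(NULL)
    mc <- DataFrame(source = rep("polyte", length(gr)),
                    type = rep(type, length(gr)))
    if (!is.null(id)) mc$ID <- id
    if (!is.null(parent)) mc$Parent <- parent
    if (!is.null(mcols(gr)$gene_id)) mc$gene_id <- mcols(gr)$gene_id
    if (!is.null(mcols(gr)$name)) mc$Name <- mcols(gr)$name
    if (!is.null(mcols(gr)$family)) {
      mc$family <- mcols(gr)$family
      mc$superfamily <- mcols(gr)$superfamily
    }
    out <- granges(gr)
    mcols(out) <- mc
    out
  }
  g <- ann$genes
  rows <- list(
    feat(g, "gene", id = paste0("gene:", mcols(g)$gene_id)),
    feat(ann$exons, "exon",
         parent = paste0("gene:", mcols(ann$exons)$gene_id)),
    feat(ann$utr5, "five_prime_UTR",
         parent = paste0("gene:", mcols(ann$utr5)$gene_id)),
    feat(ann$utr3, "three_prime_UTR",
         parent = paste0("gene:", mcols(ann$utr3)$gene_id)),
    feat(ann$tes, "transposable_element",
         id = paste0("te:", seq_along(ann$tes))))
  rows <- rows[!vapply(rows, is.null, logical(1))]
  all <- sort(suppressWarnings(do.call(c, rows)), ignore.strand = TRUE)
  seqlengths(all) <- ann$seqlengths
  rtracklayer::export(all, path, format = "gff3")
  # prepend ##sequence-region pragmas so chromosome lengths round-trip
  lines <- readLines(path)
  pragma <- sprintf("##sequence-region %s 1 %d", names(ann$seqlengths),
                    as.integer(ann$seqlengths))
  writeLines(c(lines[1], pragma, lines[-1]), path)
  invisible(path)
}

# BED is 0-based half-open; rtracklayer handles the conversion
export_bed0 <- function(gr, path) {
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}
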