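#' Genome annotation container
#'
#' Bundles the annotation tracks the landscape analyses need: gene models
#' (with exons and UTRs), annotated reference TEs, centromere positions and
#' chromosome lengths. Coordinates are 1-based inclusive ([GRanges]
#' convention) throughout.
#'
#' @param seqlengths Named numeric vector of chromosome lengths.
#' @param genes [GRanges] of gene bodies, strand set, with metadata column
#'   `gene_id`. Gene models must not overlap one another.
#' @param exons,utr5,utr3 [GRanges] of exons and UTRs, each with `gene_id`.
#' @param tes [GRanges] of annotated reference TEs with `name`, `family`,
#'   `superfamily`.
#' @param centromeres [GRanges] of centromere intervals (one per chromosome).
#' @return Object of class `genome_annotation`.
#' @export
genome_annotation <- function(seqlengths, genes, exons, utr5, utr3,
                              tes = GRanges(), centromeres = GRanges()) {
  si <- Seqinfo(seqnames = names(seqlengths), seqlengths = unname(seqlengths))
  fix <- function(gr) {
    gr <- GRanges(gr)
    GenomeInfoDb::seqlevels(gr) <- names(seqlengths)
    GenomeInfoDb::seqinfo(gr) <- si
    gr
  }
  genes <- fix(genes)
  if (length(genes) > 1L) {
    ov <- findOverlaps(genes, drop.self = TRUE, drop.redundant = TRUE)
    if (length(ov) > 0L) stop("gene models must not overlap")
  }
  ann <- structure(list(seqlengths = seqlengths,
                        genes = genes,
                        exons = fix(exons),
                        utr5 = fix(utr5),
                        utr3 = fix(utr3),
                        tes = fix(tes),
                        centromeres = fix(centromeres)),
                   class = "genome_annotation")
  ann
}

#' @export
print.genome_annotation <- function(x, ...) {
  cat("genome_annotation:", length(x$seqlengths), "chromosome(s),",
      length(x$genes), "genes,", length(x$tes), "annotated TEs\n")
  invisible(x)
}

#' Centromere midpoints of an annotation
#' @param ann A `genome_annotation`.
#' @return Named numeric vector (bp), one per chromosome with a centromere.
#' @export
centromere_midpoints <- function(ann) {
  cen <- ann$centromeres
  setNames((start(cen) + end(cen)) / 2, as.character(seqnames(cen)))
}

#' Partition the genome into prioritized categories
#'
#' Splits every base of the genome into exactly one of the eight
#' categories `utr3, utr5, exon, intron, up250, down250, near2kb,
#' intergenic`, applying the priority order 3'UTR > 5'UTR > exon > intron
#' inside genes. Outside genes, each base is attributed to its closest
#' gene (ties go to the leftmost gene) and sub-classed by distance:
#' within `near_bp` of the gene it is upstream/downstream (strand-aware),
#' within `far_bp` it is near-gene, beyond that intergenic.
#'
#' The same partition drives the synthetic generator's insertion
#' placement, [classify_sites()] and [reference_category_footprint()], so
#' the three are consistent by construction.
#'
#' @param ann A [genome_annotation()].
#' @param near_bp,far_bp Distance tiers in bp (defaults 250 and 2000).
#' @return A disjoint [GRanges] covering the genome, with metadata column
#'   `category` and, for flank tiers, `gene_id` of the attributed gene.
#' @export
category_partition <- function(ann, near_bp = 250L, far_bp = 2000L) {
  stopifnot(inherits(ann, "genome_annotation"), near_bp < far_bp)
  si <- Seqinfo(seqnames = names(ann$seqlengths),
                seqlengths = unname(ann$seqlengths))
  whole <- GRanges(names(ann$seqlengths),
                   IRanges(1L, unname(ann$seqlengths)), seqinfo = si)

  strip <- function(gr) {
    gr <- granges(gr)
    strand(gr) <- "*"
    gr
  }
  g3 <- reduce(strip(ann$utr3))
  g5 <- setdiff(reduce(strip(ann$utr5)), g3)
  used <- union(g3, g5)
  ex <- setdiff(reduce(strip(ann$exons)), used)
  used <- union(used, ex)
  gene_t <- reduce(strip(ann$genes))
  intr <- setdiff(gene_t, used)

  pieces <- list()
  add <- function(gr, category, gene_id = NA_character_) {
    if (length(gr) == 0L) return(invisible(NULL))
    mcols(gr)$category <- category
    mcols(gr)$gene_id <- gene_id
    pieces[[length(pieces) + 1L]] <<- gr
  }
  add(g3, "utr3"); add(g5, "utr5"); add(ex, "exon"); add(intr, "intron")

  clip <- function(a, b) if (a > b) NULL else c(a, b)
  for (chrom in names(ann$seqlengths)) {
    L <- ann$seqlengths[[chrom]]
    g <- ann$genes[seqnames(ann$genes) == chrom]
    if (length(g) == 0L) {
      add(GRanges(chrom, IRanges(1L, L), seqinfo = si), "intergenic")
      next
    }
    g <- g[order(start(g))]
    s <- start(g); e <- end(g); str <- as.character(strand(g))
    ids <- as.character(mcols(g)$gene_id)
    n <- length(g)
    # flank segments: (interval, owning gene, side of the gene)
    segs <- list()
    if (s[1] > 1L) segs[[length(segs) + 1L]] <-
      list(a = 1L, b = s[1] - 1L, i = 1L, side = "left")
    if (n > 1L) for (k in seq_len(n - 1L)) {
      a <- e[k] + 1L; b <- s[k + 1L] - 1L
      if (a > b) next
      mid <- floor((e[k] + s[k + 1L]) / 2)  # x <= mid is closer to gene k
      if (mid >= a) segs[[length(segs) + 1L]] <-
        list(a = a, b = min(b, mid), i = k, side = "right")
      if (mid + 1L <= b) segs[[length(segs) + 1L]] <-
        list(a = max(a, mid + 1L), b = b, i = k + 1L, side = "left")
    }
    if (e[n] < L) segs[[length(segs) + 1L]] <-
      list(a = e[n] + 1L, b = L, i = n, side = "right")

    for (sg in segs) {
      gi <- sg$i
      side_cat <- if (sg$side == "right") {
        if (str[gi] == "-") "up250" else "down250"
      } else {
        if (str[gi] == "-") "down250" else "up250"
      }
      if (sg$side == "right") {
        edge <- e[gi]
        near <- clip(sg$a, min(sg$b, edge + near_bp))
        far <- clip(max(sg$a, edge + near_bp + 1L), min(sg$b, edge + far_bp))
        out <- clip(max(sg$a, edge + far_bp + 1L), sg$b)
      } else {
        edge <- s[gi]
        near <- clip(max(sg$a, edge - near_bp), sg$b)
        far <- clip(max(sg$a, edge - far_bp), min(sg$b, edge - near_bp - 1L))
        out <- clip(sg$a, min(sg$b, edge - far_bp - 1L))
      }
      if (!is.null(near)) add(GRanges(chrom, IRanges(near[1], near[2]),
                                      seqinfo = si), side_cat, ids[gi])
      if (!is.null(far)) add(GRanges(chrom, IRanges(far[1], far[2]),
                                     seqinfo = si), "near2kb", ids[gi])
      if (!is.null(out)) add(GRanges(chrom, IRanges(out[1], out[2]),
                                     seqinfo = si), "intergenic")
    }
  }
  part <- sort(do.call(c, pieces))
  stopifnot(sum(width(part)) == sum(ann$seqlengths))
  part
}

# category of 1-bp points from a precomputed partition
partition_lookup <- function(points, partition) {
  hit <- findOverlaps(points, partition, select = "first")
  if (anyNA(hit)) stop("site on a chromosome absent from the annotation")
  as.character(mcols(partition)$category[hit])
}

# highest-priority category overlapped by each interval; intervals wider
# than one base resolve ambiguous overlaps by the priority order
classify_intervals <- function(gr, partition) {
  hit <- findOverlaps(gr, partition)
  if (length(hit) == 0L || !all(seq_along(gr) %in% queryHits(hit))) {
    stop("site on a chromosome absent from the annotation")
  }
  prio <- match(as.character(mcols(partition)$category[subjectHits(hit)]),
                CATEGORY_LEVELS)
  dt <- data.table(q = queryHits(hit), prio = prio)
  best <- dt[, .(prio = min(prio)), by = q]
  CATEGORY_LEVELS[best$prio[match(seq_along(gr), best$q)]]
}

#' Read annotation from GFF3 and centromere BED
#'
#' Parses a GFF3 file (features `gene`, `exon`, `five_prime_UTR`,
#' `three_prime_UTR`, `transposable_element`) and a BED file of centromere
#' intervals into a [genome_annotation()].
#'
#' @param gff3 Path to a GFF3 file (1-based inclusive coordinates).
#' @param centromere_bed Path to a BED file of centromeres (0-based,
#'   half-open), or `NULL`.
#' @param seqlengths Named vector of chromosome lengths; if `NULL`, taken
#'   from the GFF3 `##sequence-region` pragmas.
#' @return A `genome_annotation`.
#' @export
read_annotation <- function(gff3, centromere_bed = NULL, seqlengths = NULL) {
  gr <- rtracklayer::import(gff3, format = "gff3")
  if (is.null(seqlengths)) {
    # chromosome lengths come from the ##sequence-region pragmas
    hdr <- grep("^##sequence-region", readLines(gff3, n = 500L),
                value = TRUE)
    if (length(hdr) == 0L) stop("GFF3 lacks ##sequence-region pragmas; ",
                                "supply seqlengths explicitly")
    parts <- strsplit(trimws(hdr), "[[:space:]]+")
    seqlengths <- setNames(
      vapply(parts, function(p) as.numeric(p[4]), numeric(1)),
      vapply(parts, `[`, character(1), 2))
  }
  pick <- function(type) {
    out <- gr[gr$type == type]
    gid <- if ("gene_id" %in% names(mcols(out))) out$gene_id else out$Parent
    if (is(gid, "List")) gid <- vapply(gid, function(p)
      if (length(p)) sub("^mRNA:", "", p[[1]]) else NA_character_, character(1))
    mcols(out) <- DataFrame(gene_id = sub("^gene:", "", as.character(gid)))
    out
  }
  genes <- gr[gr$type == "gene"]
  mcols(genes) <- DataFrame(gene_id = sub("^gene:", "", genes$ID))
  tes <- gr[gr$type == "transposable_element"]
  if (length(tes) > 0L) {
    mcols(tes) <- DataFrame(name = tes$Name, family = tes$family,
                            superfamily = tes$superfamily)
  }
  cen <- GRanges()
  if (!is.null(centromere_bed)) cen <- rtracklayer::import(centromere_bed,
                                                           format = "bed")
  genome_annotation(seqlengths, genes, pick("exon"), pick("five_prime_UTR"),
                    pick("three_prime_UTR"), tes, cen)
}
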