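#' Two-reference description of a known insertion allele
#'
#' Holds the local reference sequence of a locus in its two versions —
#' with and without a TE insertion — plus the insertion interval on the
#' WITH sequence and the target-site-duplication (TSD) length. Validates
#' that removing the insertion (and collapsing the duplicated TSD copy)
#' from the WITH sequence reproduces the WITHOUT sequence.
#'
#' @param with_seq,without_seq Character or [Biostrings::DNAString] of the
#'   two allele references.
#' @param insertion_start,insertion_end 1-based interval of the inserted
#'   TE on `with_seq`.
#' @param tsd_len TSD length in bp (e.g. 5 for Copia insertions).
#' @return Object of class `allele_refs`.
#' @export
allele_refs <- function(with_seq, without_seq, insertion_start,
                        insertion_end, tsd_len) {
  with_seq <- as.character(with_seq)
  without_seq <- as.character(without_seq)
  i1 <- as.integer(insertion_start); i2 <- as.integer(insertion_end)
  if (i1 < 1L || i2 <= i1 || i2 > nchar(with_seq)) {
    stop("insertion interval outside the WITH reference")
  }
  # prefixes are identical up to the end of the TSD copy; the WITHOUT
  # suffix restarts at the single TSD copy
  t_end <- i1 - 1L
  t_start <- t_end - tsd_len + 1L
  if (t_start < 1L) stop("tsd_len larger than the upstream flank")
  pre_ok <- substr(with_seq, 1L, i1 - 1L) ==
    substr(without_seq, 1L, i1 - 1L)
  suf_ok <- substr(with_seq, i2 + 1L, nchar(with_seq)) ==
    substr(without_seq, t_start, nchar(without_seq))
  if (!pre_ok || !suf_ok) {
    stop("allele references are inconsistent: WITH minus the insertion ",
         "does not equal WITHOUT up to the TSD duplication")
  }
  structure(list(with_seq = with_seq, without_seq = without_seq,
                 insertion_start = i1, insertion_end = i2,
                 tsd_start = t_start, tsd_end = t_end,
                 tsd_len = as.integer(tsd_len)),
            class = "allele_refs")
}

#' Targeted presence/absence call at a known insertion locus
#'
#' Calls an individual carrier when at least one read aligns contiguously
#' across an insertion extremity with at least `min_flank` bases on each
#' side of the junction; non-carrier when no read bridges an extremity
#' and at least `min_tsd_reads` reads bridge the TSD (span it entirely
#' with at least one base on each side) on the insertion-free reference;
#' NA otherwise. Reads are matched to both references in both
#' orientations; only full-length contiguous matches count.
#'
#' @param reads Character vector, [Biostrings::DNAStringSet], or FASTA /
#'   FASTQ path of the individual's reads over the locus.
#' @param refs An [allele_refs()].
#' @param min_flank Minimum aligned bases on each side of a junction
#'   (default 20).
#' @param min_tsd_reads Minimum TSD-bridging reads for a confident
#'   non-carrier (default 4).
#' @param max_mismatch_rate Per-base mismatch allowance when matching
#'   reads (default 0).
#' @return List: `call` (`"carrier"`, `"non-carrier"`, `"NA"`),
#'   `bridge_count` (junction-bridging reads, both extremities pooled),
#'   `tsd_count`.
#' @export
call_locus <- function(reads, refs, min_flank = 20L, min_tsd_reads = 4L,
                       max_mismatch_rate = 0) {
  stopifnot(inherits(refs, "allele_refs"))
  if (is.character(reads) && length(reads) == 1L && file.exists(reads)) {
    fmt <- if (grepl("\\.f(ast)?q(\\.gz)?$", reads)) "fastq" else "fasta"
    reads <- readDNAStringSet(reads, format = fmt)
  }
  reads <- as.character(reads)
  with_ref <- DNAString(refs$with_seq)
  without_ref <- DNAString(refs$without_seq)
  i1 <- refs$insertion_start; i2 <- refs$insertion_end
  # junction windows a contiguous alignment must cover to bridge
  j5 <- c(i1 - min_flank, i1 + min_flank - 1L)
  j3 <- c(i2 - min_flank + 1L, i2 + min_flank)
  tsd_win <- c(refs$tsd_start - 1L, refs$tsd_end + 1L)

  ref_chr <- list(as.character(with_ref), as.character(without_ref))
  spans <- function(read, ref_idx, win) {
    mm <- floor(max_mismatch_rate * nchar(read))
    rc <- as.character(reverseComplement(DNAString(read)))
    for (pat in c(read, rc)) {
      if (mm == 0L) {
        # exact matching: plain substring search is much faster
        hits <- gregexpr(pat, ref_chr[[ref_idx]], fixed = TRUE)[[1]]
        if (hits[1] != -1L &&
            any(hits <= win[1] & hits + nchar(pat) - 1L >= win[2])) {
          return(TRUE)
        }
      } else {
        ref <- if (ref_idx == 1L) with_ref else without_ref
        m <- matchPattern(DNAString(pat), ref, max.mismatch = mm)
        if (length(m) > 0L &&
            any(start(m) <= win[1] & end(m) >= win[2])) return(TRUE)
      }
    }
    FALSE
  }
  bridge <- vapply(reads, function(r)
    spans(r, 1L, j5) || spans(r, 1L, j3), logical(1), USE.NAMES = FALSE)
  tsd <- vapply(reads, function(r)
    spans(r, 2L, tsd_win), logical(1), USE.NAMES = FALSE)
  bridge_count <- sum(bridge)
  tsd_count <- sum(tsd)
  call <- if (bridge_count >= 1L) "carrier"
  else if (tsd_count >= min_tsd_reads) "non-carrier"
  else "NA"
  list(call = call, bridge_count = bridge_count, tsd_count = tsd_count)
}

#' Simulate single-end reads over a two-allele locus
#'
#' Draws error-free reads uniformly from the WITH and/or WITHOUT
#' haplotype, at the given total coverage, to exercise [call_locus()].
#'
#' @param refs An [allele_refs()].
#' @param genotype `"hom_with"`, `"hom_without"` or `"het"` (reads split
#'   evenly between haplotypes).
#' @param coverage Total coverage (X).
#' @param read_length Read length (bp), default 100.
#' @return [Biostrings::DNAStringSet] of reads.
#' @export
simulate_locus_reads <- function(refs, genotype = c("hom_with",
                                                    "hom_without", "het"),
                                 coverage = 10, read_length = 100L) {
  genotype <- match.arg(genotype)
  haps <- switch(genotype,
                 hom_with = c(refs$with_seq),
                 hom_without = c(refs$without_seq),
                 het = c(refs$with_seq, refs$without_seq))
  cov_each <- coverage / length(haps)
  out <- character(0)
  for (h in haps) {
    L <- nchar(h)
    n <- rpois(1, cov_each * L / read_length)
    if (n == 0L) next
    s <- floor(runif(n) * (L - read_length + 1)) + 1L
    rd <- substring(h, s, s + read_length - 1L)
    # half the reads on the reverse strand
    rev <- runif(n) < 0.5
    rd[rev] <- as.character(reverseComplement(DNAStringSet(rd[rev])))
    out <- c(out, rd)
  }
  DNAStringSet(out)
}
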