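#' Simulate per-individual paired-end alignments
#'
#' Writes one coordinate-sorted SAM file per individual. For every planted
#' insertion and every haplotype of every individual, paired-end fragments
#' are drawn at the individual's per-haplotype coverage within
#' `read_window` bp of the breakpoint. Haplotypes carrying the insertion
#' yield junction reads soft-clipped at the breakpoint (clipped bases taken
#' from the TE consensus), discordant pairs whose TE-internal mate is
#' written as an unmapped record at its anchor's position, and a duplicated
#' target-site sequence (TSD); non-carrier haplotypes yield uninterrupted
#' coverage across the site. Optional uniform substitution errors and
#' genome-wide background pairs are controlled by the configuration.
#'
#' @param truth A `sim_truth` from [simulate_population()].
#' @param genome The `sim_genome` the truth was planted on.
#' @param dir Directory for the SAM files (created if missing).
#' @param cfg Optional [sim_config()]; defaults to `truth$config`.
#' @return Object of class `sim_reads`: list with `sam` (named vector of
#'   SAM paths), `evidence` (data.table ins_id x id with the emitted
#'   junction/discordant read counts: `n_up`, `n_down` are soft-clipped
#'   reads with at least 20 clipped bases at the upstream/downstream
#'   boundary, `n_disc` discordant pairs) and `dosage_haplotypes`.
#' @export
simulate_reads <- function(truth, genome, dir, cfg = truth$config) {
  stopifnot(inherits(truth, "sim_truth"), inherits(genome, "sim_genome"))
  if (cfg$read_length > cfg$insert_mean - 2 * cfg$insert_sd) {
    stop("read length exceeds usable fragment length")
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  with_stage_seed(cfg, "reads", {
    ins <- truth$insertions
    samples <- truth$samples
    rl <- cfg$read_length
    w <- cfg$read_window
    lib <- as.character(genome$te_library)
    ref <- as.character(genome$reference)

    # per-site segment templates, shared across individuals
    site_tpl <- lapply(seq_len(nrow(ins)), function(i) {
      chrom <- ins$chrom[i]; pos <- ins$pos[i]
      tsd <- ins$tsd_len[i]; te <- lib[[ins$family[i]]]
      left <- substr(ref[[chrom]], pos - w + 1, pos)
      plain <- substr(ref[[chrom]], pos - w + 1, pos + w)
      right <- substr(ref[[chrom]], pos - tsd + 1, pos + w)
      list(chrom = chrom, pos = pos, tsd = tsd, te_len = nchar(te),
           seg_c = paste0(left, te, right), seg_n = plain,
           win_start = pos - w + 1)
    })

    sam_paths <- setNames(file.path(dir, paste0(samples$id, ".sam")),
                          samples$id)
    ev <- list()
    hap_assign <- list()
    for (j in seq_len(nrow(samples))) {
      indiv <- samples$id[j]
      pl <- samples$ploidy[j]
      hapcov <- samples$coverage[j] / pl
      recs <- vector("list", nrow(ins) * pl + 1L)
      evj <- matrix(0L, nrow(ins), 3L,
                    dimnames = list(ins$ins_id, c("n_up", "n_down", "n_disc")))
      haps <- lapply(seq_len(nrow(ins)), function(i) {
        d <- truth$dosage[i, j]
        if (d > 0L) sample.int(pl, d) else integer(0)
      })
      hap_assign[[indiv]] <- haps
      k <- 0L
      for (i in seq_len(nrow(ins))) {
        tpl <- site_tpl[[i]]
        for (h in seq_len(pl)) {
          carrier <- h %in% haps[[i]]
          out <- sim_window_pairs(tpl, carrier, hapcov, cfg,
                                  sprintf("%s_%s_h%d", indiv, ins$ins_id[i], h))
          if (is.null(out)) next
          k <- k + 1L
          recs[[k]] <- out$recs
          evj[i, ] <- evj[i, ] + out$counts
        }
      }
      if (cfg$background_coverage > 0) {
        k <- k + 1L
        recs[[k]] <- sim_background_pairs(ref, cfg, indiv)
      }
      all <- rbindlist(recs[seq_len(k)])
      write_sam(all, sam_paths[[indiv]], genome$annotation$seqlengths)
      evd <- as.data.table(evj, keep.rownames = "ins_id")
      evd[, id := indiv]
      ev[[indiv]] <- evd
    }
    structure(list(sam = sam_paths, evidence = rbindlist(ev),
                   dosage_haplotypes = hap_assign, dir = dir),
              class = "sim_reads")
  })
}

# simulate the read pairs of one haplotype across one site window and map
# them back to reference coordinates as SAM-ready records
sim_window_pairs <- function(tpl, carrier, hapcov, cfg, name_stem) {
  rl <- cfg$read_length
  seg <- if (carrier) tpl$seg_c else tpl$seg_n
  seg_len <- nchar(seg)
  n_frag <- rpois(1, hapcov * seg_len / (2 * rl))
  if (n_frag == 0L) return(NULL)
  fl <- pmin(pmax(round(rnorm(n_frag, cfg$insert_mean, cfg$insert_sd)),
                  2L * rl + 2L), seg_len)
  s <- floor(runif(n_frag) * (seg_len - fl + 1)) + 1L
  # mate intervals on the segment (1-based)
  a1 <- s; b1 <- s + rl - 1L
  a2 <- s + fl - rl; b2 <- s + fl - 1L
  seq1 <- substring(seg, a1, b1)
  seq2 <- substring(seg, a2, b2)
  if (cfg$error_rate > 0) {
    seq1 <- mutate_seq(seq1, cfg$error_rate)
    seq2 <- mutate_seq(seq2, cfg$error_rate)
  }
  m1 <- map_segment_read(a1, b1, tpl, carrier)
  m2 <- map_segment_read(a2, b2, tpl, carrier)
  keep <- !(m1$unmapped & m2$unmapped)  # pairs fully inside the TE vanish
  if (!any(keep)) return(NULL)
  qname <- sprintf("%s_f%05d", name_stem, seq_len(n_frag))
  counts <- c(n_up = sum(m1$side[keep] == "up" & m1$clip[keep] >= 20) +
                sum(m2$side[keep] == "up" & m2$clip[keep] >= 20),
              n_down = sum(m1$side[keep] == "down" & m1$clip[keep] >= 20) +
                sum(m2$side[keep] == "down" & m2$clip[keep] >= 20),
              n_disc = sum(xor(m1$unmapped[keep], m2$unmapped[keep])))
  recs <- pair_records(qname[keep], tpl$chrom,
                       m1[keep, ], m2[keep, ],
                       seq1[keep], seq2[keep])
  list(recs = recs, counts = counts)
}

# map reads at local interval [a, b] of a site segment to reference
# coordinates; returns POS, CIGAR, clip side and length, unmapped flag
map_segment_read <- function(a, b, tpl, carrier) {
  n <- length(a)
  rl <- b - a + 1L
  pos <- integer(n); cig <- character(n)
  side <- rep(NA_character_, n); clip <- integer(n)
  unmapped <- rep(FALSE, n)
  if (!carrier) {
    pos <- tpl$win_start + a - 1L
    cig <- paste0(rl, "M")
    return(data.table(pos = pos, cigar = cig, side = side, clip = clip,
                      unmapped = unmapped))
  }
  w <- tpl$pos - tpl$win_start + 1L          # bases of upstream flank
  te_end <- w + tpl$te_len                   # segment coord of last TE base
  for (k in seq_len(n)) {
    if (b[k] <= w) {                         # fully upstream flank
      pos[k] <- tpl$win_start + a[k] - 1L
      cig[k] <- paste0(rl[k], "M")
    } else if (a[k] > te_end) {              # fully downstream flank
      pos[k] <- tpl$pos - tpl$tsd + (a[k] - te_end)
      cig[k] <- paste0(rl[k], "M")
    } else if (a[k] <= w && b[k] <= te_end) {  # crosses upstream junction
      m <- w - a[k] + 1L
      pos[k] <- tpl$win_start + a[k] - 1L
      cig[k] <- paste0(m, "M", rl[k] - m, "S")
      side[k] <- "up"; clip[k] <- rl[k] - m
    } else if (a[k] > w && b[k] > te_end) {    # crosses downstream junction
      m <- b[k] - te_end
      pos[k] <- tpl$pos - tpl$tsd + 1L
      cig[k] <- paste0(rl[k] - m, "S", m, "M")
      side[k] <- "down"; clip[k] <- rl[k] - m
    } else if (a[k] > w && b[k] <= te_end) {   # fully inside the TE
      unmapped[k] <- TRUE
    } else {                                   # spans the whole TE
      m <- w - a[k] + 1L
      pos[k] <- tpl$win_start + a[k] - 1L
      cig[k] <- paste0(m, "M", rl[k] - m, "S")
      side[k] <- "up"; clip[k] <- rl[k] - m
    }
  }
  data.table(pos = pos, cigar = cig, side = side, clip = clip,
             unmapped = unmapped)
}

# assemble SAM fields for read pairs given both mates' mappings
pair_records <- function(qname, chrom, m1, m2, seq1, seq2) {
  n <- length(qname)
  rec <- function(me, other, seqs, first) {
    flag <- rep(1L, n) +                     # paired
      ifelse(first, 64L, 128L) +
      ifelse(first, 0L, 16L) +               # mate 2 simulated on reverse
      ifelse(first, 32L, 0L) +
      ifelse(me$unmapped, 4L, 0L) +
      ifelse(other$unmapped, 8L, 0L) +
      ifelse(!me$unmapped & !other$unmapped, 2L, 0L)
    pos <- ifelse(me$unmapped, other$pos, me$pos)
    data.table(qname = qname, flag = flag, rname = chrom, pos = pos,
               mapq = ifelse(me$unmapped, 0L, 60L),
               cigar = ifelse(me$unmapped, "*", me$cigar),
               rnext = "=", pnext = ifelse(other$unmapped, pos, other$pos),
               tlen = 0L, seq = seqs, qual = strrep("I", nchar(seqs)))
  }
  rbind(rec(m1, m2, seq1, TRUE), rec(m2, m1, seq2, FALSE))
}

sim_background_pairs <- function(ref, cfg, indiv) {
  rl <- cfg$read_length
  recs <- list()
  for (chrom in names(ref)) {
    L <- nchar(ref[[chrom]])
    n_frag <- rpois(1, cfg$background_coverage * L / (2 * rl))
    if (n_frag == 0L) next
    fl <- pmax(round(rnorm(n_frag, cfg$insert_mean, cfg$insert_sd)),
               2L * rl + 2L)
    s <- floor(runif(n_frag) * (L - fl + 1)) + 1L
    q <- sprintf("%s_bg_%s_f%06d", indiv, chrom, seq_len(n_frag))
    mk <- function(a, first) {
      data.table(qname = q, flag = if (first) 1L + 2L + 32L + 64L
                 else 1L + 2L + 16L + 128L,
                 rname = chrom, pos = a, mapq = 60L,
                 cigar = paste0(rl, "M"), rnext = "=",
                 pnext = if (first) s + fl - rl else s,
                 tlen = 0L, seq = substring(ref[[chrom]], a, a + rl - 1L),
                 qual = strrep("I", rl))
    }
    recs[[chrom]] <- rbind(mk(s, TRUE), mk(s + fl - rl, FALSE))
  }
  rbindlist(recs)
}

mutate_seq <- function(seqs, rate) {
  vapply(seqs, function(x) {
    n <- nchar(x)
    hit <- which(runif(n) < rate)
    if (length(hit) == 0L) return(x)
    ch <- strsplit(x, "")[[1]]
    ch[hit] <- sample(DNA_BASES, length(hit), replace = TRUE)
    paste(ch, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# write a coordinate-sorted SAM file
write_sam <- function(recs, path, seqlengths) {
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           sprintf("@SQ\tSN:%s\tLN:%d", names(seqlengths),
                   as.integer(seqlengths)))
  setorder(recs, rname, pos, qname, flag)
  con <- file(path, "wb")  # binary mode: LF endings, byte-identical reruns
  writeLines(hdr, con)
  if (nrow(recs) > 0L) {
    writeLines(recs[, paste(qname, flag, rname, pos, mapq, cigar, rnext,
                            pnext, tlen, seq, qual, sep = "\t")], con)
  }
  close(con)
  invisible(path)
}
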