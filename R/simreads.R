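#' Simulate analytically aligned paired-end reads for one sample
#'
#' Draws 2 x `read_length` bp read pairs uniformly from the sample's donor
#' haplotype (the reference with that sample's insertions applied,
#' germline insertions included) and computes their alignments
#' analytically instead of running an aligner. The emulated rules are:
#'
#' * reads fully inside a reference-derived segment map uniquely
#'   (MAPQ 60, full-length match) at the donor-to-reference shifted
#'   coordinate;
#' * reads spanning an insertion junction align their largest portion:
#'   when that is a target flank they are soft-clipped exactly at the
#'   junction (the clipped tail carrying insertion sequence), producing
#'   the split reads breakpoint detection relies on;
#' * reads dominated by insertion interior map to the homologous source
#'   locus: transduced sequence to the source's downstream flank
#'   (MAPQ 60, unique), L1 sequence to the source element body (MAPQ 10,
#'   repetitive), polyA tracts to the junction with MAPQ 0; interior
#'   placements use the component midpoint and do not model per-base
#'   breakpoint precision, which only target-side clips need;
#' * mate 1 is always the donor-forward read of an FR pair; SEQ is stored
#'   in SAM convention (reverse-complemented for minus-strand
#'   alignments), and TLEN is left-minus-right signed.
#'
#' @param cfg a [simulation_config()].
#' @param sim_ref output of [simulate_reference()].
#' @param truth output of [simulate_insertions()]; germline-labelled rows
#'   are applied to every sample.
#' @param sample sample id (e.g. `"T1"`); its index in the configured
#'   sample panel seeds the per-sample RNG stream.
#' @return data.frame of alignments: `qname`, `mate`, `chrom`, `pos`
#'   (1-based leftmost), `mapq`, `strand`, `cigar`, `seq` (SAM
#'   convention), `mchrom`, `mpos`, `isize`, `proper`.
#' @export
simulate_reads <- function(cfg, sim_ref, truth, sample) {
  panel <- c(paste0("T", seq_len(cfg$n_tumor)),
             paste0("N", seq_len(cfg$n_normal)))
  sidx <- match(sample, panel)
  if (is.na(sidx)) sidx <- cfg$n_tumor + cfg$n_normal + 1L
  set.seed(cfg$seed + 100L + sidx)
  rl <- cfg$read_length
  reference <- sim_ref$reference
  sources <- sim_ref$sources
  ins_all <- truth[truth$sample == sample | truth$label == "germline", ,
                   drop = FALSE]
  out <- vector("list", length(reference))
  names(out) <- names(reference)

  for (ch in names(reference)) {
    refseq <- reference[[ch]]
    reflen <- nchar(refseq)
    ins <- ins_all[ins_all$chrom == ch, , drop = FALSE]
    ins <- ins[order(ins$pos), , drop = FALSE]
    n_ins <- nrow(ins)

    # build donor string and per-insertion donor bookkeeping
    seg_start <- integer(n_ins)
    seg_end <- integer(n_ins)
    oriented <- character(n_ins)
    chunks <- character(0)
    prev_ref <- 0L          # 0-based ref position consumed so far
    donor_len <- 0L
    if (n_ins) {
      for (j in seq_len(n_ins)) {
        bp_a <- ins$pos[j]
        bp_b <- bp_a + ins$tsd_length[j]
        oriented[j] <- if (ins$orientation[j] == "+") ins$inserted_seq[j]
          else revcomp(ins$inserted_seq[j])
        left <- substr(refseq, prev_ref + 1L, bp_b)
        chunks <- c(chunks, left, oriented[j])
        donor_len <- donor_len + nchar(left)
        seg_start[j] <- donor_len + 1L
        donor_len <- donor_len + nchar(oriented[j])
        seg_end[j] <- donor_len
        prev_ref <- bp_a
      }
      chunks <- c(chunks, substr(refseq, prev_ref + 1L, reflen))
      donor <- paste(chunks, collapse = "")
      donor_len <- nchar(donor)
    } else {
      donor <- refseq
      donor_len <- reflen
    }
    # donor -> ref shift for the reference chunk after insertion j
    shift_after <- if (n_ins) seg_end - ins$pos else integer(0)
    # shift for the chunk before insertion j (ref pos of its donor end)
    shift_before <- if (n_ins) (seg_start - 1L) - (ins$pos + ins$tsd_length)
      else integer(0)

    n_frag <- round(cfg$depth * donor_len / (2 * rl))
    flen <- pmax(2L * rl + 10L,
                 round(stats::rnorm(n_frag, cfg$insert_mean, cfg$insert_sd)))
    fstart <- floor(stats::runif(n_frag) * (donor_len - flen - 1)) + 1L
    d1a <- fstart                 # mate 1 start (donor fwd)
    d1b <- fstart + rl - 1L
    d2a <- fstart + flen - rl     # mate 2 start
    d2b <- fstart + flen - 1L

    map_plain <- function(da) {
      if (!n_ins) return(da)
      idx <- findInterval(da, seg_end + 1L)
      da - c(0L, shift_after)[idx + 1L]
    }
    overlaps_seg <- function(da, db) {
      if (!n_ins) return(rep(FALSE, length(da)))
      j <- findInterval(db, seg_start)
      j >= 1L & da <= seg_end[pmax(j, 1L)]
    }

    danger1 <- overlaps_seg(d1a, d1b)
    danger2 <- overlaps_seg(d2a, d2b)

    qname <- sprintf("%s.%s.f%d", sample, ch, seq_len(n_frag))
    seq1 <- substring(donor, d1a, d1b)
    seq2 <- substring(donor, d2a, d2b)

    res <- data.frame(
      qname = rep(qname, 2L), mate = rep(c(1L, 2L), each = n_frag),
      chrom = ch, pos = c(map_plain(d1a), map_plain(d2a)),
      mapq = 60L, strand = rep(c("+", "-"), each = n_frag),
      cigar = paste0(rl, "M"),
      seq = c(seq1, seq2),       # SAM convention == donor fwd for both
      mchrom = ch, mpos = c(map_plain(d2a), map_plain(d1a)),
      isize = c(flen, -flen), proper = TRUE,
      stringsAsFactors = FALSE
    )

    # per-read analytic alignment for reads touching an insertion
    fix_read <- function(row_i, da, db, is_mate2) {
      j <- findInterval(db, seg_start)
      gs <- seg_start[j]; ge <- seg_end[j]
      left_len <- max(0L, gs - da)
      right_len <- max(0L, db - ge)
      inside_len <- rl - left_len - right_len
      tr <- ins[j, ]
      donor_sub <- substring(donor, da, db)
      strand_flips <- as.integer(is_mate2)
      if (left_len >= right_len && left_len >= inside_len) {
        pos <- da - shift_before[j]
        cigar <- paste0(left_len, "M", rl - left_len, "S")
        mapq <- 60L
        strand <- if (is_mate2) "-" else "+"
      } else if (right_len >= inside_len) {
        pos <- tr$pos + 1L
        cigar <- paste0(rl - right_len, "S", right_len, "M")
        mapq <- 60L
        strand <- if (is_mate2) "-" else "+"
      } else {
        # interior-dominant: locate the midpoint component in element coords
        i1 <- max(da, gs) - gs   # 0-based within oriented insertion
        i2 <- min(db, ge) - gs
        ilen <- nchar(tr$inserted_seq)
        if (tr$orientation == "+") {
          e_mid <- (i1 + i2) %/% 2L
        } else {
          e_mid <- ilen - 1L - (i1 + i2) %/% 2L
          strand_flips <- strand_flips + 1L
        }
        l1 <- tr$l1_bp; ia <- tr$polya_internal_bp; td <- tr$transduction_bp
        src <- if (!is.na(tr$source_id))
          sources[sources$source_id == tr$source_id, , drop = FALSE]
          else sources[1L, , drop = FALSE]
        in_ref_src <- nrow(src) == 1L && isTRUE(src$in_reference)
        cigar <- paste0(rl, "M")
        if (left_len > 0L || right_len > 0L) {
          cigar <- paste0(
            if (left_len > 0L) paste0(left_len, "S") else "",
            inside_len, "M",
            if (right_len > 0L) paste0(right_len, "S") else "")
        }
        if (e_mid < l1) {
          # L1 body: repetitive, homologous placement in the source element
          mapq <- 10L
          if (in_ref_src) {
            off <- nchar(cfg$l1_consensus) - l1 + e_mid
            if (src$strand == "+") {
              pos <- src$start + off + 1L
            } else {
              pos <- src$end - off - inside_len
              strand_flips <- strand_flips + 1L
            }
            chpos <- src$chrom
          } else {
            pos <- tr$pos; chpos <- ch; mapq <- 0L
          }
        } else if (e_mid < l1 + ia || e_mid >= l1 + ia + td) {
          # polyA tract: effectively unplaceable
          mapq <- 0L
          pos <- tr$pos + 1L
          chpos <- ch
        } else {
          # transduced sequence: unique at the source downstream flank
          mapq <- 60L
          off <- e_mid - (l1 + ia)
          if (in_ref_src) {
            if (src$strand == "+") {
              pos <- src$end + off - inside_len %/% 2L + 1L
            } else {
              pos <- src$start - off - inside_len %/% 2L
              strand_flips <- strand_flips + 1L
            }
            chpos <- src$chrom
          } else {
            pos <- tr$pos + 1L; chpos <- ch; mapq <- 30L
          }
        }
        strand <- if (strand_flips %% 2L) "-" else "+"
        as_seq <- if (is_mate2) revcomp(donor_sub) else donor_sub
        res$seq[row_i] <<- if (strand == "-") revcomp(as_seq) else as_seq
        res$chrom[row_i] <<- chpos
        res$pos[row_i] <<- max(1L, pos)
        res$mapq[row_i] <<- mapq
        res$strand[row_i] <<- strand
        res$cigar[row_i] <<- cigar
        return(invisible(NULL))
      }
      res$pos[row_i] <<- pos
      res$mapq[row_i] <<- mapq
      res$strand[row_i] <<- strand
      res$cigar[row_i] <<- cigar
      # flank-aligned: seq already donor-forward == SAM plus orientation
      invisible(NULL)
    }

    for (k in which(danger1)) fix_read(k, d1a[k], d1b[k], FALSE)
    for (k in which(danger2)) fix_read(n_frag + k, d2a[k], d2b[k], TRUE)

    # refresh mate fields and pair flags after per-read fixes
    m1 <- seq_len(n_frag); m2 <- n_frag + m1
    res$mchrom[m1] <- res$chrom[m2]; res$mchrom[m2] <- res$chrom[m1]
    res$mpos[m1] <- res$pos[m2]; res$mpos[m2] <- res$pos[m1]
    same <- res$chrom[m1] == res$chrom[m2]
    lo <- pmin(res$pos[m1], res$pos[m2])
    hi <- pmax(res$pos[m1] + rl - 1L, res$pos[m2] + rl - 1L)
    span <- ifelse(same, hi - lo + 1L, 0L)
    fr <- res$strand[m1] != res$strand[m2]
    proper <- same & fr & span <= 2000L
    res$isize[m1] <- ifelse(same, ifelse(res$pos[m1] <= res$pos[m2],
                                         span, -span), 0L)
    res$isize[m2] <- -res$isize[m1]
    res$proper[m1] <- proper
    res$proper[m2] <- proper
    out[[ch]] <- res
  }
  aln <- do.call(rbind, out)
  rownames(aln) <- NULL
  aln[order(aln$chrom, aln$pos), , drop = FALSE]
}

#' Write an alignment table as SAM
#'
#' Emits a coordinate-sorted SAM file with `@HD`/`@SQ` headers from the
#' simulator's alignment table; [read_alignments()] converts it (or any
#' BAM/SAM with the same conventions) back.
#'
#' @param aln alignment data.frame from [simulate_reads()].
#' @param chrom_lengths named integer vector of reference lengths.
#' @param path output `.sam` path.
#' @return `path`, invisibly.
#' @export
write_sam <- function(aln, chrom_lengths, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:coordinate", con)
  for (ch in names(chrom_lengths)) {
    writeLines(sprintf("@SQ\tSN:%s\tLN:%d", ch, chrom_lengths[[ch]]), con)
  }
  flag <- 1L +
    ifelse(aln$proper, 2L, 0L) +
    ifelse(aln$strand == "-", 16L, 0L) +
    ifelse(aln$mate == 1L, 64L, 128L)
  # mate strand: within a pair the other mate's strand
  key <- paste0(aln$qname, "/", 3L - aln$mate)
  self <- paste0(aln$qname, "/", aln$mate)
  mstrand <- aln$strand[match(key, self)]
  flag <- flag + ifelse(!is.na(mstrand) & mstrand == "-", 32L, 0L)
  rnext <- ifelse(aln$mchrom == aln$chrom, "=", aln$mchrom)
  lines <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t%s\t%d\t%d\t%s\t*",
                   aln$qname, flag, aln$chrom, aln$pos, aln$mapq, aln$cigar,
                   rnext, aln$mpos, aln$isize, aln$seq)
  writeLines(lines, con)
  invisible(path)
}

#' Read alignments from SAM/BAM into the pipeline's table form
#'
#' SAM input is converted to sorted, indexed BAM via Rsamtools, then read
#' back into the column layout produced by [simulate_reads()].
#'
#' @param path a `.sam` or `.bam` file.
#' @return alignment data.frame.
#' @export
read_alignments <- function(path) {
  if (grepl("\\.sam$", path)) {
    bam <- Rsamtools::asBam(path, sub("\\.sam$", "", path),
                            overwrite = TRUE, indexDestination = TRUE)
  } else {
    bam <- path
    if (!file.exists(paste0(bam, ".bai"))) {
      stop("BAM index required: ", bam, ".bai not found")
    }
  }
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "mapq", "cigar", "seq",
             "mrnm", "mpos", "isize"))
  b <- Rsamtools::scanBam(bam, param = p)[[1]]
  flag <- b$flag
  data.frame(
    qname = b$qname,
    mate = ifelse(bitwAnd(flag, 64L) > 0L, 1L, 2L),
    chrom = as.character(b$rname), pos = b$pos, mapq = b$mapq,
    strand = ifelse(bitwAnd(flag, 16L) > 0L, "-", "+"),
    cigar = b$cigar, seq = as.character(b$seq),
    mchrom = as.character(b$mrnm), mpos = b$mpos, isize = b$isize,
    proper = bitwAnd(flag, 2L) > 0L,
    stringsAsFactors = FALSE
  )
}
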