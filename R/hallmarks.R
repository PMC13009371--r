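#' Sweep-line polyA tract detection
#'
#' Scores a sequence for the best contiguous window of the given base using
#' the sweep-line (running sum, reset at zero) scheme: each matching base
#' contributes `polya_match` (+1 by default), each other base
#' `polya_mismatch` (-3), and a tract is called present when the best
#' window's score reaches `polya_limit` (10). The running sum is floored at
#' zero, which is exactly Kadane's maximum-subarray recursion, so the
#' reported score is the maximum over all contiguous windows. The limit is
#' a detection threshold, not a cap: longer uninterrupted tracts score
#' above it.
#'
#' @param seq a single DNA string.
#' @param base the tract base, `"A"` or `"T"`.
#' @param params a [pipeline_params()] object.
#' @return list with `best_score`, `present`, and `best_interval`
#'   (1-based inclusive `c(start, end)` of the leftmost best window, or
#'   `NULL` when the best score is 0).
#' @examples
#' p <- pipeline_params()
#' polya_sweep(strrep("A", 12), "A", p)$present
#' @export
polya_sweep <- function(seq, base = "A", params = pipeline_params()) {
  stopifnot(is.character(seq), length(seq) == 1L, nzchar(seq))
  v <- ifelse(strsplit(toupper(seq), "", fixed = TRUE)[[1]] == base,
              params$polya_match, params$polya_mismatch)
  best <- 0
  best_start <- NA_integer_
  best_end <- NA_integer_
  run <- 0
  run_start <- 1L
  for (i in seq_along(v)) {
    if (run <= 0) {
      run <- 0
      run_start <- i
    }
    run <- run + v[i]
    if (run > best) {
      best <- run
      best_start <- run_start
      best_end <- i
    }
  }
  list(
    best_score = best,
    present = best >= params$polya_limit,
    best_interval = if (is.na(best_start)) NULL else c(best_start, best_end)
  )
}

#' Endonuclease cut-site score
#'
#' Scores a 6-mer flanking an insertion breakpoint against the L1
#' endonuclease consensus TTTT/AA. Each position matching the consensus
#' base earns its positional weight (1,1,3,4,1,1 by default; the two bases
#' around the nick are weighted 3 and 4). Scores of at least
#' `en_min_score` (6) qualify as endonuclease cut sites. `N` never
#' matches.
#'
#' @param flank a 6-character DNA string.
#' @param params a [pipeline_params()] object.
#' @return integer score in `[0, sum(en_weights)]`.
#' @examples
#' en_score("TTTTAA")  # 11, perfect consensus
#' @export
en_score <- function(flank, params = pipeline_params()) {
  stopifnot(is.character(flank), length(flank) == 1L)
  if (nchar(flank) != 6L) stop("EN flank must be exactly 6 bases")
  f <- strsplit(toupper(flank), "", fixed = TRUE)[[1]]
  k <- strsplit(params$en_consensus, "", fixed = TRUE)[[1]]
  as.integer(sum(params$en_weights[f == k & f %in% c("A", "C", "G", "T")]))
}

#' Extract the endonuclease flank around the initial breakpoint
#'
#' The L1 endonuclease nicks the bottom strand before target-primed reverse
#' transcription begins, so the relevant hexamer sits asymmetrically around
#' the breakpoint at the insertion's initial end: four bases upstream and
#' two downstream, read in insertion orientation. For a plus-orientation
#' insertion this is the later (3'-most) breakpoint read on the plus
#' strand; for minus orientation it is the earlier breakpoint with the
#' extraction reverse-complemented.
#'
#' Breakpoints are 0-based junction offsets: a breakpoint `b` lies between
#' reference bases `b` and `b + 1` (1-based).
#'
#' @param chrom_seq the chromosome sequence (single string).
#' @param bp_a,bp_b the 5'-most and 3'-most breakpoints (0-based junctions).
#' @param orientation `"+"` or `"-"`.
#' @return the 6-mer flank, or `NA_character_` when the breakpoint is too
#'   close to a contig edge for a full extraction.
#' @export
extract_en_flank <- function(chrom_seq, bp_a, bp_b, orientation) {
  stopifnot(orientation %in% c("+", "-"))
  n <- nchar(chrom_seq)
  if (orientation == "+") {
    b <- bp_b
    if (b < 4L || b + 2L > n) return(NA_character_)
    substr(chrom_seq, b - 3L, b + 2L)
  } else {
    b <- bp_a
    if (b < 2L || b + 4L > n) return(NA_character_)
    revcomp(substr(chrom_seq, b - 1L, b + 4L))
  }
}

#' Target site duplication length from breakpoints
#'
#' The TSD is the distance between the two insertion breakpoints. A
#' positive value is a duplication of target sequence, zero a blunt
#' junction; a negative value (breakpoints in inverted order after junction
#' assignment) indicates a target-site deletion and is preserved rather
#' than clamped.
#'
#' @param bp_a the 5'-most junction, `bp_b` the 3'-most (0-based offsets).
#' @param bp_b see `bp_a`.
#' @return signed integer length in bp.
#' @export
tsd_from_breakpoints <- function(bp_a, bp_b) {
  as.integer(bp_b - bp_a)
}

#' Insertion orientation from polyA tract polarity
#'
#' On the reference plus strand a retrotransposition event leaves an
#' A-tract for plus-orientation insertions and a T-tract for minus. Reads
#' supporting the event are scanned with [polya_sweep()] in both bases; an
#' unambiguous single polarity determines the orientation, anything else is
#' `"unknown"`.
#'
#' @param read_seqs character vector of read sequences, oriented to the
#'   reference plus strand.
#' @param params a [pipeline_params()] object.
#' @return `"+"`, `"-"`, or `"unknown"`.
#' @export
orientation_from_polya <- function(read_seqs, params = pipeline_params()) {
  read_seqs <- read_seqs[nzchar(read_seqs)]
  if (!length(read_seqs)) return("unknown")
  has_a <- any(vapply(read_seqs, function(s)
    polya_sweep(s, "A", params)$present, logical(1)))
  has_t <- any(vapply(read_seqs, function(s)
    polya_sweep(s, "T", params)$present, logical(1)))
  if (has_a && !has_t) "+" else if (has_t && !has_a) "-" else "unknown"
}

#' Assemble a hallmark annotation
#'
#' Bundles the three TPRT hallmarks (target site duplication, polyA tract,
#' endonuclease cut site) into one record with the count of positive
#' hallmarks.
#'
#' @param bp_a,bp_b breakpoints (0-based junction offsets) or `NA`.
#' @param polya_best_score best sweep-line score over supporting reads.
#' @param polya_base tract base attaining it (`"A"`/`"T"`/`NA`).
#' @param en_flank the 6-mer flank or `NA`.
#' @param orientation `"+"`, `"-"`, or `"unknown"`.
#' @param params a [pipeline_params()] object.
#' @return one-row data.frame with breakpoints, `tsd_length`,
#'   `polya_present`, `polya_best_score`, `polya_base`, `en_flank`,
#'   `en_score`, `en_cut_site`, `orientation` and `hallmark_count`.
#' @export
hallmark_annotation <- function(bp_a = NA, bp_b = NA,
                                polya_best_score = 0, polya_base = NA,
                                en_flank = NA, orientation = "unknown",
                                params = pipeline_params()) {
  tsd <- if (is.na(bp_a) || is.na(bp_b)) NA_integer_ else
    tsd_from_breakpoints(bp_a, bp_b)
  escore <- if (is.na(en_flank)) NA_integer_ else en_score(en_flank, params)
  en_cut <- !is.na(escore) && escore >= params$en_min_score
  polya_present <- polya_best_score >= params$polya_limit
  count <- sum(
    !is.na(tsd) && tsd > 0L,
    polya_present,
    en_cut
  )
  data.frame(
    breakpoint_a = as.numeric(bp_a), breakpoint_b = as.numeric(bp_b),
    tsd_length = tsd,
    polya_present = polya_present,
    polya_best_score = polya_best_score,
    polya_base = as.character(polya_base),
    en_flank = as.character(en_flank),
    en_score = if (is.na(escore)) NA_integer_ else escore,
    en_cut_site = en_cut,
    orientation = orientation,
    hallmark_count = as.integer(count),
    stringsAsFactors = FALSE
  )
}
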