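#' Scan read pairs for source-L1 tag containment
#'
#' Identifies read pairs in which one mate's sequence contains the exact
#' 30-bp tag of a catalogued source element (or its reverse complement) as
#' a substring; the other mate becomes the candidate anchor localizing the
#' insertion. Pairs where both mates carry tags have no usable anchor and
#' are dropped. Tags from sources excluded by the uniqueness filter are
#' skipped. Anchor MAPQ is recorded unfiltered; MAPQ filtering happens at
#' clustering so the raw evidence remains auditable.
#'
#' @param aln alignment table (see [simulate_reads()] /
#'   [read_alignments()]).
#' @param catalog source catalog from [build_catalog()].
#' @param sample sample id recorded in the hits.
#' @param params a [pipeline_params()] object; `max_tag_mismatches`
#'   (default 0) relaxes exact containment if ever needed.
#' @return data.frame of tag hits: `sample`, `source_id`, `qname`,
#'   `carrier_mate`, `anchor_chrom`, `anchor_pos`, `anchor_mapq`,
#'   `anchor_strand`.
#' @export
scan_reads <- function(aln, catalog, sample = "sample",
                       params = pipeline_params()) {
  usable <- catalog[catalog$usable, , drop = FALSE]
  empty <- data.frame(sample = character(), source_id = character(),
                      qname = character(), carrier_mate = integer(),
                      anchor_chrom = character(), anchor_pos = integer(),
                      anchor_mapq = integer(), anchor_strand = character(),
                      stringsAsFactors = FALSE)
  if (!nrow(usable) || !nrow(aln)) return(empty)
  reads <- Biostrings::DNAStringSet(aln$seq)
  self_key <- paste0(aln$qname, "/", aln$mate)
  mate_key <- paste0(aln$qname, "/", 3L - aln$mate)
  mate_idx <- match(mate_key, self_key)
  out <- list()
  for (i in seq_len(nrow(usable))) {
    tag <- usable$tag[i]
    mm <- params$max_tag_mismatches
    carrier <- Biostrings::vcountPattern(tag, reads, max.mismatch = mm,
                                         fixed = TRUE) > 0L
    carrier <- carrier | Biostrings::vcountPattern(revcomp(tag), reads,
                                                   max.mismatch = mm,
                                                   fixed = TRUE) > 0L
    if (!any(carrier)) next
    ci <- which(carrier)
    ai <- mate_idx[ci]
    ok <- !is.na(ai) & !carrier[ifelse(is.na(ai), 1L, ai)]
    ci <- ci[ok]
    ai <- ai[ok]
    if (!length(ci)) next
    out[[length(out) + 1L]] <- data.frame(
      sample = sample, source_id = usable$source_id[i],
      qname = aln$qname[ci], carrier_mate = aln$mate[ci],
      anchor_chrom = aln$chrom[ai], anchor_pos = aln$pos[ai],
      anchor_mapq = aln$mapq[ai], anchor_strand = aln$strand[ai],
      stringsAsFactors = FALSE)
  }
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Cluster anchor reads per source
#'
#' Single-linkage clustering of anchor positions per (source, chromosome):
#' anchors join a cluster when within `anchor_cluster_gap` (1 kbp) of the
#' nearest member. Only anchors with MAPQ at least `anchor_min_mapq` (37)
#' participate.
#'
#' @param hits tag hits from [scan_reads()] (one sample).
#' @param params a [pipeline_params()] object.
#' @return data.frame of clusters: `sample`, `source_id`, `chrom`,
#'   `start`, `end` (anchor position range, 1-based), `n_anchor_reads`,
#'   `qnames` (comma-joined).
#' @export
cluster_anchors <- function(hits, params = pipeline_params()) {
  empty <- data.frame(sample = character(), source_id = character(),
                      chrom = character(), start = integer(),
                      end = integer(), n_anchor_reads = integer(),
                      qnames = character(), stringsAsFactors = FALSE)
  hits <- hits[hits$anchor_mapq >= params$anchor_min_mapq, , drop = FALSE]
  if (!nrow(hits)) return(empty)
  out <- list()
  for (grp in split(hits, paste(hits$source_id, hits$anchor_chrom,
                                sep = "\r"))) {
    grp <- grp[order(grp$anchor_pos), , drop = FALSE]
    cid <- cumsum(c(0L, diff(grp$anchor_pos) > params$anchor_cluster_gap))
    for (cl in split(grp, cid)) {
      out[[length(out) + 1L]] <- data.frame(
        sample = cl$sample[1], source_id = cl$source_id[1],
        chrom = cl$anchor_chrom[1],
        start = min(cl$anchor_pos), end = max(cl$anchor_pos),
        n_anchor_reads = nrow(cl),
        qnames = paste(cl$qname, collapse = ","),
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$source_id, res$chrom, res$start), , drop = FALSE]
}

#' Apply cluster-level filters
#'
#' A cluster is called a transduction when it holds at least
#' `cluster_min_reads` (3) anchors and lies farther than
#' `repeat_exclusion_dist` (2 kbp) from any recorded similar site of its
#' source's tag - and from the source locus itself, whose own flank would
#' otherwise seed self-hits.
#'
#' @param clusters output of [cluster_anchors()].
#' @param catalog source catalog (similar sites populated).
#' @param params a [pipeline_params()] object.
#' @return `clusters` with logical columns `min_reads_pass`,
#'   `repeat_exclusion_pass`, `called`.
#' @export
filter_clusters <- function(clusters, catalog, params = pipeline_params()) {
  if (!nrow(clusters)) {
    clusters$min_reads_pass <- logical(0)
    clusters$repeat_exclusion_pass <- logical(0)
    clusters$called <- logical(0)
    return(clusters)
  }
  taglen <- params$tag_length
  d <- params$repeat_exclusion_dist
  clusters$min_reads_pass <- clusters$n_anchor_reads >= params$cluster_min_reads
  clusters$repeat_exclusion_pass <- vapply(seq_len(nrow(clusters)), function(i) {
    cl <- clusters[i, ]
    src <- catalog[catalog$source_id == cl$source_id, , drop = FALSE]
    if (!nrow(src)) return(TRUE)
    near <- function(chrom, lo, hi) {
      chrom == cl$chrom & lo <= cl$end + d & hi >= cl$start - d
    }
    if (near(src$chrom, src$start + 1L, src$end)) return(FALSE)
    sites <- parse_similar_sites(src$similar_sites)
    if (nrow(sites) &&
        any(near(sites$chrom, sites$start + 1L, sites$start + taglen))) {
      return(FALSE)
    }
    TRUE
  }, logical(1))
  clusters$called <- clusters$min_reads_pass & clusters$repeat_exclusion_pass
  clusters
}

#' Merge called clusters across samples
#'
#' Single-linkage merge of per-sample transduction calls arising from the
#' same source when their loci lie within `cross_sample_merge_dist`
#' (2 kbp); merged events list their supporting samples. Calls from
#' different sources never merge.
#'
#' @param events data.frame of called clusters across samples; must carry
#'   `sample`, `source_id`, `chrom` and a locus column `locus`.
#' @param params a [pipeline_params()] object.
#' @return data.frame with `merged_event_id` per input row, plus an
#'   attribute-free summary obtainable via [summarize_merged_events()].
#' @export
merge_across_samples <- function(events, params = pipeline_params()) {
  if (!nrow(events)) {
    events$merged_event_id <- character(0)
    return(events)
  }
  events$merged_event_id <- NA_character_
  counter <- 0L
  for (grp_idx in split(seq_len(nrow(events)),
                        paste(events$source_id, events$chrom, sep = "\r"))) {
    ord <- grp_idx[order(events$locus[grp_idx])]
    gap_new <- c(0L, diff(events$locus[ord])) > params$cross_sample_merge_dist
    cid <- cumsum(gap_new)
    for (u in unique(cid)) {
      counter <- counter + 1L
      events$merged_event_id[ord[cid == u]] <- sprintf("ev%04d", counter)
    }
  }
  events
}

#' Summarize merged events
#'
#' @param events output of [merge_across_samples()].
#' @return one row per merged event: `merged_event_id`, `source_id`,
#'   `chrom`, `locus` (median of member loci), `samples` (comma-joined),
#'   `n_samples`.
#' @export
summarize_merged_events <- function(events) {
  out <- lapply(split(events, events$merged_event_id), function(g) {
    data.frame(
      merged_event_id = g$merged_event_id[1], source_id = g$source_id[1],
      chrom = g$chrom[1], locus = stats::median(g$locus),
      samples = paste(sort(unique(g$sample)), collapse = ","),
      n_samples = length(unique(g$sample)), stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Flag somatic events
#'
#' An event is somatic when it is supported by exactly one sample, that
#' sample is a tumor, and no normal carries it.
#'
#' @param merged summary from [summarize_merged_events()].
#' @param sample_sheet data.frame with `sample` and `type`
#'   (`"tumor"`/`"normal"`).
#' @return `merged` with a logical `somatic` column.
#' @export
call_somatic <- function(merged, sample_sheet) {
  bad <- setdiff(sample_sheet$type, c("tumor", "normal"))
  if (length(bad)) stop("unknown sample label(s): ", paste(bad, collapse = ", "))
  type_of <- stats::setNames(sample_sheet$type, sample_sheet$sample)
  merged$somatic <- vapply(seq_len(nrow(merged)), function(i) {
    ss <- strsplit(merged$samples[i], ",", fixed = TRUE)[[1]]
    tt <- type_of[ss]
    if (any(is.na(tt))) stop("unknown sample label(s): ",
                             paste(ss[is.na(tt)], collapse = ", "))
    length(ss) == 1L && all(tt == "tumor")
  }, logical(1))
  merged
}

# clip bookkeeping: leading/trailing soft or hard clip length and the
# 0-based junction coordinate of each clip boundary
cigar_clips <- function(cigar, pos) {
  lead <- integer(length(cigar))
  has_lead <- grepl("^\\d+[SH]", cigar)
  lead[has_lead] <- as.integer(sub("^(\\d+)[SH].*$", "\\1", cigar[has_lead]))
  trail <- integer(length(cigar))
  has_trail <- grepl("\\d+[SH]$", cigar)
  trail[has_trail] <- as.integer(sub("^.*?(\\d+)[SH]$", "\\1",
                                     cigar[has_trail]))
  ref_len <- vapply(cigar, function(cg) {
    ops <- gregexpr("\\d+[MDN=X]", cg)[[1]]
    if (ops[1] < 0) return(0L)
    toks <- regmatches(cg, gregexpr("\\d+[MDN=X]", cg))[[1]]
    sum(as.integer(sub("[MDN=X]", "", toks)))
  }, integer(1), USE.NAMES = FALSE)
  list(lead = lead, trail = trail,
       lead_junction = pos - 1L,            # 0-based junction before start
       trail_junction = pos - 1L + ref_len) # 0-based junction after end
}

#' Characterize a called cluster
#'
#' Extracts reads within `characterization_window` (500 bp) of the anchor
#' interval and derives the insertion's breakpoints and hallmarks:
#' split-read clip boundaries vote for the two modal split positions
#' (ties toward the leftmost), the TSD is the distance between them, polyA
#' polarity and score come from sweeping the mate sequences of discordant
#' pairs (insert size beyond `discordant_min_insert`, mates on different
#' chromosomes, or non-FR orientation) oriented to the target plus strand,
#' orientation follows the tract polarity, and the endonuclease flank is
#' read from the reference at the orientation-appropriate breakpoint.
#' Missing evidence degrades gracefully: hallmarks are annotation, never
#' filters.
#'
#' @param aln the sample's full alignment table.
#' @param cluster one row of [filter_clusters()] output.
#' @param reference reference genome (any [build_catalog()]-accepted form).
#' @param params a [pipeline_params()] object.
#' @return one-row data.frame: cluster fields + [hallmark_annotation()]
#'   fields + `locus` (modal breakpoint, else anchor midpoint).
#' @export
characterize_cluster <- function(aln, cluster, reference,
                                 params = pipeline_params()) {
  ref <- as_reference(reference)
  w <- params$characterization_window
  lo <- cluster$start - w
  hi <- cluster$end + w
  sel <- aln$chrom == cluster$chrom & aln$pos >= lo & aln$pos <= hi
  wr <- aln[sel, , drop = FALSE]

  # split reads: clip boundaries of sufficiently clipped alignments
  breaks <- c()
  if (nrow(wr)) {
    cl <- cigar_clips(wr$cigar, wr$pos)
    breaks <- c(cl$lead_junction[cl$lead >= params$min_clip_len],
                cl$trail_junction[cl$trail >= params$min_clip_len])
  }
  bp_a <- bp_b <- NA_integer_
  if (length(breaks)) {
    tab <- sort(table(breaks), decreasing = TRUE)
    vals <- as.integer(names(tab))
    top <- vals[tab == max(tab)]
    first <- min(top)
    rest <- setdiff(vals, first)
    second <- if (length(rest)) {
      tab2 <- tab[as.character(rest)]
      cand <- rest[tab2 == max(tab2)]
      min(cand)
    } else first
    bp_a <- min(first, second)
    bp_b <- max(first, second)
  }

  # discordant pairs: fetch mate sequences oriented to the target plus strand
  polya_best <- 0
  polya_base <- NA_character_
  orientation <- "unknown"
  if (nrow(wr)) {
    self_key <- paste0(aln$qname, "/", aln$mate)
    mate_idx <- match(paste0(wr$qname, "/", 3L - wr$mate), self_key)
    mstrand <- aln$strand[mate_idx]
    rf <- !is.na(mstrand) & mstrand != wr$strand &
      ifelse(wr$strand == "+", wr$pos > aln$pos[mate_idx],
             wr$pos < aln$pos[mate_idx])
    disc <- (!is.na(wr$mchrom) & wr$mchrom != wr$chrom) |
      abs(wr$isize) > params$discordant_min_insert |
      (!is.na(mstrand) & mstrand == wr$strand) | rf
    di <- which(disc & !is.na(mate_idx))
    if (length(di)) {
      mates <- aln[mate_idx[di], , drop = FALSE]
      as_seq <- ifelse(mates$strand == "-", revcomp(mates$seq), mates$seq)
      target_seq <- ifelse(wr$strand[di] == "+", revcomp(as_seq), as_seq)
      a_best <- max(vapply(target_seq, function(s)
        polya_sweep(s, "A", params)$best_score, numeric(1)))
      t_best <- max(vapply(target_seq, function(s)
        polya_sweep(s, "T", params)$best_score, numeric(1)))
      polya_best <- max(a_best, t_best)
      if (polya_best > 0) polya_base <- if (a_best >= t_best) "A" else "T"
      orientation <- orientation_from_polya(target_seq, params)
    }
  }

  en_flank <- NA_character_
  if (!is.na(bp_a) && orientation %in% c("+", "-")) {
    en_flank <- extract_en_flank(ref[[cluster$chrom]], bp_a, bp_b,
                                 orientation)
  }
  ann <- hallmark_annotation(bp_a = bp_a, bp_b = bp_b,
                             polya_best_score = polya_best,
                             polya_base = polya_base, en_flank = en_flank,
                             orientation = orientation, params = params)
  locus <- if (!is.na(bp_a)) bp_a else (cluster$start + cluster$end) %/% 2L
  cbind(cluster[, setdiff(names(cluster), "qnames"), drop = FALSE], ann,
        data.frame(locus = locus))
}

#' Per-sample tag-based detection
#'
#' Runs scan, clustering, filtering and characterization for one sample's
#' alignments and returns the characterized cluster table.
#'
#' @param aln alignment table for the sample.
#' @param catalog source catalog.
#' @param reference reference genome.
#' @param sample sample id.
#' @param params a [pipeline_params()] object.
#' @return characterized cluster data.frame (all clusters, with filter
#'   flags; called clusters carry hallmark columns).
#' @export
detect_sample <- function(aln, catalog, reference, sample,
                          params = pipeline_params()) {
  hits <- scan_reads(aln, catalog, sample, params)
  clusters <- cluster_anchors(hits, params)
  clusters <- filter_clusters(clusters, catalog, params)
  called <- clusters[clusters$called, , drop = FALSE]
  if (!nrow(called)) {
    empty <- cbind(clusters[0, setdiff(names(clusters), "qnames"),
                            drop = FALSE],
                   hallmark_annotation(params = params)[0, , drop = FALSE],
                   data.frame(locus = integer(0)))
    return(empty)
  }
  rows <- lapply(seq_len(nrow(called)), function(i) {
    characterize_cluster(aln, called[i, ], reference, params)
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Multi-sample tag-based detection
#'
#' Full short-read detection across a cohort: per-sample detection, then
#' cross-sample merging and somatic calling.
#'
#' @param alignments named list (by sample) of alignment tables or SAM/BAM
#'   paths.
#' @param sample_sheet data.frame with `sample`, `type`
#'   (`"tumor"`/`"normal"`).
#' @param catalog source catalog.
#' @param reference reference genome.
#' @param params a [pipeline_params()] object.
#' @return list with `per_sample` (characterized called clusters) and
#'   `events` ([summarize_merged_events()] + `somatic`).
#' @export
detect_short <- function(alignments, sample_sheet, catalog, reference,
                         params = pipeline_params()) {
  per_sample <- list()
  for (s in sample_sheet$sample) {
    aln <- alignments[[s]]
    if (is.character(aln)) aln <- read_alignments(aln)
    if (is.null(aln)) next
    per_sample[[s]] <- detect_sample(aln, catalog, reference, s, params)
  }
  calls <- do.call(rbind, per_sample)
  if (is.null(calls) || !nrow(calls)) {
    return(list(per_sample = per_sample,
                events = data.frame(merged_event_id = character(),
                                    source_id = character(),
                                    chrom = character(), locus = numeric(),
                                    samples = character(),
                                    n_samples = integer(),
                                    somatic = logical(),
                                    stringsAsFactors = FALSE)))
  }
  rownames(calls) <- NULL
  merged <- merge_across_samples(calls, params)
  events <- call_somatic(summarize_merged_events(merged), sample_sheet)
  list(per_sample = per_sample, events = events)
}
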