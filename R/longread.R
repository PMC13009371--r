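# Local-alignment helper shared by the long-read annotation steps.
local_align <- function(pattern, subject) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -3,
                                                  baseOnly = FALSE)
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(pattern), Biostrings::DNAString(subject),
    type = "local", substitutionMatrix = mat,
    gapOpening = 5, gapExtension = 2)
  pr <- Biostrings::pattern(pa)
  sr <- Biostrings::subject(pa)
  list(
    score = Biostrings::score(pa),
    identity = Biostrings::pid(pa) / 100,
    pattern_start = Biostrings::start(pr),
    pattern_end = Biostrings::end(pr),
    subject_start = Biostrings::start(sr),
    subject_end = Biostrings::end(sr),
    aligned_len = Biostrings::end(pr) - Biostrings::start(pr) + 1L
  )
}

# length of the terminal A-tract (sweep-tolerant); 0 when absent
terminal_polya_len <- function(seq, params) {
  n <- nchar(seq)
  w <- min(120L, n)
  tail_seq <- substr(seq, n - w + 1L, n)
  sw <- polya_sweep(tail_seq, "A", params)
  if (!sw$present || is.null(sw$best_interval)) return(0L)
  if (sw$best_interval[2] < w - 3L) return(0L)   # tract must reach the end
  w - sw$best_interval[1] + 1L
}

# length of the leading A-tract of a segment (internal polyA); 0 if below
# the detection limit
leading_polya_len <- function(seq, params) {
  if (!nzchar(seq)) return(0L)
  w <- min(120L, nchar(seq))
  head_seq <- substr(seq, 1L, w)
  sw <- polya_sweep(head_seq, "A", params)
  if (!sw$present || is.null(sw$best_interval)) return(0L)
  if (sw$best_interval[1] > 4L) return(0L)       # tract must start the segment
  sw$best_interval[2]
}

#' Classify a reconstructed insertion sequence
#'
#' Decomposes an insertion sequence into its components and assigns the
#' insertion class. L1 content is located by local alignment to the L1
#' consensus (identity >= `min_l1_identity` over >=
#' `min_l1_match_len` bp); the terminal polyA tract is measured by a
#' sweep anchored at the 3' end; an internal polyA directly after the L1
#' segment is stripped; the remainder between L1 (or sequence start) and
#' the terminal tract is the candidate transduced sequence. Classes:
#' `partnered` (L1 + transduced sequence), `orphan` (transduced sequence
#' without L1), `solo` (L1 only), `unclassifiable` (no recognizable
#' content, e.g. all-N input).
#'
#' @param inserted_seq the insertion sequence (element strand).
#' @param l1_consensus consensus sequence (defaults to the packaged one).
#' @param params a [pipeline_params()] object.
#' @return list with `class`, `l1_bp`, `l1_start`, `l1_end` (1-based in
#'   the insertion, `NA` when absent), `leading_bp` (bases preceding the
#'   forward L1 match), `polya_internal_bp`, `transduction_bp`,
#'   `polya_bp`, `td_seq`, `total_bp`.
#' @export
classify_insertion <- function(inserted_seq,
                               l1_consensus = retrotag::l1_consensus(),
                               params = pipeline_params()) {
  n <- nchar(inserted_seq)
  if (n < 30L) stop("insertion sequence shorter than 30 bp")
  if (grepl("^N+$", inserted_seq)) {
    return(list(class = "unclassifiable", l1_bp = 0L, l1_start = NA_integer_,
                l1_end = NA_integer_, leading_bp = 0L,
                polya_internal_bp = 0L, transduction_bp = 0L, polya_bp = 0L,
                td_seq = "", total_bp = n))
  }
  pa_bp <- terminal_polya_len(inserted_seq, params)
  core_end <- n - pa_bp
  core <- substr(inserted_seq, 1L, core_end)

  l1_start <- l1_end <- NA_integer_
  l1_bp <- 0L
  if (nchar(core) >= params$min_l1_match_len) {
    al <- local_align(core, l1_consensus)
    if (al$aligned_len >= params$min_l1_match_len &&
        al$identity >= params$min_l1_identity) {
      l1_start <- al$pattern_start
      l1_end <- al$pattern_end
      l1_bp <- l1_end - l1_start + 1L
    }
  }
  leading_bp <- if (is.na(l1_start)) 0L else l1_start - 1L
  post <- if (is.na(l1_end)) core else
    substr(core, l1_end + 1L, nchar(core))
  int_pa <- if (is.na(l1_end)) 0L else leading_polya_len(post, params)
  td_seq <- substr(post, int_pa + 1L, nchar(post))
  td_bp <- nchar(td_seq)
  cls <- if (l1_bp > 0L && td_bp >= params$min_transduction_len) "partnered"
    else if (l1_bp > 0L) "solo"
    else if (td_bp >= params$min_transduction_len) "orphan"
    else "unclassifiable"
  if (cls == "solo") {
    # short residue after the L1 match is alignment ragging, not transduction
    td_seq <- ""
    td_bp <- 0L
  }
  list(class = cls, l1_bp = l1_bp, l1_start = l1_start, l1_end = l1_end,
       leading_bp = leading_bp, polya_internal_bp = int_pa,
       transduction_bp = td_bp, polya_bp = pa_bp, td_seq = td_seq,
       total_bp = n)
}

#' Assign a transduced segment to its source element
#'
#' Aligns the candidate transduced sequence against the downstream window
#' (`source_window` = 3 kbp, plus margin) of every catalogued element and
#' assigns the insertion to the element holding the best unique alignment.
#' Uniqueness is enforced by a best-versus-second score margin
#' (`assign_margin`), the window-level equivalent of requiring positive
#' mapping quality from a genome-wide mapper. The transduction endpoint is
#' the alignment's 3' terminus in downstream coordinates, from which the
#' transduction length (distance from the source 3' end) and its genomic
#' position follow.
#'
#' @param td_seq candidate transduced sequence.
#' @param catalog source catalog (rows with non-empty `downstream_seq`
#'   participate, full-length or not - truncated proxy elements capture
#'   calls exactly as a genome-wide mapper would place them).
#' @param params a [pipeline_params()] object.
#' @return list with `status` (`assigned` / `unassigned` /
#'   `unassigned-ambiguous`), `source_id`, `endpoint_offset` (1-based bp
#'   downstream of the source 3' end), `endpoint_genomic` (0-based),
#'   `score`, `margin`, `identity`.
#' @export
assign_source <- function(td_seq, catalog, params = pipeline_params()) {
  unassigned <- list(status = "unassigned", source_id = NA_character_,
                     endpoint_offset = NA_integer_,
                     endpoint_genomic = NA_integer_, score = NA_real_,
                     margin = NA_real_, identity = NA_real_)
  cand <- catalog[!is.na(catalog$downstream_seq) &
                    nzchar(catalog$downstream_seq), , drop = FALSE]
  if (!nrow(cand) || nchar(td_seq) < params$min_l1_match_len) {
    return(unassigned)
  }
  res <- lapply(seq_len(nrow(cand)), function(i) {
    win <- substr(cand$downstream_seq[i], 1L,
                  params$source_window + 50L)
    local_align(td_seq, win)
  })
  scores <- vapply(res, `[[`, numeric(1), "score")
  best <- which.max(scores)
  al <- res[[best]]
  if (al$aligned_len < params$min_l1_match_len ||
      al$identity < params$min_l1_identity ||
      al$subject_start > params$source_window) {
    return(unassigned)
  }
  second <- if (length(scores) > 1L) max(scores[-best]) else -Inf
  if (scores[best] - second < params$assign_margin) {
    out <- unassigned
    out$status <- "unassigned-ambiguous"
    return(out)
  }
  src <- cand[best, ]
  endpoint_offset <- al$subject_end
  endpoint_genomic <- if (!is.na(src$strand) && src$strand == "-") {
    src$start - endpoint_offset
  } else {
    src$end + endpoint_offset
  }
  list(status = "assigned", source_id = src$source_id,
       endpoint_offset = endpoint_offset,
       endpoint_genomic = endpoint_genomic, score = scores[best],
       margin = scores[best] - second, identity = al$identity)
}

#' Detect a dual polyA configuration
#'
#' Partnered transductions often carry two polyA tracts: the source
#' element's own (internal, between L1 and transduced sequence) and the
#' novel one terminating the transduction. Returns `TRUE` when both
#' disjoint tracts independently reach the sweep detection limit.
#'
#' @param inserted_seq the insertion sequence.
#' @param l1_consensus consensus for component location.
#' @param params a [pipeline_params()] object.
#' @return logical flag.
#' @export
detect_dual_polya <- function(inserted_seq,
                              l1_consensus = retrotag::l1_consensus(),
                              params = pipeline_params()) {
  comp <- classify_insertion(inserted_seq, l1_consensus, params)
  comp$polya_bp >= params$polya_limit &&
    comp$polya_internal_bp >= params$polya_limit
}

#' Detect a 5' inversion in an insertion sequence
#'
#' Twin priming inverts the 5' portion of an insertion. The segment
#' preceding the forward-aligned portion of the template (L1 consensus for
#' L1-bearing insertions, the source downstream window for orphans) is
#' aligned against the template in the opposite orientation; an inversion
#' is present when that alignment passes the identity and length floors.
#' Breakpoints are reported as the two template coordinates where the
#' orientation flips, expressed as distances from the template 3' end for
#' the L1 frame, or as downstream offsets for the transduced-sequence
#' frame.
#'
#' @param inserted_seq the insertion sequence.
#' @param template L1 consensus or source downstream window.
#' @param frame `"l1"` (distances to the L1 3' end) or `"downstream"`
#'   (offsets from the source 3' end).
#' @param params a [pipeline_params()] object.
#' @return list with `present`, `breakpoints` (sorted pair or `NULL`),
#'   `frame`.
#' @export
detect_inversion <- function(inserted_seq, template, frame = c("l1", "downstream"),
                             params = pipeline_params()) {
  frame <- match.arg(frame)
  n <- nchar(inserted_seq)
  pa_bp <- terminal_polya_len(inserted_seq, params)
  core <- substr(inserted_seq, 1L, n - pa_bp)
  absent <- list(present = FALSE, breakpoints = NULL, frame = frame)
  if (nchar(core) < 2L * params$min_l1_match_len) return(absent)
  fwd <- local_align(core, template)
  if (fwd$aligned_len < params$min_l1_match_len ||
      fwd$identity < params$min_l1_identity) {
    return(absent)
  }
  lead_end <- fwd$pattern_start - 1L
  if (lead_end < params$min_l1_match_len) return(absent)
  leading <- substr(core, 1L, lead_end)
  rev_al <- local_align(revcomp(leading), template)
  if (rev_al$aligned_len < params$min_l1_match_len ||
      rev_al$identity < params$min_l1_identity) {
    return(absent)
  }
  L <- nchar(template)
  bp <- if (frame == "l1") {
    sort(c(L - rev_al$subject_end, L - rev_al$subject_start + 1L))
  } else {
    sort(c(rev_al$subject_start, rev_al$subject_end))
  }
  list(present = TRUE, breakpoints = bp, frame = frame)
}

#' Reassign calls captured by proxy elements
#'
#' A truncated reference element carrying the transduced sequence of a
#' source that is itself absent from the reference captures that source's
#' transductions. Calls assigned to an element with a `proxy_of` link are
#' relabelled with the true source and flagged. Reassignment is one step
#' and idempotent; a proxy chain (the relabel target itself being a
#' proxy) is an error.
#'
#' @param calls annotated calls data.frame with `source_id`.
#' @param catalog source catalog with `proxy_of`.
#' @return `calls` with updated `source_id` and `proxy_reassigned` flag.
#' @export
resolve_proxy <- function(calls, catalog) {
  proxy_map <- stats::setNames(catalog$proxy_of, catalog$source_id)
  if (!"proxy_reassigned" %in% names(calls)) {
    calls$proxy_reassigned <- FALSE
  }
  for (i in seq_len(nrow(calls))) {
    sid <- calls$source_id[i]
    if (is.na(sid) || calls$proxy_reassigned[i]) next
    target <- proxy_map[sid]
    if (is.na(target) || !nzchar(target)) next
    if (!is.na(proxy_map[target]) && nzchar(proxy_map[target] %||% "")) {
      stop("proxy cycle/chain detected: ", sid, " -> ", target, " -> ",
           proxy_map[target])
    }
    calls$source_id[i] <- target
    calls$proxy_reassigned[i] <- TRUE
  }
  calls
}

#' Link multigenerational transduction cascades
#'
#' A germline transduction inserted elsewhere in the genome can itself
#' mobilize in the soma. The somatic child then carries the parent's
#' transduced sequence (including the original source tag) plus the
#' parent's genomic flanking sequence - a second transduction tag. A
#' somatic call whose transduced sequence contains both a catalog
#' source's downstream sequence and a germline call's flank is linked:
#' `cascade_parent` is the germline insertion, and the source becomes the
#' ultimate reference source (or the parent itself when only the parent's
#' flank is recognizable).
#'
#' @param calls annotated calls (somatic and germline, `label` column).
#' @param catalog source catalog.
#' @param reference reference genome.
#' @param params a [pipeline_params()] object.
#' @return `calls` with `cascade_parent` filled for linked somatic calls.
#' @export
resolve_cascade <- function(calls, catalog, reference,
                            params = pipeline_params()) {
  if (!"cascade_parent" %in% names(calls)) {
    calls$cascade_parent <- NA_character_
  }
  germ <- calls[calls$label == "germline", , drop = FALSE]
  if (!nrow(germ)) return(calls)
  ref <- as_reference(reference)
  flank_of <- function(g) {
    chrom_seq <- ref[[g$chrom]]
    lo <- g$pos + 1L
    substr(chrom_seq, lo, min(lo + 79L, nchar(chrom_seq)))
  }
  min_score <- 50  # ~25 matched bases under the local scoring scheme
  for (i in which(calls$label == "somatic")) {
    td <- calls$td_seq[i]
    if (is.na(td) || nchar(td) < params$min_l1_match_len) next
    for (j in seq_len(nrow(germ))) {
      fl <- flank_of(germ[j, ])
      al <- local_align(td, fl)
      if (al$score >= min_score && al$identity >= params$min_l1_identity) {
        calls$cascade_parent[i] <- germ$insertion_id[j]
        # ultimate source: does the child also carry a catalog source tag?
        asn <- assign_source(td, catalog, params)
        calls$source_id[i] <- if (asn$status == "assigned") asn$source_id
          else germ$insertion_id[j]
        break
      }
    }
  }
  calls
}

#' Annotate a table of reconstructed insertion sequences
#'
#' End-to-end long-read annotation: classification and component
#' measurement, source assignment via the 3-kbp downstream rule, dual
#' polyA and 5' inversion detection, full-length flagging
#' (total length strictly over `somatic_full_length_min` = 5990 bp),
#' proxy reassignment and cascade linking.
#'
#' @param calls data.frame with `insertion_id`, `sample`, `chrom`, `pos`,
#'   `label` (`"somatic"`/`"germline"`), `seq`.
#' @param catalog source catalog.
#' @param reference reference genome.
#' @param l1_cons consensus sequence.
#' @param params a [pipeline_params()] object.
#' @return annotated calls data.frame (one row per insertion).
#' @export
annotate_insertions <- function(calls, catalog, reference,
                                l1_cons = l1_consensus(),
                                params = pipeline_params()) {
  rows <- lapply(seq_len(nrow(calls)), function(i) {
    cl <- calls[i, ]
    comp <- classify_insertion(cl$seq, l1_cons, params)
    asn <- if (comp$class %in% c("partnered", "orphan")) {
      assign_source(comp$td_seq, catalog, params)
    } else {
      list(status = "not-applicable", source_id = NA_character_,
           endpoint_offset = NA_integer_, endpoint_genomic = NA_integer_,
           score = NA_real_, margin = NA_real_, identity = NA_real_)
    }
    inv <- list(present = FALSE, breakpoints = NULL)
    if (comp$class %in% c("solo", "partnered")) {
      inv <- detect_inversion(cl$seq, l1_cons, frame = "l1", params = params)
    } else if (comp$class == "orphan" && asn$status == "assigned") {
      win <- catalog$downstream_seq[catalog$source_id == asn$source_id][1]
      inv <- detect_inversion(cl$seq, substr(win, 1L, params$source_window),
                              frame = "downstream", params = params)
    }
    l1_total <- comp$l1_bp +
      if (inv$present && comp$class != "orphan") comp$leading_bp else 0L
    data.frame(
      insertion_id = cl$insertion_id, sample = cl$sample, chrom = cl$chrom,
      pos = cl$pos, label = cl$label, class = comp$class,
      total_bp = comp$total_bp, l1_bp = l1_total,
      transduction_bp = comp$transduction_bp, polya_bp = comp$polya_bp,
      polya_internal_bp = comp$polya_internal_bp,
      dual_polya = comp$class == "partnered" &&
        comp$polya_bp >= params$polya_limit &&
        comp$polya_internal_bp >= params$polya_limit,
      inversion = inv$present,
      inversion_bp_inner = if (inv$present) inv$breakpoints[1] else NA_integer_,
      inversion_bp_outer = if (inv$present) inv$breakpoints[2] else NA_integer_,
      source_id = asn$source_id, assign_status = asn$status,
      endpoint_offset = asn$endpoint_offset,
      endpoint_genomic = asn$endpoint_genomic,
      assign_margin = asn$margin,
      full_length = comp$total_bp > params$somatic_full_length_min,
      td_seq = comp$td_seq,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$proxy_reassigned <- FALSE
  out <- resolve_proxy(out, catalog)
  out$cascade_parent <- NA_character_
  out <- resolve_cascade(out, catalog, reference, params)
  out
}
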