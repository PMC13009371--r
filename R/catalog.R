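#' Count approximate genome-wide occurrences of a tag
#'
#' Counts the distinct reference loci, on both strands, where the tag
#' matches within `max_edits` insertions, deletions or substitutions.
#' Overlapping hits whose starts lie within one tag length of each other
#' collapse to a single locus, so tandem near-duplications are not
#' multiply counted. Tags occurring at more than `tag_max_genomic_hits`
#' loci are too repetitive for reliable detection and are excluded from
#' the catalog by [build_catalog()].
#'
#' @param tag the tag sequence (ACGTN alphabet).
#' @param reference reference genome (FASTA path, `DNAStringSet`, or named
#'   character vector).
#' @param max_edits maximum edit distance.
#' @return integer count of deduplicated loci.
#' @export
count_approximate_hits <- function(tag, reference,
                                   max_edits = pipeline_params()$tag_hit_max_edits) {
  stopifnot(nzchar(tag))
  ref <- as_reference(reference)
  taglen <- nchar(tag)
  total <- 0L
  for (chrom in names(ref)) {
    subject <- Biostrings::DNAString(ref[[chrom]])
    for (pat in c(tag, revcomp(tag))) {
      m <- Biostrings::matchPattern(pat, subject,
                                    max.mismatch = max_edits,
                                    with.indels = TRUE, fixed = TRUE)
      starts <- sort(unique(Biostrings::start(m)))
      if (length(starts)) {
        # collapse runs: greedy left-to-right within one tag length
        n <- 0L
        last <- -Inf
        for (s in starts) {
          if (s - last >= taglen) {
            n <- n + 1L
            last <- s
          }
        }
        total <- total + n
      }
    }
  }
  total
}

#' Find similar tag sites in the reference
#'
#' Records reference loci (both strands) matching the tag within
#' `max_mismatches` substitutions (Hamming distance, no indels). These
#' similar sites drive the repeat-exclusion filter: anchor clusters near a
#' similar site cannot be distinguished from mismapping and are discarded.
#' The source's own tag locus is excluded.
#'
#' @param tag the tag sequence.
#' @param reference as in [count_approximate_hits()].
#' @param max_mismatches maximum Hamming distance.
#' @param exclude optional list with `chrom` and `start` (0-based) of the
#'   tag's own locus to omit.
#' @return data.frame with `chrom`, `start` (0-based), `strand`.
#' @export
find_similar_sites <- function(tag, reference,
                               max_mismatches = pipeline_params()$similar_site_max_mismatches,
                               exclude = NULL) {
  ref <- as_reference(reference)
  out <- list()
  for (chrom in names(ref)) {
    subject <- Biostrings::DNAString(ref[[chrom]])
    for (strand in c("+", "-")) {
      pat <- if (strand == "+") tag else revcomp(tag)
      m <- Biostrings::matchPattern(pat, subject,
                                    max.mismatch = max_mismatches,
                                    with.indels = FALSE, fixed = TRUE)
      starts <- Biostrings::start(m) - 1L
      if (length(starts)) {
        out[[length(out) + 1L]] <- data.frame(
          chrom = chrom, start = starts, strand = strand,
          stringsAsFactors = FALSE)
      }
    }
  }
  sites <- if (length(out)) do.call(rbind, out) else
    data.frame(chrom = character(), start = integer(), strand = character(),
               stringsAsFactors = FALSE)
  if (!is.null(exclude)) {
    drop <- sites$chrom == exclude$chrom & sites$start == exclude$start &
      sites$strand == "+"
    # a minus-strand element's own tag matches as the reverse complement
    drop <- drop | (sites$chrom == exclude$chrom &
                      sites$start == exclude$start & sites$strand == "-")
    sites <- sites[!drop, , drop = FALSE]
  }
  rownames(sites) <- NULL
  sites
}

#' Annotate the internal PAS of an element
#'
#' Scans the final `internal_pas_window` (50) bp of the element sequence,
#' read on the element strand, and keeps the strongest-scoring hexamer at
#' or above the reporting floor. Where several candidates occur the
#' strongest wins.
#'
#' @param element_seq the element sequence in element orientation.
#' @param pwm a `pas_pwm` object.
#' @param params a [pipeline_params()] object.
#' @return list with `hexamer`, `score`, `position` (0-based offset of the
#'   hexamer start within the final window, measured from the window
#'   start), or `NULL` when nothing reaches the floor.
#' @export
annotate_internal_pas <- function(element_seq, pwm,
                                  params = pipeline_params()) {
  n <- nchar(element_seq)
  w <- min(params$internal_pas_window, n)
  if (w < pwm$width) return(NULL)
  tail_seq <- substr(element_seq, n - w + 1L, n)
  hits <- scan_sequence(pwm, tail_seq, min_report_score = params$pas_report_floor,
                        params = params)
  if (!nrow(hits)) return(NULL)
  j <- which.max(hits$score)
  list(hexamer = hits$hexamer[j], score = hits$score[j],
       position = hits$position[j])
}

#' Build the source-L1 catalog
#'
#' Builds one catalog row per annotated L1 element: strand-aware 30-bp tag
#' and downstream flank extraction, full-length classification
#' (5700-6700 bp), genome-wide tag uniqueness filtering (more than
#' `tag_max_genomic_hits` approximate hits excludes the element from tag
#' detection), similar-site recording at up to
#' `similar_site_max_mismatches` mismatches, and internal PAS annotation
#' over the final 50 bp. Elements failing the length bounds are retained
#' (they may act as proxies for non-reference sources) but never used for
#' tag detection.
#'
#' @param reference genome (FASTA path, `DNAStringSet`, or named character
#'   vector).
#' @param annotations data.frame with `chrom`, `start`, `end` (0-based
#'   half-open), `name`, `strand`, and optionally `provenance`,
#'   `allele_status`, `proxy_of`; or a BED6 file path.
#' @param extra_sources optional data.frame of supplemental sources with
#'   the same columns (e.g. reported polymorphic source elements).
#' @param params a [pipeline_params()] object.
#' @param pwm PAS matrix for internal-PAS annotation.
#' @return data.frame catalog; see Details for columns. `usable` marks
#'   elements eligible for tag-based detection.
#' @export
build_catalog <- function(reference, annotations, extra_sources = NULL,
                          params = pipeline_params(),
                          pwm = build_default_pwm()) {
  ref <- as_reference(reference)
  if (is.character(annotations) && length(annotations) == 1L) {
    annotations <- read_bed(annotations)
  }
  ann <- annotations
  for (col in c("provenance", "allele_status", "proxy_of")) {
    if (is.null(ann[[col]])) {
      ann[[col]] <- switch(col, provenance = "reference",
                           allele_status = "fixed", proxy_of = NA_character_)
    }
  }
  if (is.null(ann$downstream_seq)) ann$downstream_seq <- NA_character_
  if (!is.null(extra_sources)) {
    for (col in c("provenance", "allele_status", "proxy_of")) {
      if (is.null(extra_sources[[col]])) {
        extra_sources[[col]] <- switch(col, provenance = "polymorphic",
                                       allele_status = "polymorphic",
                                       proxy_of = NA_character_)
      }
    }
    if (is.null(extra_sources$downstream_seq)) {
      extra_sources$downstream_seq <- NA_character_
    }
    cols <- c("chrom", "start", "end", "name", "strand", "provenance",
              "allele_status", "proxy_of", "downstream_seq")
    ann <- rbind(ann[, cols], extra_sources[, cols])
  }
  taglen <- params$tag_length
  flanklen <- params$source_window + 50L
  rows <- lapply(seq_len(nrow(ann)), function(i) {
    a <- ann[i, ]
    if (is.na(a$chrom)) {
      # non-reference (polymorphic) source: catalogued by id only, with an
      # externally supplied downstream sequence when available
      ds <- if (!is.null(a$downstream_seq) && !is.na(a$downstream_seq))
        a$downstream_seq else ""
      pas <- if (nzchar(ds)) NULL else NULL
      return(data.frame(
        source_id = a$name, chrom = NA_character_, start = NA_integer_,
        end = NA_integer_, strand = a$strand, length = NA_integer_,
        is_full_length = NA, provenance = a$provenance,
        allele_status = a$allele_status, tag = NA_character_,
        downstream_seq = ds, tag_genomic_hit_count = NA_integer_,
        usable = FALSE, n_similar_sites = 0L, similar_sites = "",
        internal_pas_hexamer = NA_character_, internal_pas_score = NA_real_,
        internal_pas_position = NA_integer_, proxy_of = a$proxy_of,
        stringsAsFactors = FALSE))
    }
    if (!a$chrom %in% names(ref)) {
      stop("annotation '", a$name, "': unknown chromosome ", a$chrom)
    }
    chromseq <- ref[[a$chrom]]
    clen <- nchar(chromseq)
    if (a$start < 0 || a$end > clen || a$start >= a$end) {
      stop("annotation '", a$name, "': interval out of reference bounds")
    }
    len <- a$end - a$start
    is_fl <- len >= params$full_length_min & len <= params$full_length_max
    truncated_flank <- FALSE
    if (a$strand == "+") {
      tag_avail <- a$end + taglen <= clen
      tag <- if (tag_avail) substr(chromseq, a$end + 1L, a$end + taglen)
        else NA_character_
      down_end <- min(a$end + flanklen, clen)
      downstream <- if (a$end < clen)
        substr(chromseq, a$end + 1L, down_end) else ""
      truncated_flank <- (down_end - a$end) < flanklen
      element_seq <- substr(chromseq, a$start + 1L, a$end)
      tag_locus_start <- a$end
    } else {
      tag_avail <- a$start - taglen >= 0
      tag <- if (tag_avail)
        revcomp(substr(chromseq, a$start - taglen + 1L, a$start))
        else NA_character_
      down_start <- max(a$start - flanklen, 0L)
      downstream <- if (a$start > 0)
        revcomp(substr(chromseq, down_start + 1L, a$start)) else ""
      truncated_flank <- (a$start - down_start) < flanklen
      element_seq <- revcomp(substr(chromseq, a$start + 1L, a$end))
      tag_locus_start <- a$start - taglen
    }
    has_n <- !is.na(tag) && grepl("N", tag, fixed = TRUE)
    hit_count <- NA_integer_
    sim_str <- ""
    n_sim <- 0L
    usable <- is_fl && !is.na(tag) && !has_n && !truncated_flank
    if (usable) {
      hit_count <- count_approximate_hits(tag, ref, params$tag_hit_max_edits)
      if (hit_count > params$tag_max_genomic_hits) usable <- FALSE
      sites <- find_similar_sites(
        tag, ref, params$similar_site_max_mismatches,
        exclude = list(chrom = a$chrom, start = tag_locus_start))
      n_sim <- nrow(sites)
      if (n_sim) {
        sim_str <- paste(sprintf("%s:%d:%s", sites$chrom, sites$start,
                                 sites$strand), collapse = ";")
      }
    }
    pas <- annotate_internal_pas(element_seq, pwm, params)
    data.frame(
      source_id = a$name, chrom = a$chrom, start = a$start, end = a$end,
      strand = a$strand, length = len, is_full_length = is_fl,
      provenance = a$provenance, allele_status = a$allele_status,
      tag = tag, downstream_seq = downstream,
      tag_genomic_hit_count = hit_count, usable = usable,
      n_similar_sites = n_sim, similar_sites = sim_str,
      internal_pas_hexamer = if (is.null(pas)) NA_character_ else pas$hexamer,
      internal_pas_score = if (is.null(pas)) NA_real_ else pas$score,
      internal_pas_position = if (is.null(pas)) NA_integer_ else pas$position,
      proxy_of = a$proxy_of,
      stringsAsFactors = FALSE
    )
  })
  cat_df <- do.call(rbind, rows)
  rownames(cat_df) <- NULL
  cat_df
}

# parse the serialized similar-site string back to a data.frame
parse_similar_sites <- function(sim_str) {
  if (is.na(sim_str) || !nzchar(sim_str)) {
    return(data.frame(chrom = character(), start = integer(),
                      strand = character(), stringsAsFactors = FALSE))
  }
  parts <- strsplit(strsplit(sim_str, ";", fixed = TRUE)[[1]], ":",
                    fixed = TRUE)
  data.frame(
    chrom = vapply(parts, `[`, character(1), 1L),
    start = as.integer(vapply(parts, `[`, character(1), 2L)),
    strand = vapply(parts, `[`, character(1), 3L),
    stringsAsFactors = FALSE
  )
}

#' Read a BED6 file of L1 annotations
#'
#' @param path BED file (0-based half-open, name and strand columns used).
#' @return data.frame with `chrom`, `start`, `end`, `name`, `strand`.
#' @export
read_bed <- function(path) {
  bed <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE)
  if (ncol(bed) < 6) stop("BED6 required: chrom,start,end,name,score,strand")
  data.frame(chrom = bed[[1]], start = bed[[2]], end = bed[[3]],
             name = bed[[4]], strand = bed[[6]], stringsAsFactors = FALSE)
}

#' Write the catalog as TSV
#'
#' Loci are emitted 1-based inclusive (`start_1` = internal start + 1).
#'
#' @param catalog catalog data.frame from [build_catalog()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_catalog <- function(catalog, path) {
  out <- catalog
  out$start <- out$start + 1L
  names(out)[names(out) == "start"] <- "start_1"
  names(out)[names(out) == "end"] <- "end_1"
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a catalog TSV written by [write_catalog()]
#'
#' @param path input path.
#' @return catalog data.frame with internal 0-based half-open loci.
#' @export
read_catalog <- function(path) {
  x <- utils::read.table(path, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE, na.strings = "NA")
  x$start_1 <- x$start_1 - 1L
  names(x)[names(x) == "start_1"] <- "start"
  names(x)[names(x) == "end_1"] <- "end"
  x$similar_sites[is.na(x$similar_sites)] <- ""
  x
}
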