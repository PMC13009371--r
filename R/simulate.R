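#' Packaged synthetic L1 consensus sequence
#'
#' Returns the ~6-kb synthetic consensus shipped with the package. It is a
#' deterministic synthetic stand-in with the structural properties the
#' pipeline relies on - homopolymer runs capped below the polyA detection
#' limit, a single canonical AATAAA in the final 50 bp acting as the
#' internal PAS - and carries no biological L1 sequence.
#'
#' @return a single character string.
#' @export
l1_consensus <- function() {
  path <- system.file("extdata", "l1_consensus_synthetic.fa",
                      package = "retrotag")
  unname(as_reference(path))
}

#' Simulation configuration
#'
#' Defines the synthetic study the generator emulates. The defaults are
#' the package's fixed study conditions: a 3-Mb genome (3 chromosomes of
#' 1 Mb) carrying 5 full-length source elements whose relative activities,
#' modal transduction lengths and 5' inversion rates follow the most
#' active sources of a typical colorectal-cancer cohort; 4 tumor samples
#' plus 1 insertion-free normal; ~44 somatic insertions per tumor of which
#' 23% are transductions (the fraction of somatic L1 insertions with
#' traceable transductions); 80% of transduction endpoints terminating
#' 10-30 bp downstream of a planted PAS; TPRT hallmarks with TSD length
#' uniform on 5-20 bp, polyA length uniform on 10-60 bp, and 90% of
#' integration sites at a planted endonuclease consensus; 2x150 bp read
#' pairs at 30x depth with insert size 400 +/- 50 bp; and promoter
#' methylation drawn from Beta distributions with mean 35% at sample-wise
#' active promoters vs 75% at inactive ones (sd 10 points).
#'
#' @param seed integer seed governing every generator stage.
#' @param ... named overrides of any default field.
#' @return an object of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1L, ...) {
  defaults <- list(
    seed = as.integer(seed),
    n_chromosomes = 3L,
    chrom_length = 1000000L,
    l1_consensus = NULL,           # filled from the packaged fixture
    n_sources = 5L,
    source_strands = c("+", "+", "-", "+", "+"),
    activity_weights = c(78, 72, 34, 24, 18),
    length_modes = list(78L, 337L, 818L, 861L, 72L),
    mode_weights = list(1, 1, 1, 1, 1),
    geom_tail_mean = 200,
    inversion_rates = c(0.06, 0.12, 0.15, 0.32, 0.22),
    inversion_bp_mean = 250,
    inversion_bp_sd = 30,
    n_tumor = 4L,
    n_normal = 1L,
    insertions_per_sample = 44,
    frac_transduction = 0.23,
    frac_orphan = 0.25,
    frac_pas_terminated = 0.8,
    frac_mode_exact = 0.6,
    dual_polya_rate = 0.5,
    frac_full_length = 0.005,
    l1_truncation_mean = 300,
    tsd_range = c(5L, 20L),
    polya_range = c(10L, 60L),
    en_site_fraction = 0.9,
    n_en_sites = 600L,
    read_length = 150L,
    insert_mean = 400,
    insert_sd = 50,
    depth = 30,
    basecall_error = 0.01,
    meth_active_mean = 0.35,
    meth_inactive_mean = 0.75,
    meth_sd = 0.10,
    meth_coverage_mean = 20,
    min_insertion_spacing = 5000L,
    include_proxy = FALSE,
    include_cascade = FALSE
  )
  overrides <- list(...)
  bad <- setdiff(names(overrides), names(defaults))
  if (length(bad)) stop("unknown config field(s): ", paste(bad, collapse = ", "))
  defaults[names(overrides)] <- overrides
  cfg <- defaults
  if (is.null(cfg$l1_consensus)) cfg$l1_consensus <- l1_consensus()
  fracs <- c(cfg$frac_transduction, cfg$frac_orphan, cfg$frac_pas_terminated,
             cfg$frac_mode_exact, cfg$dual_polya_rate, cfg$frac_full_length,
             cfg$en_site_fraction, cfg$basecall_error,
             cfg$meth_active_mean, cfg$meth_inactive_mean)
  if (any(fracs < 0 | fracs > 1)) stop("all fractions must lie in [0, 1]")
  if (cfg$chrom_length <= 10 * nchar(cfg$l1_consensus)) {
    stop("chrom_length must exceed 10x the L1 consensus length")
  }
  structure(cfg, class = "simulation_config")
}

# remove strong PAS-like hexamers from a sequence (transcript direction)
scrub_pas <- function(s) {
  for (pat in c("AATAAA", "ATTAAA")) {
    repeat {
      p <- regexpr(pat, s, fixed = TRUE)
      if (p < 0) break
      substr(s, p + 2L, p + 2L) <- "G"
    }
  }
  s
}

#' Simulate the reference genome with planted source L1s
#'
#' Generates i.i.d. background DNA, plants one full consensus L1 copy per
#' source with a clean downstream flank (strong PAS hexamers scrubbed from
#' the background, then the configured PAS placements planted at offsets
#' `mode - 21` so that endpoints drawn 10-30 bp downstream of the PAS
#' reproduce the configured modal transduction lengths), and scatters
#' endonuclease consensus sites (TTTTAA) across the genome as candidate
#' integration targets. Optionally plants a truncated proxy element whose
#' downstream flank carries the transduced sequence of a non-reference
#' polymorphic source. Fully deterministic under `cfg$seed`.
#'
#' @param cfg a [simulation_config()].
#' @return list with `reference` (named character vector), `sources`
#'   (data.frame incl. per-source simulation truth), `bed` (annotation
#'   data.frame for [build_catalog()]), `en_sites` (planted EN junctions),
#'   and `cfg`.
#' @export
simulate_reference <- function(cfg) {
  set.seed(cfg$seed)
  cons <- cfg$l1_consensus
  L <- nchar(cons)
  chroms <- paste0("chr", seq_len(cfg$n_chromosomes))
  reference <- vapply(chroms, function(ch) random_dna(cfg$chrom_length),
                      character(1))
  flank <- 3050L
  slots_per_chrom <- ceiling(cfg$n_sources / cfg$n_chromosomes)
  usable_span <- cfg$chrom_length - 2L * (L + flank + 2000L)
  if (usable_span < (slots_per_chrom - 1) * (L + flank + 20000L)) {
    stop("layout error: sources would overlap; increase chrom_length")
  }
  empty_sources <- data.frame(
    source_id = character(), chrom = character(), start = integer(),
    end = integer(), strand = character(), activity_weight = numeric(),
    inversion_rate = numeric(), pas_offsets = character(),
    modes = character(), downstream_seq = character(),
    proxy_of = character(), in_reference = logical(),
    stringsAsFactors = FALSE)
  src_rows <- list()
  occupied <- list(data.frame(chrom = character(), lo = integer(),
                              hi = integer(), stringsAsFactors = FALSE))
  for (i in seq_len(cfg$n_sources)) {
    ch_idx <- ((i - 1L) %% cfg$n_chromosomes) + 1L
    slot <- (i - 1L) %/% cfg$n_chromosomes
    ch <- chroms[ch_idx]
    start0 <- 150000L + slot * 450000L   # 0-based element start
    strand <- cfg$source_strands[i]
    end0 <- start0 + L
    if (start0 - flank - 2000L < 0L || end0 + flank + 2000L > cfg$chrom_length) {
      stop("layout error: source ", i, " does not fit; increase chrom_length")
    }
    seqchr <- reference[[ch]]
    modes <- cfg$length_modes[[i]]
    pas_offsets <- sort(unique(pmax(modes - 21L, 1L)))
    if (strand == "+") {
      substr(seqchr, start0 + 1L, end0) <- cons
      down <- substr(seqchr, end0 + 1L, end0 + flank)
      down <- scrub_pas(down)
      for (o in pas_offsets) substr(down, o + 1L, o + 6L) <- "AATAAA"
      substr(seqchr, end0 + 1L, end0 + flank) <- down
    } else {
      substr(seqchr, start0 + 1L, end0) <- revcomp(cons)
      down <- revcomp(substr(seqchr, start0 - flank + 1L, start0))
      down <- scrub_pas(down)
      for (o in pas_offsets) substr(down, o + 1L, o + 6L) <- "AATAAA"
      substr(seqchr, start0 - flank + 1L, start0) <- revcomp(down)
    }
    reference[[ch]] <- seqchr
    src_rows[[i]] <- data.frame(
      source_id = sprintf("src%02d", i), chrom = ch, start = start0,
      end = end0, strand = strand,
      activity_weight = cfg$activity_weights[i],
      inversion_rate = cfg$inversion_rates[i],
      pas_offsets = paste(pas_offsets, collapse = ","),
      modes = paste(modes, collapse = ","),
      downstream_seq = down, proxy_of = NA_character_,
      in_reference = TRUE, stringsAsFactors = FALSE)
    occupied[[length(occupied) + 1L]] <-
      data.frame(chrom = ch, lo = start0 - flank - 2000L,
                 hi = end0 + flank + 2000L)
  }
  sources <- if (length(src_rows)) do.call(rbind, src_rows) else empty_sources

  if (cfg$include_proxy) {
    # truncated reference element whose flank is the transduced sequence of
    # a polymorphic source absent from the reference
    ch <- chroms[cfg$n_chromosomes]
    start0 <- cfg$chrom_length - 120000L
    trunc_len <- 2000L
    end0 <- start0 + trunc_len
    seqchr <- reference[[ch]]
    substr(seqchr, start0 + 1L, end0) <-
      substr(cons, L - trunc_len + 1L, L)
    down <- scrub_pas(substr(seqchr, end0 + 1L, end0 + flank))
    for (o in c(200L, 800L)) substr(down, o + 1L, o + 6L) <- "AATAAA"
    substr(seqchr, end0 + 1L, end0 + flank) <- down
    reference[[ch]] <- seqchr
    sources <- rbind(
      sources,
      data.frame(source_id = "proxy01", chrom = ch, start = start0,
                 end = end0, strand = "+", activity_weight = 10,
                 inversion_rate = 0.1,
                 pas_offsets = "200,800", modes = "300",
                 downstream_seq = down, proxy_of = NA_character_,
                 in_reference = TRUE, stringsAsFactors = FALSE),
      data.frame(source_id = "polysrc01", chrom = NA_character_,
                 start = NA_integer_, end = NA_integer_, strand = "+",
                 activity_weight = 0, inversion_rate = 0,
                 pas_offsets = "200,800", modes = "300",
                 downstream_seq = down, proxy_of = NA_character_,
                 in_reference = FALSE, stringsAsFactors = FALSE))
    sources$proxy_of[sources$source_id == "proxy01"] <- "polysrc01"
    occupied[[length(occupied) + 1L]] <-
      data.frame(chrom = ch, lo = start0 - 2000L, hi = end0 + flank + 2000L)
  }

  occupied <- do.call(rbind, occupied)
  # scatter endonuclease consensus target sites outside occupied regions;
  # plus-orientation insertions use a plus-strand TTTT/AA nick (junction
  # after the TTTT), minus-orientation ones its reverse complement TT/AAAA
  en_rows <- list()
  per_chrom <- ceiling(cfg$n_en_sites / cfg$n_chromosomes)
  for (ch in chroms) {
    occ <- occupied[occupied$chrom == ch, , drop = FALSE]
    pos <- sort(sample.int(cfg$chrom_length - 20000L, per_chrom * 5L) + 10000L)
    free <- rep(TRUE, length(pos))
    for (j in seq_len(nrow(occ))) {
      free <- free & !(pos >= occ$lo[j] & pos <= occ$hi[j])
    }
    pos <- pos[free]
    pos <- utils::head(pos[c(TRUE, diff(pos) > 1000L)], per_chrom)
    orient <- rep_len(c("+", "-"), length(pos))
    seqchr <- reference[[ch]]
    for (j in seq_along(pos)) {
      p <- pos[j]
      motif <- if (orient[j] == "+") "TTTTAA" else "TTAAAA"
      substr(seqchr, p + 1L, p + 6L) <- motif
    }
    reference[[ch]] <- seqchr
    junction <- ifelse(orient == "+", pos + 4L, pos + 2L)
    en_rows[[ch]] <- data.frame(chrom = ch, junction = junction,
                                site_orient = orient,
                                stringsAsFactors = FALSE)
  }
  en_sites <- do.call(rbind, en_rows)
  rownames(en_sites) <- NULL

  ref_src <- sources[sources$in_reference, , drop = FALSE]
  bed <- data.frame(chrom = ref_src$chrom, start = ref_src$start,
                    end = ref_src$end, name = ref_src$source_id,
                    strand = ref_src$strand,
                    proxy_of = ref_src$proxy_of,
                    stringsAsFactors = FALSE)
  list(reference = reference, sources = sources, bed = bed,
       en_sites = en_sites, cfg = cfg)
}

# draw one transduction endpoint (bp of downstream sequence transduced)
draw_td_length <- function(cfg, src) {
  offsets <- as.integer(strsplit(src$pas_offsets, ",")[[1]])
  if (stats::runif(1) < cfg$frac_pas_terminated) {
    o <- if (length(offsets) > 1L) sample(offsets, 1L) else offsets
    d <- if (stats::runif(1) < cfg$frac_mode_exact) 21L
         else sample(10:30, 1L)
    o + d
  } else {
    repeat {
      e <- 50L + stats::rgeom(1L, 1 / cfg$geom_tail_mean)
      e <- min(e, 2900L)
      if (!any(e - offsets >= 0L & e - offsets <= 40L)) return(e)
    }
  }
}

#' Simulate the somatic insertion truth set
#'
#' Draws per-sample insertion counts, classes (solo / partnered / orphan),
#' source attributions, TPRT hallmarks and 5' inversions, and constructs
#' each inserted sequence from its components. Transduction endpoints
#' terminate 10-30 bp downstream of a planted PAS with probability
#' `frac_pas_terminated`, otherwise on a geometric tail kept clear of
#' planted signals. Integration sites fall on planted endonuclease
#' consensus sites with probability `en_site_fraction`. With
#' `include_cascade`, a germline transduction is planted and one somatic
#' insertion is mobilized from it, retaining both the original source tag
#' and the germline insertion's flanking sequence.
#'
#' @param cfg a [simulation_config()].
#' @param sim_ref output of [simulate_reference()].
#' @return data.frame of truth records (one per insertion).
#' @export
simulate_insertions <- function(cfg, sim_ref) {
  set.seed(cfg$seed + 1L)
  cons <- cfg$l1_consensus
  L <- nchar(cons)
  sources <- sim_ref$sources
  active_src <- sources[sources$activity_weight > 0, , drop = FALSE]
  reference <- sim_ref$reference
  tumors <- paste0("T", seq_len(cfg$n_tumor))
  en_pool <- sim_ref$en_sites
  en_pool$used <- FALSE
  used_chrom <- character(0)
  used_pos <- integer(0)
  ref_src <- sources[sources$in_reference, , drop = FALSE]

  min_dist_ok <- function(chrom, pos) {
    if (any(used_chrom == chrom &
              abs(used_pos - pos) < cfg$min_insertion_spacing)) {
      return(FALSE)
    }
    near <- ref_src$chrom == chrom & pos > ref_src$start - 8000L &
      pos < ref_src$end + 8000L
    !any(near, na.rm = TRUE)
  }

  pick_site <- function(chrom_names, orientation) {
    if (stats::runif(1) < cfg$en_site_fraction) {
      avail <- which(!en_pool$used & en_pool$site_orient == orientation)
      for (k in avail[sample.int(length(avail))]) {
        if (min_dist_ok(en_pool$chrom[k], en_pool$junction[k])) {
          en_pool$used[k] <<- TRUE
          return(list(chrom = en_pool$chrom[k], junction = en_pool$junction[k],
                      at_en = TRUE))
        }
      }
    }
    for (try in 1:200) {
      ch <- sample(chrom_names, 1L)
      p <- sample.int(cfg$chrom_length - 20000L, 1L) + 10000L
      if (min_dist_ok(ch, p)) {
        return(list(chrom = ch, junction = p, at_en = FALSE))
      }
    }
    stop("could not place insertion after bounded retries")
  }

  rows <- list()
  make_insertion <- function(sample_id, idx, label, forced = list()) {
    cls <- forced$class %||% {
      if (stats::runif(1) < cfg$frac_transduction) {
        if (stats::runif(1) < cfg$frac_orphan) "orphan" else "partnered"
      } else "solo"
    }
    src <- if (cls == "solo") NULL else {
      j <- sample(nrow(active_src), 1L, prob = active_src$activity_weight)
      active_src[j, ]
    }
    if (!is.null(forced$source_id)) {
      src <- sources[sources$source_id == forced$source_id, ]
    }
    orientation <- forced$orientation %||% sample(c("+", "-"), 1L)
    site <- pick_site(names(reference), orientation)
    used_chrom[length(used_chrom) + 1L] <<- site$chrom
    used_pos[length(used_pos) + 1L] <<- site$junction
    tsd <- sample(cfg$tsd_range[1]:cfg$tsd_range[2], 1L)
    polya_bp <- sample(cfg$polya_range[1]:cfg$polya_range[2], 1L)

    l1_bp <- 0L
    inv_bp <- NA_character_
    inverted <- FALSE
    if (cls %in% c("solo", "partnered")) {
      l1_bp <- if (stats::runif(1) < cfg$frac_full_length) L else
        min(L, 50L + stats::rgeom(1L, 1 / cfg$l1_truncation_mean))
      inv_rate <- if (is.null(src)) mean(cfg$inversion_rates) else
        src$inversion_rate
      if (stats::runif(1) < inv_rate) {
        d_inner <- max(30L, round(stats::rnorm(1, cfg$inversion_bp_mean,
                                               cfg$inversion_bp_sd)))
        d_outer <- d_inner + 50L + sample(0:100, 1L)
        if (d_outer < L - 10L) {
          inverted <- TRUE
          l1_bp <- max(l1_bp, d_outer)
          l1_bp <- min(l1_bp, L)
          inv_bp <- paste(d_inner, d_outer, sep = ",")
        }
      }
    }
    td_bp <- 0L
    if (cls != "solo") td_bp <- forced$td_bp %||% draw_td_length(cfg, src)

    # assemble inserted sequence on the element strand
    l1_seq <- ""
    if (l1_bp > 0L) {
      if (inverted) {
        d <- as.integer(strsplit(inv_bp, ",")[[1]])
        fwd5 <- if (l1_bp > d[2]) substr(cons, L - l1_bp + 1L, L - d[2]) else ""
        invseg <- revcomp(substr(cons, L - d[2] + 1L, L - d[1]))
        fwd3 <- substr(cons, L - d[1] + 1L, L)
        l1_seq <- paste0(fwd5, invseg, fwd3)
      } else {
        l1_seq <- substr(cons, L - l1_bp + 1L, L)
      }
    }
    int_pa_bp <- 0L
    if (cls == "partnered" && stats::runif(1) < cfg$dual_polya_rate) {
      int_pa_bp <- sample(10:30, 1L)
    }
    td_seq <- if (td_bp > 0L) {
      ds <- forced$td_seq %||% src$downstream_seq
      substr(ds, 1L, td_bp)
    } else ""
    ins_seq <- paste0(l1_seq, strrep("A", int_pa_bp), td_seq,
                      strrep("A", polya_bp))

    # the EN nick is the initial breakpoint: the later one for plus
    # orientation, the earlier one for minus
    bp_a <- if (orientation == "+") site$junction - tsd else site$junction
    bp_b <- bp_a + tsd
    en_flank_truth <- extract_en_flank(reference[[site$chrom]], bp_a, bp_b,
                                       orientation)
    data.frame(
      insertion_id = sprintf("%s_ins%03d", sample_id, idx),
      sample = sample_id, chrom = site$chrom, pos = bp_a,
      source_id = if (is.null(src)) NA_character_ else src$source_id,
      class = cls, inserted_seq = ins_seq,
      l1_bp = if (l1_bp > 0L) nchar(l1_seq) else 0L,
      transduction_bp = td_bp, polya_bp = polya_bp,
      polya_internal_bp = int_pa_bp, tsd_length = tsd,
      en_flank = en_flank_truth, at_en_site = site$at_en,
      orientation = orientation, inversion_breakpoints = inv_bp,
      inverted = inverted, label = label,
      cascade_parent = forced$cascade_parent %||% NA_character_,
      stringsAsFactors = FALSE)
  }

  for (s in tumors) {
    n <- stats::rpois(1L, cfg$insertions_per_sample)
    for (i in seq_len(n)) {
      rows[[length(rows) + 1L]] <- make_insertion(s, i, "somatic")
    }
  }

  if (cfg$include_cascade) {
    src1 <- active_src[1, ]
    parent <- make_insertion("germline", 1L, "germline",
                             forced = list(class = "partnered",
                                           source_id = src1$source_id,
                                           td_bp = 200L,
                                           orientation = "+"))
    rows[[length(rows) + 1L]] <- parent
    # child reads through the germline insertion: it carries the parent's
    # transduced sequence (incl. the original source tag) plus the parent's
    # genomic flank (the second, intermediate tag)
    parent_flank <- substr(reference[[parent$chrom]],
                           parent$pos + parent$tsd_length + 1L,
                           parent$pos + parent$tsd_length + 60L)
    child_td <- paste0(substr(src1$downstream_seq, 1L, 200L),
                       strrep("A", 15L), parent_flank)
    child <- make_insertion("T1", 990L, "somatic",
                            forced = list(class = "partnered",
                                          source_id = src1$source_id,
                                          td_bp = nchar(child_td),
                                          td_seq = child_td,
                                          cascade_parent =
                                            parent$insertion_id))
    rows[[length(rows) + 1L]] <- child
  }

  truth <- do.call(rbind, rows)
  rownames(truth) <- NULL
  truth
}

#' Simulate reconstructed long-read insertion sequences
#'
#' Emits each truth record's inserted sequence with i.i.d. substitution
#' noise at `error` (emulating reconstructed insertion sequences from
#' long-read SV calling), keyed by insertion id.
#'
#' @param cfg a [simulation_config()].
#' @param truth output of [simulate_insertions()].
#' @param error substitution rate (defaults to `cfg$basecall_error`).
#' @return data.frame with `insertion_id`, `sample`, `chrom`, `pos`,
#'   `label`, `seq`.
#' @export
simulate_longread_calls <- function(cfg, truth, error = cfg$basecall_error) {
  set.seed(cfg$seed + 2L)
  if (!nrow(truth)) {
    return(data.frame(insertion_id = character(), sample = character(),
                      chrom = character(), pos = integer(),
                      label = character(), seq = character(),
                      stringsAsFactors = FALSE))
  }
  bases <- c("A", "C", "G", "T")
  seqs <- vapply(truth$inserted_seq, function(s) {
    if (error <= 0) return(s)
    n <- nchar(s)
    k <- stats::rbinom(1L, n, error)
    if (k == 0L) return(s)
    pos <- sample.int(n, k)
    ch <- strsplit(s, "", fixed = TRUE)[[1]]
    for (p in pos) ch[p] <- sample(setdiff(bases, ch[p]), 1L)
    paste(ch, collapse = "")
  }, character(1), USE.NAMES = FALSE)
  data.frame(insertion_id = truth$insertion_id, sample = truth$sample,
             chrom = truth$chrom, pos = truth$pos, label = truth$label,
             seq = seqs, stringsAsFactors = FALSE)
}

#' Simulate per-CpG promoter methylation tables
#'
#' Enumerates CpG dinucleotides in the 200-bp window around each reference
#' source element's 5' end and draws, per sample, coverage (Poisson) and a
#' methylated fraction from a Beta distribution whose mean is
#' `meth_active_mean` when the element produced transductions in that
#' sample and `meth_inactive_mean` otherwise.
#'
#' @param cfg a [simulation_config()].
#' @param sim_ref output of [simulate_reference()].
#' @param truth output of [simulate_insertions()] (defines per-sample
#'   activity); may be `NULL` for all-inactive promoters.
#' @param samples character vector of sample ids (defaults to the
#'   configured tumors and normals).
#' @return data.frame with `sample`, `chrom`, `pos` (0-based position of
#'   the CpG C), `coverage`, `methylated_fraction`.
#' @export
simulate_methylation <- function(cfg, sim_ref, truth = NULL,
                                 samples = NULL) {
  set.seed(cfg$seed + 3L)
  if (is.null(samples)) {
    samples <- c(paste0("T", seq_len(cfg$n_tumor)),
                 paste0("N", seq_len(cfg$n_normal)))
  }
  beta_draw <- function(n, m, s) {
    v <- s^2
    k <- m * (1 - m) / v - 1
    stats::rbeta(n, m * k, (1 - m) * k)
  }
  src <- sim_ref$sources[sim_ref$sources$in_reference, , drop = FALSE]
  rows <- list()
  for (i in seq_len(nrow(src))) {
    five_prime <- if (src$strand[i] == "-") src$end[i] else src$start[i]
    lo <- five_prime - 100L
    hi <- five_prime + 100L
    win <- substr(sim_ref$reference[[src$chrom[i]]], lo + 1L, hi)
    cg <- gregexpr("CG", win, fixed = TRUE)[[1]]
    if (cg[1] < 0) next
    cpg_pos <- lo + cg - 1L     # 0-based position of the C
    for (s in samples) {
      active <- !is.null(truth) && !is.na(src$source_id[i]) &&
        any(truth$sample == s & !is.na(truth$source_id) &
              truth$source_id == src$source_id[i] &
              truth$class != "solo")
      m <- if (active) cfg$meth_active_mean else cfg$meth_inactive_mean
      rows[[length(rows) + 1L]] <- data.frame(
        sample = s, chrom = src$chrom[i], pos = cpg_pos,
        coverage = stats::rpois(length(cpg_pos), cfg$meth_coverage_mean) + 1L,
        methylated_fraction = beta_draw(length(cpg_pos), m, cfg$meth_sd),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
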