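#' Pipeline parameter set
#'
#' Every tunable constant of the transduction-detection pipeline lives in a
#' single `pipeline_params` object so that each stage is driven by an
#' explicit, serializable configuration rather than scattered magic numbers.
#'
#' The defaults encode the operating point of the published tag-based
#' detection procedure: 30-bp source tags, a genome-wide uniqueness filter
#' discarding tags found at more than 1000 locations within edit distance 3,
#' similar-site recording at up to 6 mismatches, anchor reads at MAPQ >= 37
#' clustered within 1 kbp, calls requiring >= 3 supporting reads and no
#' similar tag sequence within 2 kbp, polyA sweep-line scoring (+1/-3,
#' detection limit 10), the endonuclease cut-site consensus TTTT/AA with
#' positional weights 1,1,3,4,1,1 and acceptance score >= 6, source
#' assignment within 3 kbp of an element 3' end, full-length bounds
#' 5700-6700 bp (somatic full-length strictly > 5990 bp), PAS strength
#' thresholds (> 8.1 strong, < 8 weak) with the canonical 10-30 bp
#' endpoint window, a rectangular inversion-clustering kernel of bandwidth
#' 10 bp, and promoter methylation aggregation over a 200-bp window with
#' CpG coverage 3-75.
#'
#' Thresholds printed with a strict operator are strict here as well:
#' `pas_strong_threshold` and `somatic_full_length_min` are exclusive
#' bounds, while `anchor_min_mapq`, `cluster_min_reads`, `en_min_score`
#' and `meth_min_cpgs` are inclusive.
#'
#' @param ... named overrides of any default field.
#' @return An object of class `pipeline_params` (a validated named list).
#' @examples
#' p <- pipeline_params()
#' p$tag_length
#' p2 <- pipeline_params(tag_length = 25)
#' @export
pipeline_params <- function(...) {
  defaults <- list(
    tag_length = 30L,
    tag_max_genomic_hits = 1000L,
    tag_hit_max_edits = 3L,
    similar_site_max_mismatches = 6L,
    anchor_min_mapq = 37L,
    anchor_cluster_gap = 1000L,
    cluster_min_reads = 3L,
    repeat_exclusion_dist = 2000L,
    cross_sample_merge_dist = 2000L,
    characterization_window = 500L,
    discordant_min_insert = 2000L,
    min_clip_len = 10L,
    polya_match = 1L,
    polya_mismatch = -3L,
    polya_limit = 10L,
    en_weights = c(1L, 1L, 3L, 4L, 1L, 1L),
    en_consensus = "TTTTAA",
    en_min_score = 6L,
    source_window = 3000L,
    full_length_min = 5700L,
    full_length_max = 6700L,
    somatic_full_length_min = 5990L,
    pas_strong_threshold = 8.1,
    pas_weak_threshold = 8,
    pas_report_floor = 0,
    pas_endpoint_window = c(10L, 30L),
    internal_pas_window = 50L,
    max_tag_mismatches = 0L,
    min_l1_identity = 0.8,
    min_l1_match_len = 30L,
    min_transduction_len = 10L,
    assign_margin = 5,
    inversion_bandwidth = 10L,
    meth_window_halfwidth = 100L,
    meth_cov_min = 3L,
    meth_cov_max = 75L,
    meth_min_cpgs = 3L,
    meth_min_sample_frac = 0.75,
    activity_active_min_samples = 4L,
    activity_minor_range = c(1L, 3L)
  )
  overrides <- list(...)
  if (length(overrides)) {
    bad <- setdiff(names(overrides), names(defaults))
    if (length(bad)) {
      stop("unknown parameter(s): ", paste(bad, collapse = ", "))
    }
    for (k in names(overrides)) {
      v <- overrides[[k]]
      if (is.numeric(defaults[[k]]) && !is.numeric(v)) {
        stop("parameter '", k, "' must be numeric")
      }
      if (is.integer(defaults[[k]])) v <- as.integer(round(v))
      defaults[[k]] <- v
    }
  }
  p <- structure(defaults, class = "pipeline_params")
  validate_params(p)
  p
}

#' Validate a pipeline parameter set
#'
#' Checks internal consistency: positivity of counts and lengths, the
#' negative polyA mismatch penalty, ordering of the full-length bounds,
#' ordering of the PAS thresholds, and ordered range pairs.
#'
#' @param p a `pipeline_params` object.
#' @return `p`, invisibly; errors with the offending field name otherwise.
#' @export
validate_params <- function(p) {
  stopifnot(inherits(p, "pipeline_params"))
  pos_fields <- c(
    "tag_length", "tag_max_genomic_hits", "anchor_cluster_gap",
    "cluster_min_reads", "repeat_exclusion_dist", "cross_sample_merge_dist",
    "characterization_window", "discordant_min_insert", "min_clip_len",
    "polya_match", "polya_limit", "en_min_score", "source_window",
    "full_length_min", "full_length_max", "somatic_full_length_min",
    "internal_pas_window", "inversion_bandwidth", "meth_window_halfwidth",
    "meth_cov_min", "meth_cov_max", "meth_min_cpgs",
    "activity_active_min_samples"
  )
  for (f in pos_fields) {
    if (any(p[[f]] <= 0)) stop("validation error: '", f, "' must be positive")
  }
  for (f in c("tag_hit_max_edits", "similar_site_max_mismatches",
              "anchor_min_mapq", "max_tag_mismatches")) {
    if (any(p[[f]] < 0)) stop("validation error: '", f, "' must be non-negative")
  }
  if (p$polya_mismatch >= 0) {
    stop("validation error: 'polya_mismatch' must be negative")
  }
  if (length(p$en_weights) != 6L || any(p$en_weights < 0)) {
    stop("validation error: 'en_weights' must be six non-negative integers")
  }
  if (nchar(p$en_consensus) != 6L) {
    stop("validation error: 'en_consensus' must be a hexamer")
  }
  if (!(p$full_length_min < p$somatic_full_length_min &&
        p$somatic_full_length_min < p$full_length_max)) {
    stop("validation error: need full_length_min < somatic_full_length_min < full_length_max")
  }
  if (p$pas_weak_threshold > p$pas_strong_threshold) {
    stop("validation error: 'pas_weak_threshold' must not exceed 'pas_strong_threshold'")
  }
  if (length(p$pas_endpoint_window) != 2L ||
      p$pas_endpoint_window[1] > p$pas_endpoint_window[2]) {
    stop("validation error: 'pas_endpoint_window' must be an ordered pair")
  }
  if (p$meth_cov_min > p$meth_cov_max) {
    stop("validation error: 'meth_cov_min' must not exceed 'meth_cov_max'")
  }
  if (p$meth_min_sample_frac < 0 || p$meth_min_sample_frac > 1) {
    stop("validation error: 'meth_min_sample_frac' must be in [0, 1]")
  }
  if (length(p$activity_minor_range) != 2L ||
      p$activity_minor_range[1] > p$activity_minor_range[2]) {
    stop("validation error: 'activity_minor_range' must be an ordered pair")
  }
  if (p$min_l1_identity <= 0 || p$min_l1_identity > 1) {
    stop("validation error: 'min_l1_identity' must be in (0, 1]")
  }
  invisible(p)
}

#' Load pipeline parameters from a YAML config file
#'
#' Reads a YAML file of overrides, overlays them on the defaults and
#' validates the result. Unknown keys are rejected by name so that typos do
#' not silently fall back to defaults. An empty or absent mapping yields
#' the full default set.
#'
#' @param config_file path to a YAML file (possibly empty).
#' @return a validated `pipeline_params` object.
#' @seealso [write_params()] for the inverse operation.
#' @export
load_params <- function(config_file) {
  cfg <- yaml::read_yaml(config_file)
  if (is.null(cfg)) cfg <- list()
  if (!is.list(cfg)) stop("parse error: config must be a YAML mapping")
  if (length(cfg) && (is.null(names(cfg)) || any(names(cfg) == ""))) {
    stop("parse error: all top-level config entries must be named")
  }
  do.call(pipeline_params, cfg)
}

#' Serialize pipeline parameters to YAML
#'
#' Writing then reloading a parameter set is the identity: [load_params()]
#' on the produced file reconstructs an identical object.
#'
#' @param p a `pipeline_params` object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_params <- function(p, path) {
  validate_params(p)
  yaml::write_yaml(unclass(p), path)
  invisible(path)
}

#' @export
print.pipeline_params <- function(x, ...) {
  cat("<pipeline_params> ", length(x), " fields\n", sep = "")
  for (k in names(x)) {
    cat(sprintf("  %-28s %s\n", k, paste(x[[k]], collapse = ", ")))
  }
  invisible(x)
}
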