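#' Per-source summary table of somatic transductions
#'
#' Summarizes annotated calls per source element in the style of the
#' standard per-source activity table: number of somatic insertions,
#' median insertion length, median L1 content (percent of the insertion
#' that is L1 sequence), 5' inversion rate, orphan rate, and the modal
#' unique (transduced) sequence length together with how many insertions
#' share it. The mode is the smallest value among ties and is omitted
#' (`NA`) when all unique-sequence lengths are distinct.
#'
#' @param calls annotated insertion calls (see [annotate_insertions()])
#'   restricted by the caller to the somatic set of interest; rows with an
#'   unassigned source are dropped.
#' @return data.frame with one row per source, ordered by decreasing
#'   insertion count.
#' @export
per_source_table <- function(calls) {
  calls <- calls[!is.na(calls$source_id), , drop = FALSE]
  out <- lapply(split(calls, calls$source_id), function(g) {
    lens <- g$total_bp
    l1_content <- 100 * g$l1_bp / g$total_bp
    td_lens <- g$transduction_bp[g$class %in% c("partnered", "orphan")]
    mode_len <- NA_integer_
    mode_n <- NA_integer_
    if (length(td_lens)) {
      tab <- table(td_lens)
      if (max(tab) > 1L) {
        best <- tab[tab == max(tab)]
        mode_len <- min(as.integer(names(best)))
        mode_n <- as.integer(max(tab))
      }
    }
    data.frame(
      source_id = g$source_id[1],
      n_somatic = nrow(g),
      median_length = stats::median(lens),
      median_l1_content = stats::median(l1_content),
      inversion_rate = 100 * mean(g$inversion),
      orphan_rate = 100 * mean(g$class == "orphan"),
      mode_unique_bp = mode_len,
      mode_unique_n = mode_n,
      stringsAsFactors = FALSE
    )
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(-res$n_somatic, res$source_id), , drop = FALSE]
}

#' Correlate per-sample transduction and solo-L1 burden
#'
#' Two-sided Pearson correlation between the number of transductions and
#' the total number of somatic L1 insertions per sample, the standard
#' check that transduction burden tracks overall retrotransposition
#' activity.
#'
#' @param solo_counts,transduction_counts numeric vectors, one entry per
#'   sample, in matching order.
#' @return list with `r`, `p`, `ci` (95%), `n`; or `reason` when the
#'   correlation is undefined (constant vector or n < 3).
#' @export
correlate_activity <- function(solo_counts, transduction_counts) {
  stopifnot(length(solo_counts) == length(transduction_counts))
  n <- length(solo_counts)
  if (n < 3) {
    return(list(r = NA_real_, p = NA_real_, ci = c(NA_real_, NA_real_),
                n = n, reason = "fewer than 3 samples"))
  }
  if (stats::sd(solo_counts) == 0 || stats::sd(transduction_counts) == 0) {
    return(list(r = NA_real_, p = NA_real_, ci = c(NA_real_, NA_real_),
                n = n, reason = "zero variance"))
  }
  ct <- stats::cor.test(solo_counts, transduction_counts, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, ci = unname(ct$conf.int),
       n = n)
}

#' Kruskal-Wallis tests of insertion length by group
#'
#' Compares insertion-length distributions across groups (insertion class,
#' source element, ...) with the Kruskal-Wallis rank sum test
#' (chi-square approximation with tie correction). Optionally stratifies
#' by 5' inversion status, testing within the inverted and non-inverted
#' subsets separately - the comparison under which between-source length
#' differences typically lose significance.
#'
#' @param lengths numeric vector of insertion lengths.
#' @param groups grouping vector, same length.
#' @param inversion optional logical vector for stratification.
#' @return list with `overall` (`statistic`, `df`, `p`, `medians`) and,
#'   when `inversion` is given, `by_inversion` with one such entry per
#'   stratum; degenerate strata are reported with a reason instead.
#' @export
length_tests <- function(lengths, groups, inversion = NULL) {
  run_kw <- function(l, g) {
    g <- factor(g)
    sizes <- table(g)
    if (nlevels(g) < 2) stop("length_tests requires at least 2 groups")
    if (sum(sizes >= 2) < 2) {
      return(list(statistic = NA_real_, df = NA_real_, p = NA_real_,
                  medians = tapply(l, g, stats::median),
                  reason = "fewer than 2 groups with >= 2 members"))
    }
    kw <- stats::kruskal.test(l, g)
    list(statistic = unname(kw$statistic), df = unname(kw$parameter),
         p = kw$p.value, medians = tapply(l, g, stats::median))
  }
  out <- list(overall = run_kw(lengths, groups))
  if (!is.null(inversion)) {
    out$by_inversion <- lapply(
      split(seq_along(lengths), ifelse(inversion, "inverted", "non_inverted")),
      function(idx) {
        g <- factor(groups[idx])
        if (nlevels(droplevels(g)) < 2) {
          return(list(statistic = NA_real_, df = NA_real_, p = NA_real_,
                      medians = tapply(lengths[idx], g, stats::median),
                      reason = "single group in stratum"))
        }
        run_kw(lengths[idx], groups[idx])
      })
  }
  out
}

#' Relative source activity
#'
#' The number of somatic transductions attributed to a source divided by
#' the number of samples used in the detection, allowing comparison of
#' source activity across datasets of different size.
#'
#' @param events data.frame with columns `source_id` and `dataset`.
#' @param n_samples named numeric vector: samples per dataset.
#' @return data.frame with `source_id`, `dataset`, `n_events`,
#'   `relative_activity`.
#' @export
relative_activity <- function(events, n_samples) {
  if (any(n_samples <= 0)) stop("n_samples must be positive")
  combos <- unique(events[, c("source_id", "dataset")])
  if (!nrow(combos)) {
    return(data.frame(source_id = character(), dataset = character(),
                      n_events = integer(), relative_activity = numeric(),
                      stringsAsFactors = FALSE))
  }
  combos$n_events <- vapply(seq_len(nrow(combos)), function(i) {
    sum(events$source_id == combos$source_id[i] &
          events$dataset == combos$dataset[i])
  }, integer(1))
  combos$relative_activity <-
    combos$n_events / n_samples[combos$dataset]
  rownames(combos) <- NULL
  combos
}

#' Run manifest for reproducibility
#'
#' Captures the ingredients of a pipeline run - package version, seed,
#' and a digest-free flat dump of the parameter set - as a JSON-ready
#' structure written alongside pipeline outputs.
#'
#' @param seed the seed used for the run.
#' @param params a [pipeline_params()] object.
#' @param path optional file to write JSON to.
#' @return the manifest list, invisibly when written.
#' @export
run_manifest <- function(seed, params = pipeline_params(), path = NULL) {
  m <- list(
    package = "retrotag",
    version = as.character(utils::packageVersion("retrotag")),
    r_version = as.character(getRversion()),
    seed = seed,
    params = unclass(params)
  )
  if (!is.null(path)) {
    jsonlite::write_json(m, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    return(invisible(m))
  }
  m
}
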