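#' Average promoter methylation over the 200-bp 5' window
#'
#' Aggregates per-CpG methylation into one summary per element per sample:
#' the mean methylated fraction (as a percent) over CpGs falling in the
#' 200-bp window centred on the element's 5' end (100 bp inside and 100 bp
#' outside, in element orientation) whose coverage lies within
#' `[meth_cov_min, meth_cov_max]`. A summary is flagged `included` when at
#' least `meth_min_cpgs` CpGs survive the coverage filter. Records are
#' deduplicated by (sample, chrom, position) before aggregation, so the
#' result is invariant to record order and duplication.
#'
#' @param records data.frame of per-CpG calls with columns `sample`,
#'   `chrom`, `pos` (0-based CpG position), `coverage`,
#'   `methylated_fraction` in `[0, 1]`.
#' @param element one-row data.frame (or list) with `source_id`, `chrom`,
#'   `start`, `end` (0-based half-open) and `strand`; the 5' end is
#'   `start` for `+` elements and `end` for `-` elements.
#' @param params a [pipeline_params()] object.
#' @return data.frame with one row per sample present in `records`:
#'   `source_id`, `sample`, `n_cpgs_used`, `avg_methylation` (percent,
#'   `NA` when no usable CpG) and `included`.
#' @export
window_average <- function(records, element, params = pipeline_params()) {
  five_prime <- if (element$strand == "-") element$end else element$start
  lo <- five_prime - params$meth_window_halfwidth
  hi <- five_prime + params$meth_window_halfwidth
  recs <- records[records$chrom == element$chrom &
                    records$pos >= lo & records$pos < hi, , drop = FALSE]
  recs <- recs[!duplicated(recs[, c("sample", "chrom", "pos")]), , drop = FALSE]
  usable <- recs$coverage >= params$meth_cov_min &
    recs$coverage <= params$meth_cov_max
  recs <- recs[usable, , drop = FALSE]
  samples <- unique(records$sample)
  out <- lapply(samples, function(s) {
    r <- recs[recs$sample == s, , drop = FALSE]
    n <- nrow(r)
    data.frame(
      source_id = element$source_id, sample = s, n_cpgs_used = n,
      avg_methylation = if (n) mean(r$methylated_fraction) * 100 else NA_real_,
      included = n >= params$meth_min_cpgs,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, out)
}

#' Select elements eligible for methylation analysis
#'
#' An element enters the averaged analyses when (a) the fraction of
#' samples with an included window summary is at least
#' `meth_min_sample_frac` (75%), and (b) the element is an autosomal
#' reference element fixed in the population, as recorded in the catalog.
#'
#' @param summaries data.frame of [window_average()] rows across elements
#'   and samples.
#' @param catalog source catalog with `source_id`, `chrom`, `provenance`,
#'   `allele_status`.
#' @param n_samples total number of samples analysed (denominator of the
#'   availability fraction).
#' @param params a [pipeline_params()] object.
#' @return character vector of eligible `source_id`s.
#' @export
filter_elements <- function(summaries, catalog, n_samples,
                            params = pipeline_params()) {
  autosomal <- !grepl("^(chr)?[XY]$", catalog$chrom)
  eligible_cat <- catalog$source_id[autosomal &
                                      catalog$provenance == "reference" &
                                      catalog$allele_status == "fixed"]
  tab <- tapply(summaries$included, summaries$source_id, sum)
  avail <- names(tab)[tab / n_samples >= params$meth_min_sample_frac]
  intersect(avail, eligible_cat)
}

#' Classify source-element transduction activity
#'
#' Elements are binned by the number of samples in which they produced
#' detectable transductions: `active` (at least
#' `activity_active_min_samples`, default 4), `minor` (1-3), `inactive`
#' (0). Inactive elements whose strongest internal PAS is weak form the
#' separate class `inactive_weak_pas`.
#'
#' @param positive_sample_counts named integer vector: per `source_id`,
#'   the number of samples with transductions from that element.
#' @param internal_pas data.frame from [classify_internal_pas()].
#' @param params a [pipeline_params()] object.
#' @return data.frame with `source_id`, `n_positive_samples`,
#'   `activity_class`.
#' @export
classify_activity <- function(positive_sample_counts, internal_pas,
                              params = pipeline_params()) {
  ids <- union(names(positive_sample_counts), internal_pas$source_id)
  n <- positive_sample_counts[ids]
  n[is.na(n)] <- 0L
  strength <- internal_pas$internal_pas_strength[
    match(ids, internal_pas$source_id)]
  cls <- ifelse(
    n >= params$activity_active_min_samples, "active",
    ifelse(n >= params$activity_minor_range[1] &
             n <= params$activity_minor_range[2], "minor",
           ifelse(!is.na(strength) & strength == "weak",
                  "inactive_weak_pas", "inactive")))
  data.frame(source_id = ids, n_positive_samples = as.integer(n),
             activity_class = cls, stringsAsFactors = FALSE, row.names = NULL)
}

#' Test the methylation-activity association
#'
#' Three views of the association between promoter methylation and
#' transduction activity, mirroring how hypomethylation of active source
#' elements is usually demonstrated:
#' (a) per-element Pearson correlation between the per-sample window
#' average and that element's per-sample transduction count, with a
#' two-sided p-value and Fisher-z 95% CI;
#' (b) a pooled two-sided Welch's t-test of element-sample methylation
#' values, transduction-positive vs transduction-negative element-sample
#' pairs;
#' (c) the methylation distribution per activity class.
#'
#' @param summaries [window_average()] rows (included summaries are used).
#' @param activity data.frame from [classify_activity()].
#' @param transduction_counts data.frame with `source_id`, `sample`,
#'   `n_transductions` (absent pairs count 0).
#' @return list with `per_element` (correlation table), `welch`
#'   (statistic, estimate difference positive-minus-negative, p-value, CI,
#'   or a reason when undefined), and `by_class` distribution table.
#' @export
test_association <- function(summaries, activity, transduction_counts) {
  s <- summaries[summaries$included & !is.na(summaries$avg_methylation), ,
                 drop = FALSE]
  key <- paste(s$source_id, s$sample, sep = "\r")
  ckey <- paste(transduction_counts$source_id, transduction_counts$sample,
                sep = "\r")
  s$n_transductions <- transduction_counts$n_transductions[match(key, ckey)]
  s$n_transductions[is.na(s$n_transductions)] <- 0L

  per_element <- do.call(rbind, lapply(split(s, s$source_id), function(e) {
    if (nrow(e) < 3 || stats::sd(e$n_transductions) == 0 ||
        stats::sd(e$avg_methylation) == 0) {
      return(data.frame(source_id = e$source_id[1], n = nrow(e),
                        r = NA_real_, p = NA_real_,
                        ci_lo = NA_real_, ci_hi = NA_real_,
                        note = "degenerate: constant vector or n < 3",
                        stringsAsFactors = FALSE))
    }
    ct <- stats::cor.test(e$avg_methylation, e$n_transductions,
                          method = "pearson")
    data.frame(source_id = e$source_id[1], n = nrow(e),
               r = unname(ct$estimate), p = ct$p.value,
               ci_lo = ct$conf.int[1], ci_hi = ct$conf.int[2],
               note = "", stringsAsFactors = FALSE)
  }))
  rownames(per_element) <- NULL

  pos <- s$avg_methylation[s$n_transductions > 0]
  neg <- s$avg_methylation[s$n_transductions == 0]
  welch <- if (length(pos) >= 2 && length(neg) >= 2 &&
               (stats::sd(pos) > 0 || stats::sd(neg) > 0)) {
    tt <- stats::t.test(pos, neg, var.equal = FALSE)
    list(statistic = unname(tt$statistic), difference = mean(pos) - mean(neg),
         p = tt$p.value, ci = unname(tt$conf.int),
         n_positive = length(pos), n_negative = length(neg))
  } else {
    list(statistic = NA_real_,
         difference = if (length(pos) && length(neg))
           mean(pos) - mean(neg) else NA_real_,
         p = NA_real_, ci = c(NA_real_, NA_real_),
         n_positive = length(pos), n_negative = length(neg),
         reason = "fewer than 2 values per group or zero variance in both")
  }

  s$activity_class <- activity$activity_class[
    match(s$source_id, activity$source_id)]
  by_class <- do.call(rbind, lapply(
    split(s$avg_methylation, s$activity_class), function(v) {
      data.frame(n = length(v), mean = mean(v), median = stats::median(v),
                 sd = stats::sd(v))
    }))
  by_class <- cbind(activity_class = rownames(by_class), by_class)
  rownames(by_class) <- NULL

  list(per_element = per_element, welch = welch, by_class = by_class)
}
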