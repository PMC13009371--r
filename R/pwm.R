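#' Build the default polyadenylation-signal position weight matrix
#'
#' Constructs the PAS scoring matrix shipped with the package. It is a
#' log2-odds matrix derived from the usage frequencies of the known human
#' PAS hexamer variants (AATAAA dominating, ATTAAA second, and the ten
#' rarer single-base variants), with a 0.01 pseudocount per base against a
#' uniform background, then linearly calibrated so that the canonical
#' AATAAA scores 9.0 and ATTAAA scores 8.3. Under that calibration AATAAA
#' is the unique global maximum over all 4096 hexamers, both canonical
#' variants exceed the strong threshold (> 8.1), and every non-PAS-like
#' hexamer falls well below the weak threshold (< 8).
#'
#' The matrix is an explicit package default, not a reproduction of any
#' published matrix; any user matrix in the same plain-text format can be
#' supplied instead via [read_pwm()], and scores are only comparable to the
#' strong/weak thresholds under the matrix they were calibrated with, so
#' every PWM carries a provenance label.
#'
#' @return an object of class `pas_pwm`: list with `width`, `weights`
#'   (4 x width numeric matrix, rows A,C,G,T), and `provenance`.
#' @examples
#' pwm <- build_default_pwm()
#' pwm_score(pwm, "AATAAA")
#' @export
build_default_pwm <- function() {
  variants <- c(
    AATAAA = 58.2, ATTAAA = 14.9, TATAAA = 3.2, AGTAAA = 2.7,
    AAGAAA = 2.9, AATATA = 1.7, AATACA = 1.2, CATAAA = 1.3,
    GATAAA = 1.3, AATGAA = 0.8, TTTAAA = 0.9, ACTAAA = 0.6,
    AATAGA = 0.7
  )
  bases <- c("A", "C", "G", "T")
  width <- 6L
  freq <- matrix(0.01, nrow = 4, ncol = width, dimnames = list(bases, NULL))
  for (v in names(variants)) {
    chars <- strsplit(v, "", fixed = TRUE)[[1]]
    for (j in seq_len(width)) {
      freq[chars[j], j] <- freq[chars[j], j] + variants[[v]]
    }
  }
  freq <- sweep(freq, 2, colSums(freq), "/")
  raw <- log2(freq / 0.25)
  raw_score <- function(hex) {
    chars <- strsplit(hex, "", fixed = TRUE)[[1]]
    sum(vapply(seq_len(width), function(j) raw[chars[j], j], numeric(1)))
  }
  s1 <- raw_score("AATAAA")
  s2 <- raw_score("ATTAAA")
  a <- (9.0 - 8.3) / (s1 - s2)
  b <- 9.0 - a * s1
  weights <- a * raw + b / width
  structure(
    list(width = width, weights = weights,
         provenance = "retrotag-default-v1 (human PAS variant frequencies, log2-odds, calibrated AATAAA=9.0 ATTAAA=8.3)"),
    class = "pas_pwm"
  )
}

#' Score hexamers against a PAS weight matrix
#'
#' @param pwm a `pas_pwm` object.
#' @param hexamers character vector of sequences of length `pwm$width`.
#' @return numeric vector of scores; `NA` for windows containing non-ACGT
#'   characters.
#' @export
pwm_score <- function(pwm, hexamers) {
  stopifnot(inherits(pwm, "pas_pwm"))
  vapply(toupper(hexamers), function(hex) {
    if (nchar(hex) != pwm$width) stop("sequence length must equal PWM width")
    ri <- match(strsplit(hex, "", fixed = TRUE)[[1]], rownames(pwm$weights))
    if (anyNA(ri)) return(NA_real_)
    sum(pwm$weights[cbind(ri, seq_len(pwm$width))])
  }, numeric(1), USE.NAMES = FALSE)
}

#' Classify PAS strength
#'
#' Strong signals score strictly above `pas_strong_threshold` (8.1), weak
#' signals strictly below `pas_weak_threshold` (8); scores falling in the
#' gap between the two thresholds are labelled `"intermediate"` rather
#' than silently binned.
#'
#' @param score numeric vector of PWM scores.
#' @param params a [pipeline_params()] object.
#' @return character vector: `"strong"`, `"intermediate"` or `"weak"`.
#' @export
classify_pas_strength <- function(score, params = pipeline_params()) {
  ifelse(score > params$pas_strong_threshold, "strong",
         ifelse(score < params$pas_weak_threshold, "weak", "intermediate"))
}

#' Scan a sequence for polyadenylation signals
#'
#' Scores every hexamer window of `seq` in transcript direction (PAS
#' recognition is strand-specific, so the caller supplies the sequence
#' already oriented) and returns the windows at or above the reporting
#' floor, sorted by position.
#'
#' @param pwm a `pas_pwm` object.
#' @param seq a single DNA string, length >= `pwm$width`.
#' @param min_report_score minimum score to report.
#' @param params a [pipeline_params()] object (for strength thresholds).
#' @return data.frame with `position` (0-based offset of the hexamer
#'   start), `hexamer`, `score`, `strength`.
#' @export
scan_sequence <- function(pwm, seq, min_report_score = 0,
                          params = pipeline_params()) {
  stopifnot(is.character(seq), length(seq) == 1L)
  n <- nchar(seq)
  if (n < pwm$width) stop("sequence shorter than PWM width")
  starts <- seq_len(n - pwm$width + 1L)
  hexes <- substring(seq, starts, starts + pwm$width - 1L)
  scores <- pwm_score(pwm, hexes)
  keep <- !is.na(scores) & scores >= min_report_score
  data.frame(
    position = starts[keep] - 1L,
    hexamer = hexes[keep],
    score = scores[keep],
    strength = classify_pas_strength(scores[keep], params),
    stringsAsFactors = FALSE
  )
}

#' Associate transduction endpoints with upstream PAS hits
#'
#' Canonical PAS motifs sit 10-30 bp upstream of the transcription
#' termination site, so each transduction endpoint is paired with the
#' strongest strong-class PAS whose start lies within that window upstream
#' of the endpoint (distance = endpoint - PAS start, measured in
#' transcript direction).
#'
#' @param endpoints data.frame with columns `insertion_id` and `endpoint`
#'   (coordinate in the same frame as `pas_hits$position`).
#' @param pas_hits data.frame as returned by [scan_sequence()].
#' @param params a [pipeline_params()] object.
#' @return data.frame with one row per endpoint: `insertion_id`,
#'   `endpoint`, `pas_position`, `pas_hexamer`, `pas_score`, `distance`,
#'   `associated`.
#' @export
associate_endpoints <- function(endpoints, pas_hits,
                                params = pipeline_params()) {
  win <- params$pas_endpoint_window
  strong <- pas_hits[pas_hits$strength == "strong", , drop = FALSE]
  out <- lapply(seq_len(nrow(endpoints)), function(i) {
    e <- endpoints$endpoint[i]
    d <- e - strong$position
    ok <- which(d >= win[1] & d <= win[2])
    if (length(ok)) {
      j <- ok[which.max(strong$score[ok])]
      data.frame(
        insertion_id = endpoints$insertion_id[i], endpoint = e,
        pas_position = strong$position[j], pas_hexamer = strong$hexamer[j],
        pas_score = strong$score[j], distance = d[j], associated = TRUE,
        stringsAsFactors = FALSE
      )
    } else {
      data.frame(
        insertion_id = endpoints$insertion_id[i], endpoint = e,
        pas_position = NA_integer_, pas_hexamer = NA_character_,
        pas_score = NA_real_, distance = NA_integer_, associated = FALSE,
        stringsAsFactors = FALSE
      )
    }
  })
  do.call(rbind, out)
}

#' Classify the internal PAS of each catalogued source
#'
#' Takes a source catalog whose `internal_pas_score` column was annotated
#' from the final 50 bp of each element and reports the strength class of
#' the strongest internal PAS per source, for aggregation by activity
#' class.
#'
#' @param catalog a source catalog data.frame (see [build_catalog()]).
#' @param params a [pipeline_params()] object.
#' @return data.frame with `source_id`, `internal_pas_score`,
#'   `internal_pas_strength` (`NA` when no internal PAS was reported).
#' @export
classify_internal_pas <- function(catalog, params = pipeline_params()) {
  data.frame(
    source_id = catalog$source_id,
    internal_pas_score = catalog$internal_pas_score,
    internal_pas_strength = ifelse(
      is.na(catalog$internal_pas_score), NA_character_,
      classify_pas_strength(catalog$internal_pas_score, params)),
    stringsAsFactors = FALSE
  )
}

#' Read a PAS weight matrix from a plain-text file
#'
#' Format: a header line `# provenance: <label>` followed by four
#' tab-separated rows labelled A, C, G, T with one numeric weight per
#' matrix column.
#'
#' @param path input file.
#' @return a `pas_pwm` object.
#' @export
read_pwm <- function(path) {
  lines <- readLines(path)
  prov_line <- grep("^#\\s*provenance:", lines, value = TRUE)
  provenance <- if (length(prov_line)) {
    sub("^#\\s*provenance:\\s*", "", prov_line[1])
  } else "unlabelled"
  body <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (length(body) != 4L) stop("PWM file must have exactly 4 matrix rows")
  parts <- strsplit(body, "\t", fixed = TRUE)
  bases <- vapply(parts, `[`, character(1), 1L)
  if (!setequal(bases, c("A", "C", "G", "T"))) {
    stop("PWM rows must be labelled A, C, G, T")
  }
  vals <- lapply(parts, function(p) as.numeric(p[-1]))
  width <- length(vals[[1]])
  if (any(vapply(vals, length, integer(1)) != width)) {
    stop("PWM rows have unequal width")
  }
  weights <- do.call(rbind, vals)
  rownames(weights) <- bases
  weights <- weights[c("A", "C", "G", "T"), , drop = FALSE]
  if (any(!is.finite(weights))) stop("PWM weights must all be finite")
  structure(list(width = width, weights = weights, provenance = provenance),
            class = "pas_pwm")
}

#' Write a PAS weight matrix to a plain-text file
#'
#' @param pwm a `pas_pwm` object.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_pwm <- function(pwm, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# provenance: ", pwm$provenance), con)
  for (b in c("A", "C", "G", "T")) {
    writeLines(paste(c(b, format(pwm$weights[b, ], digits = 17)),
                     collapse = "\t"), con)
  }
  invisible(path)
}
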