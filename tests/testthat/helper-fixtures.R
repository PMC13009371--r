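# Shared fixtures, built once per test run and memoized.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixtures)) {
    assign(key, force(expr), envir = .fixtures)
  }
  get(key, envir = .fixtures)
}

# a compact 2-source, 0.8-Mb study used by unit tests
small_cfg <- function(seed = 7, ...) {
  simulation_config(
    seed = seed, n_chromosomes = 2L, chrom_length = 400000L,
    n_sources = 2L, source_strands = c("+", "-"),
    activity_weights = c(2, 1), length_modes = list(78L, 337L),
    mode_weights = list(1, 1), inversion_rates = c(0.1, 0.3),
    n_tumor = 2L, insertions_per_sample = 10, n_en_sites = 100L, ...)
}

small_sim <- function() {
  memo("small_sim", {
    cfg <- small_cfg()
    sr <- simulate_reference(cfg)
    list(cfg = cfg, sr = sr,
         catalog = build_catalog(sr$reference, sr$bed),
         truth = simulate_insertions(cfg, sr))
  })
}

small_aln <- function(sample = "T1") {
  memo(paste0("small_aln_", sample), {
    s <- small_sim()
    simulate_reads(s$cfg, s$sr, s$truth, sample)
  })
}

# the full-scale study (3-Mb genome, 5 sources, 4 tumors + 1 control,
# 2x150 bp at 30x) driving the detector-recovery and hallmark checks
big_run <- function() {
  memo("big_run", {
    cfg <- simulation_config(seed = 1)
    sr <- simulate_reference(cfg)
    catalog <- build_catalog(sr$reference, sr$bed)
    truth <- simulate_insertions(cfg, sr)
    params <- pipeline_params()
    samples <- c(paste0("T", seq_len(cfg$n_tumor)), "N1")
    per_sample <- list()
    support <- integer(nrow(truth))
    n_normal_calls <- 0L
    for (s in samples) {
      aln <- simulate_reads(cfg, sr, truth, s)
      hits <- scan_reads(aln, catalog, s, params)
      anchored <- hits[hits$anchor_mapq >= params$anchor_min_mapq, ,
                       drop = FALSE]
      for (i in which(truth$sample == s)) {
        support[i] <- sum(anchored$source_id == truth$source_id[i] &
                            anchored$anchor_chrom == truth$chrom[i] &
                            abs(anchored$anchor_pos - truth$pos[i]) < 1000,
                          na.rm = TRUE)
      }
      clusters <- filter_clusters(cluster_anchors(hits, params), catalog,
                                  params)
      called <- clusters[clusters$called, , drop = FALSE]
      det <- if (nrow(called)) {
        do.call(rbind, lapply(seq_len(nrow(called)), function(i) {
          characterize_cluster(aln, called[i, ], sr$reference, params)
        }))
      } else {
        detect_sample(aln[0, ], catalog, sr$reference, s, params)
      }
      if (s == "N1") n_normal_calls <- nrow(det)
      per_sample[[s]] <- det
      rm(aln)
      gc(FALSE)
    }
    calls <- do.call(rbind, per_sample)
    rownames(calls) <- NULL
    merged <- merge_across_samples(calls, params)
    events <- call_somatic(
      summarize_merged_events(merged),
      data.frame(sample = samples,
                 type = c(rep("tumor", cfg$n_tumor), "normal")))
    truth$n_support <- support
    list(cfg = cfg, sr = sr, catalog = catalog, truth = truth,
         calls = calls, events = events, n_normal_calls = n_normal_calls)
  })
}

# planted transductions of the small sim with >= 3 anchorable supporting
# tag pairs (events whose tag lies beyond insert reach of both junctions
# produce no anchors and are invisible to the short-read assay)
eligible_truth <- function(sample = "T1") {
  memo(paste0("small_eligible_", sample), {
    s <- small_sim()
    p <- pipeline_params()
    hits <- scan_reads(small_aln(sample), s$catalog, sample, p)
    anchored <- hits[hits$anchor_mapq >= p$anchor_min_mapq, , drop = FALSE]
    td <- s$truth[s$truth$sample == sample & s$truth$class != "solo", ,
                  drop = FALSE]
    support <- vapply(seq_len(nrow(td)), function(i) {
      sum(anchored$source_id == td$source_id[i] &
            anchored$anchor_chrom == td$chrom[i] &
            abs(anchored$anchor_pos - td$pos[i]) < 1000)
    }, integer(1))
    td[support >= p$cluster_min_reads, , drop = FALSE]
  })
}

# match characterized calls to planted transductions by locus
match_calls_to_truth <- function(calls, truth, max_dist = 1000) {
  td <- truth[truth$class != "solo", , drop = FALSE]
  do.call(rbind, lapply(seq_len(nrow(calls)), function(i) {
    t <- td[td$sample == calls$sample[i] & td$chrom == calls$chrom[i] &
              abs(td$pos - calls$locus[i]) < max_dist, , drop = FALSE]
    if (!nrow(t)) return(NULL)
    cbind(calls[i, , drop = FALSE],
          truth_tsd = t$tsd_length[1], truth_polya = t$polya_bp[1],
          truth_en = t$at_en_site[1], truth_orient = t$orientation[1],
          truth_pos = t$pos[1], truth_source = t$source_id[1])
  }))
}

random_dna_str <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
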