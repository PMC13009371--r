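params <- pipeline_params()

test_that("anchor clustering follows the 1-kbp single-linkage rule", {
  hits <- data.frame(
    sample = "S", source_id = "src", qname = paste0("q", 1:4),
    carrier_mate = 1L, anchor_chrom = "chr1",
    anchor_pos = c(1000L, 1500L, 1900L, 5000L),
    anchor_mapq = 60L, anchor_strand = "+", stringsAsFactors = FALSE)
  cl <- cluster_anchors(hits, params)
  expect_equal(nrow(cl), 2L)
  expect_equal(cl$start, c(1000L, 5000L))
  expect_equal(cl$end, c(1900L, 5000L))
  expect_equal(cl$n_anchor_reads, c(3L, 1L))

  # gap of exactly 1100 > 1000 splits
  hits2 <- hits[1:2, ]
  hits2$anchor_pos <- c(1000L, 2100L)
  expect_equal(nrow(cluster_anchors(hits2, params)), 2L)
  # gap of exactly 1000 joins
  hits2$anchor_pos <- c(1000L, 2000L)
  expect_equal(nrow(cluster_anchors(hits2, params)), 1L)
})

test_that("anchors below MAPQ 37 never participate in clustering", {
  hits <- data.frame(
    sample = "S", source_id = "src", qname = paste0("q", 1:4),
    carrier_mate = 1L, anchor_chrom = "chr1",
    anchor_pos = c(1000L, 1100L, 1200L, 1300L),
    anchor_mapq = c(60L, 37L, 30L, 36L), anchor_strand = "+",
    stringsAsFactors = FALSE)
  cl <- cluster_anchors(hits, params)
  expect_equal(cl$n_anchor_reads, 2L)  # MAPQ 60 and 37 only
})

test_that("cluster filters implement the >=3-read and 2-kbp repeat rules", {
  mkcat <- function(sim_str) data.frame(
    source_id = "src", chrom = "chr9", start = 500000L, end = 506019L,
    strand = "+", similar_sites = sim_str, stringsAsFactors = FALSE)
  mkcl <- function(n, start) data.frame(
    sample = "S", source_id = "src", chrom = "chr1", start = start,
    end = start + 200L, n_anchor_reads = n, qnames = "",
    stringsAsFactors = FALSE)

  # n = 3, nearest similar site 5 kb away: both pass
  f <- filter_clusters(mkcl(3L, 10000L), mkcat("chr1:15000:+"), params)
  expect_true(f$min_reads_pass & f$repeat_exclusion_pass & f$called)
  # n = 2 fails the read floor
  f <- filter_clusters(mkcl(2L, 10000L), mkcat(""), params)
  expect_false(f$min_reads_pass)
  expect_false(f$called)
  # similar site 1.5 kb away fails repeat exclusion
  f <- filter_clusters(mkcl(5L, 10000L), mkcat("chr1:11700:+"), params)
  expect_false(f$repeat_exclusion_pass)
  # a cluster at the source locus itself is excluded
  cl_at_src <- mkcl(5L, 505000L)
  cl_at_src$chrom <- "chr9"
  f <- filter_clusters(cl_at_src, mkcat(""), params)
  expect_false(f$repeat_exclusion_pass)
})

test_that("cross-sample merging joins same-source events within 2 kbp", {
  ev <- data.frame(
    sample = c("T1", "T2", "T1", "T2", "T3"),
    source_id = c("a", "a", "a", "a", "b"),
    chrom = "chr1", locus = c(10000, 11500, 50000, 52500, 10000),
    stringsAsFactors = FALSE)
  m <- merge_across_samples(ev, params)
  s <- summarize_merged_events(m)
  # 10000/11500 merge; 50000 vs 52500 do not; source b stays apart
  expect_equal(nrow(s), 4L)
  merged_ev <- s[s$n_samples == 2, ]
  expect_equal(nrow(merged_ev), 1L)
  expect_equal(merged_ev$samples, "T1,T2")
  expect_equal(merged_ev$source_id, "a")
})

test_that("somatic calls require exactly one tumor and no normal", {
  sheet <- data.frame(sample = c("T1", "T2", "N1"),
                      type = c("tumor", "tumor", "normal"),
                      stringsAsFactors = FALSE)
  merged <- data.frame(
    merged_event_id = c("e1", "e2", "e3"), source_id = "a", chrom = "chr1",
    locus = 1:3 * 1000, samples = c("T1", "T1,T2", "T1,N1"),
    n_samples = c(1L, 2L, 2L), stringsAsFactors = FALSE)
  out <- call_somatic(merged, sheet)
  expect_equal(out$somatic, c(TRUE, FALSE, FALSE))
  bad <- merged
  bad$samples[1] <- "T9"
  expect_error(call_somatic(bad, sheet), "T9")
})

test_that("tag scanning finds planted events and is silent without insertions", {
  s <- small_sim()
  aln_t1 <- small_aln("T1")
  hits <- scan_reads(aln_t1, s$catalog, "T1", params)
  td <- eligible_truth("T1")
  expect_gte(nrow(td), 2L)
  for (i in seq_len(nrow(td))) {
    n <- sum(hits$source_id == td$source_id[i] &
               hits$anchor_chrom == td$chrom[i] &
               abs(hits$anchor_pos - td$pos[i]) < 1000)
    expect_gte(n, 3L)
  }
  # the insertion-free normal yields raw self-hits only at the source loci
  # (reference reads over the tag region), which filtering removes: no
  # called transduction survives
  aln_n1 <- small_aln("N1")
  hits_n1 <- scan_reads(aln_n1, s$catalog, "N1", params)
  expect_true(all(vapply(seq_len(nrow(hits_n1)), function(i) {
    src <- s$catalog[s$catalog$source_id == hits_n1$source_id[i], ]
    hits_n1$anchor_chrom[i] == src$chrom &&
      (abs(hits_n1$anchor_pos[i] - src$end) < 5000 ||
         abs(hits_n1$anchor_pos[i] - src$start) < 5000)
  }, logical(1))))
  det_n1 <- detect_sample(aln_n1, s$catalog, s$sr$reference, "N1", params)
  expect_equal(sum(det_n1$called), 0L)
})

test_that("detection calls planted events with accurate hallmarks", {
  s <- small_sim()
  res <- memo("small_det_T1", {
    detect_sample(small_aln("T1"), s$catalog, s$sr$reference, "T1", params)
  })
  td <- eligible_truth("T1")
  for (i in seq_len(nrow(td))) {
    row <- res[res$source_id == td$source_id[i] &
                 res$chrom == td$chrom[i] &
                 abs(res$locus - td$pos[i]) < 1000, ]
    expect_equal(nrow(row), 1L)
    expect_lte(abs(row$tsd_length - td$tsd_length[i]), 1L)
    expect_equal(row$orientation, td$orientation[i])
    expect_true(row$en_cut_site)
    expect_true(row$polya_present)
  }
})

test_that("the pipeline is invariant to alignment record order", {
  s <- small_sim()
  aln <- small_aln("T1")
  res1 <- memo("small_det_T1", {
    detect_sample(aln, s$catalog, s$sr$reference, "T1", params)
  })
  set.seed(77)
  perm <- aln[sample(nrow(aln)), ]
  res2 <- detect_sample(perm, s$catalog, s$sr$reference, "T1", params)
  key <- function(x) x[order(x$source_id, x$chrom, x$start),
                       c("source_id", "chrom", "start", "end",
                         "n_anchor_reads", "tsd_length", "locus")]
  r1 <- key(res1)
  r2 <- key(res2)
  rownames(r1) <- rownames(r2) <- NULL
  expect_equal(r1, r2)
})

test_that("detect_short orchestrates scan, merge and somatic calling", {
  s <- small_sim()
  sheet <- data.frame(sample = c("T1", "N1"), type = c("tumor", "normal"),
                      stringsAsFactors = FALSE)
  res <- detect_short(list(T1 = small_aln("T1"), N1 = small_aln("N1")),
                      sheet, s$catalog, s$sr$reference, params)
  td <- eligible_truth("T1")
  expect_equal(nrow(res$events), nrow(td))
  expect_true(all(res$events$somatic))
  expect_true(all(res$events$samples == "T1"))
})

test_that("SAM round trip preserves the alignment table", {
  s <- small_sim()
  aln <- small_aln("T1")[1:400, ]
  f <- withr::local_tempfile(fileext = ".sam")
  write_sam(aln, vapply(s$sr$reference, nchar, integer(1)), f)
  back <- read_alignments(f)
  expect_equal(nrow(back), 400L)
  o1 <- aln[order(aln$qname, aln$mate), ]
  o2 <- back[order(back$qname, back$mate), ]
  expect_equal(o2$pos, o1$pos)
  expect_equal(o2$cigar, o1$cigar)
  expect_equal(o2$seq, o1$seq)
  expect_equal(o2$mapq, o1$mapq)
})
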