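test_that("reference simulation is byte-deterministic under the seed", {
  cfg <- small_cfg()
  a <- simulate_reference(cfg)
  b <- simulate_reference(cfg)
  expect_identical(a$reference, b$reference)
  expect_identical(a$sources, b$sources)
  expect_identical(a$en_sites, b$en_sites)
})

test_that("PAS planting honors the configured offsets on both strands", {
  s <- small_sim()
  src <- s$sr$sources
  for (i in seq_len(nrow(src))) {
    offs <- as.integer(strsplit(src$pas_offsets[i], ",")[[1]])
    for (o in offs) {
      expect_equal(substr(src$downstream_seq[i], o + 1, o + 6), "AATAAA")
    }
    # downstream truth matches the strand-aware genomic extraction
    if (src$strand[i] == "+") {
      got <- substr(s$sr$reference[[src$chrom[i]]], src$end[i] + 1,
                    src$end[i] + 50)
      expect_equal(substr(src$downstream_seq[i], 1, 50), got)
    } else {
      got <- substr(s$sr$reference[[src$chrom[i]]], src$start[i] - 49,
                    src$start[i])
      expect_equal(substr(src$downstream_seq[i], 1, 50),
                   as.character(Biostrings::reverseComplement(
                     Biostrings::DNAString(got))))
    }
  }
})

test_that("a zero-source genome is valid with an empty annotation set", {
  cfg <- simulation_config(seed = 3, n_chromosomes = 1L,
                           chrom_length = 100000L, n_sources = 0L,
                           source_strands = character(0),
                           activity_weights = numeric(0),
                           length_modes = list(), mode_weights = list(),
                           inversion_rates = numeric(0))
  sr <- simulate_reference(cfg)
  expect_equal(nchar(sr$reference[["chr1"]]), 100000L)
  expect_equal(nrow(sr$bed), 0L)
})

test_that("class mix matches the configured transduction fraction", {
  cfg <- simulation_config(seed = 3, frac_transduction = 0.25,
                           n_tumor = 4L, insertions_per_sample = 500,
                           min_insertion_spacing = 800L,
                           en_site_fraction = 0, frac_full_length = 0)
  sr <- simulate_reference(cfg)
  truth <- simulate_insertions(cfg, sr)
  n <- nrow(truth)
  phat <- mean(truth$class != "solo")
  expect_gt(n, 1500)
  expect_lt(abs(phat - 0.25), 3 * sqrt(0.25 * 0.75 / n))
})

test_that("inversion rate zero yields no inversion breakpoints", {
  cfg <- small_cfg(seed = 9, inversion_rates = c(0, 0))
  sr <- simulate_reference(cfg)
  truth <- simulate_insertions(cfg, sr)
  expect_false(any(truth$inverted))
  expect_true(all(is.na(truth$inversion_breakpoints)))
})

test_that("truth records satisfy the class/component invariants", {
  s <- small_sim()
  tr <- s$truth
  expect_true(all(tr$l1_bp[tr$class == "orphan"] == 0))
  expect_true(all(tr$transduction_bp[tr$class == "solo"] == 0))
  expect_true(all(tr$l1_bp[tr$class == "partnered"] > 0))
  expect_true(all(tr$transduction_bp[tr$class == "partnered"] > 0))
  expect_equal(nchar(tr$inserted_seq),
               tr$l1_bp + tr$polya_internal_bp + tr$transduction_bp +
                 tr$polya_bp)
})

test_that("cascade children retain both the source and intermediate tags", {
  cfg <- small_cfg(seed = 13, include_cascade = TRUE)
  sr <- simulate_reference(cfg)
  truth <- simulate_insertions(cfg, sr)
  child <- truth[!is.na(truth$cascade_parent), ]
  expect_equal(nrow(child), 1L)
  parent <- truth[truth$insertion_id == child$cascade_parent, ]
  expect_equal(parent$label, "germline")
  src <- sr$sources[sr$sources$source_id == parent$source_id, ]
  source_tag <- substr(src$downstream_seq, 1, 30)
  parent_flank <- substr(sr$reference[[parent$chrom]],
                         parent$pos + parent$tsd_length + 1,
                         parent$pos + parent$tsd_length + 30)
  expect_true(grepl(source_tag, child$inserted_seq, fixed = TRUE))
  expect_true(grepl(parent_flank, child$inserted_seq, fixed = TRUE))
})

test_that("long-read sequences carry the configured substitution noise", {
  s <- small_sim()
  clean <- simulate_longread_calls(s$cfg, s$truth, error = 0)
  expect_identical(clean$seq, s$truth$inserted_seq)
  cfg <- s$cfg
  one <- s$truth[rep(1, 50), ]
  one$inserted_seq <- strrep("ACGT", 250)  # length 1000
  noisy <- simulate_longread_calls(cfg, one, error = 0.01)
  hd <- vapply(noisy$seq, function(x) {
    sum(strsplit(x, "")[[1]] != strsplit(one$inserted_seq[1], "")[[1]])
  }, numeric(1), USE.NAMES = FALSE)
  expect_lt(abs(mean(hd) - 10), 3 * sqrt(10) / sqrt(50))
  empty <- simulate_longread_calls(cfg, s$truth[0, ], error = 0)
  expect_equal(nrow(empty), 0L)
})

test_that("read simulation is deterministic and clean on insertion-free samples", {
  s <- small_sim()
  a1 <- simulate_reads(s$cfg, s$sr, s$truth, "N1")
  a2 <- simulate_reads(s$cfg, s$sr, s$truth, "N1")
  expect_identical(a1, a2)
  expect_true(all(a1$proper))
  expect_false(any(grepl("S", a1$cigar)))
  expect_true(all(a1$mapq == 60L))
})

test_that("planted transductions yield anchored tag-carrying read pairs", {
  s <- small_sim()
  aln <- small_aln("T1")
  td <- s$truth[s$truth$sample == "T1" & s$truth$class != "solo", ]
  src_tags <- substr(s$sr$sources$downstream_seq, 1, 30)
  names(src_tags) <- s$sr$sources$source_id
  for (i in seq_len(nrow(td))) {
    tag <- src_tags[[td$source_id[i]]]
    carrier <- grepl(tag, aln$seq, fixed = TRUE) |
      grepl(as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(tag))), aln$seq, fixed = TRUE)
    expect_gte(sum(carrier), 3L)
  }
})

test_that("junction-bearing loci in the reads match the truth set", {
  s <- small_sim()
  aln <- small_aln("T1")
  cl <- aln[grepl("S", aln$cigar), ]
  tr <- s$truth[s$truth$sample == "T1", ]
  found <- vapply(seq_len(nrow(tr)), function(i) {
    any(cl$chrom == tr$chrom[i] & abs(cl$pos - tr$pos[i]) < 500)
  }, logical(1))
  expect_true(all(found))
})

test_that("methylation tables are deterministic and separate activity states", {
  s <- small_sim()
  m1 <- simulate_methylation(s$cfg, s$sr, s$truth)
  m2 <- simulate_methylation(s$cfg, s$sr, s$truth)
  expect_identical(m1, m2)
  expect_true(all(m1$methylated_fraction >= 0 & m1$methylated_fraction <= 1))
  expect_true(all(m1$coverage > 0))
})
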