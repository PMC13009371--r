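params <- pipeline_params()
cons <- l1_consensus()
L <- nchar(cons)

# constructed catalog with two distinguishable downstream windows
make_fixture_catalog <- function(seed = 61) {
  set.seed(seed)
  data.frame(
    source_id = c("sA", "sB"), chrom = c("chr1", "chr2"),
    start = c(100000L, 200000L), end = c(106019L, 206019L),
    strand = c("+", "+"), is_full_length = TRUE,
    provenance = "reference", allele_status = "fixed",
    downstream_seq = c(random_dna_str(3100), random_dna_str(3100)),
    proxy_of = NA_character_, stringsAsFactors = FALSE)
}

test_that("classification decomposes partnered, orphan and solo inserts", {
  cat_fx <- make_fixture_catalog()
  l1_tail <- substr(cons, L - 499, L)
  uniq <- paste0(substr(cat_fx$downstream_seq[1], 1, 79), "C")
  partnered <- paste0(l1_tail, uniq, strrep("A", 30))
  cp <- classify_insertion(partnered, cons, params)
  expect_equal(cp$class, "partnered")
  expect_equal(cp$l1_bp, 500L, tolerance = 0.01)
  expect_equal(cp$transduction_bp, 80L, tolerance = 0.05)
  expect_equal(cp$polya_bp, 30L)

  orphan <- paste0(uniq, strrep("A", 30))
  co <- classify_insertion(orphan, cons, params)
  expect_equal(co$class, "orphan")
  expect_equal(co$l1_bp, 0L)

  solo <- paste0(l1_tail, strrep("A", 25))
  cs <- classify_insertion(solo, cons, params)
  expect_equal(cs$class, "solo")
  expect_equal(cs$transduction_bp, 0L)

  expect_equal(classify_insertion(strrep("N", 100), cons, params)$class,
               "unclassifiable")
})

test_that("component lengths are conserved on clean fixtures", {
  cat_fx <- make_fixture_catalog()
  set.seed(8)
  for (i in 1:20) {
    l1 <- sample(100:1500, 1)
    td <- sample(40:400, 1)
    pa <- sample(12:50, 1)
    ipa <- sample(c(0L, 15L), 1)
    seqi <- paste0(substr(cons, L - l1 + 1, L), strrep("A", ipa),
                   substr(cat_fx$downstream_seq[1], 1, td), strrep("A", pa))
    comp <- classify_insertion(seqi, cons, params)
    total <- comp$l1_bp + comp$polya_internal_bp + comp$transduction_bp +
      comp$polya_bp
    expect_lte(abs(total - nchar(seqi)), 5L)
  }
})

test_that("source assignment requires a unique in-window alignment", {
  cat_fx <- make_fixture_catalog()
  seg <- substr(cat_fx$downstream_seq[1], 9, 89)
  asn <- assign_source(seg, cat_fx, params)
  expect_equal(asn$status, "assigned")
  expect_equal(asn$source_id, "sA")
  expect_equal(asn$endpoint_offset, 89L)
  expect_equal(asn$endpoint_genomic, cat_fx$end[1] + 89L)

  # identical windows are ambiguous
  amb_cat <- cat_fx
  amb_cat$downstream_seq[2] <- amb_cat$downstream_seq[1]
  expect_equal(assign_source(seg, amb_cat, params)$status,
               "unassigned-ambiguous")

  # sequence from far beyond the 3-kbp window is unassigned
  set.seed(62)
  far_seg <- random_dna_str(150)
  expect_equal(assign_source(far_seg, cat_fx, params)$status, "unassigned")
})

test_that("dual polyA needs two disjoint tracts at the detection limit", {
  cat_fx <- make_fixture_catalog()
  l1_tail <- substr(cons, L - 399, L)
  uniq <- substr(cat_fx$downstream_seq[1], 1, 90)
  expect_true(detect_dual_polya(
    paste0(l1_tail, strrep("A", 20), uniq, strrep("A", 25)), cons, params))
  expect_false(detect_dual_polya(
    paste0(l1_tail, uniq, strrep("A", 25)), cons, params))
  expect_false(detect_dual_polya(
    paste0(l1_tail, strrep("A", 5), uniq, strrep("A", 25)), cons, params))
})

test_that("5' inversions are detected with junction breakpoints", {
  d_inner <- 250L
  d_outer <- 650L
  inv_seg <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(
    substr(cons, L - d_outer + 1, L - d_inner))))
  fwd_seg <- substr(cons, L - d_inner + 1, L)
  inv <- detect_inversion(paste0(inv_seg, fwd_seg, strrep("A", 20)), cons,
                          frame = "l1", params = params)
  expect_true(inv$present)
  expect_equal(inv$breakpoints[1], d_inner, tolerance = 0.02)
  expect_equal(inv$breakpoints[2], d_outer, tolerance = 0.02)

  plain <- detect_inversion(paste0(substr(cons, L - 899, L), strrep("A", 20)),
                            cons, frame = "l1", params = params)
  expect_false(plain$present)

  # orphan with an inverted 5' transduced segment, downstream frame
  cat_fx <- make_fixture_catalog()
  ds <- cat_fx$downstream_seq[1]
  inv_td <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(
    substr(ds, 101, 220))))
  orphan <- paste0(inv_td, substr(ds, 221, 400), strrep("A", 20))
  oinv <- detect_inversion(orphan, substr(ds, 1, 3000),
                           frame = "downstream", params = params)
  expect_true(oinv$present)
  expect_equal(oinv$breakpoints[1], 101, tolerance = 0.05)
  expect_equal(oinv$breakpoints[2], 220, tolerance = 0.05)
})

test_that("proxy reassignment is one-step, flagged and idempotent", {
  cat_fx <- make_fixture_catalog()
  cat_fx$proxy_of <- c(NA, "polyX")
  calls <- data.frame(insertion_id = c("i1", "i2"),
                      source_id = c("sB", "sA"), stringsAsFactors = FALSE)
  out <- resolve_proxy(calls, cat_fx)
  expect_equal(out$source_id, c("polyX", "sA"))
  expect_equal(out$proxy_reassigned, c(TRUE, FALSE))
  again <- resolve_proxy(out, cat_fx)
  expect_identical(again, out)
  # proxy chains are refused
  chain_cat <- rbind(cat_fx, cat_fx[1, ])
  chain_cat$source_id[3] <- "polyX"
  chain_cat$proxy_of[3] <- "sA"
  expect_error(resolve_proxy(calls, chain_cat), "proxy")
})

test_that("cascade links follow parent flank evidence", {
  cfg <- small_cfg(seed = 13, include_cascade = TRUE)
  sr <- simulate_reference(cfg)
  cat_df <- build_catalog(sr$reference, sr$bed)
  truth <- simulate_insertions(cfg, sr)
  lr <- simulate_longread_calls(cfg, truth, error = 0)
  ann <- annotate_insertions(lr, cat_df, sr$reference, params = params)
  child_truth <- truth[!is.na(truth$cascade_parent), ]
  child <- ann[ann$insertion_id == child_truth$insertion_id, ]
  expect_equal(child$cascade_parent, child_truth$cascade_parent)
  expect_equal(child$source_id, child_truth$source_id)
  # ordinary transductions stay unlinked
  ordinary <- ann[ann$label == "somatic" &
                    ann$insertion_id != child_truth$insertion_id, ]
  expect_true(all(is.na(ordinary$cascade_parent)))
})

test_that("a child with only the parent tag is linked to the parent", {
  cat_fx <- make_fixture_catalog()
  set.seed(63)
  flank <- random_dna_str(60)
  chrom <- paste0(random_dna_str(5000), flank, random_dna_str(1000))
  calls <- data.frame(
    insertion_id = c("parent1", "child1"),
    sample = c("G", "T1"), chrom = "chrF", pos = c(4999L, 2000L),
    label = c("germline", "somatic"),
    td_seq = c(substr(cat_fx$downstream_seq[1], 1, 150),
               paste0(flank, random_dna_str(10))),
    source_id = c("sA", NA), stringsAsFactors = FALSE)
  out <- resolve_cascade(calls, cat_fx, c(chrF = chrom), params)
  expect_equal(out$cascade_parent[2], "parent1")
  expect_equal(out$source_id[2], "parent1")
})

test_that("full-length somatic insertions are flagged above 5990 bp", {
  cat_fx <- make_fixture_catalog()
  full <- paste0(cons, strrep("A", 30))
  calls <- data.frame(insertion_id = "f1", sample = "T1", chrom = "chr3",
                      pos = 1000L, label = "somatic", seq = full,
                      stringsAsFactors = FALSE)
  ann <- annotate_insertions(calls, cat_fx, NULL, params = params)
  expect_true(ann$full_length)
  expect_equal(ann$class, "solo")
})
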