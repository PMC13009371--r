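params <- pipeline_params()

# a hand-built mini reference: one plus- and one minus-strand element with
# known flanks
make_mini_ref <- function(seed = 31) {
  set.seed(seed)
  cons <- l1_consensus()
  bg1 <- random_dna_str(30000)
  bg2 <- random_dna_str(30000)
  chr1 <- paste0(substr(bg1, 1, 10000), cons, substr(bg1, 10001, 30000))
  # minus-strand element on chr2
  rc_cons <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(cons)))
  chr2 <- paste0(substr(bg2, 1, 12000), rc_cons, substr(bg2, 12001, 30000))
  list(
    reference = c(chr1 = chr1, chr2 = chr2),
    ann = data.frame(
      chrom = c("chr1", "chr2"), start = c(10000L, 12000L),
      end = c(10000L + nchar(cons), 12000L + nchar(cons)),
      name = c("p1", "m1"), strand = c("+", "-"), stringsAsFactors = FALSE),
    cons = cons)
}

test_that("tags are the 30-mer immediately 3' of the element, strand-aware", {
  mini <- make_mini_ref()
  cat_df <- build_catalog(mini$reference, mini$ann, params = params)
  e <- mini$ann$end[1]
  expect_equal(cat_df$tag[1], substr(mini$reference[["chr1"]], e + 1, e + 30))
  s <- mini$ann$start[2]
  expect_equal(cat_df$tag[2], as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(substr(mini$reference[["chr2"]], s - 29, s)))))
  expect_true(all(cat_df$is_full_length))
  expect_true(all(cat_df$usable))
  expect_equal(cat_df$tag_genomic_hit_count, c(1L, 1L))
})

test_that("tag extraction is an involution under strand flip", {
  mini <- make_mini_ref()
  cat_fwd <- build_catalog(mini$reference, mini$ann, params = params)
  flipped_ref <- vapply(mini$reference, function(s)
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(s))),
    character(1))
  lens <- vapply(mini$reference, nchar, integer(1))
  ann2 <- mini$ann
  ann2$start <- lens[ann2$chrom] - mini$ann$end
  ann2$end <- lens[ann2$chrom] - mini$ann$start
  ann2$strand <- ifelse(mini$ann$strand == "+", "-", "+")
  cat_rev <- build_catalog(flipped_ref, ann2, params = params)
  expect_equal(cat_rev$tag, cat_fwd$tag)
  expect_equal(cat_rev$downstream_seq, cat_fwd$downstream_seq)
})

test_that("short elements are retained but excluded from tag detection", {
  mini <- make_mini_ref()
  ann <- mini$ann
  ann$end[1] <- ann$start[1] + 5000L   # truncated element
  cat_df <- build_catalog(mini$reference, ann, params = params)
  expect_false(cat_df$is_full_length[1])
  expect_false(cat_df$usable[1])
  expect_equal(cat_df$source_id[1], "p1")
})

test_that("out-of-bounds annotations error with the record name", {
  mini <- make_mini_ref()
  ann <- mini$ann
  ann$end[2] <- nchar(mini$reference[["chr2"]]) + 50L
  expect_error(build_catalog(mini$reference, ann, params = params), "m1")
})

test_that("approximate hit counting agrees with an edit-distance oracle", {
  set.seed(55)
  tag <- random_dna_str(30)
  bg <- random_dna_str(5000)
  mutate <- function(s, k) {
    ch <- strsplit(s, "")[[1]]
    pos <- sample(length(ch), k)
    for (p in pos) ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
    paste(ch, collapse = "")
  }
  # plant: exact, 2-sub, 3-sub, 5-sub, and a reverse-complement copy
  variants <- c(tag, mutate(tag, 2), mutate(tag, 3), mutate(tag, 5),
                as.character(Biostrings::reverseComplement(
                  Biostrings::DNAString(tag))))
  genome <- paste0(substr(bg, 1, 500), variants[1], substr(bg, 501, 1500),
                   variants[2], substr(bg, 1501, 2500), variants[3],
                   substr(bg, 2501, 3500), variants[4],
                   substr(bg, 3501, 4500), variants[5],
                   substr(bg, 4501, 5000))
  got <- count_approximate_hits(tag, c(chrT = genome), max_edits = 3)
  # oracle: sliding Levenshtein distance (utils::adist), same dedup rule
  dists <- vapply(variants, function(v) adist(tag, v), numeric(1))
  expected_fwd <- sum(dists[1:4] <= 3)
  expect_equal(got, as.integer(expected_fwd + 1L))  # +1 for the rc copy
})

test_that("hyper-repetitive tags are excluded by the 1000-location filter", {
  set.seed(56)
  tag <- random_dna_str(30)
  copies <- 1100L
  spacer <- random_dna_str(50)
  genome <- paste(rep(paste0(tag, spacer), copies), collapse = "")
  cnt <- count_approximate_hits(tag, c(chrR = genome), max_edits = 3)
  expect_gt(cnt, params$tag_max_genomic_hits)
})

test_that("similar sites are Hamming matches excluding the source locus", {
  set.seed(57)
  tag <- random_dna_str(30)
  mutate_n <- function(s, k) {
    ch <- strsplit(s, "")[[1]]
    for (p in sample(length(ch), k)) {
      ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
    }
    paste(ch, collapse = "")
  }
  near <- mutate_n(tag, 4)   # within 6 mismatches
  far <- mutate_n(tag, 7)    # beyond
  bg <- random_dna_str(4000)
  genome <- paste0(substr(bg, 1, 1000), tag, substr(bg, 1001, 2000), near,
                   substr(bg, 2001, 3000), far, substr(bg, 3001, 4000))
  sites <- find_similar_sites(tag, c(chrS = genome), max_mismatches = 6,
                              exclude = list(chrom = "chrS", start = 1000L))
  expect_equal(nrow(sites), 1L)
  expect_equal(sites$start, 2030L)
  none <- find_similar_sites(far, c(chrP = paste0(substr(bg, 1, 1000), far)),
                             max_mismatches = 6,
                             exclude = list(chrom = "chrP", start = 1000L))
  expect_equal(nrow(none), 0L)
})

test_that("internal PAS annotation keeps the strongest final-window hit", {
  pwm <- build_default_pwm()
  seq1 <- paste0(random_dna_str(500), strrep("C", 20), "AATAAA",
                 strrep("C", 24))
  pas <- annotate_internal_pas(seq1, pwm, params)
  expect_equal(pas$hexamer, "AATAAA")
  # two candidates: the stronger (AATAAA > ATTAAA) wins
  seq2 <- paste0(random_dna_str(500), "ATTAAA", strrep("C", 10), "AATAAA",
                 strrep("C", 28))
  expect_equal(annotate_internal_pas(seq2, pwm, params)$hexamer, "AATAAA")
  # all-C tail has nothing above the floor
  seq3 <- paste0(random_dna_str(500), strrep("C", 50))
  expect_null(annotate_internal_pas(seq3, pwm, params))
})

test_that("catalog TSV round-trips with 1-based loci in the file", {
  mini <- make_mini_ref()
  cat_df <- build_catalog(mini$reference, mini$ann, params = params)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_catalog(cat_df, f)
  first <- read.table(f, sep = "\t", header = TRUE, nrows = 1)
  expect_equal(first$start_1, cat_df$start[1] + 1L)
  back <- read_catalog(f)
  expect_equal(back$start, cat_df$start)
  expect_equal(back$tag, cat_df$tag)
})
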