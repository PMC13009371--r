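# retrotag

Detection and characterization of somatic LINE-1 (L1) 3' transductions.

## The problem

Active "hot" L1 source elements drive most somatic retrotransposition in
colorectal and other cancers. When transcription reads through a source
element's polyadenylation signal (PAS), unique downstream genomic sequence
is co-mobilized with the new insertion — a **3' transduction** — and acts
as a fingerprint tracing the insertion back to its source locus. Short
transductions are systematically missed by conventional short-read
callers, biasing the catalog of active elements toward sources that
produce long transductions.

`retrotag` implements the full computational procedure for a
transduction-centric survey of L1 activity, for genomics researchers who
want each stage as a tested, reusable function:

* **Tag-based short-read detection** — each full-length source element
  (5700–6700 bp) defines a *tag*, the exact 30-bp sequence 3' of its end.
  Read pairs containing a tag are fished out of the alignments; the mate
  (the *anchor*, MAPQ ≥ 37) localizes the insertion. Anchors cluster
  within 1 kbp; clusters with ≥ 3 reads, more than 2 kbp from any site
  resembling the tag (≤ 6 mismatches), are transduction calls. Calls merge
  across samples within 2 kbp; events private to a single tumor are
  somatic.
* **Hallmark scoring** — target site duplication from the two modal
  split-read positions, polyA tracts by a sweep-line score (+1 match,
  −3 mismatch, detection limit 10), and the endonuclease cut site by a
  positionally weighted match (weights 1,1,3,4,1,1) to the TTTT/AA
  consensus, cut sites scoring ≥ 6.
* **Long-read insertion annotation** — classification into
  solo/partnered/orphan, source assignment by unique alignment within
  3 kbp of a source 3' end, component lengths, dual polyA, 5' inversion
  detection, proxy reassignment and multigenerational cascade linking;
  somatic insertions > 5990 bp are flagged full-length.
* **PAS model** — a calibrated position-weight-matrix scan (strong > 8.1,
  weak < 8) associating transduction endpoints with a PAS 10–30 bp
  upstream, and grading the internal PAS in each element's final 50 bp.
* **Inversion clustering** — rectangular-kernel (bandwidth 10 bp)
  clustering of 5' inversion breakpoints as distances to the L1 3' end.
* **Methylation analysis** — promoter methylation averaged over the
  200-bp window at each element's 5' end (CpG coverage 3–75, ≥ 3 CpGs,
  ≥ 75% sample availability), element activity classes, and Welch /
  Pearson association tests.
* **A seeded synthetic-data generator** producing a complete miniature
  study — reference genome with planted sources, insertion truth sets
  with TPRT hallmarks, analytically aligned paired-end reads,
  reconstructed long-read sequences, per-CpG methylation — so every stage
  is verifiable without protected patient data.

See `vignettes/l1-transduction-methods.Rmd` for the models, parameter
meanings and design choices.

## Worked example

Simulate a small two-source study, detect the planted transductions in
one tumor, and inspect the hallmarks:

```r
library(retrotag)

cfg <- simulation_config(
  seed = 7, n_chromosomes = 2, chrom_length = 400000,
  n_sources = 2, source_strands = c("+", "-"),
  activity_weights = c(2, 1), length_modes = list(78L, 337L),
  mode_weights = list(1, 1), inversion_rates = c(0.1, 0.3),
  n_tumor = 2, insertions_per_sample = 10, n_en_sites = 100)

sr      <- simulate_reference(cfg)
catalog <- build_catalog(sr$reference, sr$bed)
truth   <- simulate_insertions(cfg, sr)
aln     <- simulate_reads(cfg, sr, truth, "T1")
calls   <- detect_sample(aln, catalog, sr$reference, "T1")

calls[, c("source_id", "chrom", "locus", "tsd_length",
          "polya_present", "en_score", "orientation")]
#>   source_id chrom locus tsd_length polya_present en_score orientation
#> 1     src01  chr1 32379         13          TRUE       11           +
#> 2     src01  chr1 77537          8          TRUE       11           -
#> 3     src02  chr1 89947          6          TRUE       11           -
```

The study plants four transductions in T1; three are within reach of the
2×150 bp / 400 bp-insert assay and all three are recovered at their exact
breakpoints (`locus` is the 5'-most junction, 0-based; the fourth, a
partnered event whose tag lies beyond one insert length from both
junctions, produces no anchorable read pairs — the physical blind spot of
short-read tag detection). The TSD lengths match the planted 13/8/6 bp
duplications, every call shows a polyA tract and a perfect endonuclease
consensus (score 11 of a maximum 11, a TTTT/AA cut site), and the A/T
polarity of the tract gives the insertion orientation. The long-read
side, across both tumors, has no such blind spot:

```r
lr  <- simulate_longread_calls(cfg, truth, error = 0)
ann <- annotate_insertions(lr, catalog, sr$reference)
table(ann$class, useNA = "ifany")
#>   orphan partnered      solo
#>        1         4        10
```

matching the planted class mix exactly.

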