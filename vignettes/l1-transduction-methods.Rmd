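---
title: "Detecting somatic L1 3' transductions: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting somatic L1 3' transductions: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(retrotag)
```

## The problem

LINE-1 (L1) is the only autonomous human retrotransposon that remains
active, and in many cancers — colorectal cancer prominently — a handful of
"hot" source L1 loci generate most new somatic insertions. When
transcription of a source element reads through its polyadenylation signal
(PAS), the downstream genomic sequence is co-mobilized with the new copy: a
*3' transduction*. Because that downstream sequence is unique in the
genome, it acts as a fingerprint of the source locus, allowing a somatic
insertion to be traced back to the element that produced it. Insertions
carrying both L1 and downstream sequence are *partnered* transductions;
those carrying downstream sequence only are *orphans*; insertions with L1
sequence alone are *solo* and untraceable.

`retrotag` implements the computational machinery of this analysis as a
reusable, fully testable pipeline:

* **tag-based detection** of transductions in short-read alignments,
* **annotation of reconstructed long-read insertion sequences**
  (classification, source assignment, inversions, proxies, cascades),
* **retrotransposition hallmark scoring** (target site duplication, polyA
  tail, endonuclease cut site),
* **PAS scanning** with a position weight matrix,
* **rectangular-kernel clustering** of 5' inversion breakpoints,
* **promoter methylation aggregation** and its association with source
  activity,

plus a seeded **synthetic-data generator** that produces a complete
miniature study so every stage can be verified without protected patient
data.

## Tag-based short-read detection

Each catalogued full-length source element (5700–6700 bp) contributes a
*tag*: the exact 30-bp sequence immediately 3' of its annotated end, on the
element strand (`build_catalog()`). Tags that occur at more than 1000
genomic locations within edit distance 3 are too repetitive and exclude
their element from detection; positions matching a tag within 6
substitutions are recorded as *similar sites* for later filtering.

Detection then proceeds per sample (`detect_sample()`):

1. `scan_reads()` finds read pairs in which one mate contains a usable tag
   (or its reverse complement) as an exact substring; the other mate is the
   candidate *anchor*. Pairs in which both mates carry tags have no anchor
   and are dropped.
2. `cluster_anchors()` single-links anchors with MAPQ ≥ 37 within 1 kbp,
   per source and chromosome.
3. `filter_clusters()` calls a cluster a transduction when it has ≥ 3
   anchors and lies more than 2 kbp from any similar site of its source's
   tag — and from the source locus itself, whose own flank otherwise seeds
   self-hits.
4. `merge_across_samples()` single-links same-source calls within 2 kbp
   across samples; `call_somatic()` labels events supported by exactly one
   tumor and no normal as somatic.
5. `characterize_cluster()` annotates each call: soft-clip boundaries of
   reads in a ±500 bp window vote for the two modal split positions
   (breakpoints; ties toward the leftmost); the TSD is their signed
   distance (negative values, target-site deletions, are preserved); polyA
   polarity and score come from sweeping the mate sequences of discordant
   pairs oriented to the target plus strand; the tract polarity (A = plus,
   T = minus) sets the insertion orientation; and the endonuclease flank is
   read from the reference at the orientation-appropriate breakpoint.
   Hallmarks are annotation, never filters — missing evidence degrades to
   `NA`.

## Hallmark scores

**PolyA sweep.** A tract is scored by a running sum over the sequence (+1
per matching base, −3 per mismatch) floored at zero — Kadane's recursion —
so the reported score is the maximum over all contiguous windows. A score
of ≥ 10 declares the tract present. We read "10 as the limit" as a
*detection threshold*, not a score cap: under the cap reading a short
disrupted tract could never fail detection, which contradicts the score's
purpose.

**Endonuclease cut site.** The L1 endonuclease nicks at a degenerate
TTTT/AA consensus. The 6-mer around the initial breakpoint (four bases
upstream, two downstream, in insertion orientation; the later breakpoint
for plus-orientation events, the earlier for minus) is scored positionally
with weights 1,1,3,4,1,1 — the bases flanking the nick dominate — and
scores ≥ 6 qualify as cut sites.

**TSD.** The distance between the two breakpoints; positive is a
duplication, zero blunt, negative a target-site deletion.

## Long-read annotation

Reconstructed insertion sequences (the output shape of long-read SV
callers) are decomposed by `classify_insertion()`: local alignment to the
L1 consensus locates L1 content (identity ≥ 0.8 over ≥ 30 bp; both are
package choices exposed in `pipeline_params()`, since the original
analysis used whole-genome mapping instead of window alignment); a
sweep-tolerant scan anchored at the 3' end measures the terminal polyA; an
internal tract directly after the L1 segment is stripped; the remainder is
the candidate transduced sequence.

`assign_source()` aligns that candidate against the 3-kbp downstream
window of every catalogued element and requires the best window to beat
the second best by ≥ 5 score units — the window-level equivalent of the
"MAPQ > 0" uniqueness requirement of a genome-wide mapper. The alignment's
3' terminus defines the transduction endpoint, hence the transduction
length. Ties are reported as `unassigned-ambiguous` rather than guessed.

Three refinements follow:

* **Dual polyA** (`detect_dual_polya()`): partnered events with both an
  internal and a terminal tract at the detection limit.
* **5' inversions** (`detect_inversion()`): the segment preceding the
  forward-aligned template portion is aligned against the template in the
  opposite orientation; breakpoints are reported as distances from the L1
  3' end (or as downstream offsets for orphans, whose inversions live in
  transduced sequence).
* **Proxies and cascades** (`resolve_proxy()`, `resolve_cascade()`): a
  truncated reference element carrying the transduced sequence of a
  non-reference source captures that source's calls; `proxy_of` links
  relabel them (one step, idempotent, chains refused). A somatic call
  whose transduced sequence contains both a source's downstream sequence
  and a germline insertion's genomic flank is a second-generation event:
  it is linked to the germline parent and attributed to the ultimate
  source, or to the parent itself when only the parent's flank is
  recognizable.

Insertions longer than 5990 bp (strictly) are flagged full-length — the
rare somatic events capable of seeding further cascades.

## PAS model

The paper-scale thresholds (strong > 8.1, weak < 8) are only meaningful
relative to a concrete matrix, and the original matrix is not
reproducible from printed information. The package therefore ships its own
documented default (`build_default_pwm()`): position frequencies from the
usage table of known human PAS hexamer variants (AATAAA ≈ 58%,
ATTAAA ≈ 15%, eleven rarer single-base variants), 0.01 pseudocounts,
log2-odds against a uniform background, then a linear calibration pinning
AATAAA to 9.0 and ATTAAA to 8.3. Under this calibration AATAAA is the
unique argmax over all 4096 hexamers, exactly the two canonical variants
are strong, and scores in the printed gap (8, 8.1] are labelled
`intermediate` rather than silently binned. Every PWM carries a
provenance label that propagates into outputs; any user matrix can be
supplied as a plain-text file (`read_pwm()`).

Scanning is single-stranded in transcript direction (PAS recognition is
strand-specific). `associate_endpoints()` pairs each transduction endpoint
with the strongest strong-class PAS starting 10–30 bp upstream — the
canonical spacing between PAS and cleavage site; `classify_internal_pas()`
grades the strongest hexamer in each element's final 50 bp.

## Inversion breakpoint clustering

Both breakpoints of every 5' inversion enter one pooled set of distances
to the L1 3' end. The density is a rectangular kernel with bandwidth
10 bp; clusters are the maximal runs of positive density, equivalent to
single-linkage with gap ≤ 2×bandwidth — the unique parameter-free reading
of "rectangular kernel clustering". Cluster modes are the most frequent
member distance (ties toward the smallest). A numerical note: the density
is piecewise constant with jumps at data ± bandwidth, so its integral is
computed exactly by midpoint sums over unit cells (`rect_kde_eval()`); a
trapezoid on the integer grid would carry O(1) boundary error.

## Promoter methylation

`window_average()` aggregates per-CpG methylated fractions over the
200-bp window centred on the element's 5' end in element orientation
(100 bp inside, 100 bp outside; for minus-strand elements the window is
centred on the annotated end coordinate). CpGs with coverage outside
3–75 are discarded; a summary needs ≥ 3 surviving CpGs to count, and an
element enters cross-sample analyses only when ≥ 75% of samples have a
usable summary and the element is autosomal, reference, and fixed.
Elements are classed `active` (transductions in ≥ 4 samples), `minor`
(1–3), `inactive` (0), or `inactive_weak_pas` (0 with a weak internal
PAS). `test_association()` reports per-element Pearson correlations
(two-sided, Fisher-z CI) between methylation and per-sample transduction
counts, and a pooled two-sided Welch's t-test of transduction-positive vs
-negative element–samples. Haplotype-resolved methylation is out of scope:
the module operates on haplotype-collapsed records.

## The synthetic study

The generator (`simulation_config()` and the `simulate_*` functions)
defines the package's fixed study conditions:

* a 3-Mb genome (3 × 1 Mb chromosomes) with 5 planted full-length source
  elements whose relative activities (78/72/34/24/18), modal transduction
  lengths (78/337/818/861/72 bp) and 5' inversion rates (6–32%) follow the
  most active sources of a colorectal-cancer cohort; one source is on the
  minus strand;
* 4 tumor samples (~44 somatic insertions each, Poisson) plus one
  insertion-free normal; 23% of insertions carry transductions, of which
  a quarter are orphans;
* transduction endpoints terminate 10–30 bp downstream of a planted PAS
  with probability 0.8 (the planted offsets are `mode − 21`, so endpoints
  reproduce the modal lengths); the remaining endpoints follow a geometric
  tail kept ≥ 50 bp clear of planted signals, which is what makes the
  endpoint–PAS association recoverable *and* falsifiable;
* TPRT hallmarks: TSD uniform 5–20 bp, polyA uniform 10–60 bp, 90% of
  integration sites at planted endonuclease consensus motifs
  (orientation-stratified: plus-strand TTTTAA for plus events, TTAAAA for
  minus events, so the asymmetric 4+2 flank reads TTTT/AA in insertion
  orientation either way);
* 2 × 150 bp read pairs at 30× with insert 400 ± 50 bp, aligned
  *analytically*: junction-spanning reads soft-clip exactly at junctions
  when a target flank dominates; interior-dominant reads are placed at the
  homologous source locus by component midpoint (transduced sequence →
  downstream flank, MAPQ 60; L1 body → element body, MAPQ 10; polyA →
  MAPQ 0). No aligner binary is needed and tests are hermetic;
* long-read insertion sequences as the truth sequences with i.i.d.
  substitution noise (1% default);
* per-CpG methylation from Beta distributions (mean 35% at sample-wise
  active promoters vs 75% inactive, sd 10 points; coverage Poisson,
  mean 20). The Beta family and the TSD/polyA ranges are package choices —
  the underlying study reports no generative model for them.

Every generator stage is byte-deterministic under the configuration seed.

What the generator does *not* emulate — and therefore what green tests do
not certify on real data: sequencing errors in short reads, indel errors
in long reads, tumor purity and subclonality, reference gaps and
low-complexity regions, multi-mapping beyond the planted repeats, and
germline-vs-somatic insertion-length differences (length scales are
configurable but the biological cause is not modelled).

## Numerical choices and degenerate inputs

Thresholds printed with a strict operator are strict (PAS > 8.1, full
length > 5990); printed "≥" are inclusive (MAPQ ≥ 37, ≥ 3 reads, EN ≥ 6,
≥ 3 CpGs). Tags containing `N` are unusable, not errors. All-`N`
insertion sequences are `unclassifiable`. Ties: leftmost best polyA
window; smallest mode among equally frequent breakpoint distances;
smallest value among tied per-source length modes (and the mode is omitted
when all lengths are distinct). Kruskal–Wallis uses the chi-square
approximation with tie correction. Degenerate statistics (constant
vectors, groups under 2 members) are reported as undefined with a reason,
never silently dropped. Genomic intervals are 0-based half-open
internally; emitted tables are 1-based inclusive where noted.

## Problem sizes used in the checks

The packaged checks run the full detector on the 3-Mb / 5-source / 30×
study (about 1.5 M read pairs across 5 samples), annotate ~200 long-read
insertion sequences at 0% and 1% noise, recover the methylation contrast
on 30 samples, and calibrate the length test on 1000 null replicates —
sizes chosen so the whole suite exercises every stage end-to-end at
desk scale.

## Limitations

Tag detection inherits the assay's physical limits: a partnered event
whose tag lies more than one insert length from both junctions produces no
anchorable pairs and is invisible to short reads regardless of
implementation — the generator reproduces this, and such events are
reported via the long-read path instead. Source assignment resolution is
bounded by downstream-window homology; identical windows are reported
ambiguous rather than resolved. The PAS scale is calibrated, not copied,
so absolute scores are comparable only within one matrix provenance.
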