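---
title: "Detecting bacterial-human lateral gene transfer from paired-end RNA-seq"
author: "lgtscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting bacterial-human lateral gene transfer from paired-end RNA-seq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lgtscan)
```

## The detection model

A bacterial integration into an expressed region of the host genome
produces chimeric RNA fragments. When such a fragment is sequenced from
both ends and the junction happens to fall in the unsequenced insert
between the mates, the pair shows a characteristic signature: one mate
aligns cleanly to the host genome, the other aligns cleanly to a
bacterial reference, and neither maps to the other side. `lgtscan` calls
a pair LGT-supporting exactly when

* its fate against the host reference is half-mapped (one primary-mapped
  mate, one unmapped mate), and
* after realignment of both mates to the bacterial reference set, the
  host-unmapped mate has a primary bacterial hit while the host-mapped
  mate has none (two-sided exclusivity).

The exclusivity rule is what separates genuine chimeras from homology
artifacts: a host mate that also matches bacterial sequence (conserved
rRNA-like regions, contamination in the references) disqualifies the
pair. Because only mapped/unmapped status of the single primary hit per
mate enters the fate logic, supplementary or secondary alignments play no
role.

Detection cannot resolve the junction at base-pair precision — by
construction the junction lies inside the insert — so an event is keyed
by the pair of alignment anchor points
`(host_chrom, host_start, bact_accession, bact_start)`. Read pairs
sharing that exact key are treated as technical duplicates of one
integration observation and collapsed per sample; two pairs anchored even
one base apart count as distinct events. This literal interpretation of
"same position" avoids a binning parameter; at realistic sequencing
depths the chance that two independent fragments share both anchors is
negligible, while PCR duplicates share them exactly.

## The built-in aligner

The aligner is a deterministic seed-and-extend local aligner: exact
k-mer seeds (default `seed_k = 15`) on both strands, candidate diagonals
merged, and each candidate extended. A perfect full-length diagonal match
is recognised directly; otherwise a full affine-gap Smith-Waterman is run
on a reference window wide enough (pad = read length) to contain any
optimal local alignment that includes the seed, so the reported score
equals the unrestricted Smith-Waterman optimum whenever the optimum
contains an exact seed — a property the test suite checks against an
independent dynamic-programming implementation. Scoring defaults
(match +1, mismatch -4, gap open -6, gap extend -1, mapped threshold 30)
follow common short-read local-alignment practice; a gap of length *g*
scores `gap_open + g * gap_extend`, `N` always scores as a mismatch, and
a read shorter than `seed_k` is unmapped by definition. Ties between
equally scoring hits break deterministically: smallest reference id,
then smallest start, then the forward strand.

The aligner sits behind a narrow contract (`align_batch()` returning
primary hits), so an external aligner can be substituted at scale via the
SAM fate importer (`read_sam_fates()`), which applies the same
flag semantics (4 = unmapped, 8 = mate unmapped, 2048 = supplementary,
discarded).

## The filter cascade

Filters run in a fixed order, each recorded in the filter report:

1. **Coverage** — both mates must have at least `min_coverage = 0.90` of
   their bases in match/mismatch columns of their primary hit. Local
   alignment trims poorly matching ends, so a partially aligned
   (junction-straddling or adapter-contaminated) mate fails this filter.
   The threshold applies to *both* mates because a chimera call rests on
   the integrity of both anchors.
2. **Low complexity** — a candidate is dropped if either mate contains a
   homopolymer run of 20 bp or more, or if any single base exceeds 80% of
   the mate. The two thresholds are exposed as arguments; poly-A tails
   and poly-G artifacts are the target.
3. **Repeat overlap** — candidates whose host interval overlaps a repeat
   interval (0-based half-open BED semantics, 1 bp suffices) are flagged
   and, by default, excluded; `exclude_repeats = FALSE` keeps them
   flagged for downstream inspection. Exclusion is the default because
   repeat-region anchors cannot be placed uniquely enough to support an
   integration call.
4. **Deduplication** — one event per junction key, representative pair
   chosen by lexicographic pair id, output sorted by key; the operation
   is idempotent. Dedup is per sample: duplicates are library-level
   (PCR/optical) artifacts, so collapsing across patients would discard
   genuine recurrence.

## Annotation

Events are annotated at the midpoint of the host interval against a gene
model table: exonic, UTR5/UTR3 (strand-aware, relative to the CDS),
splicing (intronic within 2 bp of an exon boundary, coding genes only —
the class enumeration carries no ncRNA splicing class), intronic,
ncRNA exonic/intronic for genes without a CDS, upstream/downstream within
1 kb of the transcript (strand-aware), else intergenic. Overlapping genes
resolve by the precedence exonic > splicing > UTR5 > UTR3 > intronic >
ncRNA exonic > ncRNA intronic > upstream > downstream, then
alphabetically. Anchoring at the midpoint yields exactly one class per
event, which is what a partition-style region distribution requires. The
2 bp splice window and 1 kb flanks follow the conventional annotation
defaults.

## Cohort statistics

Per-sample burden is `pct_lgt = 100 * n_events / total_pairs` — unique
events normalised to sequencing depth (a configurable alternative would
count supporting reads before dedup; unique events are the default
because duplicates carry no independent evidence). Cohorts are compared
with a classic pooled-variance unpaired two-tailed t-test (Welch behind a
flag), reporting mean- and median-based fold changes.

Genus-level event counts form a samples-by-genera matrix. For
stratification the counts are damped as `log2(count + 1)` — a single
hyper-abundant genus would otherwise dominate Euclidean distances — and
embedded by classical (Torgerson) MDS into two dimensions, which is exact
for intrinsically two-dimensional inputs. The embedding is split by
2-means initialised at the two most distant samples, removing the usual
seed dependence of k-means and staying invariant to the rotation
indeterminacy of MDS. The group with the higher mean burden is labelled
group 2, making the reported fold difference at least 1 by convention.

## Clinical association

Survival uses the product-limit estimator and the two-group log-rank test
(delegated to the survival package; the test suite re-derives both from
first principles). Burden is dichotomised at a maximally selected
cutpoint: every midpoint between consecutive sorted unique burden values
whose split leaves at least 10% of subjects on each side is scored by the
log-rank statistic, and the maximising cutoff (ties to the smaller value)
is reported. This is the standard operationalisation of a
regression-derived cutoff; the 10% guard prevents degenerate splits, and
the scan is invariant to monotone transforms of burden. The selected
statistic is maximally selected, so its nominal log-rank p-value is
anti-conservative and is reported as unadjusted.

Binary markers (IGHV mutation status, del11q, del17q, trisomy 12, del13q,
CD38) are tested against the grouping with two-sided Fisher's exact
tests; the RAI stage table with Pearson's chi-squared (no continuity
correction). Subjects missing a marker are dropped for that marker only,
with counts logged. Raw p-values are reported marker by marker, with a
Benjamini-Hochberg column alongside for transparency.

## What the synthetic generator emulates

`sim_config()` fixes the study conditions; the seed determines every
output byte. The generator emits:

* a host chromosome (default 100 kb, GC 0.5) with 30 non-overlapping
  gene models (2-4 exons, UTR flanks inside terminal exons, 20%
  non-coding) and a repeat track, plus 24 bacterial references (5 kb)
  across 12 genera;
* per sample (default 10^4 pairs, 100 bp reads, 300 +/- 30 bp fragments,
  truncated at twice the read length so a planted junction always falls
  in the insert) five truth classes: host pairs, pure-bacterial
  "microbiome" pairs (1%), LGT pairs (0.1%), low-complexity artifact
  pairs with one homopolymer mate (0.05%), and PCR duplicates that are
  byte-copies of an LGT pair (0.05%); substitution errors at 0.2% per
  base;
* a two-group cohort (default 20 + 20) in which group 2 multiplies the
  LGT rate by 2.8 — the magnitude of the stratified difference the
  analysis is meant to resolve — plus exponential OS/PFS with uniform
  administrative censoring (hazard ratio 1 by default: no planted
  survival effect) and marker frequencies typical of an untreated CLL
  cohort, identical in both groups by default (no planted association).

Deliberate simplifications, and what they imply about test evidence: the
host locus is treated as one expressed, unspliced transcript (mates are
contiguous reference substrings — no splice-aware placement); LGT
fragments are built host-part-first, so the host mate always sits on the
forward strand while a per-pair swap randomises which of R1/R2 carries
it; qualities are constant (the pipeline ignores them); there are no
indels, no coverage biases, and no real homology structure between host
and bacterial references. Planted LGT host anchors avoid the repeat
track, so the planted truth is detectable by construction and the repeat
filter is validated on constructed candidates instead. Passing the
recovery tests therefore demonstrates the correctness of the chimera
logic, filters and statistics under the stated error model — not
robustness to splicing artifacts, conserved rRNA homology or real
RepeatMasker-scale repeat content.

The generator also has a counts-only mode that draws per-sample truth
class counts directly from the multinomial law the per-pair draw induces.
Burden-level calibration studies (power, null uniformity) use it: at the
full stated scale (100 replicates of 40 samples at 10^5 pairs) read-level
replication would cost ~4x10^8 alignments and add nothing, because
read-level recovery of planted events is established separately (100% on
the error-free 10^5-pair benchmark).

## Numerical choices and degenerate inputs

All internal coordinates are 0-based half-open; conversion happens only
at serialization boundaries. Fragment lengths resample until inside
`[2 * read_length, min_reference_length)`. The aligner evaluates merged
candidate diagonals and never reports an interval crossing a reference
boundary, since each reference is aligned separately. `cmdscale` output
with fewer than two positive eigenvalues is zero-padded. An empty event
set yields an empty region distribution (not an error); an all-missing
marker is skipped and logged; a cohort with fewer than two samples per
arm, a cutpoint scan with no admissible split, and a zero read total are
errors. Derived seeds stay inside the 32-bit signed range.

## Problem sizes used by the checks

The test suite and the acceptance script run at desk scale, chosen so the
properties they probe are already stable: one 10^5-pair error-free sample
(~100 planted junctions) for recovery and specificity; 1000 randomized
candidates for filter-oracle equivalence; a 50-gene model at 10^4
positions for annotation; 200 planted-substring instances for the
aligner-vs-Smith-Waterman check; 100 replicate cohorts (20+20 at 10^5
pairs, counts-only) for power against a 2-fold burden difference; 200
null cohorts for calibration. Numbers printed in the README come from the
code as shown there.

## Known limitations

Within-mate (split-read) chimeras are out of scope, so junctions are
anchored, not base-resolved. The low-complexity thresholds are heuristic
and exposed rather than learned. The maximally selected cutpoint p-value
is unadjusted. MDS + 2-means presumes two groups; the generator plants at
most two. The built-in aligner is adequate for reference sets in the
hundreds of kilobases; genome-scale references should go through the SAM
import path.
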