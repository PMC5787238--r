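---
title: "Multi-region 16S profiling: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-region 16S profiling: model, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smurf16S)
```

## The reconstruction model

smurf16S estimates the composition of a microbial community from short
reads sequenced over several independently amplified 16S rRNA gene
regions.  The estimand is a mixture over *full-length reference
sequences*: every sequence `j` in the (ambiguity-expanded) reference is a
mixture component, and the data are the retained unique reads with their
counts, pooled over all regions.

Three model ingredients:

1. **Amplification.**  Sequence `j` is amplified in a region when both
   primers match it with at most two substitutions (IUPAC-aware,
   no indels).  The amplicon excludes the primer bases, because reads have
   their primers trimmed before matching.  `R_j` is the number of
   amplified regions.
2. **Emission.**  An amplified region emits one read-length k-mer per
   sequence in paired-end mode (first `k` bases of the amplicon
   concatenated with the first `k` bases of its reverse complement), or
   the two `k`-length ends separately in single-end mode.  The mixture
   matrix `M` assigns these k-mers probability `1/R_j` (paired) or
   `0.5/R_j` (single) so each amplified sequence's column sums to one.
3. **Errors.**  Reads are matched to same-region k-mers within two
   mismatches, with
   `E_ih = (p_e/3)^n_e (1 - p_e)^(L - n_e)` under a constant per-base
   error probability and positional independence.

With `Q = E M`, the likelihood of the `N` matched reads is
`prod_i (sum_j Q_ij pi_j)^{c_i}` — convex in the read-proportion vector
`pi` — and is maximized by the multiplicative EM fixed point implemented
in `em_reconstruct()`.  Frequencies are then
`x_j = (pi_j/R_j) / sum(pi_j/R_j)`: `pi` is a distribution over *reads*,
and dividing by the per-sequence k-mer count converts it to a
distribution over *organisms* (a sequence amplified in more regions
yields proportionally more reads at equal abundance).

Key model assumptions: uniform error rate along the read (no
quality-aware emission), substitutions only, equal sequencing effort per
k-mer of a given sequence, and a reference that actually contains the
community members — a sequence absent from the reference can only be
absorbed by its nearest 2-mismatch neighbours or dropped.

## Parameters that matter

| parameter | default | units | where | rationale |
|---|---|---|---|---|
| `p_e` | 0.005 | errors/base | `smurf()` | typical Illumina substitution rate; profiles are nearly invariant to it (tested at 0.001/0.005/0.02) |
| primer mismatch cap | 2 | bases | `locate_amplicons()` | the amplification definition |
| read/k-mer cap | 2 | bases | `compute_read_kmer_probabilities()` | matching tolerance; beyond it `E` is treated as 0 |
| read filter | 1e-4 | fraction of region reads | `collapse_and_filter_reads()` | sets the 0.01% detection floor; strictly-below counts are discarded |
| quality filter | >25% bases < Q30; >3 bases < Q10; any N | — | `quality_filter_reads()` | all three rules strict |
| group floor `min_freq` | 0.001 | fraction | `postprocess_profile()` | merged entries under 0.1% discarded, rest renormalized |
| EM `tol` | 1e-8 | max abs change in `pi` | `em_reconstruct()` | fixed-point steps are cheap; cap 10,000 iterations |
| trimmed length `L` | 75 | nt | `prepare_reads()` | see below |

**The 75 vs 76 nt question.**  With 100-nt reads, a 7-nt barcode and
18-nt primers, 100 − 7 − 18 = 75 nt remain, although trimmed multi-region
reads are sometimes described as 76 bp.  `L` is therefore a configuration
parameter defaulting to 75; nothing downstream depends on the specific
value as long as the database is built with the same `k`.

## The EM and its numerics

* `pi` starts uniform over candidates; the update preserves the simplex
  exactly (each iterate is an average of normalized rows), and the
  log-likelihood trace is asserted non-decreasing in the tests.
* Convexity means the fixed point finds the global optimum; the test
  suite cross-checks the final log-likelihood against an independent
  brute-force simplex grid search (coarse step 1e-3, refined to 1e-6) on
  instances with up to three candidates, agreeing within 1e-6.
* Likelihoods are accumulated in log space; the update itself works with
  ratios, which are stable because stored `E` entries are bounded below
  by `(p_e/3)^2 (1-p_e)^L`.
* After convergence, `pi` entries below 1e-12 are zeroed before
  normalization — numeric cleanup far below the 0.1% reporting floor.
* Reads that match no k-mer within the cap — or whose matched k-mers all
  belong to filtered-out candidates — are excluded from `N`: the
  likelihood is defined over matched reads only.

**Candidate filtering.**  A sequence is dropped before the EM when some
*sequenced* region exists in which its primers match perfectly yet none
of its k-mers received a single read.  Restricting the rule to regions
with at least one retained read is a deliberate choice: applied to a
region with no data at all the rule would vacuously remove every
amplified sequence, and an unsequenced database region carries no
evidence against anyone.  Sequences amplified only through imperfect
primer sites are never dropped by this rule.

**The strict filter boundaries.**  Both preprocessing filters discard on
strict inequality (a unique read with count exactly `threshold * N` is
kept; a read with exactly 25% of bases under Q30 is kept).  The
frequency cutoff is compared with a 1e-9 absolute epsilon so that
thresholds without an exact binary representation cannot flip the
boundary case.

## Footprints, groups and ambiguity

Sequences with identical k-mers over all amplified regions — including
*which* regions amplify them — have identical `Q` columns and are
fundamentally indistinguishable; they form a *group*.  Profiles are
reported per group (`assign_groups()`), and per-organism resolution is
the *ambiguity*: group frequencies are split equally among member
sequences, normalized over the organism's groups, and the exponent of
the Shannon entropy (natural log) of that weight vector is returned.
Equal within-group splitting is the unique convention consistent with
the single-group case, where ambiguity must equal the group size; how to
weight sequences when an organism spans several groups is otherwise
underdetermined, and the equal-split rule is declared here as the
package's convention.  Adding a region can only refine footprints, so
group sizes — and single-group ambiguities — are monotonically
non-increasing in the region set; this is asserted as a regression test.

## What the simulator emulates — and what it does not

`synthetic_reference()` builds toy references with exact primer sites and
per-region core pools; shrinking a region's pool forces sequences to
share that region's k-mer, reproducing the footprint-collision structure
that makes single-region profiling ambiguous.  Communities follow the
1/rank power law (`sample_power_law_community()`): in a 100-member
community the bottom half carries only ~13% of the mass, so most members
are rare and the low-frequency filter and read depth genuinely matter.
`simulate_region_reads()` splits a constant read budget equally across
regions (the split is not otherwise specified anywhere; equal division
is the natural choice and makes the per-region depth fall as regions are
added), renormalizes member frequencies over the sequences amplified in
each region (PCR dropout), and corrupts bases i.i.d. at a configurable
substitution rate (default 0.005), with `sampling = "expected"`
available for exact-recovery experiments.

Deliberately **not** modelled: position- or motif-dependent error
profiles, indels, chimeras, quality-score degradation along the read,
PCR efficiency differences between templates (amplification bias), and
16S copy-number variation.  Passing the simulation suite therefore
demonstrates correctness of the estimator and the resolution machinery
under the stated error model — not robustness to every artefact of real
sequencing runs.  On real data the main visible differences are
frequency biases against primer-mismatched templates and false positives
from contamination, neither of which a simulator of this kind exercises.

## Problem sizes used by the test suite

Tests run on generated toy instances chosen to exercise every code path
at desk scale: references of 2–200 sequences with 1–3 regions, read sets
of 2,000–30,000 reads, EM instances up to 40 unique reads × 10
candidates, 20 seeded replicates for the precision-improvement
experiment, and grid-search oracles restricted to ≤ 3 candidates.  The
end-to-end recovery checks use noiseless reads with exactly proportional
counts, where the estimator must reproduce the designed frequencies to
1e-6 (1e-4 percentage points for the even ten-member mixture).

## Known limitations

* Exact-sequence evaluation (`weighted_precision_recall()`) counts a
  reconstruction one base away from the truth as a complete error, by
  design; it is a resolution benchmark, not an ecological distance.
* The reference is held in memory as a plain data frame; profiling
  against a million-sequence database is I/O- and memory-feasible only
  via the persisted k-mer database directory, and the dense per-region
  Hamming matching is the bottleneck at that scale.
* Taxonomy merging uses the reference lineage string at a chosen rank as
  the classification stand-in; no external classification service is
  called.
* `R_j` counts amplified regions only; 16S operon copy-number correction
  is out of scope.
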