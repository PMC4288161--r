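---
title: "Discovering motifs and motif modules in open chromatin: methods"
author: "modmotif"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering motifs and motif modules in open chromatin: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the model

DNase I hypersensitive sites (DHSs) are short stretches of open chromatin,
typically a few hundred base pairs, in which most transcription-factor
(TF) binding takes place.  Because several TFs usually bind together
within one cis-regulatory module, the binding sites of their motifs
*co-occur* in the same short regions far more often than independence
would predict.  `modmotif` turns that observation into a discovery
principle: instead of asking whether a single sequence pattern is
over-represented, it asks whether a *set* of patterns lands in
significantly many regions together.  This lets individually
under-represented motifs surface through their co-factors, and it
suppresses the false positives that plague single-pattern
over-representation at this scale.

The pipeline on one DHS dataset:

1. **Preprocess regions.** Every region shorter than 800 bp is extended
   evenly from both ends to 800 bp (cis-regulatory modules are typically
   at least that long); regions longer than 5000 bp are discarded.
   Repeats and exons are masked to `N`.
2. **Rank k-mers.** All 8-mer patterns are counted over both strands in
   the masked sequences (a pattern and its reverse complement are one
   double-stranded word, keyed by the lexicographically smaller string;
   windows containing `N` are skipped) and ranked by a Poisson
   z-statistic, `(observed - expected) / sqrt(expected)`, against an
   order-2 Markov background fitted on the same masked sequences.  The
   top 2000 patterns become candidate motifs — around 1500
   sequence-specific human TFs exist and one TF can bind several motifs,
   so 2000 candidates cover the plausible motif space of one condition.
3. **Discover modules.** A *motif module* is a set of 2–6 candidate
   patterns whose exact-match occurrences co-occur in significantly many
   regions.  With marginal region frequencies $p_i$, the null
   co-occurrence probability of a set is $q=\prod_i p_i$ and the p-value
   the exact upper binomial tail $P(X \ge \mathrm{support} \mid n, q)$.
   All pairs are tested with a Bonferroni factor of $\binom{m}{2}$; a
   set of size $s\ge 3$ is a candidate only when each of its
   $(s-1)$-subsets is itself significant, with a per-level Bonferroni
   factor equal to the number of candidate sets at that level
   (significance closure).  Pairs of patterns that are shifts of one
   another (exact overlap of more than `pattern_overlap_max = 5` bp in
   either orientation) are ineligible: such a pair is two windows onto
   one longer word, and its "co-occurrence" reflects a single site.
4. **Iterate.** Patterns contained in significant modules are emitted as
   motifs, excluded from the ranking, and the ranking/discovery round
   repeats until 2000 motifs have been found or `stop_rounds_r = 3`
   consecutive rounds add none.  (A round that adds no motif leaves the
   exclusion list unchanged, so every later round is identical; the stop
   is reached deterministically.)
5. **Refine motifs.** Each discovered pattern becomes a position weight
   matrix (PWM) from its exact-match sites (additive pseudocount 0.25
   per base; minus-strand sites reverse-complemented).  Flanking columns
   whose information content, $2+\sum_b p_b\log_2 p_b$, reaches at
   least `ic_min = 0.5` bits are appended (higher-information side
   first, ties to the right); terminal columns below the threshold are
   trimmed; widths stay within [6, 16].  Sites and modules are updated
   accordingly, and motifs whose adjusted site sets coincide are merged.

## Motif similarity and its E-values

Across datasets the same underlying motif re-appears with small
variations, so downstream analyses need a calibrated notion of "the same
motif".  Two column metrics are combined, each guarding against a
different failure mode:

* **Pearson column correlation** — insensitive to information content
  but robust to length artifacts (a uniform, zero-variance column scores
  0 by convention);
* **Average log-likelihood ratio (ALLR)** against a flat background —
  rewards *informative* agreement, so low-information patterns cannot
  masquerade as matches.

Motif pairs are aligned ungapped at every offset with at least
`min(6, shorter width)` overlapping columns, in both orientations, and
the best mean per-column score is kept.  Raw scores are converted to
E-values against a null of `null_samples = 2000` random-motif
comparisons per width pair (each random row is four uniform(0,1) draws
normalized to sum to one).  Two tail estimates are available:

* `method = "empirical"`: the add-one empirical tail
  $E = n_{\mathrm{comp}}\,(1+\#\{\mathrm{null}\ge s\})/(1+|\mathrm{null}|)$,
  whose floor is $n_{\mathrm{comp}}/(1+|\mathrm{null}|)\approx 5\times
  10^{-4}$;
* `method = "fitted"` (pipeline default): a Gaussian fitted to the null
  scores.  Because each score is a mean over at least six aligned
  columns, the null is close to normal, and the fitted tail extrapolates
  smoothly below the empirical floor — necessary because the clustering
  thresholds (anchor E < 1e-8) lie far beneath what any affordable
  empirical null can resolve.  A heavier-tailed extreme-value fit was
  considered and rejected: its tail is so slow that even identical
  sharp motifs would not reach 1e-8, which contradicts the intended
  semantics of the thresholds.

Two motifs are *similar* when (corr E < 0.5 **and** ALLR E < 1e-4) or
(corr E < 1 **and** ALLR E < 1e-5).  The rule is symmetric, and adding
uninformative flanking columns rarely changes the verdict (checked as a
property test).

## Non-redundant clustering

Clusters are built sequentially: every motif of the dataset with the
most motifs seeds a cluster; motifs from the remaining datasets (in
descending motif-count order) join the first cluster, in creation order,
that satisfies the anchor-and-membership rule — ALLR E < 1e-8 to at
least one member, and ALLR E < 1e-5 to all members when the cluster has
fewer than 4, or to at least 90% of members otherwise.  Motifs joining
no cluster are pooled; mutually similar pooled motifs found new clusters
(greedy, seeding from the motif with the most pooled similars), the rest
become singletons.  Each cluster is represented by the member similar to
the most other members (ties to the earliest added), and clusters with
pairwise-similar representatives are refined by average-linkage
hierarchical clustering on one minus the normalized ALLR score, cut at
the coarsest level whose clusters all satisfy the membership rule
internally, for at most 10 iterations.  Processing datasets in ascending
order instead changes the final cluster count by well under 1% on the
synthetic benchmark, mirroring the robustness expected of the procedure.

## Genomic region types and enrichment

From a gene annotation, 16 region types are built with 0-based half-open
coordinates: proximal TSS and proximal TTS windows (2.5 kb, strand
aware — upstream of a minus-strand gene lies to its right), 5' and 3'
UTRs, first and other introns, and 5'/3' distal territories at cutoffs
of 2.5, 5, 10, 20 and 100 kb.  The 5' > x distal territory of a gene is
its upstream ray beyond distance x from the TSS minus every other
gene's body expanded by x on both sides; 3' territories mirror this
downstream.  "Pure" variants subtract the opposing type (proximal TSS
vs TTS; 5' vs 3' distal at the same cutoff).  A motif's enrichment in a
type is the exact upper binomial tail of its site count inside the type
(a site lies in a type iff its midpoint does; an any-overlap convention
can be substituted), with success probability the fraction of DHS base
pairs the type covers, Bonferroni-corrected over motifs × types at
level 0.01.

## Validation and classification

Predicted motifs are validated by coverage of a known-motif collection
(a collection motif is covered iff similar to at least one prediction),
against a baseline of random motifs matched in number and width,
repeated 10 times.  Motif modules are validated by mapping each motif to
the TF of its most similar labelled reference motif (lowest ALLR
E-value; ties by corr E-value, then lexicographic) and comparing module
TF pairs with known interaction lists on the universe of pairs whose TFs
occur among the mapped TFs.  Finally, dataset cell/tissue types are
classified from binary presence-of-cluster features with one-vs-rest
linear SVMs trained by kernlab's SMO solver under stratified 10-fold
cross-validation; types with fewer than 8 datasets are excluded first.
Out-of-fold decision values give per-class one-vs-rest AUCs and their
class-size-weighted mean.  The linear kernel is the minimal choice
consistent with an SMO-trained maximum-margin classifier and keeps the
desk-scale runtime trivial; a count-based feature encoding can be
substituted for the binary one.

## The synthetic-data generator

Real DHS collections are hundreds of datasets of ~10^5 regions each;
the generator reproduces their statistical structure at desk scale:

* **Background genome**: an order-2 Markov chain (orders 0–3 available)
  whose conditional distributions are log-normally perturbed around the
  target composition but constrained to carry exactly the target GC
  mass, so genome-wide GC concentrates tightly on the target.
* **Regions**: fixed-length (default 800 bp) and *non-overlapping*
  within a dataset, as real DHS peaks are.  Overlapping regions would
  duplicate genomic sequence across regions and manufacture
  co-occurrence between unrelated patterns, invalidating the
  independence null — an effect large enough to produce thousands of
  false modules.
* **Planted motifs**: sharp PWMs with dominant-base probability 0.9
  (~1.5 bits per column, a strong but realistic TF motif; exact 8-mer
  matching needs roughly this sharpness for consensus sites to recur).
  `make_motif_families()` draws families whose consensus strings agree
  at no more than half their aligned positions in any orientation —
  planted families stand for distinct TFs, so they are distinguishable
  by construction.
* **Modules**: each region hosts a module independently with the
  module's planting probability; one site per member motif is sampled
  from its PWM and placed at non-overlapping offsets (also avoiding
  sites of other modules) on random strands.  A complete site log
  (region, motif, offset, strand, sampled string) is kept; rescanning
  the sequences reproduces it exactly.
* **Masking**: background positions are masked to `N` in geometric
  stretches (mean 20 bp) up to the target fraction; planted sites are
  never masked, so recovery rates stay interpretable.
* **Typed collections**: each dataset of a type plants the shared
  motifs plus its type's specific motifs, in co-occurring pairs (module
  discovery requires co-occurrence, so singleton planting would erase
  the type signal from the pipeline's features).

What the generator does *not* model: DNase cut bias and footprint
shapes, read-level signal, overlapping binding sites, compositional
heterogeneity along the genome (isochores, CpG islands), and motifs
with gapped or variable-spacing architecture.  Passing tests on this
generator therefore show that the statistics and algorithms are
implemented correctly and behave as designed under their own model
assumptions — not that the pipeline's numbers transfer quantitatively
to real DNase-seq data.

## Numerical and design choices

* Exact binomial tails come from `stats::pbinom`; tests verify them to
  1e-12 against an independent log-space summation.
* `r = 3` stopping rounds: the iteration count is left symbolic in the
  procedure this pipeline follows; 3 is the exposed default.
* The Bonferroni factor for pairs is $\binom{m}{2}$ even though
  overlap-ineligible pairs are never tested — conservative and
  independent of the search path.
* Ties everywhere have declared deterministic resolutions: ranking ties
  are lexicographic; extension ties go right; cluster assignment is
  first-fit in creation order; representative ties go to the earliest
  member; TF-mapping ties fall back to corr E-value, then lexicographic.
* All randomness flows from one seed through `stage_seed()` substreams,
  so identical seeds give identical pipeline output and adding a stage
  does not perturb the others.
* Degenerate inputs have defined results: empty member sets give module
  p-value 1; saturated nulls (q = 1) give p-value 1; `p_bg = 0` with
  sites inside gives p-value 0 and a degeneracy flag; empty collections
  and empty module lists are flagged rather than erroring.
* Region extension at chromosome ends clamps and shifts the shortfall to
  the other side; odd deficits put the extra base on the right.

## Problem sizes

The shipped tests and the acceptance script run, per invocation: 20
background null datasets and planted-recovery datasets of 2000 × 800 bp
regions on genomes of 1–2.5 Mb; clustering benchmarks of 200 motifs (10
families × 20 perturbed copies over 10 datasets); similarity nulls of
2000 samples per width pair; a 30-dataset typed collection of 2000
regions each for end-to-end classification; and 100-replicate type-I
controls for enrichment.  A planted pair must clear a Bonferroni
correction over roughly 2 x 10^6 candidate pairs, so per-dataset
recovery needs the expected co-occurrence count
(regions x planting rate x both-consensus rate, the last about 0.18 at
0.9 sharpness) several binomial standard deviations above its null
expectation; the collection sizes above give corrected p-values around
1e-13 per planted pair.  These sizes were chosen as the smallest at
which every statistical property under test (binomial concentration,
Bonferroni control, planted-partition recovery, CV accuracy) has
comfortable margins.

## Known limitations

* Discovery uses exact 8-mer matches; degenerate positions enter only
  through PWM building and length adjustment.  Gapped motifs are out of
  scope by design.
* The significance-closure search cannot report a size-s module whose
  member pairs are not individually significant; with exact matching
  and realistic planting rates this case is statistically marginal, but
  it is a real restriction relative to an unconstrained lattice search.
* E-value scales are calibrated against this package's own random-motif
  null; they are not numerically comparable to E-values of external
  motif-comparison tools, only threshold-compatible in intent.
* The clustering is greedy and order-dependent by construction; the
  ascending/descending robustness check bounds, but does not eliminate,
  that dependence.
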