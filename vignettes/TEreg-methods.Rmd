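---
title: "Detecting regulatory transposable-element families: models and methods"
author: "TEreg package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting regulatory transposable-element families: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
suppressMessages({
  library(TEreg)
  library(GenomicRanges)
})
```

## The scientific question

Transposable elements (TEs) — in particular the long terminal repeats of
endogenous retroviruses (ERVs) — carry transcription-factor binding sites
and can be co-opted as tissue-specific enhancers or promoters. In
trophoblast, the fetal cell lineage of the placenta, several ERV families
show hallmarks of regulatory activity: their copies are recurrently covered
by H3K27ac peaks, lie in placenta-specific open chromatin, and sit near
genes with trophoblast-biased, often species-specific, expression. `TEreg`
implements the computational pipeline that turns epigenomic peak sets,
repeat annotations, gene models and expression matrices into these
family-level statements, and ships a seeded synthetic-data module so that
every stage can be validated against planted ground truth.

The pipeline has six analysis stages:

1. **Per-family peak enrichment** (`familyEnrichment`): a permutation test
   of how many peaks overlap each repeat family versus shuffled controls.
2. **Candidate-family selection** (`concordantFamilies`,
   `dnaseSpecificityFilter`, `selectCandidateFamilies`): concordance across
   two cell contexts plus open-chromatin tissue specificity.
3. **Chromatin-state combinations** (`classifyElements`,
   `familyStateProportions`): which histone-mark combinations each family
   copy carries (active enhancer, poised enhancer, promoter-like...).
4. **Distance-stratified expression association** (`computeLog2FC`,
   `stratifyByDistance`, `tePromoterTranscripts`, `nearestPeakTargets`,
   `familyTargetFc`): do genes near marked elements change expression?
5. **Cross-species stratification** (`liftInterval`,
   `reciprocalOrthologMap`, `crossSpeciesStratifiedFc`): are expression
   differences between species linked to species-specific elements?
6. **Synthetic data** (`simulationConfig`, `simulateGenome`,
   `simulatePeaks`, `simulateExpression`, `simulateTwoSpecies`).

## The enrichment model

For a peak set $P$ and a family $f$ with copies $E_f$, the observed
statistic is $k_f = \#\{p \in P : p \text{ overlaps some } e \in E_f\}$,
with overlap meaning at least one shared base pair. The null distribution
is obtained by shuffling: each peak is re-placed uniformly at random among
all positions on its own chromosome where it fits entirely inside a single
mappable segment (the complement of the unmappable-region mask). With $N$
permutations yielding null counts $k_f^{(1)}, \dots, k_f^{(N)}$:

$$
p_f = \frac{1 + \#\{i : k_f^{(i)} \ge k_f\}}{N + 1}, \qquad
\text{fold}_f = \frac{k_f}{\max(\bar{k}_f^{\text{null}},\ 1/N)}.
$$

The add-one empirical p-value never returns zero and its minimum is
exactly $1/(N+1)$; the default $N = 1000$ therefore bounds p at
$1/1001 \approx 10^{-3}$. The fold denominator is the null mean, floored
at $1/N$ so that families never hit under the null still get a finite
fold. A family is called significant when $p < 0.05$, fold $> 2$ (both
strict) and at least ten of its copies are overlapped by peaks — the
copies-hit condition suppresses families whose enrichment rides on one or
two recurrently hit copies. Benjamini–Hochberg q-values across families
are reported for context, but the significance rule itself uses the raw
p-value, matching how the three-part criterion is stated.

Design choices worth making explicit, since the underlying references
leave them open:

* **Shuffling is per-chromosome.** A peak stays on its chromosome, which
  preserves per-chromosome peak density and is the more conservative null
  when chromosomes differ in coverage.
* **Shuffled peaks may overlap each other.** No collision rule is
  applied, matching the behaviour of the common interval-shuffling tools.
* **A shuffled peak may not straddle a masked gap** — placement is
  uniform over valid starts within single mappable segments, a strict
  reading of "avoiding unmappable regions".
* **Fold uses the null mean**, the conventional expectation estimator,
  rather than the median, which is ill-behaved at the low counts typical
  of small families.
* **Reproducibility:** one master seed; permutation $i$ draws from the
  deterministic sub-seed $\text{seed} + i$, so single permutations can be
  re-derived and whole runs are byte-identical.

## Selection of candidate families

Families must be significant in **both** cell contexts (e.g. primary
cells and a stem-cell model) — a plain intersection of the two
significant sets. The surviving families then face an open-chromatin
specificity rule over a panel of datasets labelled placenta / kidney /
liver / lung: strictly more than 80% of placental datasets must show fold
$> 2$, and the median placental fold must exceed the pooled median of the
three comparison tissues by strictly more than 2. The comparison tissues
are pooled into a single group (per-tissue medians are reported as
diagnostics only), medians of even-sized groups are midpoint averages,
and the per-dataset folds come from the same `familyEnrichment` machinery
run on each dataset's peaks — no separate statistic is introduced. Both
rules are anti-monotone in their thresholds: raising any threshold can
only shrink the selected set, a property the test suite checks over a
threshold grid.

## Chromatin-state combinations

Each family copy is classified by the subset of histone-mark peak sets it
overlaps (H3K27ac, H3K4me1, H3K4me3, H3K9me3, H3K27me3; at least 1 bp).
Labels are plain combination strings — `K27ac+K4me1` (active
enhancer-like), `K4me1_only` (poised enhancer-like), anything containing
`K4me3` (promoter-like), `none` — rather than a fixed ontology, because
mark panels differ between analyses; figure-style categories are
recovered by grouping labels. Repressive marks participate in
combinations without any precedence rule suppressing active labels.
Because the natural denominators differ between questions ("what fraction
of all copies" versus "what fraction of H3K27ac-marked copies"), both are
exposed: `familyStateProportions(calls, denominator = "all")` and
`denominator = "H3K27ac"`, plus the convenience `familyMarkProportion()`
for co-marking fractions.

## Distance-stratified expression association

Per-gene log2 fold changes between two conditions are
$\log_2\!\big((\bar{a} + c)/(\bar{b} + c)\big)$ with arithmetic
per-condition means of linear-scale abundances and pseudocount $c = 1$
(default; recorded with the output). Genes below the minimal-expression
threshold (`minExpr`, default 1 — deliberately a required, logged choice,
since the appropriate value depends on normalization) in *both*
conditions are dropped; passing in either condition keeps a gene.

Genes are binned by the distance from their span to the nearest marked
element: overlap, $\le$10 kb, 10–50 kb, 50–100 kb, and an open reference
bin beyond 100 kb (edges configurable). Distance is measured from the
gene body by default — an intronic element is "at distance 0" from its
host gene, which matches how proximity is described for intronic
enhancers — with a TSS-anchored mode behind the `anchor` flag. The
default test is one-way ANOVA with Tukey honest significant differences
against the open reference bin; a two-group rank-sum mode with BH
correction is available where only two sets are compared. Bins with
fewer than two genes are excluded from testing with a warning.

TE-derived promoters are detected as multi-exonic transcripts
(`exon_count >= 2`) whose TSS lies inside an active element; the
multi-exon condition guards against single-exon assembly artefacts.

## Cross-species comparison

A coordinate map is consumed as a plain list of equal-length aligned
block pairs (chain-file parsing is out of scope; precomputed block maps
or lifted coordinates are the supported input). `liftInterval` maps the
pieces of an interval through the blocks, merges them on the target, and
accepts the merged region carrying the most mapped bases when it covers
at least `minFrac` (default 0.5, inspired by the customary remap
threshold of lift-over tools) of the interval. A TE copy has an ortholog
when it lifts, the lifted interval lifts back, and the back-lift overlaps
the original copy (reciprocal mapping); optionally the lifted interval
must additionally overlap an annotated same-family element in the target
species — both modes are exposed because the stricter reading cannot be
distinguished from the looser one in the underlying description.

For expression, one-to-one orthologous genes within a window (100 kb for
the two-group design, 50 kb conventionally for the three-group design) of
a marked element are grouped by whether every such element has an
ortholog. When several marked elements fall in a gene's window,
"species-specific" wins: a single species-specific element suffices to
hypothesise species-specific regulation, and the per-gene assignment is
reported so the choice is auditable. Each species' mean abundances are
median-scaled over the ortholog set before the ratio (no cross-species
normalization is assumed), and a small pseudocount of 0.01 is added on
that scale: abundances are positive by construction, and a large
pseudocount would shrink genuine log-ratios of median-level genes, which
matters because recovery of planted effects is asserted to ±0.2.

## What the synthetic data emulate — and what they do not

The generators are pure functions of `(config, seed)` (independent
sub-streams per stage: genome, peaks, expression, second species), and
every stage emits a truth record sufficient to score downstream calls
without re-deriving ground truth.

* `simulateGenome`: TE copies placed uniformly without overlapping each
  other or the mask; genes placed uniformly with strand-aware TSS; one
  transcript per gene, a configurable fraction multi-exonic.
* `simulatePeaks`: an exact `round(fraction * count)` of peaks planted to
  overlap (≥1 bp) uniformly chosen copies of target families — matching
  the ≥1 bp enrichment overlap rule — and the rest placed uniformly over
  mappable space.
* `simulateExpression`: per-gene log2 baselines
  $\mathcal{N}(\mu_0, \sigma_0)$, a planted `log2fc` added in condition A
  iff the gene is within `window_bp` of a marked element, per-sample
  Gaussian noise on the log2 scale, all emitted as linear abundances
  ($2^{(\cdot)}$) so effect sizes stay interpretable in log2 units.
* `simulateTwoSpecies`: species B is species A with an exact per-family
  subset of TE copies deleted; coordinate maps carry deletions as
  unmapped gaps; gene baselines are conserved so cross-species ratios
  isolate the planted effect; in species B the effect applies only to
  genes whose nearby marked elements are all shared.

Deliberately *not* modelled: sequence content and divergence (deletions,
not substitutions, create species specificity — the statistics under test
depend only on presence/absence and coordinates), read-level noise and
peak-calling uncertainty, GC or replication-timing biases in peak
placement, correlated TE insertions (age structure), and biological
covariance between expression and chromatin beyond the planted distance
rule. Consequently a green test suite demonstrates that the statistics
recover what they are designed to recover under their own assumptions —
not that those assumptions hold in any particular real dataset.

## Numerical choices and degenerate inputs

* Internal coordinates are 1-based closed (`GRanges`); BED and block-map
  input/output converts at the boundary, GTF and RepeatMasker are taken
  verbatim. One convention internally eliminates off-by-one drift.
* Overlap requires ≥1 shared bp; intervals sharing only a boundary point
  of the half-open source format never overlap. Strand is carried but
  ignored by overlap and distance. Chromosome names match by exact string
  equality — synthetic data control their naming; real data may need
  alias normalization upstream.
* Distances are unsigned edge-to-edge gaps (0 when overlapping or
  book-ended; `Inf` when the chromosome has no target, which files the
  gene into the open reference bin).
* Empty peak sets give every family `n_obs_peaks = 0`, `p = 1`,
  `fold = 0`; an empty annotation gives an empty record set; a family
  whose every null count is zero gets the `1/N` fold floor; ties in the
  null are counted in the "as or more extreme" direction.
* A peak longer than every mappable segment on its chromosome is a hard
  error naming the peak, not a silent drop.

## Problem sizes used in the shipped checks

The package's own validation runs at desk scale, chosen so each check is
informative yet quick: the null-calibration fixture uses 300 families ×
10 copies on a 20 Mb two-chromosome genome with 15,000 peaks and 999
permutations — sized analytically so expected per-family overlap counts
are ~15, large enough that the discrete empirical p-value is close to
uniform under the null (at low expected counts the add-one estimator is
conservative and the nominal 5% level is unreachable by construction).
Planted-enrichment recovery uses 500 peaks with 40% planted into a family
occupying ~0.1% of mappable space, 199 permutations, 20 replicates.
Distance-effect recovery plants a +1 log2 fold change within 50 kb on
4,000 genes (~100–900 genes per bin; noise sd 0.5, 4 samples per
condition). The two-species fixture deletes half of a 40-copy marked
family and plants a 0.8 log2 species effect over ~600 in-window genes.

## Known limitations

* The permutation null preserves peak lengths and chromosome assignment
  but not inter-peak spacing or GC composition; families residing in
  atypical sequence may need a matched null outside this package's scope.
* The DNase specificity rule presumes the four tissue labels used here;
  other panels require relabelling.
* `crossSpeciesStratifiedFc` assumes abundances already normalized within
  species; median scaling corrects global level shifts only.
* Coordinate maps must be non-overlapping block lists; genuine chain
  files must be flattened upstream.
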