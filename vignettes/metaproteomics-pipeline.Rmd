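---
title: "Models and methods of the metaproteomr pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods of the metaproteomr pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metaproteomr)
```

## The problem

Shotgun metaproteomics of a complex microbial community — the human
intestinal microbiota being the motivating system — asks three questions of
one LC-MS/MS dataset: *which* proteins are present (identification against
very large, partly redundant sequence collections), *who* makes them
(taxonomic assignment of short tryptic peptides), and *what they relate to*
in the community's composition (association of protein levels with 16S-based
phylotype abundances). metaproteomr implements this pipeline end to end and
pairs it with a synthetic-data generator whose ground truth is known, so
that every stage can be validated quantitatively rather than anecdotally.

## Identification: target-decoy FDR over multiple databases

Peptide-spectrum matches (PSMs) carry E-value-like scores (lower is
better) and arrive per search database, with hits against reversed (decoy)
sequences flagged. For a score cutoff $t$ the false discovery rate among
hits at or better than $t$ is estimated by the concatenated-search
estimator

$$\widehat{\mathrm{FDR}}(t) \;=\; \min\!\left(1,\;
  \frac{2\,R(t)}{F(t) + R(t)}\right),$$

where $F$ and $R$ count forward and reversed hits. The factor 2 encodes
the assumption that an incorrect match is equally likely to land in the
forward or the reversed half of the concatenated database; consequently the
estimator is calibrated for the proportion of false matches *on the
accepted list including its decoys*, and that is the quantity the
calibration test measures (the package's synthetic PSMs label exactly which
hits are incorrect). Measured against accepted targets alone the estimator
is conservative by roughly a factor two on the decoy share — a property of
the formula, not a defect of the implementation.

`filter_at_fdr()` scans the unique scores from best to worst and keeps the
*loosest* cutoff whose estimate does not exceed the level (default 5%),
maximising identifications; it does not monotonise the estimate into
q-values. Each database is filtered separately at the level, the survivors
are pooled, and spectra identified differently in different databases are
resolved to a single record: identical peptides keep the best-scoring
record, conflicting peptides keep the minimum score, and exact ties break
by lexicographically smaller peptide and then database priority, so the
result is independent of input order. Re-searching conflicting spectra
against the union of candidate sequences, as the original workflow did with
its search engine, is replaced by this best-original-score rule; per-database
FDR semantics are preserved by filtering before pooling.

## Digestion and database preparation

Tryptic digestion cuts after K and R (optionally not before proline — off
by default), and a peptide is *fully tryptic* when both flanks are cleavage
sites or protein termini and it contains at most the allowed number of
missed cleavage sites (default 1). Reference databases are pre-filtered to
proteins of at least 33 residues that yield at least one fully tryptic
peptide of 5 or more residues; shorter proteins cannot be identified and
would only inflate the decoy space. Peptide-to-protein mapping uses the
digest of each protein as a lookup, which is provably the same relation as
substring matching with flank checks.

## Protein inference

Proteins identified by exactly the same peptides are indistinguishable and
are merged; a protein whose identified peptide set is a strict subset of
another's contributes no independent evidence and is absorbed into the
superset's group. Subset chains collapse to the maximal set; when several
maximal supersets exist, the one with more peptides and then the smallest
accession hosts the subset, making the partition unique and
order-invariant. The surviving groups have pairwise non-nested peptide
sets. Each group is named after the member with most identified peptides,
ties going to the reference-isolate database and then the smallest
accession. Spectral counting attributes each accepted PSM to every group
containing its peptide (a strict unique-peptides-only mode is available for
sensitivity analysis), sums technical replicates per biological sample
(subject × time point), and reports only groups with at least two distinct
peptides.

## Core metaproteome and COG profiling

A group belongs to the core when it has peptide evidence in every subject,
at any time point. COGs come from a tabular BLAST hit file: the best hit at
E ≤ 1e-10 per query wins, ties resolved by subject identifier so row order
is irrelevant. Core spectra are summed per COG and expressed as percent of
all core spectra; functional-category roll-ups split multi-letter
categories (e.g. "EH") equally across letters so totals are conserved
(first-letter assignment is available by flag), proteins without a COG fall
into a "not in COG" bucket.

## Peptide taxonomy

Each accepted peptide is matched exactly (100% identity, tryptic flanks
enforced, I/L equivalence off by default) against the lineage-annotated
reference; the assignment is the deepest rank at which all matched taxa
agree with a non-missing value — a missing intermediate rank stops the
descent, and disagreement at superkingdom leaves the peptide unassigned.
Spectral counts aggregate to any rank; peptides whose assignment is
shallower than the requested rank count as unassigned there, so
percentages always total 100. Trend comparison between metaproteome- and
phylotype-derived compositions flags, per subject and phylum, whether the
between-time-point change goes in the same direction.

## Feature-matrix variance analysis

All similarity analyses run on log10 intensities. Pairwise Pearson
correlations between runs are classified as *experimental* (same subject
and time point), *temporal* (same subject, different time point) or
*subject* (different subjects), and summarised per class as mean, SD and
number of pairs; per-experiment summaries combine across experiment blocks
as the n-weighted mean of the per-block means (the only convention under
which two blocks of 0.72 over 50 pairs and 0.58 over 35 pairs combine to
0.66). A one-way ANOVA across classes treats each pairwise correlation as
one observation, exactly as the source workflow did. Because pairs share
runs they are not independent: under a true null (technical noise only)
the F-test is markedly conservative — the package's null simulations
reject in well under 5% of seeds — so its p-values should be read as
descriptive. Hierarchical clustering uses complete linkage on the distance
$d = 1 - r$, with columns sorted by label beforehand so distance ties
cannot make the tree depend on input order; tree comparison counts the
symmetric difference of the two trees' clade sets (0 for identical
topologies). PCA is computed on run profiles centred per feature, with
variance percentages that sum to 100.

## Protein-phylotype association

Each protein's per-sample level is predicted from all phylotype abundances
with a 500-tree random-forest regression. The per-phylotype permutation
importances are Z-scored across phylotypes (mean 0, SD 1) and covariates
with $Z > 1.96$ — the two-sided 5% standard-normal critical value — are
declared significant. The *raw* permutation importance stored by the
forest is used; dividing by the permutation standard error is an optional
extra step that costs sensitivity at small sample sizes. Significant
phylotypes are then tested per genus-like group for enrichment with the
one-sided Fisher exact test (hypergeometric tail) at p < 0.05, and
enriched protein-genus pairs are summarised per COG functional category
(equal split for multi-letter categories), ready for the usual
log10-colour heatmap.

Two caveats are inherited deliberately from the procedure being
implemented: a dozen samples against hundreds of covariates is severely
under-determined, and no multiple-testing correction is applied beyond the
raw 0.05 thresholds. The Z-score tail is calibrated in the many-covariate
regime the method is meant for (the package's null simulations use
150-200 phylotypes, emulating a 1,000-phylotype microarray at desk scale);
with very small panels (~30 covariates) Z-scoring a short, right-skewed
importance sample over-flags (≈4.5% instead of 2.5%).

## The synthetic-data generator

The generator emulates a repeated-measures faecal study: 3 subjects × 2
time points × 2 technical replicates (12 runs), a nested taxonomy over
superkingdom…species with realistic gut phyla, 5 proteins per taxon built
from tryptic blocks, and planted protein-phylotype links.

* **Abundances.** Each taxon's log10 abundance per (subject, time point)
  is `base + subject effect + time effect` with independent Gaussian
  effects. A taxon's proteins are expressed in a sample when the abundance
  exceeds a threshold, which couples proteome and composition; expressed
  proteins contribute at least two distinct-peptide spectra per run, so
  presence is observable and the planted core is recoverable.
* **Scores.** Correct matches draw log10 E-values uniformly from
  [-12, -6]; incorrect matches (40% of PSMs, split evenly between target
  and decoy sequences, matching the estimator's own assumption) draw from
  the same shape shifted 7 log-units worse. The shift is the dial that
  controls target/decoy separation.
* **Features.** Log10 feature intensities follow
  `base_feature + subject + time + technical` with SDs 0.8, 0.65, 0.45 and
  0.3: the technical < temporal < subject hierarchy that produces the
  expected ordering of class correlations and subject-wise dendrogram
  clades. 300 features stand in for the tens of thousands a real run
  yields; correlations are correspondingly tighter than real Table-style
  values, but their ordering is the property of interest.
* **Phylotypes and planted links.** One phylotype per taxon equals the
  taxon abundance with lognormal noise (SD 0.3 in log10); genus-like
  groups follow the true genera. Planted proteins follow one phylotype's
  standardised log abundance with effect size exactly 2× the unit residual
  noise SD — the boundary condition at which recovery is promised; all
  other protein levels are independent noise, so the association ground
  truth is unambiguous.
* **Identifiability.** Tryptic blocks are 8-15 residues long; with ~20^8
  possible blocks, unrelated proteins essentially never share a peptide,
  which keeps presence/core ground truth identifiable from peptide
  evidence. (An early variant with 5-residue blocks produced chance
  collisions in a few percent of communities.)
* **Determinism.** Every artifact is a pure function of its spec and seed;
  regeneration is byte-identical, and all stochastic stages of the
  pipeline take explicit seeds.

What the generator does *not* emulate: raw spectra, chromatography,
feature detection and alignment, database redundancy across five
overlapping collections, human/food contaminants, and compositionality of
real microbiome data. Passing tests therefore demonstrate the correctness
and calibration of the algorithms under the stated model, not performance
on real data.

## Problem sizes and numerical choices

The validation suite runs at desk scale chosen once: 2,000 PSMs × 100
seeds for FDR calibration; 1,000 random bipartite graphs (≤12 proteins ×
≤15 peptides) for grouping; 10,000 random taxon sets from a 200-leaf
taxonomy for LCA; 100 seeds of the default design for the variance
hierarchy; 50 seeds for exact core recovery; 50 seeds × 5 planted links
plus 200 null replicates for association recovery; every 2×2 table with
margins ≤ 12 for the Fisher test. Numerical conventions: FDR capped at 1;
loosest-cutoff threshold scan; deterministic tie-breaks everywhere
(lexicographic peptide/accession, database priority, label-sorted
clustering input); equal-split category roll-ups; missing ranks stop the
LCA descent; log base 10 throughout (configurable).

## Limitations

Spectral counts are a coarse abundance proxy; the ANOVA on dependent
pairwise correlations is descriptive; the association stage implements the
published procedure faithfully rather than a statistically optimal design
(no multiplicity control, n ≪ p); and real headline counts (numbers of
identified proteins, core size, association totals) depend on real raw
data and are out of scope.
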