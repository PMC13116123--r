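---
title: "Network-proximity screening: model, null, and companion metrics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Network-proximity screening: model, null, and companion metrics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(proxscreen)
```

## The screening problem

Given a protein–protein interaction (PPI) network, a set of disease-associated
seed proteins *S* (the disease module), and for each candidate compound the set
*T* of proteins it binds with measured bioactivity, the screen asks: do this
compound's targets sit closer to the disease module than chance would place
them? Compounds whose targets crowd the module are predicted to be
pharmacologically relevant to the disease.

The distance statistic is the **closest-distance proximity**

$$d(S,T) \;=\; \frac{1}{|S|+|T|}\left(\sum_{t \in T}\min_{s \in S} d(s,t)
\;+\; \sum_{s \in S}\min_{t \in T} d(s,t)\right),$$

where $d(s,t)$ is the unweighted shortest-path length. It is symmetric in the
two sets, zero exactly when they coincide, and sensitive to both directions of
coverage: targets near the module *and* module proteins near some target.

Raw distance is confounded by degree — hub proteins are close to everything —
so the statistic is standardized against a **degree-preserving permutation
null**: the node sets are replaced by random sets drawn degree-bin-by-degree-bin
(`degree_matched_sample()`), the proximity recomputed `n_perm` times (1000 by
default), and

$$Z = \frac{d(S,T) - \mu}{\sigma}$$

reported together with an add-one empirical p-value
$(1 + \#\{d_{\text{perm}} \le d_{\text{obs}}\})/(1 + n_{\text{perm}})$ and the
lower-tail normal approximation. Lower z means closer than expected for the
degree profile; `rank_compounds()` orders a screen ascending by z with ties
broken by observed distance and then compound id.

## Randomization mode

Published descriptions of this statistic family rarely state whether the
permutation replaces the target set, the disease module, or both. Both modes
are implemented (`randomize = "both"` or `"targets"`), with `"both"` the
default for screening. The difference matters for calibration experiments:
when an observed target set is *itself* produced by the degree-matched sampler
and the module is held fixed, targets-only permutation makes the null exactly
the generating distribution of the observed statistic, so z is calibrated by
construction (mean 0, s.d. 1). Under `"both"`, the observed statistic uses the
real, cohesive module while the null scatters it into degree-matched singletons;
a cohesive module covers the graph differently than a scattered one, so null z
is mildly overdispersed. That overdispersion is a property of the statistic,
not an error — but it is why the package's own calibration checks run in
`"targets"` mode, while screens (where the extra module contrast sharpens true
positives) use `"both"`.

## Degree bins

Nodes are sorted by degree and contiguous degree groups merged until each bin
holds at least `min_bin_size` nodes (default 100, the conventional choice at
interactome scale; reduced automatically with a warning on small graphs). Wider
bins blur degree matching, narrower bins starve the sampler; 100 is a
reasonable middle on graphs of a few thousand nodes and upward. Unreachable or
absent nodes are dropped from the statistic with counts carried in the result
rather than poisoning it with infinities.

## What the synthetic data emulates

Every input of the pipeline can be generated with known ground truth, so the
whole screen runs end to end without any external database:

* **PPI network** — preferential attachment (`gen_ppi_network()`). The default
  study condition is 2000 nodes with attachment count 2. Attachment growth
  reproduces the one property the permutation null is sensitive to, strong
  degree heterogeneity, and the sparse default keeps typical shortest paths
  above two hops so the proximity statistic retains dynamic range; at higher
  density everything on a small graph is within two hops of everything and the
  statistic saturates. Real interactome features beyond degree heterogeneity
  (clustering, community structure, annotation bias) are deliberately out of
  scope, so a passing screen here certifies the statistic and its null, not
  performance on a real interactome.
* **Disease module** — breadth-first growth from a random start
  (`gen_disease_module()`), giving a connected, cohesive seed set. The default
  size of 15 on 2000 nodes mirrors the proportion of curated disease seed
  lists to interactome size (a hundred-odd seeds among tens of thousands of
  proteins).
* **Compound screens** — `gen_compound_screen()` plants compounds whose 10
  targets (the scale of harmonized bioactivity records per compound) are drawn
  from within one hop of the module; background compounds draw degree-matched
  targets from *outside* that neighborhood. The exclusion keeps ground truth
  honest: with unrestricted degree-matched draws, roughly one background
  compound per ten screens lands several targets inside the module
  neighborhood and becomes a true positive wearing a negative label, so that
  recovery rates would measure label noise rather than the method.
* **Bioactivity tables** — `gen_bioactivity_table()` plants records violating
  exactly one inclusion criterion each, disjointly, so filter attribution is
  exactly testable.
* **Fingerprints** — cluster prototypes with independent per-bit flips;
  flip probabilities at or above 0.5 destroy the signal and are rejected.
* **PK profiles** — biexponential IV-bolus curves with multiplicative
  lognormal noise (concentrations are positive; assay error is relative).
  Default constants give a terminal half-life of about 10.1 h over a 5 min to
  48 h sampling schedule, a realistic profile for a lipophilic compound.
* **Cohorts** — exponential time-to-dementia with log hazard linear in the
  annual fruit-and-vegetable consumption (AFVC), administrative censoring, and
  questionnaire fields that reproduce each participant's AFVC exactly.

All generators are pure functions of their arguments including the seed; each
generator consumes an independent child stream derived from one master seed,
so adding a generator to a run never perturbs the others.

## Bioactivity harmonization

`filter_bioactivity()` applies four inclusion criteria in a fixed order, so a
record violating several is reported once, deterministically: (i) the activity
type is a binding/potency measurement (Ki, Kd, IC50, EC50, potency; a synonym
map folds spelling variants case-insensitively, unknown types are rejected
here); (ii) the organism designates human (matched against a whitelist of
"Homo sapiens", "human", and taxid 9606); (iii) the target carries an
accession matching the UniProt lexical pattern; (iv) the SMILES string is
lexically parseable (balanced brackets, legal atom tokens, paired ring
closures — a syntactic gate, with semantic canonicalization left to a
cheminformatics toolkit when one is in the stack). `dedupe_to_map()` then
collapses accepted records to unique InChIKey–accession pairs, keeping support
counts as provenance; filter-then-dedupe is idempotent.

## Clustering

Compound fingerprints are compared by Jaccard distance (the complement of the
Tanimoto similarity; two empty fingerprints are at distance 0 by convention)
and clustered agglomeratively (`stats::hclust`; average linkage by default,
complete and single exposed). Cutting the tree at *k* gives the cluster
labels, renumbered in order of first appearance. Cuts are nested — the
k-partition refines the (k−1)-partition — and row order only relabels the
result. The default `k = 10` matches the scale at which structural families
(flavones, benzoic acids, triterpenoids, ...) separate in screens of about a
hundred compounds, but it is a parameter, not a finding.

## Pharmacokinetics

`nca_summary()` is standard non-compartmental analysis for IV bolus dosing.
The terminal slope is fit by least squares on log concentration over candidate
windows (the last *n* points after and excluding Cmax), selecting the window
with maximal adjusted R²; ties within 10⁻⁴ prefer the longer window. AUC and
AUMC use the linear-up/log-down trapezoid (a linear option is kept), with the
tail beyond the last quantifiable sample extrapolated as $C_{last}/\lambda_z$
and $t_{last}C_{last}/\lambda_z + C_{last}/\lambda_z^2$. Clearance is
dose/AUC (reported in mL/min/kg), mean residence time AUMC/AUC, and the
steady-state volume Vss = CL·MRT (L/kg) — the moment method, the natural
choice when only bolus data exist. Below-LLOQ samples are excluded from
estimation. The replicate-precision statistic
$S = \sqrt{\sum D^2/(2N-1)}$ with $D = 100(x_1-x_2)/\bar{x}$ summarizes
duplicate standard-curve scatter on a percent scale.

## Respirometry and simple indices

The oxygen-consumption metrics follow the standard mitochondrial stress-test
definitions: non-mitochondrial respiration (after rotenone/antimycin A) is
subtracted from the basal and FCCP-uncoupled rates; ATP-linked respiration is
the oligomycin-sensitive part; proton leak the oligomycin-insensitive
remainder; spare capacity the maximal minus basal difference. The identity
ATP-linked + proton leak = basal holds exactly by construction. Some published
figure captions circulate with duplicated definitions for maximal and spare
respiration; the standard definitions are implemented and the discrepancy
noted here rather than propagated. The kinome %Ctrl score anchors 0% at the
positive control and 100% at the negative control, unclipped but flagged
outside that range; the selectivity score S(35) counts non-mutant kinases
strictly below 35% of control (the strict inequality matches the usual
printed form "<35").

## The exposure metric

AFVC sums `times_per_month × grams_per_time` over questionnaire items and
converts grams/month to kg/year by ×12/1000. Questionnaire write-ups sometimes
print the conversion as ×1000×12, which contradicts the stated kg/year units;
the dimensionally consistent form is the default and the literal form is
available behind `literal = TRUE` for traceability. Stratification at a
threshold (median by default) uses an inclusive boundary — a participant
exactly at the cut is "high" — and reports crude incidence per group; formal
survival comparisons belong to the survival machinery, not this package.

## Numerical choices and degenerate inputs

* Permutation σ = 0 (degenerate null) yields `NaN` z with a warning instead of
  an error, so batch screens complete; empirical p is still reported.
* The empirical p uses the add-one estimator, bounded below by
  1/(n_perm + 1); it can never be zero.
* Proximity over sets that lose all members to network intersection or
  unreachability returns an invalid result with a reason, ranked last.
* Distances are unweighted hop counts throughout; weighted or directed
  variants are out of scope.
* On graphs of at most 5000 nodes the full distance matrix is precomputed once
  per screen and shared across permutations; beyond that each permutation runs
  its own breadth-first searches.

## Simulation sizes used by the test suite

The packaged checks run at the study conditions above: 200 random graphs of up
to 60 nodes for exactness against brute force; 200 replicates of 1000
permutations on one 2000-node network for null calibration; 100 screen
instances (50 compounds, 1 planted, 200 permutations each) for recovery; 100
noisy PK profiles; 100 simulated cohorts of 2000. These sizes give binomial
standard errors of a few percent on the rates they estimate while keeping a
full run in the minutes range on a single core.

## Known limitations

Synthetic networks certify the statistic, not real-interactome performance;
published z-scores from proprietary interactomes and licensed bioactivity
snapshots are not reproducible here and are not targets. The SMILES gate is
lexical, not chemical. The cohort generator's exponential hazard is a
convenience, not an epidemiological model; it exists to give the exposure
metric and stratification something with known direction of effect.
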