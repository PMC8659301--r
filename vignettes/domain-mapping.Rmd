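---
title: "Mapping compounds to protein domains from bioactivity data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping compounds to protein domains from bioactivity data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(domainmapr)
```

## The idea

Proteins are modular: their structural domains fold, function, and evolve
semi-independently, and a small molecule that binds one protein usually does
so at a particular domain. If we can identify *which* domain carries the
interaction, every other protein containing that domain becomes a candidate
target for the compound — including proteins with no measured bioactivity at
all. `domainmapr` turns this idea into a statistical pipeline:

1. **Label** compound–target pairs as active or inactive from xC50-type
   bioactivity values.
2. **Score** each compound against every domain occurring in its active
   targets, treating "contains the domain" as a binary classifier of the
   compound's active/inactive target sets.
3. **Filter** the scored mappings, keep domain pairs only when they beat
   their constituent single domains, and **propagate**: cross mapped
   compounds with every protein carrying the mapped feature, extend to
   structurally similar compounds, and subtract what is already known.
4. **Evaluate** a mapping set against a reference of experimentally
   determined compound–domain interactions.

## The mapping score

For a compound $c$ with active target set $A$ and inactive target set $I$,
and a candidate single domain $d$:

* an active target containing $d$ is a true positive (TP);
* an inactive target containing $d$ is a false positive (FP);
* an active target lacking $d$ is a false negative (FN);
* an inactive target lacking $d$ is a true negative (TN).

From these counts, `compute_scores()` derives recall, precision, accuracy,
F1, and the Matthews correlation coefficient:

$$\mathrm{MCC} = \frac{TP \cdot TN - FP \cdot FN}
  {\sqrt{(TP+FP)(TP+FN)(TN+FP)(TN+FN)}}.$$

MCC is the primary ranking metric because the active/inactive target sets
are usually imbalanced. Any metric whose denominator is zero is defined as
0, which keeps thresholding total for all-positive or all-negative subjects;
an undefined score would otherwise have to be special-cased at every filter.

A worked example with three active targets carrying the domain, one inactive
carrying it, and two inactives lacking it:

```{r}
compute_scores(3, 1, 0, 2)
```

**Domain hierarchies.** Related domains are grouped in trees (as InterPro
does for entries from the same functional family), and profiles from the
same tree are often near-interchangeable. Penalizing a mapping because an
active target carries a *sibling* of the mapped domain instead of the domain
itself would underestimate the association, so with a hierarchy supplied,
`count_confusion()` counts an active target containing any same-tree domain
as TP (and an inactive one as FP). "Same tree" means *shared root*: the
hierarchy text could also be read as direct parent/child, but the shared
root is the broader, documented tree notion and is what we implement. Pair
features never use hierarchy substitution — the substitution rule is defined
for single domains only.

**Domain pairs.** Some interactions need an interface of two domains. All
unordered pairs of distinct domain ids per protein are enumerated ("bag of
domains": positions and order on the sequence are ignored, because domains
distant in sequence can be adjacent after folding) and scored exactly like
single domains. After thresholding, a pair mapping is kept only when its MCC
*strictly* exceeds the best constituent single-domain MCC of the same
compound (`positive`); ties are `neutral` — the second domain adds nothing —
and are discarded. Homotypic pairs (a domain with itself) are not
enumerated; the scoring cannot distinguish one copy from two.

## Parameters and defaults

| Parameter | Default | Meaning |
|---|---|---|
| `active_um` | 10 | activity < 10 uM is active |
| `inactive_um` | 20 | activity > 20 uM is inactive |
| `min_compound_targets` | 3 | eligibility: actives and inactives per compound |
| `min_cluster_targets` | 5 | eligibility per compound cluster |
| `cluster_tanimoto` | 0.7 | cluster membership threshold |
| `propagate_tanimoto` | 0.8 | similarity-propagation threshold |
| `mapping_score` | 0.5 | score threshold on the mappings |

Values in the closed band [10, 20] uM are ambiguous and discarded — too
potent to call inactive, too weak to call active; placing the boundary
values inside the band makes the three classes an exhaustive partition.
Duplicated measurements for a pair are collapsed to their median *before*
classification, jointly across sources (`dedup_scope = "global"`), which
makes label contradictions impossible by construction; the alternative
`"per_source"` aggregates each source separately and drops pairs that end up
with both labels.

The eligibility minima exist because a compound with one active and one
inactive target trivially achieves a perfect score; three per side is the
smallest count at which the confusion table carries any evidence, and
pooled clusters need five because pooling borrows evidence across compounds.

The score threshold is applied as the **minimum over all five metrics**.
Four metrics (recall, precision, accuracy, F1) define the filter in the
benchmark analysis while ranking elsewhere is MCC-based; thresholding on all
five is the strictest reading consistent with both, and the metric list is
configurable (`threshold_metrics`).

## Chemistry

Compounds are encoded as extended-connectivity fingerprints of diameter 4
(ECFP4), computed from SMILES via OpenBabel (through `ChemmineOB`) and
folded to 4096 bits, OpenBabel's fold length. Similarity is the Tanimoto
coefficient on the bit sets, defined as 0 when both vectors are empty so
featureless molecules never cluster spuriously.

Clusters are **seed-centered**: one cluster per compound, containing every
compound at Tanimoto ≥ 0.7 to the seed. This reading (rather than
transitively closed components) is chosen because it produces overlapping
clusters in roughly seed-per-compound numbers, consistent with a cluster
count several times the eligible-compound count; `cluster_mode =
"connected_components"` gives the disjoint alternative. A cluster pools its
members' active and inactive targets by union (targets with conflicting
member labels are dropped with a warning), is scored like a compound, and
its scores are propagated to every member; when a compound holds both an
individual and a cluster-derived score for a feature, the larger MCC wins,
with the compound's own evidence preferred on ties.

Prediction extension is a **single** similarity round: predictions of a
mapped compound are copied to its ≥ 0.8 neighbors, but not onward from
those neighbors — chaining would compound the similarity error. Known pairs
of *either* label are removed from the final predictions: actives are
already known, and predicting a known inactive would contradict the
evidence.

## Benchmarking

`benchmark_mappings()` compares the single-domain mappings against a
reference set across score thresholds. At each threshold the analysis is
restricted to the compounds and domains occurring in **both** the
thresholded mapping set and the reference; over the finite universe of all
such compound × domain combinations, pairs in both sets are TP,
reference-only FN, mapping-only FP, and the rest TN. The cross product is
the only universe construction under which the four counts partition
something finite. Coverage (shared entities) and coverage extension (newly
mapped entities) are reported relative to the *fixed* intersecting totals of
the raw mapping set, so rows at different thresholds are comparable.

Fold enrichment at threshold $t$ is observed over expected,
$E_t = (m_t/n_t)/(M_t/N_t)$, with $m_t$ the retrieved-and-true count, $n_t$
the retrieved count, and $M_t/N_t$ the reference rate in the retrieved
set's own compound × domain universe; significance is the upper-tail
hypergeometric probability $P(X \ge m_t)$, computed with `stats::phyper`
and verified in the tests against an explicit combinatorial sum.

## The synthetic world

`generate_world()` builds a self-contained chemogenomics world with planted
ground truth: a proteome (default 100 proteins, 1–4 distinct domains each,
averaging ~2.4 — matching the typical domain count of annotated drug
targets), a flat domain hierarchy (30 domains under 24 roots), and 50
compounds, half of which carry a planted (compound, domain) association
realized as 6 active-band records against proteins containing the domain
and 6 inactive-band records against proteins carrying nothing from the
domain's tree. Unplanted compounds receive 8 random records per band so
they are score-eligible but carry no signal. Activities are log-normal
around 1 uM (actives) and 100 uM (inactives) with log-sd 0.75, so the
10/20 uM band separates the classes cleanly; `label_noise` flips a record's
band and `ambiguous_fraction` redraws records inside [10, 20] uM. SMILES
come from 20 hand-written drug-like scaffolds crossed with 20 small
substituents, giving controllable high-similarity neighborhoods for the
clustering and propagation stages.

What the world emulates: the data model (labeled records, domain
architectures, hierarchies) and the statistical structure the method relies
on. What it does not: real chemistry–target correlation (a compound's
fingerprint is unrelated to its planted domain), assay heterogeneity,
biased negative reporting, or InterPro's actual tree shapes. A passing
recovery test therefore demonstrates the machinery recovers plantable
signal at the stated noise — not real-world predictive accuracy.

**Recovery accounting.** With hierarchy-aware counting, a mapping to a
sibling of the planted domain is *indistinguishable* from the planted
mapping — the scoring rule counts shared-root containment. Recovery and
rejection rates are therefore computed at hierarchy-root level: a retained
candidate whose root matches the planted domain's root (for the same
compound) counts as recovered, and "non-planted" candidates are those that
match no planted association at root level. At the default conditions with
5% label noise, 20 seeded worlds recover ≥ 95% of planted associations at
the 0.5 threshold while ≥ 99% of non-planted candidates are rejected
(measured in `tests/testthat/test-acceptance.R` and recomputed by
`scripts/acceptance.R`).

## Numerical and degenerate-input choices

* Zero-denominator metrics are 0 (see above).
* Boundary activity values 10 and 20 uM are ambiguous.
* An empty mapping/reference intersection yields a flagged all-zero
  benchmark row, not an error.
* Pair features serialize lexicographically (`"IPRa+IPRb"`), so feature
  identity is order-free.
* Unknown domain ids are their own hierarchy roots; hierarchy cycles are
  rejected at construction.
* Problem sizes in the tests (worlds of 8–50 compounds, 30–100 proteins,
  10–30 domains; 20 replicate worlds for recovery, 100 for structural
  invariants) are chosen so the whole suite exercises every stage —
  including real fingerprint computation — at desk scale.

## Known limitations

* Domain combinations beyond pairs are not scored; triples and higher
  explode combinatorially and the pair analysis already shows most pairs
  are neutral.
* The method inherits reporting bias from bioactivity databases: inactive
  measurements are scarce, so eligible compounds skew toward well-studied
  chemotypes.
* A compound binding domains from entirely different hierarchies is scored
  against each independently; cross-tree substitution is not modeled.
* Identifier harmonization between reference sets and the mapping
  vocabulary (e.g. Pfam-to-InterPro) is assumed done upstream.
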