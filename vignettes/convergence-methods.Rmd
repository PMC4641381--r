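---
title: "Methods: burden testing, isobaric quantification and semantic convergence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: burden testing, isobaric quantification and semantic convergence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`ftdconv` chains five analysis stages that, together, ask whether a
candidate gene's rare variants are enriched in a disease cohort and whether
the downstream proteome of carriers converges on disease-relevant biology.
This vignette records the models, the conventions we pinned where the
methodology left room, and what the synthetic generators do and do not
establish.

## Rare-variant burden

Variants are banded by minor allele frequency: *rare* below 1 %,
*low-frequency* from 1 % to 5 % with **both boundaries inclusive** (the
band is read as "between 1–5 %"), *frequent* above 5 %. Carrier collapsing
counts an individual with any number of qualifying variants as **one
mutated allele** — phase is typically unknown, so multi-variant carriers
must not be double counted.

The association test is built on the allele-level 2×2 table under a
heterozygous-carrier assumption: each cohort contributes `2N` chromosomes,
`carriers` of them mutated. This choice is deliberate: with the reference
counts 60/529 vs 73/920 the allele table (a=60, b=998, c=73, d=1767)
reproduces OR 1.46 and Woolf CI 1.03–2.07 exactly, whereas a carrier-based
table (60/469 vs 73/847) gives OR 1.48 and is rejected. Pearson's χ² is
used **without** Yates continuity correction (with correction χ² = 4.07,
P = 0.044, which does not match the reference statistics). Zero cells make
the OR/CI undefined and are flagged explicitly rather than silently
corrected.

One numerical footnote: exact arithmetic on that table gives χ² = 4.4528
and P = 0.034844, which rounds to 0.0348. The reference value 0.0349 equals
the χ² tail evaluated at the statistic's two-decimal display precision
(`pchisq(4.45, 1, lower.tail = FALSE)` = 0.03490) — a display-rounding
artifact of the original software chain, not a model difference. The
acceptance test asserts both facts.

When a variant table lacks MAF values they are imputed cohort-internally
from control allele counts, `carriers / (2 N_ctrl)` — controls approximate
the population frequency. An external MAF column always takes precedence.

## Isobaric 8-plex quantification

The eight reporter labels are 113–119 and 121 (120 does not exist in the
8-plex kit). Only PSMs with **all eight channels present and positive** are
quantified. Conventions where the procedure is commonly underspecified,
pinned here and in the tests:

* Within-group combination: **geometric mean** of the group's channel
  intensities — consistent with log-scale ratios.
* Protein aggregation: **median** of PSM-level log2 ratios (robust to a
  single aberrant PSM); the mean is available by flag.
* Significance: per comparison, mean μ and **sample** standard deviation σ
  (n−1) of the protein log2 ratios; significant iff |ratio − μ| > 2σ with a
  **strict** inequality, so a boundary z of exactly 2 is not called. A
  consequence worth knowing: with n proteins the largest attainable sample
  z is (n−1)/√n, so no call is possible at all below n = 6.
* Direction is *relative to the comparison mean* μ, not to 0, because
  significance itself is defined relative to μ.
* The mean/SD are per comparison (not pooled), an interpretation choice;
  no channel normalization is applied beyond the log2 ratio transform.

Ratios are invariant to PSM row order and to uniform rescaling of a PSM's
channels, and a group whose channels equal the controls scores exactly 0;
all three are asserted as properties.

## Venn separation

Each significant protein is assigned to the exact subset of comparisons in
which it is significant (7 regions for three comparisons). Its class is
*up* or *down* when every direction agrees and *contra* when **any one
pair disagrees** — any disagreement breaks coherence, including three-way
mixed patterns. The *common coherent core* is the triple-region,
non-contra subset; *unique sets* are the singleton regions. Regions are
disjoint and cover the union of the inputs; relabeling comparisons permutes
regions consistently (both property-tested).

## Over-representation and the hybrid score

Enrichment of a query against a GMT annotation uses the one-sided
hypergeometric upper tail P(X ≥ k); the EASE-style penalization (one hit
removed, P(X ≥ k−1)) is available by flag since DAVID-lineage tools use it
— which variant produced any given published table is usually unknowable.
The enrichment factor is fold enrichment `(k/n)/(K/N)`, and the hybrid
score is `(−log10 p) · EF · k`. Filters follow the field convention: at
least 2 query proteins per term, raw p ≤ 0.05 (no multiple-testing
correction by default; Benjamini–Hochberg by flag). When invoked from the
pipeline the background is the set of all quantified proteins — the correct
universe for detection-conditioned enrichment.

## Latent semantic indexing

Documents are tokenized (lower-case alphanumerics, versioned stop-word
list), weighted by log-scaled TF and smoothed IDF
(`log((1+N)/(1+df)) + 1`), L2-normalized, and factorized by truncated SVD;
`latent_dim` defaults to `min(100, rank)` and is clipped with a warning.
Documents and queries are represented by projection onto the left singular
vectors (`Uᵀx`), a gene by the **centroid** of its linked documents
(concatenation would be the alternative; centroid is pinned). Cosines are
clipped to [0, 1] — negative latent cosines carry no meaning on the 0–1
association scale — and ≥ 0.1 is flagged as an implicit association.

Two documented subtleties. First, the full-rank/TF-IDF-cosine equivalence
holds exactly only when the factorization spans the whole term space
(rank = number of terms, i.e. at least as many linearly independent
documents as terms); otherwise the projected query loses its out-of-span
component and the latent cosine can only exceed the raw one. The oracle
tests therefore use corpora with singleton documents guaranteeing full term
rank. Second, IDF is corpus-dependent: removing even a gene-unlinked
document changes document counts, hence IDF, hence scores — IDF is not
frozen.

Dataset scores sum the qualifying cosines (≥ 0.1) over a gene set and
divide by the **set cardinality**; "taking relative sizes into account" is
read as this simplest normalization and pinned in configuration. The
combined score sums the size-adjusted per-term scores. Scores are invariant
to duplication and permutation of genes and terms.

## Expression statistics

Relative quantities use `E^(minCt_gene − Ct)` with amplification efficiency
E fixed at 2.0 (configurable; no efficiency was reported for the reference
assays), anchored at each gene's lowest mean Ct. The normalization factor
is the geometric mean of the housekeeping genes' quantities (GAPDH and
ACTB by default, the multi-reference-gene convention). Adding a constant
to all Cts of one sample cancels through the normalization factor; only
the minCt anchor can move, which rescales a gene's levels by a common
factor — between-sample ratios are exactly invariant, and the anchor is a
convention, not a claim about absolute abundance.

Group comparison is a two-sided Mann–Whitney U: exact (via the exact U
distribution) when both groups have ≤ 8 untied observations, otherwise a
normal approximation with midranks and tie correction and **no** continuity
correction. The exact path is verified against exhaustive permutation
enumeration for all group sizes ≤ 6. Stars: `*` < 0.05, `**` < 0.01,
`***` < 0.001.

## The synthetic stated world

The generators produce data with the statistical structure each stage
assumes, at the reference regime:

* **Cohort**: 529 cases / 920 controls, carrier frequencies 0.113 / 0.079;
  3 % of control carriers receive 2–3 distinct variants to exercise
  collapsing; heterozygous carriers only (matching the burden test's allele
  accounting). Variant ids are drawn from a pool large enough that
  per-variant MAFs stay below 1 %.
* **Reporters**: lognormal intensities around protein×channel means with
  log2-scale noise SD 0.2; planted common/unique/contra sets shift the
  affected groups by ±2 log2 units (≈ 4 call-SDs at the default planted
  fraction); missingness is missing-completely-at-random on a single
  channel — the minimal mechanism that exercises the completeness filter.
  No reporter noise model is established for this platform; lognormal is a
  configurable stand-in.
* **Corpus**: bag-of-terms documents, one linked gene each; planted
  (gene, term) pairs co-occur at 0.6–0.8 versus background 0.05.
* **qPCR**: flat housekeeping genes, a fold-change shift of
  `−log2(FC)` cycles on targets, duplicate measurements with 0.15-cycle
  technical noise.

What a green test does *not* establish: real acquisitions have correlated
channel noise, ratio compression from co-isolation, peptide-level missing
patterns, polysemous vocabulary and citation structure — none of which are
emulated. The published per-comparison protein counts (294/326/337
significant, 71 common) depend on the unavailable raw MS data and are
treated as anchors, not reproducible targets; the simulation-based
acceptance criteria (sensitivity ≥ 0.95 at ≥ 4σ planted effects, null
false-call rate ≈ the 4.6 % two-sided 2-SD tail) are the testable
substitute.

## Other design notes

* Channel-design and pipeline-configuration files are JSON rather than
  YAML: the deployment environment guarantees a JSON parser but no YAML
  parser, and the content is a flat map either way.
* Per-stage seeds are derived from the master seed by a fixed affine map
  (kept below 2³¹); every generator isolates and restores the global RNG
  state, so pipeline stages cannot perturb each other.
* The control carrier count 73 used by the burden fixture is derived
  (round(0.079 × 920)), shipped with that provenance note, and validated by
  exact reproduction of the reference OR/CI.
* The pipeline writes a deterministic JSON manifest (config, seed, package
  version, artifact list; no timestamps), so reruns are bit-identical.
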