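---
title: "Identifying common driver genes of two diseases on an interaction network"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying common driver genes of two diseases on an interaction network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem and the model

Two diseases can be clinically intertwined — obstructive sleep apnea and
dementia are the motivating pair — while sharing no risk variants at all.
`nicd` asks a weaker, topological question: which genes are *directly
wired*, on a gene–gene interaction network, to known risk genes of
**both** diseases? Such "common drivers" are candidate mechanistic links
between the two conditions even when their variant-level genetics are
disjoint.

The procedure has four stages.

**1. Disease gene sets.** A disease is a list of UMLS CUIs. The
disease–variant table contributes every variant recorded for any of those
CUIs; the variant–gene table maps those variants to genes. Membership is
deliberately unfiltered — any mapping record qualifies a gene — because
the method's statistics are computed downstream, not at assembly time.
The two gene sets may be wildly asymmetric (1108 vs 23 genes in the
reference study); nothing in the method assumes balance.

**2. Primary candidates.** On the network (undirected, unweighted,
simple; the reference interactome is PCNet v1.3 with the near-universal
hub UBC removed, since a gene adjacent to everything would link any pair
of disease sets), gene $g$ is a primary candidate iff

$$N(g) \cap A \neq \emptyset \quad\text{and}\quad N(g) \cap B \neq \emptyset,$$

where $N(g)$ is the set of direct neighbors. By default $g$ itself must
not belong to $A \cup B$ (`exclude_seeds = TRUE`): in the reference
driver table every driver is distinct from its supporting disease genes,
so seed genes are not reported as drivers. The flag is configurable for
sensitivity analysis. Candidacy is binary — we record the supporting
neighbors but do not score by their number or by degree.

**3. Permutation test.** The null asks how often a candidate would be
rediscovered if the disease inputs were random. Each replicate redraws
two input sets of the observed sizes, uniformly without replacement,
independently of each other (the two draws may overlap), reruns stage 2
with the same seed-exclusion flag, and increments a counter $x(g)$ for
every observed candidate found again. With $n$ candidates and the default
$100 \cdot n$ replicates,

$$p(g) = \frac{x(g)}{100\,n},$$

followed by Benjamini–Hochberg correction across candidates and selection
at $q \le \alpha$ ($\alpha = 0.05$ by default; the threshold is always
recorded in the run's provenance because results are meaningless without
it). The choice $n =$ *number of primary candidates* (not of final
drivers) matters: the reference study's printed p-values are integer
multiples of $1/361000 = 1/(100 \times 3610)$, which the shipped fixture
and the test suite verify, and which would not hold for any other
denominator. $p = x/\text{iterations}$ exactly, so $p = 0$ is possible; an
opt-in `plus_one` mode gives the conservative $(x+1)/(\text{iterations}+1)$.

Two sampling universes are first-class:

* `disease_id` (default): replicates draw CUI sets of the observed query
  sizes from all distinct CUIs of the disease–variant table and re-expand
  them through the tables. This emulates "querying the database with
  random diseases" and inherits the empirical CUI-to-gene-set size
  distribution.
* `gene`: replicates draw gene sets of the observed disease-set sizes
  directly from the network nodes.

`disease_id` is only meaningful when the CUI universe is much larger than
the queries (real DisGeNET has tens of thousands of CUIs). The synthetic
benchmark below carries exactly $14 + 3$ CUIs, so there the `gene` mode is
the appropriate null and is what the end-to-end tests use.

**4. Enrichment.** Significant drivers are annotated against GMT pathway
libraries with the one-sided hypergeometric tail on the 2×2 overlap
table, BH-corrected within each library. This is the exact-test core of
Enrichr-style enrichment; the combined z-score ranking is intentionally
not reproduced, since its constants are service-internal. The background
defaults to the union of the library's genes and can be overridden (e.g.
to the network size). Report rows carry per-library flags marking
membership in *any* term passing $q \le \alpha$, mirroring the
olfactory/GPCR check-marks of the reference driver table.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `excluded_genes` | `UBC` | hubs removed from the network before analysis |
| `exclude_seeds` | `TRUE` | drivers must not be disease genes themselves |
| `mode` | `disease_id` | permutation sampling universe |
| `iterations` | `100 * n` | permutation replicates (`n` = candidates) |
| `alpha` | `0.05` | BH FDR threshold for driver selection |
| `plus_one` | `FALSE` | conservative p-value estimator |
| `background_size` | library union | Fisher-test universe |

Gene identifiers are opaque uppercased strings; no symbol/Entrez
translation is attempted, because silently mixing identifier spaces would
corrupt the set intersections the whole method is built on. An optional
two-column mapping file can be applied at network load time when the
interactome and the variant tables use different spaces.

## The synthetic benchmark and what it does (not) show

`scenario_config()` describes a self-contained two-disease world:
independent-edge background graph, disease genes grouped under synthetic
CUIs with DisGeNET-format variant tables, *planted drivers* guaranteed at
least one edge into each disease set, and *one-sided decoys* whose edges
into the opposite disease set are severed. Defaults — 2000 genes, edge
probability 0.002 (mean degree 4), 14 + 3 CUIs with 3 genes each (42 vs 9
disease genes, echoing the reference study's asymmetry at desk scale),
5 planted drivers, 5 + 5 decoys, 2 variants per gene — are fixed study
conditions, not knobs to tune per run. Generation is byte-deterministic
given the seed, and `verify_truth()` re-derives every invariant from the
files alone.

By construction planted drivers are always primary candidates and decoys
never are; what the permutation stage must then demonstrate — and what the
acceptance tests measure across 10 seeds — is that planted drivers survive
FDR control while chance background candidates carry larger p-values. The
generator emulates the *statistical structure* the method relies on, not
real biology: degree distributions are binomial rather than scale-free,
variants are unique to their gene (no pleiotropy or linkage), and CUI gene
sets are disjoint. Passing these tests shows the machinery is correct and
calibrated on its own terms; it does not certify performance on real
interactomes, whose hubs and modularity change the null substantially
(hence the UBC exclusion in the reference profile).

## Numerical choices and degenerate inputs

* The exact enumerable toy null (5 genes, single-gene draws, candidate
  probability $4/25$) anchors the permutation engine; empirical estimates
  are required to sit within 4 binomial standard errors.
* BH is delegated to `stats::p.adjust` after domain validation and is
  cross-checked in the tests against an independently hand-coded step-up;
  $q \ge p$ and monotonicity of $q$ in $p$ are asserted as properties.
* The hypergeometric tail is `stats::phyper`, cross-checked against
  direct combinatorial enumeration on every 2×2 table with $N \le 20$ and
  against Monte-Carlo draws.
* Self-loops are dropped (their endpoints kept as isolated nodes),
  duplicate and reversed edges collapse; `exclude_genes` is idempotent.
* Empty driver sets produce header-only reports with a warning, not an
  error; seed genes absent from the network are skipped with a logged
  count; a sample size exceeding its universe is an error.
* Ties in driver ordering are broken by gene identifier, so reports are
  byte-stable across reruns with one seed.

## Problem sizes used by the shipped checks

The test suite validates the candidate finder against a brute-force
double-loop oracle on 200 random graphs of up to 300 nodes, the toy null
at 50,000 replicates, BH on 1,000 random p-vectors, enrichment on all
small tables, and driver recovery on 10 full synthetic scenarios at the
default study conditions. The acceptance script re-runs the benchmark on
3 scenario seeds. These sizes keep a complete run in the low tens of
seconds on a laptop while leaving the statistical assertions sharp
(4-standard-error bands; exact equality for deterministic quantities).

## Known limitations

* Candidacy ignores *how many* supports a gene has; a gene with one
  neighbor in each set ranks equally with one having twenty, before the
  permutation stage.
* The null preserves input-set sizes but not network degree structure;
  degree-preserving rewiring would be a different (and stricter) null and
  is deliberately out of scope.
* `disease_id` sampling treats CUIs as exchangeable, which is generous to
  diseases with unusually large gene sets.
* Identifier-level variant comparison means build/allele differences
  between sources silently reduce overlaps; curate inputs accordingly.
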