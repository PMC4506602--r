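---
title: "Methods: druggability screening and network enrichment in netpharm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: druggability screening and network enrichment in netpharm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netpharm)
```

## The workflow and its assumptions

`netpharm` implements the compound-screening workflow of network
pharmacology: a multi-herb formula is represented as the union of its herbs'
reported phytochemicals, each compound carries a vector of molecular
descriptors, and bioactivity candidates are the compounds that (i) look like
oral drugs and (ii) connect, through interaction databases, to pathways or
disease classes relevant to the indication. The workflow assumes that
compound identity across databases can be resolved by name, that descriptor
values supplied by the source databases are trustworthy as inputs, and that
interaction evidence — confidence-scored compound–protein links and
occurrence-counted compound–gene links — is informative about mechanism even
though it is literature-derived and incomplete.

## Compound identity and catalog merging

Catalogs from different sources overlap heavily, so merging is
provenance-aware. Identity is the case-folded, punctuation-normalized
compound name (`normalize_compound_id()`); an explicit structure key
overrides the name when both records carry one. Name-based identity is the
pragmatic choice because source databases rarely publish consistent
structural keys, but it cannot detect synonyms with different spellings —
a known limitation, not a bug, and the reason pre-deduplication views retain
every record. When sources disagree on a descriptor by more than a relative
`1e-6`, the conflict is reported and the earliest-listed source wins: input
order is the priority order, which keeps merges deterministic.

## The druggability screen

Three criteria, all inclusive at their boundaries:

| parameter | default | units | meaning |
|---|---|---|---|
| `max_violations` | 1 | count | Lipinski violations tolerated among MW ≤ 500 Da, HBD ≤ 5, HBA ≤ 10, AlogP ≤ 5 |
| `ob_min` | 30 | percent | minimum oral bioavailability |
| `dl_min` | 0.18 | index | minimum Tanimoto drug-likeness |

The "at most one violation" reading of Lipinski's rule follows the rule's
own phrasing (a compound failing *two or more* criteria is unlikely to be
orally active); it is also the only reading under which high-AlogP sterols
such as stigmasterol (AlogP 7.64, one violation) survive, as they do in the
published screens this package reproduces. Inclusive thresholds matter at
the margins: a compound with DL exactly 0.18 passes.

The drug-likeness index is the Tanimoto similarity
`F(A,B) = A·B / (A·A + B·B − A·B)` between the compound's property vector
and a reference profile averaging a drug collection. Two properties of this
index are documented and tested because they surprise users: it is symmetric
in its arguments, and it is *scale-sensitive* — unlike a cosine, rescaling
one vector changes the value, so the property set and units of the reference
profile must match the compound vectors exactly. Published DL values are
always preferred when present; computing DL from descriptors is an optional
path, and the shipped reference profile
(`reference_profile_synthetic.tsv`) is a synthetic stand-in with plausible
magnitudes for an eight-property set (MW, AlogP, HBD, HBA, rotatable bonds,
TPSA, ring count, heavy atoms), because no authoritative average-drug
profile is published alongside the 0.18 threshold.

Records missing a required descriptor are *indeterminate*: excluded from the
retained set and flagged in the verdict table. Silently passing them would
inflate counts; silently failing them would hide data problems.

Per-herb summary percentages are `100 * count / total` rounded
half-away-from-zero to one decimal. That rounding rule reproduces every
percentage cell of the published per-herb summary exactly, which is the test
the suite runs; banker's rounding does not.

## Interaction filtering

Protein interactions are kept at confidence ≥ 0.5 by default — the "medium
confidence" level of STITCH-style scores. The comparison is inclusive
because the methods convention is "≥ 0.5", but a strict `>` flag is exposed:
source texts are not always consistent about the boundary, and the package
makes the choice explicit rather than hiding it.

Gene interactions carry evidence as row multiplicity, so a gene's frequency
is simply its row count. The frequency filter's default mode computes the
threshold as the *mean frequency of the data* rather than any fixed
constant: published analyses quote rounded constants (1.67, 1.74) that
cannot both be the mean of the same data, and the data-driven mean is the
only self-consistent reading. `mode = "fixed"` reproduces any printed
constant. Genes at exactly the mean are retained (≥). The max-frequency gene
is always ≥ the mean, so the filter never empties a non-empty table.

## Enrichment: Fisher's exact test and the XD-style proximity score

Overlap significance is the hypergeometric upper tail: drawing the target
set uniformly from the universe, the p-value is the probability of an
overlap at least as large as observed (over-representation only — depletion
is not of interest here). Target identifiers absent from the annotation
universe are dropped with a message, mirroring real annotation coverage
gaps. Multiple testing uses Benjamini–Hochberg step-up, the field default;
the package states this as its own choice since published q-values rarely
name their procedure.

The network proximity score reinterprets a "deviation from the average
distance" statistic whose original implementation (a Cytoscape plugin) is
not fully specified in print. Our construction: random walk with restart
(default restart probability 0.3) from the target proteins over the
interaction network yields stationary node scores; a pathway's raw score is
the mean node score over its members on the network; its XD score is the raw
score minus the across-pathway mean raw score. Positive XD means
closer-than-average to the targets. **No numeric agreement with published
XD values is claimed** — the published 0.67 threshold lives on that tool's
score scale, and the package reproduces only the threshold-filtering
behaviour on printed tables. On our scale, `xd_min = 0` (above-average
proximity) is the natural analogue, and XD scores always average to zero
across scored sets.

Numerical choices in the propagation: iteration `s ← (1−r)·W·s + r·e` with
column-normalized adjacency `W` (weights honoured), uniform restart vector
`e` over the seeds, L1 convergence tolerance `1e-10`, cap 10,000 iterations.
Mass leaving degree-zero nodes is redirected to the restart distribution, so
the score vector sums to exactly 1 at every iteration — an isolated seed
node keeps its restart mass rather than leaking it. The implementation is
checked against a dense linear-system solve `s = r(I − (1−r)W)⁻¹e` on small
graphs.

Threshold filtering (`xd_score ≥ xd_min`, `p ≤ p_max`, `q ≤ q_max`) is
inclusive in every criterion and preserves row order; it is monotone in each
threshold, which the suite tests.

## The pipeline and the final intersection

`run_pipeline()` executes catalog → druggability → interactions → enrichment
→ report, persisting each intermediate and logging one line per stage with
row counts (these counts are the headline numbers of a screening study).
Outputs are pure functions of inputs and configuration; reruns are
byte-identical, and a stage failure names the stage and removes a freshly
created output directory.

A compound is linked to a significant pathway iff one of its
*confidence-retained* edges points at a protein in that pathway's annotation
set; disease linkage goes through frequency-retained genes analogously.
Which significant sets count as indication-relevant is a curated judgment,
so the pipeline accepts an explicit linkage table (compound → set name)
rather than hard-coding disease semantics; the packaged example links the
twenty compounds a published study footnoted as menopause-associated. The
final flag is `druggable AND linked to ≥ 1 significant set`, and every
flagged compound is traceable to a retained edge and a retained enrichment
row.

## What the synthetic generator emulates — and what it does not

`synthetic_scenario()` fixes every distributional knob; one global seed fans
out to independent substreams for the catalog, interaction and network
generators, so stages can be regenerated in isolation. Defaults:

* **Catalog** — six herbs × 100 compounds; MW log-normal (median 350 Da),
  AlogP normal (2.5 ± 1.8), HBD/HBA Poisson (2.5, 5), OB beta(2,3) scaled
  to [0,100] %, DL beta(1.5,4). Each compound is planted druggable with
  probability 0.2 (descriptors then forced to satisfy every criterion) or
  planted to fail a definite criterion. The operating point — roughly
  10–30 % of compounds passing — mirrors the per-herb pass rates
  (1.7–30.2 %) seen in real formula screens. Duplicates are injected at
  rate 0.1 as cross-herb, cross-source copies.
* **Interactions** — Poisson(4) protein edges per compound with beta(2,2)
  confidences; Poisson(4) gene edges with 20 hub genes drawing 10× the
  sampling weight, planting the frequency skew the ranking stage detects.
* **Network and annotations** — scale-free (preferential attachment, m = 2)
  background over 2,000 proteins; planted modules sample members with
  weight = enrichment factor for true targets and are wired internally at
  the stated density; 20 background sets of sizes 20–400.

The generator emulates the *statistical structure* the analysis assumes, not
real databases: it draws independent descriptors (real descriptors are
correlated — MW with heavy atoms, AlogP with TPSA), name collisions are
exact (no synonym noise), confidence scores are exchangeable across
compounds, and the network has no protein-complex or pathway-topology
structure beyond the planted modules. Passing tests therefore demonstrate
that the pipeline recovers planted signal under its own model assumptions —
they do not certify performance on any real database export.

## Problem sizes and statistical tests in the suite

The simulation suite uses: an exhaustive-enumeration Fisher oracle on
universes up to 12 (every draw enumerated); a null calibration with
universe 2,000, 200 uniform targets and 20 sets of sizes 20–400 over 1,000
replicates (the exact attained level of the discrete test under these sizes,
computed analytically from the hypergeometric tail, is 0.039 — any single
small set size would sit further below 0.05 purely from discreteness, which
is a property of exact tests, not of the implementation); planted-module
recovery (factor 5, universe 2,000) over 100 replicates against a BH
q ≤ 0.05 power bound of 0.9; and dense-module XD ranking (density 0.8,
500-node networks) over 100 replicates. These sizes keep the whole suite in
the tens of seconds while leaving the Monte-Carlo error an order of
magnitude below each acceptance band.

## Known limitations

* Name-based deduplication cannot merge true synonyms or split homonyms;
  multi-database merges of real exports should be audited via the conflict
  warnings and pre-dedup views.
* OB and DL are consumed as inputs; the package does not predict
  bioavailability, and the optional DL computation depends on a reference
  profile the user must supply for real use.
* The XD score is a reinterpretation; its values are not comparable across
  networks of different density, and only within-run rankings and
  threshold behaviour are meaningful.
* Disease enrichment against curated gene–disease collections depends
  entirely on the annotation GMT supplied; the package ships none.
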