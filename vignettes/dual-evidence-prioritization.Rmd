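---
title: "Dual-evidence candidate gene prioritization: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual-evidence candidate gene prioritization: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dualscreen)
```

## The procedure

`dualscreen` prioritizes candidate regulator genes by requiring two
independent lines of evidence to converge on the same symbol:

* **Arm 1 — phenotypic chemical screen.** Embryos exposed to a chemical
  library are scored per embryo for four mouth characteristics
  (stomodeum present, open mouth, cleft-like open mouth, no observable
  mouth). A chemical is a *hit* when enough of its embryos retain a
  stomodeum with the mouth not open — a persistent buccopharyngeal
  membrane, the phenotype of interest. Hit chemicals are mapped to their
  known protein targets through a frozen chemical→target table, and each
  target is scored by the number of **distinct** hit chemicals acting on
  it. Targets reaching `min_chemicals` (default 3) form the focused
  target list.
* **Arm 2 — patient copy-number deletions.** Each patient contributes a
  set of deletion intervals; a gene is *affected* for that patient when
  any deletion overlaps any of the gene's loci. Each patient counts at
  most once per gene, however many of their deletions cover it. Genes
  affected in at least a fraction of the cohort (default 0.10) form the
  focused gene list.
* **Functional overlap.** Both arms' full gene lists (all unique hit
  targets; all deleted genes) are profiled against a frozen
  gene→category map; categories with `min_genes` (default 5) members in
  an arm are retained, and categories retained in *both* arms are
  reported as shared. This is a descriptive count, deliberately without
  enrichment statistics: the procedure it re-implements reports raw
  category sizes, and attaching p-values would claim more than the data
  support.
* **Intersection.** The candidate set is the intersection of the two
  focused lists after symbol normalization. An empty intersection is a
  valid, explicitly reported outcome.

The intersection is reported descriptively, without a permutation null on
its size: the evidence combination is a filter, not a test, and the
package does not attach significance to it.

## Symbol and coordinate conventions

The two arms name genes in different conventions (frog protein targets
vs. human gene symbols), so every comparison happens after
normalization: uppercase, whitespace stripped, and trailing *Xenopus
laevis* homeolog suffixes (`.L`/`.S`, also stacked) removed, repeating
suffix stripping and re-trimming until the string is stable so the
function is idempotent. An optional user-supplied synonym table (applied
once, before suffix handling) covers renamings the mechanical rule cannot,
e.g. a prose target name mapping to its official symbol.

All intervals are held internally in a single canonical convention,
0-based half-open, the convention of BED. DECIPHER-style clinical extracts
are 1-based inclusive and are converted on read; the conversion is a
bijection, and writers always emit the canonical dialect with a header
comment naming it. Readers reject rather than repair malformed rows —
inverted intervals, unparseable coordinates and unrecognized boolean
spellings all error with row numbers, because silent coercion hides
scoring mistakes.

Chromosome naming ("chr1" vs "1") is reconciled by an optional
harmonization pass, on by default with a logged note. If the deletions and
annotation share no chromosome names *because their naming styles differ*,
that is an error with a remediation hint, never a silent zero-overlap
result; genuinely disjoint chromosome sets in the same style are a legal
empty result.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| hit rule mode | `majority` | strict majority of scoreable embryos shows the phenotype |
| `exclude_no_mouth` | `TRUE` | embryos with no observable mouth leave the denominator |
| `min_chemicals` (*k*) | 3 | distinct hit chemicals per focused target |
| `patient_fraction` | 0.10 | cohort fraction per focused gene |
| `threshold_mode` | `ceil` | integer threshold from `fraction × N` |
| `overlap_rule` | `any_overlap` | ≥ 1 bp of a deletion over a gene locus counts |
| `min_genes` | 5 | category size floor, both arms |

Design choices that were genuinely open:

* **Hit aggregation.** Six embryos are scored per well, but no fixed
  number of affected embryos defines a hit; the default is a strict
  majority of scoreable embryos, which tolerates a single dead or
  aberrant embryo, with `all` and `fraction` modes available. Under the
  `all` mode every embryo in the well must show the phenotype — including
  `no_mouth` embryos, which by definition cannot — so `all` is strictly
  harsher than `majority` and ignores the exclusion flag. Embryos scored
  `no_mouth` are never evidence *for* a hit (the phenotype class requires
  an observable stomodeum); by default they are also excluded from the
  denominator.
* **"Approximately 10%".** The recurrence cutoff is exposed as a fraction
  plus an explicit integer-threshold mode rather than a hard-coded count:
  for an 83-patient cohort `ceil` gives 9, `floor` gives 8, and the
  resolved threshold is recorded in the report provenance so the
  ambiguity is surfaced, not hidden. `at_least` compares on the real line
  and coincides with `ceil` for integer counts; it exists so a
  configuration can state the comparison it means.
* **Overlap rule.** `any_overlap` is the default because a deletion
  removing part of a gene still disrupts it; `full_containment` is
  available for sensitivity analysis and always yields a subset.
* **Category matching** is by category id, not display name — display
  names drift between releases of classification resources.
* **Cohort denominator.** Patients with zero mapped genes stay in the
  cohort size: the recurrence fraction is over ascertained patients, not
  informative ones.
* **Category threshold on both arms.** The ≥ 5-gene category floor is
  applied to both arms' classifications by default (`min_genes_cnv`
  overrides the CNV arm) — the shared-category comparison is only
  meaningful between tables filtered the same way.
* **Retest confirmation.** The screening protocol retests hits; the
  package models this as optionally AND-combining a second screen's
  calls, off by default since curated hit lists are typically
  post-retest. (Run `call_hits` on both tables and intersect
  `hit_chemicals`.)
* **Manual curation** (hand-picking developmental regulators from the
  long lists) is human judgment, not computation; it is represented only
  as an optional `highlight` list echoed in the report when its symbols
  occur in either arm.

## The synthetic-data generators

The generators emulate the statistical structure of every input at the
study's stated conditions: 1200 chemicals with a hit rate of 41/1200 and
six embryos per well at 30 µM; 83 patients; thresholds *k* = 3,
fraction 0.10, `min_genes` 5; seven planted shared categories. The
simplified genome (5000 genes over 23 chromosomes, uniform 5–100 kb
gene lengths with 1–50 kb gaps; the cohort-scale figure the package's
acceptance checks use) supplies non-overlapping loci; deletion lengths
are log-uniform between one mean gene length and half a chromosome,
reflecting deletions that range up to large chromosomal regions.

The planted signal is constructed with margins above the thresholds
(target hit by *k* + 2 = 5 distinct chemicals; gene deleted in
`ceil(0.10·N)` + 2 = 11 distinct patients) while background is held
*strictly below* them: hit-chemical links are only drawn from targets
whose running degree stays below *k*, deletions of planted patients cover
the planted locus without touching its neighbors, background deletions
are redrawn if they touch the planted locus, and any background gene that
reaches the patient threshold triggers a redraw of one offending
patient's deletions. Recovery of the planted candidate is therefore exact
by construction — the generators test the *pipeline* (its filters, joins,
normalizations and I/O), not the biology. Every generator is a pure
function of its spec, seed included.

What the synthetic data deliberately does **not** emulate: real human
genome coordinates or gene density, linkage between deletions and
genomic features, chemical structure or dose–response, polypharmacology
patterns beyond random target assignment, and realistic category
ontologies. A clean pass on synthetic data therefore demonstrates
correctness of the computation, and nothing about the biological validity
of any particular screen.

## Numerical and degenerate-input choices

* Frequency tables sort by count descending with an alphabetical
  tie-break, making every ranking deterministic.
* Percent tabulations round to one decimal (the reporting convention of
  the phenotype-proportion panels); counts are preserved alongside so no
  information is lost to rounding.
* Empty inputs flow through: an empty hit set yields an empty frequency
  table, an empty cohort a zero-size table, and an empty candidate set a
  successful run with an explicit empty report.
* A chemical with zero embryo rows is an error at hit-calling time (there
  is no evidence to call), not a silent non-hit.
* Reports contain no timestamps, and all set-valued fields are sorted, so
  identical inputs and configuration serialize byte-identically.

## Problem sizes used in the checks

The test suite validates the interval engine against an exhaustive
pairwise scan (20 fixtures of 200 × 50 in the unit tests; 100 fixtures of
1000 intervals × 200 genes in the acceptance checks), runs 20 seeded
study-scale bundles (1200 chemicals / 83 patients / 5000 genes) for exact
planted recovery, and exercises threshold grids for monotonicity. These
sizes make the whole suite complete in about a minute while covering the
full study scale.

## Known limitations

* Identifier resolution beyond the synonym table (genome-build liftover,
  cross-database id mapping) is out of scope; the gene annotation is user
  input and its digest is recorded in provenance, because clinical CNV
  extracts do not always state their genome build.
* The chemical→target and gene→category tables are frozen inputs; the
  package performs no live database queries.
* Copy-number *gains* and dosage-sensitivity scoring are not modeled;
  only deletions are considered.
* The two arms are treated symmetrically at intersection time; no
  weighting by evidence strength (e.g. 5 vs 3 chemicals) is applied.
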