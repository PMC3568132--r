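---
title: "Rare-variant prioritization in multiplex families: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rare-variant prioritization in multiplex families: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(exomesieve)
```

## The analytical model

`exomesieve` targets the classic study design for genetically heterogeneous
familial disease: a small number of multiplex families (here, the defaults
describe seven, each with many affected women and no *BRCA1*/*BRCA2*
mutation), one or two affected members exome-sequenced per family, and a
reference panel of unrelated controls sequenced on the same platform. The
underlying genetic assumptions are:

* the causal allele is **rare** — hence exclusion against a known-variant
  database and a control panel removes mostly neutral polymorphism;
* it acts **dominantly** in **heterozygous** carriers — hence heterozygote
  selection for SNVs and the expectation that both sequenced relatives
  share it;
* it is **functional** — hence the consequence filter and the optional
  cancer-gene allowlist;
* it is **well supported** by reads — hence the allele-balance scores.

None of these assumptions is guaranteed; the cascade is therefore built as
a set of independent, individually relaxable stages (every threshold is a
`cascade_config()` field), and candidate evaluation afterwards relies on
orthogonal evidence: case-control association, co-segregation and
predicted impact.

## Scores and thresholds

The Depth Score and Quality Score are percentage-scale allele ratios,

$$\mathrm{DS} = 100\,\frac{d_\mathrm{alt}}{d_\mathrm{ref}}, \qquad
  \mathrm{QS} = 100\,\frac{q_\mathrm{alt}}{q_\mathrm{ref}},$$

with $d$ read depths and $q$ Phred-scaled quality masses per allele. A
clean heterozygote sits near 100; systematic artifacts pile up near 0 or
at very large values. When the reference term is zero the score is
*undefined* — deliberately distinct from zero, because a missing
denominator certifies nothing. Undefined scores fail the SNV filter.

The defaults are the calibrated operating point of the pipeline:

| parameter | default | meaning |
|---|---|---|
| `snp_score_low/high` | 20, 210 | inclusive DS *and* QS window for SNVs |
| `indel_ds_max` | 140 | strict DS ceiling for INDELs |
| `indel_phred_min` | 10 | strict floor, variant-allele quality mass |
| `indel_snpq_min` | 10 | strict floor, caller site quality |
| `indel_min_reads_each` | 3 | reads required per allele |
| `het_only` | TRUE | SNVs restricted to heterozygotes |

Boundary semantics follow the filter definitions literally: the SNV window
is inclusive ("between 20 and 210"), the INDEL bounds are strict
("< 140", "> 10"). The read-QC rules are strict too ("more than 5" N's,
"more than 70%" single-base), so boundary reads survive.

Which allele goes in the numerator is not derivable from the filter
bounds alone — the window semantics are symmetric under inversion — so
the orientation is a config switch (`score_orientation`), with
variant-over-reference as the default: an upper bound of 210 on a
percentage-format score only makes sense when values above 100 (more
variant than reference evidence) are legal.

## Threshold calibration

`calibrate_thresholds()` reproduces the tuning procedure: take the panel's
calls, mark those already present in the known-variant database as truth,
and grid-search threshold combinations for the one that keeps at least the
target fraction (default 95%) of known variants while retaining the fewest
calls overall. Ties prefer higher retention, then the lexicographically
smallest thresholds, making the choice reproducible. The default grids
(SNV window lows 0–50 by 5, highs 100–300 by 10; INDEL DS ceiling 50–300
by 10) cover the plausible range at desk scale; the grid actually searched
in any given study is a user decision and both grids are arguments.
Known variants with undefined scores count as lost — the conservative
reading, since their window membership cannot be certified. With
well-separated score distributions (SNV-like data) the chosen point
retains ≥ 95% of truth; with heavy overlap and thin read support
(INDEL-like data) retention collapses under the stringent criteria — the
qualitative behaviour expected from artifact-rich unfiltered indel calls.

## Funnel accounting

`summarize_funnel()` mirrors the conventions of published
filtering-summary tables. The first stage is counted per sequenced sample;
a family's stage-1 value is the mean of its samples. Later stages are
per-family (the shared set). The `Average` row is the mean over families,
rounded half-away-from-zero to an integer; the `Percentage remaining` row
divides the *reported* (rounded) averages by the reported stage-1 average.
Deriving percentages from the rounded averages, rather than from unrounded
intermediates, keeps the two printed rows mutually consistent — the two
conventions differ by one unit in the second decimal in rare cases, and
the reported-average convention is the one that reproduces typeset tables
exactly.

## Association, segregation, prioritization

Rare-variant association uses allele-count tables built from carrier
counts under a no-homozygote assumption (each carrier contributes one
variant allele): `(a, b, c, d) = (k_1, 2n_1 - k_1, k_2, 2n_2 - k_2)`.
The two-sided Fisher exact p-value follows the point-probability rule —
the sum of hypergeometric probabilities of all tables with the observed
margins that are no more probable than the observed table (relative
tolerance `1e-7`), matching the convention of standard association
software. The odds ratio CI is Woolf's log-scale interval with $z = 1.96$;
zero cells yield `NA` by default or Haldane's +0.5 correction on request.
Printed confidence intervals in the literature are not always recoverable
from printed counts (the method used is often unstated), so the CI is
reported but should not be treated as a cross-implementation invariant.

Segregation is the fraction of available affected relatives with known
genotype who carry the variant; the pass rule defaults to ≥ 50% (the
boundary case is included, and a strict `"gt"` rule is available).
Affected non-carriers diagnosed at or after 70 years are flagged as
candidate phenocopies: in late-onset disease, an elderly sporadic case in
a high-risk family is unremarkable, and the single exemplar available for
anchoring (diagnosis at 76) offers no rule, so 70 is a configurable
default chosen at the conventional boundary for late-onset breast cancer.

`prioritize()` encodes the final triage: (OR > 2 **or** zero control
carriers) **and** damaging in at least one predictor **and** segregation
passing or not assessable. Missing evidence fails its criterion, except
segregation, whose absence (families where no further relatives exist)
is explicitly non-disqualifying.

## The synthetic-data generator

The generator produces the statistical structure each stage consumes,
with generation-time truth as an independent oracle:

* **Reads**: 78-bp reads, uniform sequence with per-position N
  substitution (2%) and a mono-base contamination fraction (5–10%); truth
  evaluates both QC rules directly on the base matrix.
* **Family variant sets**: per-sample heterozygous SNV counts uniform in
  26,500–30,700 and INDEL counts in 25,200–36,200 (the per-sample ranges
  observed in real exome call sets of this design after heterozygote
  selection); a 3-singleton + 4-pair family layout; 32% of a pair's
  variants shared by both members (shared keys copied, evidence drawn
  independently per member — the cascade compares keys, not evidence);
  database membership Bernoulli per variant (87% known-database, 70%
  control-panel, drawn independently); consequence labels and gene
  symbols drawn from configurable distributions; scores from a
  good/noise mixture (noise much commoner among INDELs, 70% vs 10%).
* **Implants**: one causal variant per designated family — shared, novel,
  stopgain, allowlisted gene, evidence passing every filter by
  construction — whose keys are the recovery truth.
* **Case-control cohorts**: exact configured carrier counts placed
  uniformly at random among individuals.

Coordinates are synthetic (`c1`–`c22`, positions uniform on 1–2×10⁸);
no reference genome, linkage structure, mapping realism or indel
left-alignment is modeled. Passing tests on this data therefore
demonstrates the *logic* of the pipeline — filter semantics, sharing,
exclusion, score arithmetic, funnel accounting — not robustness to
alignment error, batch effects or annotation disagreement in real data.

All generators are pure functions of their configuration: they seed a
private RNG stream (fixed offsets from the config seed) and restore the
caller's RNG state, so identical configs give byte-identical outputs.

## Numerical and interface choices

* Variant identity is the allele-aware key `(chrom, pos, ref, alt)`;
  site-set exclusion matches on the full key, the conservative
  reproducible reading of database exclusion (position-only matching is
  obtainable by building the site set accordingly). Indels are compared
  as given, without left-alignment — a documented dialect limitation.
* Evidence fields for a family-shared variant are taken from a
  configurable index member (default: first listed), since scoring is
  per-sample but one record per family is reported.
* The joint "score and gene" stage applies scores then the allowlist;
  the two orders give identical counts, and both component filters are
  exported separately.
* Missing per-record depth/quality values parse to `NA` and make scores
  undefined; a FORMAT field absent from a VCF entirely is an error, so
  silent all-`NA` columns cannot arise from a misnamed dialect field.
* Rounding of reported funnel rows is half-away-from-zero (`round()`'s
  banker's rounding would differ at exact halves).
* Problem sizes in the test-suite property sweeps are chosen at desk
  scale: exhaustive Fisher enumeration over all 2×2 tables with total
  ≤ 40, 100 synthetic cohorts of ~60–90 SNVs and ~40–70 INDELs per
  sample for cascade/oracle and implant-recovery checks, full-scale
  (~28k/31k per sample) generation exercised once for magnitude checks.

## Known limitations

* The gene allowlist is user input; no attempt is made to reproduce
  manual gene-function curation.
* Consequence and gene annotations are consumed as input columns; there
  is no annotation engine, liftover or transcript model.
* The synthetic generator draws database membership independently per
  variant, so the panel/database overlap structure of real data (panel
  variants being largely a subset of the database) is only approximated.
* Case-control statistics assume no homozygous carriers, appropriate for
  MAF ≪ 1% but not for commoner variants.
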