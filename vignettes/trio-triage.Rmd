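---
title: "Trio variant triage: models, rules and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Trio variant triage: models, rules and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(triotriage)
```

## Scope

`triotriage` automates the filtering stage of a clinical trio-sequencing
workflow: from annotated variant calls (VCF), CNV calls, a pedigree and a
DDG2P-style gene panel to a short list of flagged candidates with complete
reason trails, plus the cohort bookkeeping (predictive value, diagnostic
yield) used to audit such a workflow. It deliberately does *not* call
variants, compute consequence or pathogenicity annotations (they are
consumed as-is), detect uniparental disomy or mosaicism, or automate the
clinical phenotype review — where a panel entry requires specific phenotype
terms, candidates are annotated as matching or mismatching, never removed,
because a filtering tool should not silently discard what experts would
review by hand.

## The inheritance model

Genotypes are alt-allele counts; males are hemizygous (ploidy 1) on X. The
classifier enumerates which (maternal gamete, paternal gamete) combinations
are consistent with the stated parental genotypes and labels the child's
alt source by set membership:

* no consistent combination: `de_novo` when both parents carry zero alt
  copies, otherwise `mendelian_error`;
* a het child whose alt could only have come from one parent gets that
  parent's label — note this is decided by *transmission*, not carrier
  status: with a hom-alt mother and het father, the het child's alt is
  necessarily maternal, because the mother must transmit an alt allele;
* both parents possible sources: `inherited_ambiguous`;
* hom-alt child with consistent parents: `biparental`;
* missing parental genotypes, or no alt in the child: `uninformative`.

The classifier is deterministic on the given genotypes; there is no
quality-based posterior. Genotyping error therefore surfaces as
`mendelian_error`, and those records are diverted to a diagnostics table
rather than flagged — in production workflows such sites are resolved by
orthogonal validation, which is out of scope here. The test suite pins the
classifier to an independently written gamete-enumeration oracle across all
27 autosomal and all X-chromosome genotype combinations for both proband
sexes.

Pseudoautosomal regions are not modelled: all of X is treated as hemizygous
in males. `segregates_with_disease()` treats biparental or ambiguous
transmission as segregating when at least one potentially transmitting
parent is affected; this is an assumption (the behaviour of dominant genes
with two affected parents is genuinely underdetermined) and is confined to
that one function.

## The cascade and its parameters

Filters are a pure conjunction, so order cannot change the flagged set; the
implemented order (frequency → function → panel gene → genotype/requirement
→ inheritance) fixes the reason trails and the short-circuit cost.
`filter_config()` exposes:

| parameter | default | rationale |
|---|---|---|
| `maf_threshold` | 0.01 | rare-disease convention; boundary inclusive (MAF = 1% is kept), and a *missing* frequency is kept — most diagnostic variants are novel |
| `dominant_maf_threshold` | off | optional stricter 0.001 for dominant-acting genes |
| `cnv_loss_min_bp` / `cnv_gain_min_bp` | 100 000 / 250 000 | size rule for de novo or segregating genic CNVs; strict `>`, so a 100 000 bp loss is dropped |
| `cnv_unknown_inheritance_min_bp` | 500 000 | any genic CNV of unclear inheritance |
| `apply_x_missense_exclusion` | TRUE | inherited X missense has low prior probability of causality; exceptions: family history, known-pathogenic database membership |
| `xld_require_segregation` | TRUE | whether X-linked dominant genes follow the same segregation rule as autosomal dominant ones; exposed as configuration because either policy is defensible |
| `benign_missense_score_cutoff` | off | optional PolyPhen-style exclusion of low-scoring *inherited* missense candidates |
| `mode` | trio | `proband_only` ignores parental genotypes entirely |

Two behaviours deserve explicit justification:

* **Dosage entries are CNV-only.** Panel entries whose mechanism is
  `increased_gene_dosage` are matched only by CNV gains (which overlap the
  gene); sequence variants cannot produce a dosage gain, so the SNV/indel
  path skips those entries.
* **Losses require containment, gains require overlap.** A deletion only
  ablates a gene it fully contains; a duplication can perturb dosage of any
  gene it touches.

In trio mode, variants lacking parental genotypes fall back to proband-only
semantics for the inheritance-dependent rules (logged), so partially
genotyped cohorts degrade gracefully instead of erroring.

Compound heterozygotes pair only in *trans*: one maternal and one paternal
member, a de novo member with anything, and unknown-phase members
permissively. Cis pairs (same transmitting parent) never pair. Counting
operations collapse compound-het events to one per gene per proband, and an
event is de novo if any member is.

## Reporting arithmetic

`predictive_value(reviewed, reported)` is the nearest-integer percentage of
reviewed candidates judged likely diagnostic; `diagnostic_yield(d, n)` is
the nearest-integer percentage of the cohort, rendered to one decimal for
classes below 1%. Rounding is half-away-from-zero (base `round()` is
half-even, which does not match clinical tables). The overall yield counts
distinct diagnosed probands, while per-class yields count reported
findings; the difference between reported findings and diagnosed probands
is exactly the number of multi-finding probands, which the summary derives
from the candidate-level table rather than taking as input. With the
bundled reference-cohort counts, two published per-class predictive values
differ by one unit from nearest-integer rounding of their own printed
counts (they appear to have been computed on a post-validation subset); the
package reports the values implied by the counts and makes no attempt to
reproduce those cells.

## The synthetic cohort generator

`simulation_params()` defaults encode the structure of the reference
cohort: a Poisson mean of 400 rare protein-altering variants per proband
with 30 of them in panel genes (panel membership is an independent 30/400
Bernoulli per variant), and 11% / 2% of trios with one / both affected
parents. The remaining rates are the package's own choices, fixed once:
a consequence mix dominated by missense (70%), allele frequencies drawn
uniformly below 1% (30% missing) for the rare component and above 1.1% for
the common component — only the threshold crossing matters to the cascade,
so no site-frequency spectrum is fitted; a de novo rate of 1.5 coding
events per proband (the order observed in exome studies); a 5% per-proband
compound-het rate; two CNV calls per proband with log-uniform lengths
spanning the 100/250/500 kb thresholds. Genes are synthetic identifiers on
synthetic coordinates; the panel has 126 reportable genes across all four
allelic requirements, a handful of multi-mode genes and non-reportable
entries.

Spike-ins insert constructed candidates with known expectations in both
analysis modes (`de_novo_dominant`, `recessive_hom`, `compound_het_trans`,
`compound_het_cis`, `common_control`, `nonfunctional_control`,
`x_inherited_missense`), and `truth_eval()` scores triage output against
them.

What passing these tests shows — and does not show: the generator respects
Mendelian transmission exactly, uses error-free genotypes by default (an
optional error rate exists solely to exercise `mendelian_error` handling),
and draws variants independently. Real cohorts have genotyping error,
linkage, population structure, annotation disagreement and incomplete
penetrance; recovery rates of 100% on synthetic data therefore validate the
*logic* of the cascade, not its clinical sensitivity. Relatedly, the
trio-versus-proband-only flag ratio produced at default parameters (around
an order of magnitude) depends on generator calibration and is a
qualitative, not quantitative, reproduction of published cohorts.

## Numerical and degenerate-input choices

* CNV length is `end − start + 1` (1-based closed intervals); all size
  thresholds are strict.
* Candidate ordering is fully deterministic (proband, chromosome rank,
  position, category, event id), so byte-identical reruns are guaranteed;
  the synthetic generator is likewise byte-identical given its seed.
* Empty inputs are valid everywhere: a zero-trio simulation writes valid
  headers, an empty candidate table summarises to zeros, and a review table
  with no reviewed candidates renders predictive value as missing rather
  than dividing by zero.
* Multi-allelic sites are decomposed one alt per record with per-sample
  dosage conserved; consequence-term spellings are normalised to
  underscores.
* A variant matching several mechanism entries of the same gene and
  requirement is one candidate with the mechanisms aggregated, preventing
  double counting in genes curated with multiple mechanisms.

## Problem sizes used in the test suite

The bundled checks run 200-trio cohorts at default parameters for the
subset/monotonicity properties and a 60-trio cohort for spike-in recovery;
these sizes give stable 0/100% outcomes for the logical properties while
keeping the whole suite under a minute on a laptop. Unit tests use 6–40
trio cohorts with reduced per-proband variant counts.

## Known limitations

* No UPD or mosaicism detection; those findings enter only through the
  review-outcome tables.
* Phase is inferred from parental genotypes only; read-backed phasing is
  not used, so double-het parents leave pairs `inherited_ambiguous` and
  (permissively) paired.
* The panel model fixes two small vocabularies (four allelic requirements,
  six mechanisms); richer published vocabularies must be mapped on load,
  and common aliases ("autosomal dominant"/"autosomal recessive") are
  normalised automatically.
* Indel left-alignment is assumed, not enforced.
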