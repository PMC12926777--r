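---
title: "Qualifying-variant criteria files: model, semantics, and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Qualifying-variant criteria files: model, semantics, and validation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qvtools)
```

## The problem and the model

Variant filtering rules decide what a genomic analysis sees, yet they usually
live as literals inside pipeline code. `qvtools` treats them as data: a
*qualifying variant* (QV) criteria document is a YAML or JSON file with five
components — meta, filters, criteria, notes, and plain-language description
fields — that a pipeline reads at run time. The package's claim is not that a
declarative rule file is novel, but that it can be made **exactly**
equivalent to the hard-coded filtering it replaces, and verifiably so: the
test suite drives the same rules through the engine and through an
independent, hard-coded oracle and requires record-identical output.

A condition is one `field operator value` test. Field expressions map onto
the structure of a VCF record:

* `QUAL` — the site quality;
* `INFO/<key>` — site INFO fields;
* `FORMAT/<key>` — per-sample values (these make the enclosing rule
  *per-sample*);
* a bare name (`CLASS`, `popAF`, ...) — an annotation column of the variant
  table;
* `OVERLAP(<path>)` — how many intervals of a BED file intersect the record's
  reference span.

Operators form a closed set (`==`, `!=`, `>`, `>=`, `<`, `<=`, `in`,
`not_in`); anything else is a validation error that names the set. Conditions
combine into `any_of` / `all_of` groups, nested arbitrarily. Filters wrap one
condition (or group) in `keep_if`/`drop_if` logic; criteria wrap several and
only ever *flag* records.

## Three-valued evaluation and the missing policy

Every condition evaluates to pass, fail, or **missing**. Missing arises when
the resolved value is absent, and — for per-sample conditions — whenever the
sample's genotype is missing, regardless of the tested FORMAT value: a depth
of 40 reads on an uncalled genotype is still an uncalled genotype. Groups
combine outcomes with Kleene-style logic: `all_of` fails if any member fails,
else is missing if any member is missing; `any_of` passes if any member
passes, else is missing if any member is missing.

The policy at the record level is that *missing is never pass*. `keep_if`
therefore drops records (or samples) with missing operands, and `drop_if`
retains them. This is the conservative QC reading; the alternative (treating
missing as pass for `drop_if`-style exclusions) would silently keep
unmeasurable records in inclusion rules, which is the error this format
exists to make visible. Per-sample outcomes aggregate with `all_samples`
(every sample must pass) or `any_sample`; when a rule does not say,
`all_samples` is assumed, the stricter default for family-trio QC.

Two resolution details deserve a note. First, `INFO/DP` resolves through the
computed site depth: the site INFO value when present, otherwise the sum of
per-sample `FORMAT/DP` over samples where depth was recorded. That is the
semantics trio-style site-depth thresholds need, and raw access to every
other INFO key is unaffected. Second, bare names resolve only against
annotation columns; `read_vcf()` promotes a configurable set of INFO keys
(`CLASS`, `GENE`, `popAF`, `known_pathogenic_aa`, `functional_evidence`) to
columns, and header-declared Flag keys promote to logical columns even when
no record carries them.

## Coordinates and degenerate inputs

VCF positions are 1-based inclusive; BED intervals are 0-based half-open. A
record's reference span is `[pos, pos + nchar(ref) - 1]`, so a BED interval
`chr1 100 200` covers 1-based positions 101–200 and a variant at position 100
does **not** overlap it — the test suite pins this convention, and overlap
counting (delegated to `GenomicRanges`) is cross-checked against a per-base
brute-force scan. Multiallelic records are evaluated per VCF line against
their first ALT; splitting multiallelics upstream is recommended but not
enforced. Empty filter lists are identity pipelines; empty BED files yield
zero overlaps; an all-missing genotype matrix has call rate zero, and a QC
step that empties an axis leaves later steps operating on (and returning)
empty sets rather than erroring.

## Canonical form, identifiers, and the registry

Checksums must not depend on serialization accidents, so digests are taken
over a canonical byte form: UTF-8 JSON with keys sorted lexicographically at
every level, filters/criteria as arrays ordered as in the document (order is
semantics: filters compose conjunctively in document order), group sentinels
resolved to nested groups, operators normalized (typographic primes and
internal whitespace stripped, so a printed `'> ='` means `>=`), integer-valued
numbers written as integers, whitespace in free-text fields folded, empty
optional fields dropped, and a single trailing newline. Canonicalization is a
fixed point, and the same logical document parsed from YAML or JSON
canonicalizes to identical bytes — both properties are tested, the latter
against an independently written sorted-key serializer and a second SHA-256
implementation (`openssl`) alongside `digest`.

Identifiers follow `^[a-z0-9_]+_v[0-9]+(\.[0-9]+)*_[0-9]{8}$`, generalizing
the printed examples of the format (a name token, a dotted major version, a
date stamp). The registry is an append-only TSV binding `(qv_set_id,
version)` to a digest; re-registering changed content under a released
version is a conflict. Both canonical and raw-file-bytes digest modes are
exposed because a released artifact may want either; canonical is the
default, since it survives innocent re-serialization while still detecting
every content edit.

## The exact Hardy–Weinberg test

`hwe_exact_p()` implements the standard exact test: conditional on the
observed allele counts, the heterozygote count has a known distribution, and
the p-value is the total probability of all configurations no more probable
than the observed one. The distribution is computed with the ratio recurrence
anchored at its mode and normalized — no factorials are formed, so the
computation is stable for any realistic cohort — and p-values are accumulated
by ascending-order summation. Ties are included with a relative tolerance of
`1e-9`: the mirror-image configuration of the observed one has *exactly* the
same probability in exact arithmetic but not always in floating point, and
without a tolerance the inclusion set would flicker. The recurrence groups
the homozygote-count product so results are bit-identical under allele
relabeling. The independent oracle used in tests evaluates each
configuration's weight directly from log-factorials (`lgamma`) and agrees
with the recursion to within 1e-12 relative error over every configuration
with up to 200 genotypes; for large balanced counts the exact p-value also
approaches the one-degree-of-freedom chi-square approximation.

GWAS QC applies its four thresholds in a fixed order — sample call rate,
then variant call rate, minor allele frequency, and HWE — with variant
statistics recomputed after sample removal. The order of the two axes is not
derivable from first principles; the listing order of the thresholds is
adopted and documented, and re-running QC on its own output removes nothing.

## ACMG-style criteria

PS1 (known pathogenic amino-acid change), PS3 (functional evidence), and PM2
(population frequency below `1e-4` by default) are ordinary annotation-driven
criteria evaluated through the engine; their annotation sources are
column-driven and configurable, since upstream annotation tooling varies.
PS5 (compound heterozygosity) is the one relational computation: for each
sample and gene, every unordered pair of loci at which the sample is
heterozygous, with PM3 flagged when a partner is classified P/LP. Phase is
generally unavailable, so unphased pairs are assumed *in trans* — the
standard screening assumption — with `require_phase = TRUE` restricting to
phased opposite-haplotype pairs when parental phasing exists. PS2 and PS4
are recognized names that report *not applicable* (`NA` flags) rather than
silently false. No ACMG combining rules are applied: the package emits flags
and a per-variant criterion count for ranking, nothing more.

## What the simulators emulate — and what they do not

`sim_cohort()` generates the study conditions the validation needs: genes
laid out on five chromosomes with a panel covering half of them (so panel
restriction has real positives and negatives), allele frequencies drawn from
a rare-skewed Beta(0.7, 3), genotypes in Hardy–Weinberg proportions except a
planted 1% of all-heterozygous loci, Poisson depth around 30×, a 90/10
high/low genotype-quality mixture, 2% genotype missingness, site QUAL from a
Gamma with occasional missing values, `INFO/DP` present for only 80% of sites
(exercising the computed-depth fallback), and class annotations with
realistic rarity (P 1%, LP 2%, VUS 27%, LB 30%, B 40%) coupled to lower
population frequencies and enriched evidence annotations for P/LP variants.
`sim_trio()` adds Mendelian transmission and a pedigree. Everything generated
is recorded in the returned table, so every expected outcome in the tests is
computed from that truth table — never from the engine under test — and all
generators are seed-deterministic down to the written VCF bytes without
disturbing the session RNG.

What passing tests therefore show is that the engine applies declared rules
*exactly* — identically to an independent implementation — on data whose
marginal distributions resemble sequencing cohorts. The simulators do not
model linkage disequilibrium, population structure, batch effects,
multiallelic sites, or genotyping-error correlation with depth, so the tests
say nothing about whether any particular threshold is *wise* on real data —
only that it is applied faithfully. That is the correct scope: the format
externalizes criteria, it does not choose them.

## Validation design and problem sizes

The equivalence experiment runs 210 seeded scenarios — 80 cohort
panel-plus-quality scenarios (15 samples × 150 variants), 70 trio
QUAL/DP/GQ scenarios (120 variants, alternating both sample aggregations),
and 60 GWAS QC chains (30 samples × 200 variants) — each compared
record-for-record against a clean-room oracle written as plain loops in a
separate module that shares no evaluation code with the engine. The
acceptance script scales the cohort design up to 50 samples × 2000 variants.
These sizes give every scenario non-trivial attrition at each rule while
keeping the whole suite fast enough to run on every change; the equivalence
property being exact, larger sizes add runtime but no information.

## Known limitations

* Biallelic orientation: `gt_matrix()` and the QC chain require biallelic
  genotypes; multiallelic handling is first-ALT per line.
* The registry is a local file format, deliberately: governance of a shared
  community registry (who assigns identifiers) is outside an artifact.
* Criteria are labels; reproducing a pipeline step that *removes*
  non-flagged records is done explicitly with a second filter over the flag
  (`filter_flagged()`), keeping the remove/label distinction visible.
* The statement builder maps flat `path=value` text to documents with
  documented override/append semantics (numeric segments address list
  elements; `notes`, `meta.authors`, `meta.tags` append); it does not model
  any interactive UI behavior beyond that mapping.
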