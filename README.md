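# qvtools

Variant filtering rules are usually buried inside pipeline code: a QUAL
threshold here, a panel BED there, an allele-frequency cutoff hard-coded in a
script nobody versioned. `qvtools` implements the *qualifying variant* (QV)
criteria file — a portable, versioned, checksummed YAML/JSON document that
externalizes those rules — together with the machinery to apply a QV file to
VCF data and to demonstrate that QV-driven filtering is record-identical to
the hard-coded filtering it replaces.

It is written for people who build and audit genomic analysis pipelines:
rare-disease and GWAS analysts who need their filtering criteria to be
shareable and reviewable, and clinical bioinformaticians who need to prove,
months later, exactly which thresholds produced a report.

## The model

A QV document has five logical components:

1. **meta** — `qv_set_id` (pattern `<name>_v<major>_<YYYYMMDD>`), `title`,
   semantic `version`, plus optional authors, date, tags, and free-text
   `description_patient` / `description_ppie` fields that never touch the
   computation;
2. **filters** — rules with `keep_if`/`drop_if` logic over one condition or a
   compound `any_of`/`all_of` group;
3. **criteria** — compound blocks (e.g. ACMG-style evidence codes) that *flag*
   variants without removing them;
4. **notes** — free-text caveats;
5. **descriptions** — the plain-language fields above.

Each condition is a `field operator value` triple. Fields resolve against the
VCF namespaces `QUAL`, `INFO/<key>`, `FORMAT/<key>` (per sample), bare
annotation columns such as `CLASS`, and `OVERLAP(<bed>)`, the number of panel
intervals intersecting the record's reference span. Evaluation is
three-valued — pass / fail / **missing** — and missing is never pass: a
per-sample condition on a missing genotype is missing, `keep_if` drops on
missing, `drop_if` retains. Per-sample conditions aggregate across samples
with `all_samples` or `any_sample`. `INFO/DP` falls back to the computed site
depth (the sum of per-sample `FORMAT/DP`) when the site field is absent.

Cohort QC adds the derived statistics `SAMPLE_CALL_RATE`, `VARIANT_CALL_RATE`,
`MAF`, and `HWE_P` (an exact Hardy–Weinberg test: the total conditional
probability, given allele counts, of all heterozygote configurations no more
probable than the observed one). Releases are bound to a SHA-256 digest over
a canonical byte form (sorted-key JSON), so re-serializing YAML to JSON or
reordering keys never changes a document's checksum — editing a threshold
always does.

## A worked example

```r
library(qvtools)

sim <- sim_cohort(n_samples = 20, n_variants = 500, seed = 42)
doc <- read_qv(system.file("extdata", "qv_disease_panel_example.yaml",
                           package = "qvtools"))
res <- apply_qv(doc, sim$variants,
  regions = list(`targets.disease_panel.bed` = region_index(sim$panel)))
res
#> <qv_result> qv_disease_panel_v1_20250828
#>   records: 500 in, 173 kept
#>   rules:
#>     region_include       keep_if: 500 -> 173 (dropped 327, of which 0 via missing)
#>   criterion flags:  pathogenic=4
```

The document's one filter kept the 173 records overlapping the panel BED and
dropped the 327 outside it (none via missing operands); its one criterion
flagged 4 of the survivors as class P/LP without removing anything.
`tidy(res)` returns that per-rule table as a tibble, `glance(res)` a one-row
summary, and `autoplot(res)` the attrition bar chart. The same document is
checksummable and registrable:

```r
qv_checksum(doc)
#> [1] "abb396eacb113c3fbd62883d0153ec5790bc11784a1d7558e879e5fbd40adfad"
```

GWAS-style QC runs from the same kind of document:

```r
qc <- apply_gwas_qc(qv_gwas_doc(), gt_matrix(sim$variants))
tidy(qc)
#> # A tibble: 4 × 8
#>   step              axis    field             operator threshold n_before n_removed n_after
#> 1 sample_call_rate  sample  SAMPLE_CALL_RATE  >=        0.95           20         0      20
#> 2 variant_call_rate variant VARIANT_CALL_RATE >=        0.95          500        27     473
#> 3 maf               variant MAF               >=        0.01          473        66     407
#> 4 hwe               variant HWE_P             >=        0.000001      407         0     407
```

A command-line wrapper ships in `inst/exec/qv` with verbs `validate`,
`build`, `apply`, `qc`, `checksum`, `register`, `verify`, and `simulate`
(exit codes: 0 ok, 1 validation/verification failure, 2 usage, 3 data error).
Applied output VCFs carry criterion flags as `QV_<name>` INFO fields and a
`##QV_SET_ID` header line, and contain no timestamps, so repeated runs are
byte-identical and checksum-comparable.

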