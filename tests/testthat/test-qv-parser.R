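# Parsing, serialization, and the key=value statement builder.

test_that("the printed disease-panel document parses to its five components", {
  doc <- read_qv(box1_path())
  expect_identical(doc$meta$qv_set_id, "qv_disease_panel_v1_20250828")
  expect_identical(doc$meta$version, "1.0.0")
  expect_match(doc$meta$description_patient, "family history")
  expect_match(doc$meta$description_ppie, "PPIE")

  expect_length(doc$filters, 1)
  f <- doc$filters[[1]]
  expect_identical(f$name, "region_include")
  expect_identical(f$logic, "keep_if")
  expect_identical(f$condition$field, "OVERLAP(targets.disease_panel.bed)")
  expect_identical(f$condition$operator, ">=")
  expect_equal(f$condition$value, 1)

  expect_length(doc$criteria, 1)
  cr <- doc$criteria[[1]]
  expect_identical(cr$name, "pathogenic")
  expect_identical(cr$logic, "and")
  expect_length(cr$conditions, 1)
  grp <- cr$conditions[[1]]
  expect_s3_class(grp, "qv_group")
  expect_identical(grp$mode, "any_of")
  expect_identical(
    vapply(grp$members, function(m) paste(m$field, m$operator, m$value), ""),
    c("CLASS == P", "CLASS == LP")
  )
  expect_length(doc$notes, 2)
})

test_that("degenerate and sentinel-broken inputs are handled", {
  doc <- parse_qv("{}", "json")
  expect_false(qv_is_valid(validate_qv(doc)))
  expect_true(any(validate_qv(doc)$path == "meta"))

  expect_error(
    parse_qv("
meta: {qv_set_id: qv_x_v1_20200101, title: t, version: 1.0.0}
criteria:
  c:
    conditions:
      - group: 'any_of: start'
      - {field: CLASS, operator: '==', value: P}
"),
    "unclosed"
  )
  expect_error(
    parse_qv("
criteria:
  c:
    conditions:
      - {field: CLASS, operator: '==', value: P}
      - group: 'any_of: end'
"),
    "unmatched"
  )
})

test_that("serialize/parse round trips are identities under canonical form", {
  doc <- read_qv(box1_path())
  for (fmt in c("yaml", "json")) {
    back <- parse_qv(serialize_qv(doc, fmt), fmt)
    expect_identical(canonicalize_qv(back), canonicalize_qv(doc))
  }
  # all five components survive re-emission
  back <- parse_qv(serialize_qv(doc, "yaml"))
  expect_identical(back$meta$qv_set_id, doc$meta$qv_set_id)
  expect_length(back$filters, 1)
  expect_length(back$criteria, 1)
  expect_identical(back$notes, doc$notes)
  expect_identical(back$meta$description_ppie, doc$meta$description_ppie)
})

test_that("statements fold into a document with typing and overrides", {
  doc <- build_from_statements(c(
    "# a comment",
    "meta.qv_set_id=qv_x_v1_20250101",
    "meta.version=1.0.0",
    "meta.title=T",
    "",
    "filters.f1.logic=keep_if",
    "filters.f1.field=QUAL",
    "filters.f1.operator=>=",
    "filters.f1.value=30"
  ))
  expect_true(qv_is_valid(validate_qv(doc)))
  expect_length(doc$filters, 1)
  f <- doc$filters[[1]]
  expect_identical(f$condition$field, "QUAL")
  expect_identical(f$condition$operator, ">=")
  expect_identical(f$condition$value, 30L)

  # typed scalars: integer, float, booleans, quoting forces string
  doc2 <- build_from_statements(c(
    "meta.qv_set_id=qv_x_v1_20250101", "meta.version=1.0.0", "meta.title=T",
    "filters.a.logic=keep_if", "filters.a.field=popAF",
    "filters.a.operator=<", "filters.a.value=1e-4",
    "filters.b.logic=keep_if", "filters.b.field=known_pathogenic_aa",
    "filters.b.operator===", "filters.b.value=true",
    "filters.c.logic=keep_if", "filters.c.field=CLASS",
    "filters.c.operator===", "filters.c.value='30'"
  ))
  expect_identical(doc2$filters[[1]]$condition$value, 1e-4)
  expect_identical(doc2$filters[[2]]$condition$value, TRUE)
  expect_identical(doc2$filters[[3]]$condition$value, "30")

  # later statements override scalars; list paths append
  doc3 <- build_from_statements(c(
    "meta.qv_set_id=qv_x_v1_20250101", "meta.version=1.0.0",
    "meta.title=first", "meta.title=second",
    "notes=one", "notes=two"
  ))
  expect_identical(doc3$meta$title, "second")
  expect_identical(doc3$notes, c("one", "two"))
})

test_that("statements reconstruct the printed document byte-for-byte canonically", {
  stmts <- c(
    "meta.qv_set_id=qv_disease_panel_v1_20250828",
    "meta.version=1.0.0",
    "meta.title=Disease panel filter",
    "meta.description_patient=We have a strong family history of early heart attacks.",
    "meta.description_ppie=The PPIE group reviewed the criteria and approved them on 2025-08-15.",
    "filters.region_include.description=Restrict to curated disease gene panel",
    "filters.region_include.logic=keep_if",
    "filters.region_include.field=OVERLAP(targets.disease_panel.bed)",
    "filters.region_include.operator=>=",
    "filters.region_include.value=1",
    "criteria.pathogenic.description=Variant classified as pathogenic or likely pathogenic",
    "criteria.pathogenic.logic=and",
    "criteria.pathogenic.conditions.1.any_of.1.field=CLASS",
    "criteria.pathogenic.conditions.1.any_of.1.operator===",
    "criteria.pathogenic.conditions.1.any_of.1.value=P",
    "criteria.pathogenic.conditions.1.any_of.2.field=CLASS",
    "criteria.pathogenic.conditions.1.any_of.2.operator===",
    "criteria.pathogenic.conditions.1.any_of.2.value=LP",
    "notes=Gene panel file defines the target regions.",
    "notes=Additional quality filters may be added as needed."
  )
  built <- build_from_statements(stmts)
  expect_identical(
    canonicalize_qv(built),
    canonicalize_qv(read_qv(box1_path()))
  )
})

test_that("type conflicts in statement paths are build errors naming the path", {
  expect_error(
    build_from_statements(c("a.b=1", "a.b.c=2")),
    '"a.b"'
  )
  expect_error(
    build_from_statements(c("a.b.c=2", "a.b=1")),
    '"a.b"'
  )
})
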