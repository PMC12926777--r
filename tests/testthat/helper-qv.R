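# Shared fixtures and independent mini-oracles for the test suite.

`%||%` <- function(a, b) if (is.null(a)) b else a

box1_path <- function() {
  system.file("extdata", "qv_disease_panel_example.yaml", package = "qvtools")
}

minimal_meta <- function(id = "qv_test_v1_20250101") {
  list(qv_set_id = id, title = "test", version = "1.0.0")
}

# One-record variant table built by hand.
make_rec <- function(chrom = "chr1", pos = 100L, ref = "A", alt = "T",
                     qual = 50, info = list(), gt = NULL, dp = NULL, gq = NULL,
                     ...) {
  n <- max(length(gt), length(dp), length(gq))
  samples <- if (n > 0) {
    tibble::tibble(
      sample = sprintf("S%d", seq_len(n)),
      GT = if (is.null(gt)) rep("0/1", n) else gt,
      DP = if (is.null(dp)) rep(NA_real_, n) else as.numeric(dp),
      GQ = if (is.null(gq)) rep(NA_real_, n) else as.numeric(gq)
    )
  } else {
    tibble::tibble(sample = character())
  }
  tibble::tibble(
    chrom = chrom, pos = as.integer(pos), id = NA_character_,
    ref = ref, alt = alt, qual = as.numeric(qual), filter = NA_character_,
    info = list(info), samples = list(samples), ...
  )
}

# Independent three-valued logic oracle: Kleene semantics with
# fail = 0, missing = 1/2, pass = 1; conjunction = min, disjunction = max.
kleene_combine <- function(mode, states) {
  num <- c(fail = 0, missing = 0.5, pass = 1)[states]
  v <- if (mode == "all_of") min(num) else max(num)
  c("fail", "missing", "pass")[match(v, c(0, 0.5, 1))]
}

# Record + conditions realizing an arbitrary vector of member states:
# column s<i> holds 1 (pass), 0 (fail) or NA (missing) tested with s<i> == 1.
state_fixture <- function(states) {
  vals <- lapply(states, function(s) switch(s,
    pass = 1,
    fail = 0,
    missing = NA_real_
  ))
  names(vals) <- paste0("s", seq_along(states))
  rec <- do.call(make_rec, vals)
  conds <- lapply(names(vals), function(nm) qv_condition(nm, "==", 1))
  list(rec = rec, conds = conds)
}

# Independent sorted-key JSON serializer (kept deliberately separate from
# canonicalize_qv) for canonical-form cross-checks.
indep_json <- function(x) {
  if (is.list(x)) {
    nm <- names(x)
    if (!is.null(nm) && all(nzchar(nm))) {
      x <- x[order(nm)]
      inner <- vapply(seq_along(x), function(i) {
        paste0('"', names(x)[i], '":', indep_json(x[[i]]))
      }, "")
      return(paste0("{", paste(inner, collapse = ","), "}"))
    }
    return(paste0("[", paste(vapply(x, indep_json, ""), collapse = ","), "]"))
  }
  if (is.character(x)) {
    return(paste0('"', gsub('"', '\\\\"', x), '"'))
  }
  if (is.logical(x)) {
    return(tolower(as.character(x)))
  }
  as.character(x)
}

read_file_bytes <- function(path) readBin(path, "raw", file.size(path))

# Second hashing library as the digest oracle; normalized to a plain string.
indep_sha256 <- function(bytes) {
  paste(unclass(as.character(openssl::sha256(bytes))), collapse = "")
}
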