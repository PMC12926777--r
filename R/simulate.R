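# Seeded synthetic fixtures: annotated cohort VCFs with a gene panel, and
# family trios with pedigree. Every generated value is recorded in the
# returned table (the truth table), so expected filter outcomes can be
# computed independently of the engine.

with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(code)
}

base_other <- function(b) {
  vapply(b, function(x) sample(setdiff(c("A", "C", "G", "T"), x), 1), "",
    USE.NAMES = FALSE
  )
}

sim_genes <- function(n_genes, panel_frac, gene_size, gap, n_chrom) {
  g <- seq_len(n_genes)
  slot <- (g - 1) %/% n_chrom
  tibble::tibble(
    gene = sprintf("GENE%03d", g),
    chrom = paste0("chr", (g - 1) %% n_chrom + 1),
    start = as.integer(1e6 + slot * (gene_size + gap)),
    end = as.integer(1e6 + slot * (gene_size + gap) + gene_size),
    in_panel = g %in% sample(n_genes, round(panel_frac * n_genes))
  )
}

#' Simulate an annotated cohort VCF with a gene panel
#'
#' Generates a deterministic (seeded) cohort of biallelic SNV/indel records
#' laid out across gene intervals and intergenic space. Genotypes are drawn
#' under Hardy-Weinberg proportions at a Beta-distributed allele frequency,
#' except at a planted fraction of out-of-equilibrium loci (all-heterozygous).
#' Per-sample depth is Poisson, genotype quality is a high/low mixture,
#' genotypes go missing at `missing_rate`, site `INFO/DP` is present only with
#' probability `info_dp_rate` (exercising the computed-site-depth fallback),
#' and each record carries pathogenicity-class (`CLASS` in P/LP/VUS/LB/B),
#' `GENE`, population-frequency and evidence annotations. The returned table
#' is both engine-ready and the truth table: it records every generated value,
#' including `in_panel`, `p_alt`, and `hwe_outlier`.
#'
#' @param n_samples,n_variants Cohort dimensions.
#' @param seed Integer seed; the same seed reproduces the output exactly.
#' @param n_genes,panel_frac,gene_size,gap,n_chrom Gene/panel layout.
#' @param intergenic_frac Fraction of variants placed outside any gene.
#' @param missing_rate Per-genotype missingness probability.
#' @param mean_depth Mean per-sample read depth (Poisson).
#' @param low_gq_rate Probability a genotype gets a low-quality GQ draw.
#' @param qual_missing_rate Probability the site QUAL is missing.
#' @param info_dp_rate Probability the site carries `INFO/DP`.
#' @param class_probs Named probabilities over classes P, LP, VUS, LB, B.
#' @param af_shape Beta shape parameters of the alternate allele frequency.
#' @param hwe_outlier_rate Fraction of loci planted out of Hardy-Weinberg.
#' @return A `qv_sim_cohort`: list with `variants` (variant/truth table),
#'   `genes`, `panel` (BED-style tibble of panel gene intervals), `samples`,
#'   and `params`.
#' @examples
#' sim <- sim_cohort(n_samples = 5, n_variants = 50, seed = 1)
#' dplyr::count(sim$variants, CLASS)
#' @export
sim_cohort <- function(n_samples = 50, n_variants = 2000, seed = 1,
                       n_genes = 40, panel_frac = 0.5, gene_size = 10000L,
                       gap = 5000L, n_chrom = 5, intergenic_frac = 0.3,
                       missing_rate = 0.02, mean_depth = 30,
                       low_gq_rate = 0.1, qual_missing_rate = 0.01,
                       info_dp_rate = 0.8,
                       class_probs = c(P = 0.01, LP = 0.02, VUS = 0.27, LB = 0.30, B = 0.40),
                       af_shape = c(0.7, 3), hwe_outlier_rate = 0.01) {
  stopifnot(n_samples >= 1, n_variants >= 1)
  class_probs <- class_probs / sum(class_probs)
  if (any(class_probs < 0)) stop("class_probs must be non-negative", call. = FALSE)
  with_seed(seed, {
    genes <- sim_genes(n_genes, panel_frac, gene_size, gap, n_chrom)
    samples <- sprintf("S%03d", seq_len(n_samples))

    intergenic <- stats::runif(n_variants) < intergenic_frac
    gene_idx <- sample(n_genes, n_variants, replace = TRUE)
    pos <- integer(n_variants)
    chrom <- character(n_variants)
    genic <- !intergenic
    pos[genic] <- genes$start[gene_idx[genic]] +
      sample(gene_size, sum(genic), replace = TRUE)
    pos[intergenic] <- genes$end[gene_idx[intergenic]] +
      sample(gap, sum(intergenic), replace = TRUE)
    chrom <- genes$chrom[gene_idx]
    # de-duplicate colliding sites
    for (iter in 1:20) {
      dup <- duplicated(paste(chrom, pos))
      if (!any(dup)) break
      shift <- ifelse(genic[dup], sample(gene_size, sum(dup), replace = TRUE),
        sample(gap, sum(dup), replace = TRUE)
      )
      pos[dup] <- ifelse(genic[dup], genes$start[gene_idx[dup]],
        genes$end[gene_idx[dup]]
      ) + shift
    }

    ref1 <- sample(c("A", "C", "G", "T"), n_variants, replace = TRUE)
    del_len <- ifelse(stats::runif(n_variants) < 0.05,
      sample(2:5, n_variants, replace = TRUE), 1L
    )
    ref <- vapply(seq_len(n_variants), function(i) {
      paste(c(ref1[i], sample(c("A", "C", "G", "T"), del_len[i] - 1, replace = TRUE)),
        collapse = ""
      )
    }, "")
    alt <- base_other(ref1)

    p_alt <- pmin(0.5, pmax(0.005, stats::rbeta(n_variants, af_shape[1], af_shape[2])))
    hwe_outlier <- stats::runif(n_variants) < hwe_outlier_rate
    dosage <- matrix(stats::rbinom(n_variants * n_samples, 2, rep(p_alt, n_samples)),
      nrow = n_variants
    )
    dosage[hwe_outlier, ] <- 1L # planted heterozygote excess

    gt <- matrix(c("0/0", "0/1", "1/1")[dosage + 1L], nrow = n_variants)
    gt[matrix(stats::runif(n_variants * n_samples) < missing_rate,
      nrow = n_variants
    )] <- NA_character_
    dp <- matrix(stats::rpois(n_variants * n_samples, mean_depth), nrow = n_variants)
    gq_hi <- matrix(pmin(99L, stats::rpois(n_variants * n_samples, 60)),
      nrow = n_variants
    )
    gq_lo <- matrix(stats::rpois(n_variants * n_samples, 8), nrow = n_variants)
    low <- matrix(stats::runif(n_variants * n_samples) < low_gq_rate,
      nrow = n_variants
    )
    gq <- ifelse(low, gq_lo, gq_hi)
    dp[matrix(stats::runif(n_variants * n_samples) < 0.01, nrow = n_variants)] <- NA
    gq[matrix(stats::runif(n_variants * n_samples) < 0.01, nrow = n_variants)] <- NA

    qual <- round(stats::rgamma(n_variants, shape = 4, scale = 15), 1)
    qual[stats::runif(n_variants) < qual_missing_rate] <- NA

    info_dp_present <- stats::runif(n_variants) < info_dp_rate
    site_dp <- rowSums(dp, na.rm = TRUE)
    info_dp <- ifelse(info_dp_present,
      pmax(1L, round(site_dp * stats::runif(n_variants, 0.9, 1.1))), NA
    )

    class <- sample(names(class_probs), n_variants, replace = TRUE, prob = class_probs)
    gene <- ifelse(intergenic, NA_character_, genes$gene[gene_idx])
    pathogenic <- class %in% c("P", "LP")
    pop_af <- pmin(0.5, pmax(
      1e-6,
      p_alt * exp(stats::rnorm(n_variants, 0, 0.5)) * ifelse(pathogenic, 0.01, 1)
    ))
    known_aa <- stats::runif(n_variants) < ifelse(pathogenic, 0.5, 0.01)
    func_ev <- stats::runif(n_variants) < ifelse(pathogenic, 0.3, 0.02)

    samples_col <- lapply(seq_len(n_variants), function(i) {
      tibble::tibble(sample = samples, GT = gt[i, ], DP = as.numeric(dp[i, ]),
        GQ = as.numeric(gq[i, ]))
    })
    info_col <- lapply(seq_len(n_variants), function(i) {
      if (is.na(info_dp[i])) list() else list(DP = as.numeric(info_dp[i]))
    })

    variants <- tibble::tibble(
      chrom = chrom, pos = pos, id = sprintf("var%05d", seq_len(n_variants)),
      ref = ref, alt = alt, qual = qual, filter = NA_character_,
      info = info_col, samples = samples_col,
      CLASS = class, GENE = gene, popAF = pop_af,
      known_pathogenic_aa = known_aa, functional_evidence = func_ev,
      in_panel = !is.na(gene) & gene %in% genes$gene[genes$in_panel],
      p_alt = p_alt, hwe_outlier = hwe_outlier
    )
    variants <- variants[order(variants$chrom, variants$pos), ]

    panel <- genes[genes$in_panel, c("chrom", "start", "end", "gene")]
    names(panel)[4] <- "name"
    structure(
      list(
        variants = variants, genes = genes, panel = panel, samples = samples,
        params = list(
          n_samples = n_samples, n_variants = n_variants, seed = seed,
          missing_rate = missing_rate, mean_depth = mean_depth,
          class_probs = class_probs, hwe_outlier_rate = hwe_outlier_rate
        )
      ),
      class = "qv_sim_cohort"
    )
  })
}

#' Simulate a sequenced family trio with pedigree
#'
#' Three samples (FATHER, MOTHER, PROBAND) with Mendelian transmission:
#' parental genotypes are drawn under Hardy-Weinberg at a uniform allele
#' frequency and the child inherits one allele from each parent. Depth,
#' genotype quality, missingness and site QUAL/INFO-DP are generated as in
#' [sim_cohort()]; low-GQ and missing genotypes are planted so that
#' all-samples versus any-sample aggregation give different outcomes at
#' predictable loci.
#'
#' @param n_variants Number of records.
#' @param seed Integer seed.
#' @param missing_rate,mean_depth,low_gq_rate,qual_missing_rate,info_dp_rate
#'   As in [sim_cohort()].
#' @return A `qv_sim_trio`: list with `variants` (truth table), `ped`
#'   (pedigree tibble: `fam`, `id`, `father`, `mother`, `sex`, `phenotype`),
#'   `samples`, `params`.
#' @export
sim_trio <- function(n_variants = 400, seed = 1, missing_rate = 0.03,
                     mean_depth = 30, low_gq_rate = 0.15,
                     qual_missing_rate = 0.02, info_dp_rate = 0.7) {
  stopifnot(n_variants >= 1)
  with_seed(seed, {
    samples <- c("FATHER", "MOTHER", "PROBAND")
    chrom <- paste0("chr", sample(1:22, n_variants, replace = TRUE))
    pos <- sample(1e6:5e7, n_variants)
    ref <- sample(c("A", "C", "G", "T"), n_variants, replace = TRUE)
    alt <- base_other(ref)
    p <- stats::runif(n_variants, 0.05, 0.5)
    dad <- stats::rbinom(n_variants, 2, p)
    mom <- stats::rbinom(n_variants, 2, p)
    kid <- stats::rbinom(n_variants, 1, dad / 2) + stats::rbinom(n_variants, 1, mom / 2)
    dosage <- cbind(FATHER = dad, MOTHER = mom, PROBAND = kid)
    gt <- matrix(c("0/0", "0/1", "1/1")[dosage + 1L], ncol = 3)
    gt[matrix(stats::runif(n_variants * 3) < missing_rate, ncol = 3)] <- NA_character_
    dp <- matrix(stats::rpois(n_variants * 3, mean_depth), ncol = 3)
    low <- matrix(stats::runif(n_variants * 3) < low_gq_rate, ncol = 3)
    gq <- ifelse(low, stats::rpois(n_variants * 3, 8),
      pmin(99L, stats::rpois(n_variants * 3, 60))
    )
    qual <- round(stats::rgamma(n_variants, shape = 4, scale = 15), 1)
    qual[stats::runif(n_variants) < qual_missing_rate] <- NA
    info_dp_present <- stats::runif(n_variants) < info_dp_rate
    info_dp <- ifelse(info_dp_present,
      pmax(1L, round(rowSums(dp) * stats::runif(n_variants, 0.9, 1.1))), NA
    )
    samples_col <- lapply(seq_len(n_variants), function(i) {
      tibble::tibble(sample = samples, GT = gt[i, ], DP = as.numeric(dp[i, ]),
        GQ = as.numeric(gq[i, ]))
    })
    info_col <- lapply(seq_len(n_variants), function(i) {
      if (is.na(info_dp[i])) list() else list(DP = as.numeric(info_dp[i]))
    })
    variants <- tibble::tibble(
      chrom = chrom, pos = pos, id = sprintf("tri%05d", seq_len(n_variants)),
      ref = ref, alt = alt, qual = qual, filter = NA_character_,
      info = info_col, samples = samples_col, p_alt = p
    )
    variants <- variants[order(variants$chrom, variants$pos), ]
    ped <- tibble::tibble(
      fam = "FAM1",
      id = samples,
      father = c("0", "0", "FATHER"),
      mother = c("0", "0", "MOTHER"),
      sex = c(1L, 2L, 1L),
      phenotype = c(1L, 1L, 2L)
    )
    structure(
      list(
        variants = variants, ped = ped, samples = samples,
        params = list(
          n_variants = n_variants, seed = seed, missing_rate = missing_rate,
          mean_depth = mean_depth, low_gq_rate = low_gq_rate
        )
      ),
      class = "qv_sim_trio"
    )
  })
}

#' Write a pedigree tibble as a PED file
#'
#' @param ped Tibble with columns `fam`, `id`, `father`, `mother`, `sex`,
#'   `phenotype`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ped <- function(ped, path) {
  lines <- do.call(paste, c(
    unname(as.list(ped[c("fam", "id", "father", "mother", "sex", "phenotype")])),
    sep = "\t"
  ))
  writeLines(lines, path)
  invisible(path)
}

#' @export
print.qv_sim_cohort <- function(x, ...) {
  cat("<qv_sim_cohort> ", nrow(x$variants), " variants x ",
    length(x$samples), " samples (seed ", x$params$seed, ")\n",
    sep = ""
  )
  invisible(x)
}

#' @export
print.qv_sim_trio <- function(x, ...) {
  cat("<qv_sim_trio> ", nrow(x$variants), " variants (seed ",
    x$params$seed, ")\n",
    sep = ""
  )
  invisible(x)
}
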