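# Genome sizes (Telomere-to-Telomere consortium): standard, female, male
GENOME_SIZE_STD <- 3031865587
GENOME_SIZE_F <- 3054815472
GENOME_SIZE_M <- 3008915703

#' Mitochondrial fold coverage from read counts
#'
#' chrM coverage = mapped chrM reads x read length / chrM length.
#'
#' @param stats a `mito_covstats` (or anything with `chrm_reads` and
#'   `read_len`).
#' @param L mitochondrial genome length.
#' @export
chrm_coverage <- function(stats, L = 16569L) {
  if (stats$chrm_reads == 0) return(0)
  if (is.na(stats$read_len) || stats$read_len <= 0)
    stop("read length must be positive")
  stats$chrm_reads * stats$read_len / L
}

#' Nuclear genome fold coverage under three conventions
#'
#' `metadata` passes through an externally supplied coverage; `recomputed`
#' divides total mapped bases by the standard genome size (3,031,865,587);
#' `sex_adjusted` divides by the female (3,054,815,472) or male
#' (3,008,915,703) genome size.
#'
#' @param stats a `mito_covstats`.
#' @param method one of "metadata", "recomputed", "sex_adjusted".
#' @export
genome_coverage <- function(stats, method = c("recomputed", "metadata",
                                              "sex_adjusted")) {
  method <- match.arg(method)
  switch(method,
    metadata = {
      if (is.null(stats$metadata_cov)) stop("no metadata coverage supplied")
      stats$metadata_cov
    },
    recomputed = stats$total_mapped_bases / GENOME_SIZE_STD,
    sex_adjusted = {
      if (is.na(stats$sex) || !stats$sex %in% c("F", "M"))
        stop("sex-adjusted coverage requires sex 'F' or 'M'")
      stats$total_mapped_bases /
        if (stats$sex == "F") GENOME_SIZE_F else GENOME_SIZE_M
    })
}

#' Mitochondrial DNA copy number
#'
#' CN = 2 x chrM coverage / genome coverage. Samples with CN below 100 are
#' flagged: at low copy number NUMT-derived reads make up a larger share of
#' apparent mitochondrial coverage and can yield false heteroplasmies.
#'
#' @param chrm_cov mitochondrial fold coverage.
#' @param genome_cov nuclear genome fold coverage.
#' @param low_cn_cutoff flagging threshold.
#' @return numeric CN with attribute `low_cn_flag`.
#' @export
compute_cn <- function(chrm_cov, genome_cov, low_cn_cutoff = 100) {
  if (any(genome_cov <= 0)) stop("genome coverage must be positive")
  cn <- 2 * chrm_cov / genome_cov
  attr(cn, "low_cn_flag") <- cn < low_cn_cutoff
  cn
}

#' Copy-number metrics under all applicable methods
#'
#' @param stats a `mito_covstats`.
#' @param L mitochondrial genome length.
#' @return one-row data.frame with chrm_cov, the three genome coverages,
#'   the three CN values and `low_cn_flag` (based on the recomputed CN, or
#'   the metadata CN if bases are unavailable).
#' @export
cn_metrics <- function(stats, L = 16569L) {
  cc <- chrm_coverage(stats, L)
  g_meta <- if (!is.null(stats$metadata_cov)) stats$metadata_cov else NA_real_
  g_rec <- if (!is.na(stats$total_mapped_bases))
    genome_coverage(stats, "recomputed") else NA_real_
  g_sex <- if (!is.na(stats$sex) && stats$sex %in% c("F", "M") &&
               !is.na(stats$total_mapped_bases))
    genome_coverage(stats, "sex_adjusted") else NA_real_
  cn_of <- function(g) if (is.na(g)) NA_real_ else as.numeric(compute_cn(cc, g))
  cn_rec <- cn_of(g_rec)
  primary <- if (!is.na(cn_rec)) cn_rec else cn_of(g_meta)
  data.frame(chrm_reads = stats$chrm_reads, chrm_cov = cc,
             genome_cov_metadata = g_meta, genome_cov_recomputed = g_rec,
             genome_cov_sex = g_sex, cn_metadata = cn_of(g_meta),
             cn_recomputed = cn_rec, cn_sex = cn_of(g_sex),
             low_cn_flag = !is.na(primary) & primary < 100)
}

#' Simulate a mixed-sex cohort for copy-number metric comparison
#'
#' Each synthetic sample has sex ~ Bernoulli(0.5), true copy number
#' ~ log-normal(meanlog, sdlog), total mapped bases around `depth` x its
#' sex-specific genome, and chrM read counts drawn binomially from the
#' expected mitochondrial read share.
#'
#' @param n cohort size.
#' @param seed integer seed.
#' @param meanlog,sdlog log-normal CN parameters.
#' @param depth nominal genome coverage.
#' @param read_len read length.
#' @param L mitochondrial genome length.
#' @return data.frame with sex, cn_true, cn_recomputed, cn_sex.
#' @export
simulate_cn_cohort <- function(n = 1000L, seed = 1L, meanlog = 5, sdlog = 0.4,
                               depth = 30, read_len = 150L, L = 16569L) {
  with_seed(seed, {
    sex <- ifelse(runif(n) < 0.5, "F", "M")
    gsize <- ifelse(sex == "F", GENOME_SIZE_F, GENOME_SIZE_M)
    cn_true <- rlnorm(n, meanlog, sdlog)
    gcov <- pmax(rnorm(n, depth, depth / 20), depth / 3)
    total_reads <- round(gcov * gsize / read_len)
    exp_chrm_reads <- cn_true * gcov / 2 * L / read_len
    chrm_reads <- rbinom(n, size = total_reads,
                         prob = pmin(1, exp_chrm_reads / total_reads))
    out <- lapply(seq_len(n), function(i) {
      st <- coverage_stats(chrm_reads[i], read_len,
                           total_mapped_bases = total_reads[i] * read_len,
                           sex = sex[i])
      cc <- chrm_coverage(st, L)
      data.frame(sex = sex[i], cn_true = cn_true[i],
                 cn_recomputed = as.numeric(
                   compute_cn(cc, genome_coverage(st, "recomputed"))),
                 cn_sex = as.numeric(
                   compute_cn(cc, genome_coverage(st, "sex_adjusted"))))
    })
    do.call(rbind, out)
  })
}
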