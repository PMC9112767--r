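#' Score calls against a simulator truth set
#'
#' A heteroplasmic call matches a truth record when position and both
#' alleles agree (INDELs may match within `match_window` positions after
#' left-alignment). False negatives are unmatched truth records; false
#' positives are unmatched heteroplasmic calls.
#'
#' @param calls calls data.frame (reference coordinates, normalized).
#' @param truth truth data.frame (pos/ref/alt/vaf, as from
#'   [inject_heteroplasmies()] or [read_variant_vcf()]).
#' @param match_window positional slack for INDEL matching (default 0).
#' @return a `mito_truthcmp` list: true_positives, false_negatives,
#'   false_positives, per-type breakdown `by_type`, and `matched_vafs`.
#' @export
compare_to_truth <- function(calls, truth, match_window = 0L) {
  het <- calls[calls$klass == "HETEROPLASMY" &
                 !has_filter(calls$filters, "NO_CALL"), , drop = FALSE]
  truth$type <- variant_type(truth$ref, truth$alt)
  het_key <- paste(het$pos, het$ref, het$alt)
  truth_key <- paste(truth$pos, truth$ref, truth$alt)
  matched_truth <- truth_key %in% het_key
  matched_call <- het_key %in% truth_key
  if (match_window > 0L) {
    for (i in which(!matched_truth)) {
      if (truth$type[i] == "SNV") next
      j <- which(!matched_call & het$type == truth$type[i] &
                   abs(het$pos - truth$pos[i]) <= match_window &
                   nchar(het$ref) == nchar(truth$ref[i]) &
                   nchar(het$alt) == nchar(truth$alt[i]))
      if (length(j)) {
        matched_truth[i] <- TRUE
        matched_call[j[1L]] <- TRUE
      }
    }
  }
  by_type <- lapply(c(SNV = "SNV", INDEL = "INDEL"), function(ty) {
    tt <- if (ty == "SNV") truth$type == "SNV" else truth$type != "SNV"
    ct <- if (ty == "SNV") het$type == "SNV" else het$type != "SNV"
    list(true_positives = sum(matched_truth & tt),
         false_negatives = sum(!matched_truth & tt),
         false_positives = sum(!matched_call & ct))
  })
  mt <- match(het_key, truth_key)
  mv <- data.frame(truth_vaf = truth$vaf[mt[!is.na(mt)]],
                   called_vaf = het$vaf[!is.na(mt)],
                   depth = het$depth[!is.na(mt)])
  structure(list(true_positives = sum(matched_truth),
                 false_negatives = sum(!matched_truth),
                 false_positives = sum(!matched_call),
                 by_type = by_type, matched_vafs = mv,
                 n_truth = nrow(truth), n_calls = nrow(het)),
            class = "mito_truthcmp")
}

#' @export
print.mito_truthcmp <- function(x, ...) {
  cat(sprintf("<mito_truthcmp> truth %d | TP %d FN %d FP %d\n",
              x$n_truth, x$true_positives, x$false_negatives,
              x$false_positives))
  invisible(x)
}

#' Per-sample variant summary
#'
#' Counts calls by class, type, and homopolymer context; heteroplasmy
#' counts are partitioned into homopolymer and non-homopolymer sites, the
#' split that separates slippage-prone calls from the biologically
#' informative ones. Samples with more than 5 heteroplasmies are flagged
#' HIGH_HET; with cohort context, counts above mean + 3 SD are flagged
#' OUTLIER.
#'
#' @param calls annotated calls data.frame (see [annotate_call()]).
#' @param sample_id sample identifier.
#' @param haplogroup assigned haplogroup label (or NA).
#' @param contamination a `mito_mixture` or NULL.
#' @param cohort_mean,cohort_sd optional cohort heteroplasmy-count context.
#' @return one-row data.frame.
#' @export
summarize_sample <- function(calls, sample_id = "sample",
                             haplogroup = NA_character_,
                             contamination = NULL, cohort_mean = NULL,
                             cohort_sd = NULL) {
  ok <- !has_filter(calls$filters, "NO_CALL")
  calls <- calls[ok, , drop = FALSE]
  hp <- if ("HP" %in% names(calls)) calls$HP else rep(FALSE, nrow(calls))
  het <- calls$klass == "HETEROPLASMY"
  n_het <- sum(het)
  flags <- character(0)
  if (n_het > 5L) flags <- c(flags, "HIGH_HET")
  if (!is.null(cohort_mean) && !is.null(cohort_sd) &&
      n_het > cohort_mean + 3 * cohort_sd)
    flags <- c(flags, "OUTLIER")
  data.frame(sample = sample_id, haplogroup = haplogroup,
             n_homoplasmic = sum(calls$klass == "HOMOPLASMY"),
             n_heteroplasmic = n_het,
             n_snv = sum(calls$type == "SNV"),
             n_indel = sum(calls$type != "SNV"),
             n_heteroplasmic_nonHP = sum(het & !hp),
             n_heteroplasmic_HP = sum(het & hp),
             contaminated = !is.null(contamination) &&
               isTRUE(contamination$flagged),
             iteration = if (nrow(calls)) max(calls$iteration) else NA_integer_,
             flags = paste(flags, collapse = ";"),
             stringsAsFactors = FALSE)
}

#' Write the pipeline's output files
#'
#' Produces the three output surfaces: a copy-number summary TSV, a variant
#' summary TSV, and per-sample annotated VCFs for each calling iteration.
#' Output is deterministic (sorted by sample id).
#'
#' @param summaries data.frame of [summarize_sample()] rows.
#' @param cn data.frame of [cn_metrics()] rows with a `sample` column (or
#'   NULL to skip).
#' @param vcfs named list (by sample id) of lists of calls data.frames, one
#'   per iteration.
#' @param outdir output directory (created if needed).
#' @param ref a `mito_ref` for VCF headers.
#' @return invisible vector of written paths.
#' @export
write_outputs <- function(summaries, cn, vcfs, outdir,
                          ref = mito_reference()) {
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  ids <- sort(unique(summaries$sample))
  if (!setequal(ids, names(vcfs)))
    stop("sample ids differ between summaries and vcfs: ",
         paste(union(setdiff(ids, names(vcfs)),
                     setdiff(names(vcfs), ids)), collapse = ", "))
  if (!is.null(cn) && !setequal(ids, cn$sample))
    stop("sample ids differ between summaries and cn metrics: ",
         paste(union(setdiff(ids, cn$sample),
                     setdiff(cn$sample, ids)), collapse = ", "))
  paths <- character(0)
  p <- file.path(outdir, "variant_summary.tsv")
  write.table(summaries[order(summaries$sample), , drop = FALSE], p,
              sep = "\t", quote = FALSE, row.names = FALSE)
  paths <- c(paths, p)
  if (!is.null(cn)) {
    p <- file.path(outdir, "cn_summary.tsv")
    write.table(cn[order(cn$sample), , drop = FALSE], p, sep = "\t",
                quote = FALSE, row.names = FALSE)
    paths <- c(paths, p)
  }
  for (id in ids) {
    for (it in seq_along(vcfs[[id]])) {
      p <- file.path(outdir, sprintf("%s.iter%d.vcf", id, it))
      write_calls_vcf(vcfs[[id]][[it]], p, contig = ref$name, L = ref$L)
      paths <- c(paths, p)
    }
  }
  invisible(paths)
}
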