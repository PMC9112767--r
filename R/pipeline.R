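#' Two-iteration mitochondrial variant-calling pipeline for one sample
#'
#' Maps read pairs to the circularized reference, removes duplicates,
#' down-samples to `target_cov`, splits origin-spanning alignments and calls
#' variants (iteration 1); then rebuilds the sample consensus, remaps,
#' re-calls against it and lifts the calls back to reference coordinates
#' (iteration 2).
#'
#' @param reads read-pair data.frame (`read_id`, `seq1`, `qual1`, `seq2`,
#'   `qual2`).
#' @param ref a `mito_ref`.
#' @param cfg a `mito_caller_config`.
#' @param target_cov down-sampling target fold coverage.
#' @param seed seed for down-sampling.
#' @param params aligner parameters.
#' @param index optional prebuilt `mito_index` for `ref`.
#' @param iterations 1 or 2.
#' @return list with `calls1`, `calls2`, `consensus`, `validation`,
#'   `coverage` (post-dedup fold coverage) and `aln1` (iteration-1
#'   alignments, canonical split coordinates).
#' @export
mito_pipeline <- function(reads, ref, cfg = caller_config(),
                          target_cov = 2000, seed = 1L,
                          params = aligner_params(), index = NULL,
                          iterations = 2L) {
  if (is.null(index)) index <- build_index(ref)
  aln <- map_sample(reads, index, params = params)
  aln <- mark_duplicates(aln)
  cov <- alignment_coverage(aln, ref$L)
  aln <- downsample(aln, target_cov, ref$L, seed = seed)
  aln <- split_origin_spanning(aln, ref$L)
  hp <- find_homopolymer_regions(ref$seq)
  calls1 <- call_sample(aln[aln$mapped & !aln$is_duplicate, , drop = FALSE],
                        ref, cfg, hp_regions = hp)
  out <- list(calls1 = calls1, calls2 = NULL, consensus = NULL,
              validation = NULL, coverage = cov, aln1 = aln)
  if (iterations >= 2L) {
    it2 <- second_iteration(reads, calls1, ref, cfg = cfg,
                            target_cov = target_cov, seed = seed,
                            params = params)
    out$calls2 <- it2$calls
    out$consensus <- it2$consensus
    out$validation <- it2$validation
  }
  out
}

#' Run the simulation benchmark suite
#'
#' Simulates `n_samples` haplogroup datasets under `cfg`, runs the
#' two-iteration pipeline on each, and scores both iterations against the
#' injected truth.
#'
#' @param n_samples number of haplogroup datasets (profiles are taken in
#'   panel order).
#' @param ref a `mito_ref`.
#' @param cfg a `mito_sim_config`; per-sample seeds are derived from
#'   `cfg$seed`.
#' @param caller_cfg a `mito_caller_config`.
#' @param profiles haplogroup panel (defaults to the bundled 30).
#' @param target_cov down-sampling target.
#' @return data.frame, one row per sample: haplogroup, truth size, FN/FP
#'   for each iteration, heteroplasmic site counts, mean called VAF.
#' @export
run_benchmark_suite <- function(n_samples = 10L, ref = mito_reference(),
                                cfg = sim_config(), caller_cfg = caller_config(),
                                profiles = NULL, target_cov = 2000) {
  if (is.null(profiles)) profiles <- haplogroup_profiles(ref)
  stopifnot(n_samples <= length(profiles))
  index <- build_index(ref)
  hp_track <- new_track("HP", intervals = find_homopolymer_regions(ref$seq))
  rows <- lapply(seq_len(n_samples), function(i) {
    cfg_i <- cfg
    cfg_i$seed <- cfg$seed + 101L * i
    ds <- simulate_dataset(profiles[[i]], ref, cfg_i, hp_track = hp_track)
    res <- mito_pipeline(ds$reads, ref, cfg = caller_cfg,
                         target_cov = target_cov, seed = cfg_i$seed,
                         index = index)
    cmp1 <- compare_to_truth(res$calls1, ds$truth)
    cmp2 <- compare_to_truth(res$calls2, ds$truth)
    mv <- cmp2$matched_vafs
    in_ci <- mapply(function(tv, cv, d) {
      lo <- qbinom(0.005, d, tv); hi <- qbinom(0.995, d, tv)
      cv * d >= lo - 0.5 & cv * d <= hi + 0.5
    }, mv$truth_vaf, mv$called_vaf, mv$depth)
    data.frame(sample = profiles[[i]]$name,
               n_truth = nrow(ds$truth),
               sites1 = cmp1$true_positives + cmp1$false_positives,
               fn1 = cmp1$false_negatives, fp1 = cmp1$false_positives,
               sites2 = cmp2$true_positives + cmp2$false_positives,
               fn2 = cmp2$false_negatives, fp2 = cmp2$false_positives,
               mean_called_vaf = mean(cmp2$matched_vafs$called_vaf),
               mean_truth_vaf = mean(ds$truth$vaf),
               frac_vaf_in_ci = mean(in_ci),
               coverage = res$coverage,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
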