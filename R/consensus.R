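#' Build a per-sample consensus mitochondrial genome
#'
#' Applies every homoplasmic call and every heteroplasmic call whose major
#' allele exceeds 50% VAF (ties at exactly 0.5 keep the reference; the
#' highest-VAF allele wins at multiallelic sites) to the reference, and
#' records an invertible piecewise coordinate map between consensus and
#' reference space.
#'
#' @param ref a `mito_ref`.
#' @param calls calls data.frame from [call_sample()].
#' @return a `mito_consensus` with `consensus_seq`, `edits`, and mapping
#'   tables (`blocks`, `insertions`, `deletions`).
#' @export
build_consensus <- function(ref, calls) {
  sel <- calls[!has_filter(calls$filters, "NO_CALL") &
                 (calls$klass == "HOMOPLASMY" | calls$vaf > 0.5), ,
               drop = FALSE]
  if (nrow(sel)) {
    sel <- sel[order(sel$pos, -sel$vaf), , drop = FALSE]
    sel <- sel[!duplicated(sel$pos), , drop = FALSE]  # highest VAF per site
    ref_end <- sel$pos + nchar(sel$ref) - 1L
    if (nrow(sel) > 1L) {
      overlap <- which(sel$pos[-1L] <= ref_end[-nrow(sel)])
      if (length(overlap))
        stop("overlapping consensus edits at positions ",
             paste(sel$pos[c(overlap, overlap + 1L)], collapse = ", "))
    }
  }
  edits <- sel[, c("pos", "ref", "alt", "vaf"), drop = FALSE]
  rownames(edits) <- NULL
  consensus_seq <- apply_edits(ref$seq, edits)
  map <- build_offset_map(ref$L, edits)
  structure(list(name = paste0(ref$name, "_consensus"),
                 consensus_seq = consensus_seq, edits = edits,
                 blocks = map$blocks, insertions = map$insertions,
                 deletions = map$deletions, L = ref$L,
                 Lc = nchar(consensus_seq)),
            class = "mito_consensus")
}

#' @export
print.mito_consensus <- function(x, ...) {
  cat(sprintf("<mito_consensus> %d bp (%+d vs reference), %d edits\n",
              x$Lc, x$Lc - x$L, nrow(x$edits)))
  invisible(x)
}

# piecewise linear map between reference and consensus coordinates; only
# length-changing edits create new blocks
build_offset_map <- function(L, edits) {
  blocks <- data.frame(rcrs_start = 1L, rcrs_end = L, cons_start = 1L,
                       cons_end = L)
  insertions <- data.frame(cons_start = integer(0), cons_end = integer(0),
                           anchor = integer(0))
  deletions <- data.frame(rcrs_start = integer(0), rcrs_end = integer(0),
                          anchor = integer(0))
  indels <- edits[nchar(edits$ref) != nchar(edits$alt), , drop = FALSE]
  if (nrow(indels) == 0L)
    return(list(blocks = blocks, insertions = insertions,
                deletions = deletions))
  indels <- indels[order(indels$pos), , drop = FALSE]
  b_rs <- integer(0); b_re <- integer(0); b_cs <- integer(0); b_ce <- integer(0)
  cur_r <- 1L; cur_c <- 1L
  for (i in seq_len(nrow(indels))) {
    p <- indels$pos[i]
    lr <- nchar(indels$ref[i]); la <- nchar(indels$alt[i])
    # identity block up to and including the anchor base
    b_rs <- c(b_rs, cur_r); b_re <- c(b_re, p)
    b_cs <- c(b_cs, cur_c); b_ce <- c(b_ce, cur_c + (p - cur_r))
    anchor_c <- cur_c + (p - cur_r)
    if (la > lr) {  # insertion: consensus bases with no reference image
      insertions <- rbind(insertions,
                          data.frame(cons_start = anchor_c + 1L,
                                     cons_end = anchor_c + (la - lr),
                                     anchor = p))
      cur_r <- p + 1L
      cur_c <- anchor_c + (la - lr) + 1L
    } else {        # deletion: reference bases with no consensus image
      deletions <- rbind(deletions,
                         data.frame(rcrs_start = p + 1L,
                                    rcrs_end = p + (lr - la),
                                    anchor = p))
      cur_r <- p + (lr - la) + 1L
      cur_c <- anchor_c + 1L
    }
  }
  if (cur_r <= L) {
    b_rs <- c(b_rs, cur_r); b_re <- c(b_re, L)
    b_cs <- c(b_cs, cur_c); b_ce <- c(b_ce, cur_c + (L - cur_r))
  }
  list(blocks = data.frame(rcrs_start = b_rs, rcrs_end = b_re,
                           cons_start = b_cs, cons_end = b_ce),
       insertions = insertions, deletions = deletions)
}

#' Map reference positions to consensus coordinates
#' @param cons a `mito_consensus`.
#' @param pos reference positions.
#' @return consensus positions (NA where the position was deleted).
#' @export
consensus_forward <- function(cons, pos) {
  b <- cons$blocks
  idx <- findInterval(pos, b$rcrs_start)
  out <- rep(NA_integer_, length(pos))
  ok <- idx >= 1L & pos <= b$rcrs_end[pmax(idx, 1L)]
  out[ok] <- b$cons_start[idx[ok]] + (pos[ok] - b$rcrs_start[idx[ok]])
  out
}

#' Map consensus positions back to reference coordinates
#' @param cons a `mito_consensus`.
#' @param pos consensus positions.
#' @return data.frame with `rcrs_pos` (insertion anchor when inside an
#'   inserted block) and `in_insertion`.
#' @export
consensus_inverse <- function(cons, pos) {
  b <- cons$blocks
  idx <- findInterval(pos, b$cons_start)
  rcrs <- rep(NA_integer_, length(pos))
  ok <- idx >= 1L & pos <= b$cons_end[pmax(idx, 1L)]
  rcrs[ok] <- b$rcrs_start[idx[ok]] + (pos[ok] - b$cons_start[idx[ok]])
  in_ins <- rep(FALSE, length(pos))
  if (any(!ok) && nrow(cons$insertions)) {
    ins <- cons$insertions
    for (i in which(!ok)) {
      hit <- which(pos[i] >= ins$cons_start & pos[i] <= ins$cons_end)
      if (length(hit)) {
        rcrs[i] <- ins$anchor[hit[1L]]
        in_ins[i] <- TRUE
      }
    }
  }
  data.frame(rcrs_pos = rcrs, in_insertion = in_ins)
}

#' Write the consensus-to-reference liftover table
#' @param cons a `mito_consensus`.
#' @param path output TSV (consensus_pos, rcrs_pos).
#' @export
write_liftover <- function(cons, path) {
  inv <- consensus_inverse(cons, seq_len(cons$Lc))
  write.table(data.frame(consensus_pos = seq_len(cons$Lc),
                         rcrs_pos = inv$rcrs_pos),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Lift consensus-space calls back to reference coordinates
#'
#' Positions are mapped through the inverse offset map; calls inside a
#' consensus insertion are anchored to the insertion site and tagged
#' `IN_CONSENSUS_INS`. When a consensus edit made the reference allele the
#' minor allele, the record is re-expressed against the reference allele
#' with `vaf` flipped to the consensus allele's fraction, tagged
#' `ALLELE_SWITCH`, and the minor-allele fraction kept in `minor_vaf`.
#'
#' @param calls calls on consensus coordinates.
#' @param cons a `mito_consensus`.
#' @param ref the `mito_ref` the consensus was built from.
#' @return calls in reference coordinates.
#' @export
lift_to_reference <- function(calls, cons, ref) {
  if (nrow(calls) == 0L) {
    calls$minor_vaf <- numeric(0)
    return(calls)
  }
  inv <- consensus_inverse(cons, calls$pos)
  if (anyNA(inv$rcrs_pos)) stop("call position outside consensus bounds")
  calls$pos <- inv$rcrs_pos
  calls$minor_vaf <- NA_real_
  calls$filters[inv$in_insertion] <-
    paste_filters(calls$filters[inv$in_insertion], "IN_CONSENSUS_INS")
  for (i in seq_len(nrow(calls))) {
    if (inv$in_insertion[i]) next
    p <- calls$pos[i]
    if (calls$type[i] == "SNV") {
      rbase <- substr(ref$seq, p, p)
      if (calls$ref[i] == rbase) next
      if (calls$alt[i] == rbase) {
        # second-iteration minor allele is the reference allele
        calls$minor_vaf[i] <- calls$vaf[i]
        calls$vaf[i] <- 1 - calls$vaf[i]
        calls$alt[i] <- calls$ref[i]
        calls$ref[i] <- rbase
        calls$filters[i] <- paste_filters(calls$filters[i], "ALLELE_SWITCH")
      } else {
        calls$ref[i] <- rbase  # third allele at a consensus-edited site
      }
      calls$klass[i] <- if (calls$vaf[i] >= 0.97 - 1e-9) "HOMOPLASMY"
                        else "HETEROPLASMY"
    } else {
      lr <- nchar(calls$ref[i])
      rseq <- substr(ref$seq, p, p + lr - 1L)
      if (rseq != calls$ref[i]) {
        # a consensus edit overlaps the indel span; re-express best effort
        calls$filters[i] <- paste_filters(calls$filters[i], "NEAR_CONS_EDIT")
        calls$alt[i] <- paste0(substr(rseq, 1L, 1L),
                               substr(calls$alt[i], 2L, nchar(calls$alt[i])))
        calls$ref[i] <- rseq
      }
      nv <- normalize_variant(ref$seq, calls$pos[i], calls$ref[i],
                              calls$alt[i])
      calls$pos[i] <- nv$pos; calls$ref[i] <- nv$ref; calls$alt[i] <- nv$alt
    }
  }
  calls <- calls[order(calls$pos, calls$ref, calls$alt), , drop = FALSE]
  rownames(calls) <- NULL
  calls
}

#' Validate consensus coverage from exact alignments
#'
#' Keeps alignments that match the consensus exactly over their full length
#' (100% identity, 100% length), merges their intervals when they overlap by
#' at least `min_overlap` bases, and reports whether the circular consensus
#' is fully covered. Pass alignments in extended coordinates (pre origin
#' split); spans are projected onto the circle for the coverage check.
#'
#' @param aln alignment data.frame (extended coordinates).
#' @param Lc consensus length.
#' @param min_overlap merge threshold (default 5, i.e. intervals overlapping
#'   by fewer than 5 bases stay separate).
#' @return list(fully_covered, uncovered data.frame, merged data.frame).
#' @export
validate_consensus <- function(aln, Lc, min_overlap = 5L) {
  m <- aln[aln$mapped & !aln$is_duplicate & aln$mapq > 0L, , drop = FALSE]
  rl <- cpp_cigar_ref_len(m$cigar)
  exact <- m$nm == 0L & grepl("^[0-9]+M$", m$cigar)
  s <- m$start[exact]; e <- s + rl[exact] - 1L
  merged <- data.frame(start = integer(0), end = integer(0))
  if (length(s)) {
    o <- order(s, e)
    s <- s[o]; e <- e[o]
    ms <- s[1L]; me <- e[1L]
    for (i in seq_along(s)[-1L]) {
      if (s[i] <= me - min_overlap + 1L) me <- max(me, e[i])
      else { merged <- rbind(merged, data.frame(start = ms, end = me))
             ms <- s[i]; me <- e[i] }
    }
    merged <- rbind(merged, data.frame(start = ms, end = me))
  }
  covered <- rep(FALSE, Lc)
  for (i in seq_len(nrow(merged))) {
    p <- merged$start[i]:merged$end[i]
    covered[((p - 1L) %% Lc) + 1L] <- TRUE
  }
  gaps <- data.frame(start = integer(0), end = integer(0))
  if (any(!covered)) {
    r <- rle(covered)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    gaps <- data.frame(start = starts[!r$values], end = ends[!r$values])
  }
  list(fully_covered = all(covered), uncovered = gaps, merged = merged)
}

#' Second-iteration variant calling against the sample consensus
#'
#' Builds the consensus from first-iteration calls, circularizes it, remaps
#' the sample's reads, re-calls variants, and lifts the calls back to
#' reference coordinates (tagged `iteration = 2`). Homoplasmies absorbed
#' into the consensus no longer appear; residual calls are the sample's
#' heteroplasmies expressed against its own genome.
#'
#' @param reads read-pair data.frame (as simulated or read from FASTQ).
#' @param first_calls first-iteration calls data.frame.
#' @param ref the `mito_ref` used in iteration 1.
#' @param cfg a `mito_caller_config`.
#' @param target_cov down-sampling target.
#' @param seed seed for down-sampling.
#' @param params aligner parameters.
#' @return list(consensus, calls, validation).
#' @export
second_iteration <- function(reads, first_calls, ref,
                             cfg = caller_config(), target_cov = 2000,
                             seed = 1L, params = aligner_params()) {
  cons <- build_consensus(ref, first_calls)
  bundle <- reference_bundle(cons$name, cons$consensus_seq,
                             ext_len = min(300L, cons$Lc - 1L))
  idx <- build_index(bundle)
  aln <- map_sample(reads, idx, params = params)
  aln <- mark_duplicates(aln)
  aln <- downsample(aln, target_cov, bundle$L, seed = seed)
  val <- validate_consensus(aln, cons$Lc)
  aln <- split_origin_spanning(aln, bundle$L)
  hp <- find_homopolymer_regions(bundle$seq)
  calls <- call_sample(aln[aln$mapped & !aln$is_duplicate, , drop = FALSE],
                       bundle, cfg, hp_regions = hp)
  calls <- lift_to_reference(calls, cons, ref)
  if (nrow(calls)) calls$iteration <- 2L
  list(consensus = cons, calls = calls, validation = val)
}
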