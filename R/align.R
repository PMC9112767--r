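#' Build an exact k-mer index over the extended circular reference
#'
#' @param ref a `mito_ref` bundle.
#' @param k k-mer size (>= 11; must not exceed the read length).
#' @return a `mito_index` object.
#' @export
build_index <- function(ref, k = 21L) {
  if (k < 11L) stop("k must be >= 11")
  structure(list(ptr = cpp_build_index(ref$ext_seq, as.integer(k)),
                 k = as.integer(k), ref = ref),
            class = "mito_index")
}

#' Number of reference offsets held in the index
#' @param index a `mito_index`.
#' @export
index_n_offsets <- function(index) cpp_index_n_offsets(index$ptr)

#' Look up the extended-reference offsets of an exact k-mer
#' @param index a `mito_index`.
#' @param kmer a k-length nucleotide string.
#' @return integer vector of 1-based offsets (empty if absent).
#' @export
index_lookup <- function(index, kmer) cpp_index_lookup(index$ptr, kmer)

#' Aligner scoring defaults (short-read mapper style)
#' @param match,mismatch,gap_open,gap_ext alignment scores/penalties; a gap
#'   of length g costs `gap_open + g * gap_ext`.
#' @param band half-width of the alignment band.
#' @param min_score minimum accepted alignment score.
#' @export
aligner_params <- function(match = 1L, mismatch = -4L, gap_open = 6L,
                           gap_ext = 1L, band = 16L, min_score = 30L) {
  list(match = as.integer(match), mismatch = as.integer(mismatch),
       gap_open = as.integer(gap_open), gap_ext = as.integer(gap_ext),
       band = as.integer(band), min_score = as.integer(min_score))
}

revcomp_str <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}
rev_str <- function(x) cpp_reverse_strings(x)

# map a vector of reads; returns one row per read with extended-reference
# coordinates plus the read sequence/qualities oriented to the reference
map_read_vector <- function(seqs, quals, index, params, seed_step = 5L) {
  res <- cpp_map_reads(index$ptr, seqs, index$ref$L, params$band,
                       params$match, params$mismatch, params$gap_open,
                       params$gap_ext, params$min_score, as.integer(seed_step))
  minus <- res$mapped & res$strand == "-"
  oriented <- seqs
  oq <- quals
  if (any(minus)) {
    oriented[minus] <- revcomp_str(seqs[minus])
    oq[minus] <- rev_str(quals[minus])
  }
  data.frame(mapped = res$mapped, start = res$start, strand = res$strand,
             cigar = res$cigar, score = res$score, mapq = res$mapq,
             nm = res$nm, seq = oriented, qual = oq,
             stringsAsFactors = FALSE)
}

#' Map one read pair to the extended circular reference
#'
#' Seeds exact k-mers, votes on diagonals, extends with a banded affine-gap
#' alignment, and reports the best placement per end. Pairs are checked for
#' proper forward/reverse orientation within a maximum circular insert of
#' 1000 bases; the lower-scoring end of an improper pair has its mapping
#' quality set to 0 (excluded from pileups).
#'
#' @param pair list or one-row data.frame with `seq1`, `qual1`, `seq2`,
#'   `qual2` (and optionally `read_id`).
#' @param index a `mito_index`.
#' @param params see [aligner_params()].
#' @return alignment data.frame (two rows, one per end; unmapped ends have
#'   `mapped = FALSE`) on canonical coordinates.
#' @export
map_read_pair <- function(pair, index, params = aligner_params()) {
  df <- as.data.frame(pair, stringsAsFactors = FALSE)
  map_sample(df, index, params = params)
}

#' Map a table of read pairs
#'
#' @param reads data.frame with `read_id`, `seq1`, `qual1`, `seq2`, `qual2`
#'   (as produced by [simulate_reads()] / [read_reads_fastq()]).
#' @param index a `mito_index`.
#' @param params see [aligner_params()].
#' @param max_insert maximum circular insert size for a proper pair.
#' @return alignment data.frame with columns `read_id`, `end` (1/2),
#'   `mapped`, `start` (canonical 1-based), `strand`, `cigar`, `mapq`,
#'   `score`, `nm`, `seq`, `qual`, `mate_start`, `mate_strand`, `proper`,
#'   `is_duplicate`. Alignments may still span the origin; see
#'   [split_origin_spanning()].
#' @export
map_sample <- function(reads, index, params = aligner_params(),
                       max_insert = 1000L) {
  if (is.null(reads$read_id))
    reads$read_id <- sprintf("read%06d", seq_len(nrow(reads)))
  L <- index$ref$L
  a1 <- map_read_vector(reads$seq1, reads$qual1, index, params)
  a2 <- map_read_vector(reads$seq2, reads$qual2, index, params)
  wrap <- function(s, m) ifelse(m, wrap_position(pmax(s, 1L), L, index$ref$ext_len), NA)
  a1$start <- wrap(a1$start, a1$mapped)
  a2$start <- wrap(a2$start, a2$mapped)
  # proper-pair check on the circle
  circ_dist <- function(s1, s2) {
    d <- abs(s1 - s2)
    pmin(d, L - d)
  }
  proper <- a1$mapped & a2$mapped & (a1$strand != a2$strand) &
    circ_dist(a1$start, a2$start) <= max_insert
  both <- a1$mapped & a2$mapped
  bad <- both & !proper
  if (any(bad)) {
    drop1 <- bad & (a1$score < a2$score)
    drop2 <- bad & !drop1
    a1$mapq[drop1] <- 0L
    a2$mapq[drop2] <- 0L
  }
  n <- nrow(reads)
  out <- rbind(
    cbind(data.frame(read_id = reads$read_id, end = 1L,
                     stringsAsFactors = FALSE), a1,
          data.frame(mate_start = a2$start, mate_strand = a2$strand)),
    cbind(data.frame(read_id = reads$read_id, end = 2L,
                     stringsAsFactors = FALSE), a2,
          data.frame(mate_start = a1$start, mate_strand = a1$strand)))
  out$proper <- rep(proper, 2L)
  out$is_duplicate <- FALSE
  out <- out[order(rep(seq_len(n), 2L), out$end), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Split alignments that span the circular origin
#'
#' An alignment whose reference span crosses position `L` is cut into two
#' alignments, `[start..L]` and `[1..remainder]`, with the cigar (and read
#' bases) partitioned at the junction; an insertion at the junction stays
#' with the piece containing its anchor. Total aligned reference and read
#' bases are conserved.
#'
#' @param aln alignment data.frame (canonical coordinates, from
#'   [map_sample()]).
#' @param L canonical reference length.
#' @return alignment data.frame with spanning rows replaced by two rows.
#' @export
split_origin_spanning <- function(aln, L) {
  if (nrow(aln) == 0L) return(aln)
  span <- ifelse(aln$mapped, cpp_cigar_ref_len(aln$cigar), 0L)
  rdlen <- ifelse(aln$mapped, cpp_cigar_read_len(aln$cigar), 0L)
  if (any(aln$mapped & rdlen != nchar(aln$seq)))
    stop("cigar inconsistent with read length")
  crosses <- aln$mapped & (aln$start + span - 1L > L)
  if (!any(crosses)) return(aln)
  pieces <- lapply(which(crosses), function(i) {
    row <- aln[i, , drop = FALSE]
    keep_ref <- L - row$start + 1L  # ref bases in the first piece
    cp <- cut_cigar(row$cigar, keep_ref)
    p1 <- row; p2 <- row
    p1$cigar <- cp$cigar1
    p1$seq <- substr(row$seq, 1L, cp$read1)
    p1$qual <- substr(row$qual, 1L, cp$read1)
    p2$cigar <- cp$cigar2
    p2$start <- 1L
    p2$seq <- substr(row$seq, cp$read1 + 1L, nchar(row$seq))
    p2$qual <- substr(row$qual, cp$read1 + 1L, nchar(row$qual))
    rbind(p1, p2)
  })
  out <- rbind(aln[!crosses, , drop = FALSE], do.call(rbind, pieces))
  out <- out[order(!out$mapped, out$read_id, out$end, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# cut a cigar after `keep_ref` reference bases; insertions at the cut point
# stay with the first piece (their anchor is the last base of piece 1)
cut_cigar <- function(cigar, keep_ref) {
  len <- as.integer(regmatches(cigar, gregexpr("[0-9]+", cigar))[[1L]])
  op <- regmatches(cigar, gregexpr("[MIDSX=]", cigar))[[1L]]
  ref_used <- 0L; read_used <- 0L
  c1 <- character(0); c2 <- character(0)
  i <- 1L
  while (i <= length(op)) {
    consumes_ref <- op[i] %in% c("M", "D", "X", "=")
    if (ref_used >= keep_ref) {
      # insertion exactly at the junction anchors to piece 1
      if (op[i] == "I" && length(c2) == 0L && ref_used == keep_ref) {
        c1 <- c(c1, paste0(len[i], op[i]))
        read_used <- read_used + len[i]
      } else c2 <- c(c2, paste0(len[i], op[i]))
      i <- i + 1L
      next
    }
    if (consumes_ref && ref_used + len[i] > keep_ref) {
      take <- keep_ref - ref_used
      c1 <- c(c1, paste0(take, op[i]))
      c2 <- c(c2, paste0(len[i] - take, op[i]))
      if (op[i] != "D") read_used <- read_used + take
      ref_used <- keep_ref
    } else {
      c1 <- c(c1, paste0(len[i], op[i]))
      if (consumes_ref) ref_used <- ref_used + len[i]
      if (op[i] %in% c("M", "I", "S", "X", "=")) read_used <- read_used + len[i]
    }
    i <- i + 1L
  }
  if (ref_used < keep_ref) stop("cigar inconsistent with reference span")
  list(cigar1 = paste(c1, collapse = ""), cigar2 = paste(c2, collapse = ""),
       read1 = read_used)
}

#' Mark duplicate read pairs
#'
#' Pairs sharing both ends' (start, strand) are duplicates; the pair with
#' the highest summed base quality is retained (ties broken by read id).
#'
#' @param aln alignment data.frame from [map_sample()] (pre-split).
#' @return the same data.frame with `is_duplicate` set.
#' @export
mark_duplicates <- function(aln) {
  m <- aln[aln$mapped, , drop = FALSE]
  if (nrow(m) == 0L) return(aln)
  qsum <- cpp_qual_sums(m$qual)
  per_pair <- tapply(qsum, m$read_id, sum)
  e1 <- m[m$end == 1L & !is.na(m$mate_start), , drop = FALSE]
  key <- paste(pmin(e1$start, e1$mate_start), pmax(e1$start, e1$mate_start),
               ifelse(e1$start <= e1$mate_start,
                      paste(e1$strand, e1$mate_strand),
                      paste(e1$mate_strand, e1$strand)))
  q <- as.numeric(per_pair[e1$read_id])
  o <- order(key, -q, e1$read_id)
  dup_ids <- e1$read_id[o][duplicated(key[o])]
  aln$is_duplicate <- aln$read_id %in% dup_ids & aln$mapped
  aln
}

#' Down-sample alignments to a target coverage
#'
#' If the observed coverage exceeds `target_cov`, each read pair is kept
#' independently with probability `target_cov / coverage`; otherwise the
#' input is returned unchanged. Seeded and a strict subset of the input.
#'
#' @param aln alignment data.frame.
#' @param target_cov target fold coverage (default 2000).
#' @param L reference length.
#' @param seed integer seed.
#' @return alignment data.frame subset.
#' @export
downsample <- function(aln, target_cov = 2000, L, seed = 1L) {
  stopifnot(target_cov > 0)
  m <- aln$mapped & !aln$is_duplicate
  cov <- sum(cpp_cigar_ref_len(aln$cigar[m])) / L
  if (cov <= target_cov) return(aln)
  ids <- unique(aln$read_id[m])
  keep <- with_seed(seed, ids[runif(length(ids)) < target_cov / cov])
  out <- aln[aln$read_id %in% keep | !(aln$read_id %in% ids), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Observed fold coverage of an alignment set
#' @param aln alignment data.frame.
#' @param L reference length.
#' @export
alignment_coverage <- function(aln, L) {
  m <- aln$mapped & !aln$is_duplicate
  sum(cpp_cigar_ref_len(aln$cigar[m])) / L
}

#' Per-position depth from alignments (canonical, split coordinates)
#' @param aln alignment data.frame (post [split_origin_spanning()]).
#' @param L reference length.
#' @return integer vector of length L.
#' @export
alignment_depth <- function(aln, L) {
  m <- aln[aln$mapped & !aln$is_duplicate & aln$mapq > 0L, , drop = FALSE]
  pu <- cpp_pileup(L, m$start, m$strand, m$cigar, m$seq, m$qual, 0L)
  pu$depth
}

#' Write alignments as a SAM file
#'
#' @param aln alignment data.frame (canonical coordinates).
#' @param path output path.
#' @param ref a `mito_ref` for the header.
#' @export
write_sam <- function(aln, path, ref) {
  header <- c("@HD\tVN:1.6\tSO:unsorted",
              sprintf("@SQ\tSN:%s\tLN:%d", ref$name, ref$L),
              "@PG\tID:mitovar\tPN:mitovar")
  m <- aln[aln$mapped, , drop = FALSE]
  mate_rev <- !is.na(m$mate_strand) & m$mate_strand == "-"
  flag <- 1L + 64L * (m$end == 1L) + 128L * (m$end == 2L) +
    16L * (m$strand == "-") + 32L * mate_rev +
    2L * m$proper + 1024L * m$is_duplicate
  lines <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t=\t%d\t0\t%s\t%s",
                   m$read_id, flag, ref$name, m$start, m$mapq, m$cigar,
                   ifelse(is.na(m$mate_start), 0L, m$mate_start),
                   m$seq, m$qual)
  writeLines(c(header, lines), path)
  invisible(path)
}
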