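#' Variant-caller configuration
#'
#' Frequency-and-strand threshold calling: a non-reference allele is called
#' when its allele fraction is at least `vaf_min` (3% by default, the level
#' reliably detectable at ~2000x mitochondrial coverage) with at least
#' `min_reads_per_strand` supporting reads on each strand. Calls at or above
#' `homoplasmy_vaf` are classed homoplasmic, otherwise heteroplasmic.
#'
#' @param vaf_min minimum variant allele fraction.
#' @param min_reads_per_strand minimum alt reads per strand.
#' @param homoplasmy_vaf heteroplasmy/homoplasmy class boundary.
#' @param min_baseq minimum base quality counted toward allele support.
#' @param min_depth minimum site depth for any call.
#' @export
caller_config <- function(vaf_min = 0.03, min_reads_per_strand = 2L,
                          homoplasmy_vaf = 0.97, min_baseq = 20L,
                          min_depth = 10L) {
  stopifnot(vaf_min > 0, vaf_min < homoplasmy_vaf, homoplasmy_vaf <= 1,
            min_reads_per_strand >= 0L, min_depth >= 1L)
  structure(list(vaf_min = vaf_min,
                 min_reads_per_strand = as.integer(min_reads_per_strand),
                 homoplasmy_vaf = homoplasmy_vaf,
                 min_baseq = as.integer(min_baseq),
                 min_depth = as.integer(min_depth)),
            class = "mito_caller_config")
}

BASES <- c("A", "C", "G", "T")

#' Build a strand-aware pileup
#'
#' Walks the cigars of mapped, non-duplicate, uniquely placed alignments on
#' canonical coordinates (run [split_origin_spanning()] first). Bases below
#' `min_baseq` are excluded from allele counts but still contribute to
#' depth; insertions are keyed to their anchor position; deletions appear
#' both as spanning events at the deleted positions and as an anchored DEL
#' allele.
#'
#' @param aln alignment data.frame.
#' @param ref a `mito_ref`.
#' @param min_baseq base-quality floor.
#' @return a `mito_pileup` object.
#' @export
build_pileup <- function(aln, ref, min_baseq = 20L) {
  use <- aln$mapped & !aln$is_duplicate & aln$mapq > 0L
  m <- aln[use, , drop = FALSE]
  ends <- m$start + cpp_cigar_ref_len(m$cigar) - 1L
  if (any(m$start < 1L) || any(ends > ref$L))
    stop("alignment outside [1, L]; split origin-spanning alignments first")
  pu <- cpp_pileup(ref$L, m$start, m$strand, m$cigar, m$seq, m$qual,
                   as.integer(min_baseq))
  structure(c(pu, list(L = ref$L, ref_seq = ref$seq,
                       min_baseq = as.integer(min_baseq))),
            class = "mito_pileup")
}

#' @export
print.mito_pileup <- function(x, ...) {
  cat(sprintf("<mito_pileup> %d positions, mean depth %.1f\n",
              x$L, mean(x$depth)))
  invisible(x)
}

#' Extract one pileup column
#'
#' @param pu a `mito_pileup`.
#' @param pos 1-based position.
#' @return list with `position`, `depth`, `spanning_deletions` and an
#'   `alleles` data.frame (`allele` coded as A/C/G/T, `+SEQ` for an
#'   insertion after the position, `-N` for an N-base deletion anchored at
#'   the position; `fwd`, `rev`, `meanq`).
#' @export
pileup_column <- function(pu, pos) {
  fwd <- pu$counts[pos, 1:4]; rev <- pu$counts[pos, 5:8]
  keep <- (fwd + rev) > 0L
  al <- data.frame(allele = BASES[keep], fwd = fwd[keep], rev = rev[keep],
                   meanq = ifelse(fwd[keep] + rev[keep] > 0,
                                  pu$qualsum[pos, keep] / (fwd[keep] + rev[keep]),
                                  NA_real_),
                   stringsAsFactors = FALSE)
  ins <- pu$inss[pu$inss$anchor == pos, , drop = FALSE]
  if (nrow(ins))
    al <- rbind(al, data.frame(allele = paste0("+", ins$seq), fwd = ins$fwd,
                               rev = ins$rev, meanq = NA_real_,
                               stringsAsFactors = FALSE))
  del <- pu$dels[pu$dels$anchor == pos, , drop = FALSE]
  if (nrow(del))
    al <- rbind(al, data.frame(allele = paste0("-", del$dlen), fwd = del$fwd,
                               rev = del$rev, meanq = NA_real_,
                               stringsAsFactors = FALSE))
  list(position = pos, depth = pu$depth[pos],
       spanning_deletions = pu$del_span[pos], alleles = al)
}

#' Call variant alleles at one pileup column
#'
#' Every non-reference allele with allele fraction >= `vaf_min` and at least
#' `min_reads_per_strand` supporting reads on each strand is emitted; all
#' passing alleles at a site are reported (multiallelic records preserved).
#' A site below `min_depth` yields a single `NO_CALL` filter record.
#'
#' @param col a column from [pileup_column()] (or a compatible list).
#' @param ref_base reference base at the column position.
#' @param cfg a `mito_caller_config`.
#' @return data.frame with coded alleles (see [pileup_column()]), `vaf`,
#'   `depth`, `fwd`, `rev`, `klass`, `filters`.
#' @export
call_site <- function(col, ref_base, cfg = caller_config()) {
  empty <- data.frame(pos = integer(0), allele = character(0),
                      vaf = numeric(0), depth = integer(0), fwd = integer(0),
                      rev = integer(0), meanq = numeric(0),
                      klass = character(0), filters = character(0),
                      stringsAsFactors = FALSE)
  if (col$depth < cfg$min_depth) {
    out <- data.frame(pos = col$position, allele = NA_character_,
                      vaf = NA_real_, depth = col$depth, fwd = NA_integer_,
                      rev = NA_integer_, meanq = NA_real_,
                      klass = NA_character_, filters = "NO_CALL",
                      stringsAsFactors = FALSE)
    return(out)
  }
  al <- col$alleles
  al <- al[al$allele != ref_base, , drop = FALSE]
  if (nrow(al) == 0L) return(empty)
  tot <- al$fwd + al$rev
  vaf <- tot / col$depth
  pass <- (tot >= cfg$vaf_min * col$depth - 1e-9) &
    al$fwd >= cfg$min_reads_per_strand & al$rev >= cfg$min_reads_per_strand
  al <- al[pass, , drop = FALSE]
  if (nrow(al) == 0L) return(empty)
  vaf <- vaf[pass]
  data.frame(pos = col$position, allele = al$allele, vaf = vaf,
             depth = col$depth, fwd = al$fwd, rev = al$rev, meanq = al$meanq,
             klass = ifelse(vaf >= cfg$homoplasmy_vaf - 1e-9,
                            "HOMOPLASMY", "HETEROPLASMY"),
             filters = "", stringsAsFactors = FALSE)
}

# convert coded alleles to anchored VCF representation against `ref_seq`
decode_alleles <- function(calls, ref_seq) {
  n <- nrow(calls)
  ref <- alt <- character(n)
  type <- character(n)
  chars_at <- function(p, l) substr(ref_seq, p, p + l - 1L)
  for (i in seq_len(n)) {
    a <- calls$allele[i]; p <- calls$pos[i]
    rb <- chars_at(p, 1L)
    if (startsWith(a, "+")) {
      ref[i] <- rb; alt[i] <- paste0(rb, substr(a, 2L, nchar(a)))
      type[i] <- "INS"
    } else if (startsWith(a, "-")) {
      dl <- as.integer(substr(a, 2L, nchar(a)))
      ref[i] <- chars_at(p, dl + 1L); alt[i] <- rb
      type[i] <- "DEL"
    } else {
      ref[i] <- rb; alt[i] <- a; type[i] <- "SNV"
    }
  }
  calls$ref <- ref; calls$alt <- alt; calls$type <- type
  calls
}

#' Call variants across a sample
#'
#' Builds the pileup, applies the frequency/strand thresholds at every
#' position, converts passing alleles to anchored, left-aligned VCF
#' representation and sorts by position. Positions where the reference base
#' is N are skipped. INDELs within 150 bases of a homopolymer region are
#' flagged `HP_ADJACENT` (they are retained in the output but excluded from
#' headline SNV summaries).
#'
#' @param aln alignment data.frame (canonical, split coordinates).
#' @param ref a `mito_ref`.
#' @param cfg a `mito_caller_config`.
#' @param hp_regions optional data.frame of homopolymer intervals (defaults
#'   to scanning `ref`).
#' @return calls data.frame with columns pos/ref/alt/vaf/depth/fwd/rev/
#'   meanq/type/klass/filters.
#' @export
call_sample <- function(aln, ref, cfg = caller_config(), hp_regions = NULL) {
  if (nrow(aln) == 0L || !any(aln$mapped)) {
    warning("no mapped alignments; returning empty call set")
    return(empty_calls())
  }
  if (is.null(hp_regions)) hp_regions <- find_homopolymer_regions(ref$seq)
  pu <- build_pileup(aln, ref, min_baseq = cfg$min_baseq)
  chars <- strsplit(ref$seq, "", fixed = TRUE)[[1L]]
  refcode <- match(chars, BASES)  # NA for N
  depth <- pu$depth
  mrs <- cfg$min_reads_per_strand
  # vectorized candidate screen using exactly the call_site predicates
  cand <- logical(pu$L)
  for (b in 1:4) {
    f <- pu$counts[, b]; r <- pu$counts[, b + 4L]
    pass <- !is.na(refcode) & refcode != b & depth >= cfg$min_depth &
      f >= mrs & r >= mrs & (f + r) >= cfg$vaf_min * depth - 1e-9
    cand <- cand | pass
  }
  for (tb in list(pu$inss, pu$dels)) {
    if (nrow(tb)) {
      d <- depth[tb$anchor]
      pass <- !is.na(refcode[tb$anchor]) & d >= cfg$min_depth &
        tb$fwd >= mrs & tb$rev >= mrs &
        (tb$fwd + tb$rev) >= cfg$vaf_min * d - 1e-9
      cand[tb$anchor[pass]] <- TRUE
    }
  }
  sites <- which(cand)
  if (length(sites) == 0L) return(empty_calls())
  rows <- lapply(sites, function(p)
    call_site(pileup_column(pu, p), chars[p], cfg))
  calls <- do.call(rbind, rows)
  calls <- calls[!is.na(calls$allele), , drop = FALSE]
  if (nrow(calls) == 0L) return(empty_calls())
  calls <- decode_alleles(calls, ref$seq)
  # left-align indels
  ind <- which(calls$type != "SNV")
  for (i in ind) {
    nv <- normalize_variant(ref$seq, calls$pos[i], calls$ref[i], calls$alt[i])
    calls$pos[i] <- nv$pos; calls$ref[i] <- nv$ref; calls$alt[i] <- nv$alt
  }
  if (length(ind) && nrow(hp_regions)) {
    near_hp <- vapply(calls$pos[ind], function(p)
      any(p >= hp_regions$start - 150L & p <= hp_regions$end + 150L),
      logical(1))
    calls$filters[ind][near_hp] <-
      paste_filters(calls$filters[ind][near_hp], "HP_ADJACENT")
  }
  calls$iteration <- 1L
  calls <- calls[order(calls$pos, calls$ref, calls$alt), , drop = FALSE]
  rownames(calls) <- NULL
  calls[, c("pos", "ref", "alt", "vaf", "depth", "fwd", "rev", "meanq",
            "type", "klass", "filters", "iteration")]
}

empty_calls <- function() {
  data.frame(pos = integer(0), ref = character(0), alt = character(0),
             vaf = numeric(0), depth = integer(0), fwd = integer(0),
             rev = integer(0), meanq = numeric(0), type = character(0),
             klass = character(0), filters = character(0),
             iteration = integer(0), stringsAsFactors = FALSE)
}

paste_filters <- function(cur, new) {
  ifelse(is.na(cur) | !nzchar(cur), new, paste(cur, new, sep = ";"))
}

has_filter <- function(filters, tag) {
  !is.na(filters) & grepl(tag, filters, fixed = TRUE)
}
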