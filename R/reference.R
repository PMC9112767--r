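#' Reference bundles: a linear mitochondrial genome plus its circular extension
#'
#' The mitochondrial chromosome is circular, but short-read aligners (and this
#' package's aligner) operate on linear sequences. A `mito_ref` bundle holds
#' the linear reference together with an extended copy in which the first
#' `ext_len` bases are appended after the last position, so reads spanning the
#' origin align contiguously and are split back onto canonical coordinates
#' afterwards.
#'
#' @param name contig name.
#' @param seq nucleotide string (A/C/G/T/N).
#' @param ext_len number of bases from the start of the sequence appended
#'   after the end (default 300, i.e. the first 300 bases follow position L).
#' @return an object of class `mito_ref` with fields `name`, `seq`, `L`,
#'   `ext_len`, `ext_seq`.
#' @export
reference_bundle <- function(name, seq, ext_len = 300L) {
  seq <- toupper(seq)
  if (!nzchar(seq)) stop("reference sequence is empty")
  if (grepl("[^ACGTN]", seq)) stop("reference contains non-nucleotide characters")
  ext_len <- as.integer(ext_len)
  L <- nchar(seq)
  if (ext_len >= L) stop("ext_len must be smaller than the sequence length")
  structure(
    list(name = name, seq = seq, L = L, ext_len = ext_len,
         ext_seq = paste0(seq, substr(seq, 1L, ext_len))),
    class = "mito_ref")
}

#' @export
print.mito_ref <- function(x, ...) {
  cat(sprintf("<mito_ref> %s: %d bp (+%d bp circular extension)\n",
              x$name, x$L, x$ext_len))
  invisible(x)
}

#' Load a single-record FASTA as a circularized reference bundle
#'
#' @param path FASTA file with exactly one record of A/C/G/T/N.
#' @param ext_len circular extension length, see [reference_bundle()].
#' @return a `mito_ref` bundle.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">toy", "ACGT"), fa)
#' load_fasta(fa, ext_len = 2)$ext_seq  # "ACGTAC"
#' @export
load_fasta <- function(path, ext_len = 300L) {
  if (!file.exists(path)) stop("no such file: ", path)
  set <- Biostrings::readDNAStringSet(path)
  if (length(set) == 0L) stop("FASTA contains no records: ", path)
  if (length(set) > 1L) stop("expected a single-record FASTA, found ",
                             length(set), " records in ", path)
  seq <- as.character(set[[1L]])
  if (grepl("[^ACGTN]", seq)) stop("non-nucleotide characters in ", path)
  name <- sub("\\s.*$", "", names(set)[1L])
  reference_bundle(name, seq, ext_len = ext_len)
}

#' Write a reference sequence to FASTA
#' @param seq nucleotide string.
#' @param name record name.
#' @param path output path.
#' @export
write_fasta <- function(seq, name, path) {
  x <- Biostrings::DNAStringSet(seq)
  names(x) <- name
  Biostrings::writeXStringSet(x, path, width = 70L)
  invisible(path)
}

#' The bundled synthetic mitochondrial reference
#'
#' Returns the 16,569-bp mitochondrial reference shipped with the package.
#' This sequence is a *synthetic* rCRS-like stand-in: it has the canonical
#' length, the documented polycytosine tracts around positions 300-320 and
#' 450-470, an N placeholder at position 3107, nine C-homopolymer regions,
#' and rCRS alleles at the landmark sites used by the bundled annotation
#' tracks. It is not the GenBank NC_012920 sequence; analyses of real data
#' should load the true rCRS with [load_fasta()].
#'
#' @param ext_len circular extension length.
#' @return a `mito_ref` bundle with `L == 16569`.
#' @export
mito_reference <- function(ext_len = 300L) {
  path <- system.file("extdata", "chrM_synthetic.fa", package = "mitovar",
                      mustWork = TRUE)
  load_fasta(path, ext_len = ext_len)
}

#' Map positions on the extended (circularized) reference back to canonical
#' coordinates
#'
#' The extension appends the first `ext_len` bases after position `L`, so an
#' extended position `p > L` is the canonical position `p - L`.
#'
#' @param p integer vector of 1-based positions on the extended reference.
#' @param L canonical reference length.
#' @param ext_len extension length (range check only).
#' @return canonical 1-based positions; idempotent on canonical input.
#' @export
wrap_position <- function(p, L, ext_len = 300L) {
  p <- as.numeric(p)
  if (any(p < 1 | p > L + ext_len)) stop("position out of range [1, L + ext_len]")
  ifelse(p > L, p - L, p)
}

#' Find C-homopolymer regions
#'
#' Scans for low-complexity tracts of `base` (polycytosine by default), the
#' regions where polymerase slippage makes short-read variant calls
#' unreliable. A qualifying window contains at least `min_run` copies of
#' `base` with at most `max_mismatch` single-base interior interruptions;
#' interruptions are interior only when flanked by `base` on both sides.
#' Windows are extended by `pad` bases on each side, clipped to the sequence,
#' and overlapping windows are merged.
#'
#' @param seq nucleotide string.
#' @param min_run minimum number of `base` copies in a window (>= 2).
#' @param base the repeated base (default "C"; set "G" to scan the
#'   reverse-complement strand's C-runs).
#' @param max_mismatch maximum interior non-`base` positions per window.
#' @param pad bases added to each end of a qualifying window.
#' @return data.frame with columns `start`, `end`, `label` (1-based
#'   inclusive), non-overlapping and sorted.
#' @export
find_homopolymer_regions <- function(seq, min_run = 5L, base = "C",
                                     max_mismatch = 1L, pad = 1L) {
  if (min_run < 2L) stop("min_run must be >= 2")
  n <- nchar(seq)
  if (n == 0L) stop("empty sequence")
  isb <- strsplit(seq, "", fixed = TRUE)[[1L]] == base
  r <- rle(isb)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  bs <- starts[r$values]      # starts of base runs
  bl <- r$lengths[r$values]   # lengths of base runs
  if (length(bs) == 0L)
    return(data.frame(start = integer(0), end = integer(0),
                      label = character(0), stringsAsFactors = FALSE))
  # gap (in non-base positions) between run i and run i+1
  gaps <- if (length(bs) > 1L) bs[-1L] - (bs[-length(bs)] + bl[-length(bl)])
          else integer(0)
  cand_s <- integer(0); cand_e <- integer(0)
  for (i in seq_along(bs)) {
    j <- i
    # extend the chain while the next gap is a single interior base and the
    # mismatch budget allows it
    while (j < length(bs) && gaps[j] == 1L && (j - i + 1L) <= max_mismatch) j <- j + 1L
    total <- sum(bl[i:j])
    if (total >= min_run) {
      cand_s <- c(cand_s, bs[i])
      cand_e <- c(cand_e, bs[j] + bl[j] - 1L)
    }
  }
  if (length(cand_s) == 0L)
    return(data.frame(start = integer(0), end = integer(0),
                      label = character(0), stringsAsFactors = FALSE))
  ir <- IRanges::IRanges(pmax(1L, cand_s - pad), pmin(n, cand_e + pad))
  ir <- IRanges::reduce(ir)
  data.frame(start = IRanges::start(ir), end = IRanges::end(ir),
             label = "HP", stringsAsFactors = FALSE)
}

track_kinds_interval <- c("HP", "HV", "HS", "GENIC", "DLOOP")
track_kinds_site <- c("NUMT", "HG", "DBSNP")

new_track <- function(kind, intervals = NULL, sites = NULL) {
  structure(list(kind = kind, intervals = intervals, sites = sites),
            class = "mito_track")
}

#' @export
print.mito_track <- function(x, ...) {
  n <- if (!is.null(x$intervals)) nrow(x$intervals) else nrow(x$sites)
  cat(sprintf("<mito_track> %s: %d %s\n", x$kind, n,
              if (!is.null(x$intervals)) "intervals" else "sites"))
  invisible(x)
}

read_bed_track <- function(path, kind) {
  lines <- readLines(path)
  keep <- which(!grepl("^(#|track|browser)", lines) & nzchar(lines))
  out <- data.frame(start = integer(0), end = integer(0),
                    label = character(0), stringsAsFactors = FALSE)
  if (length(keep)) {
    fields <- strsplit(lines[keep], "\t", fixed = TRUE)
    for (k in seq_along(fields)) {
      f <- fields[[k]]
      if (length(f) < 3L || is.na(suppressWarnings(as.integer(f[2L]))) ||
          is.na(suppressWarnings(as.integer(f[3L]))))
        stop(sprintf("malformed BED line %d in %s", keep[k], path))
    }
    start0 <- vapply(fields, function(f) as.integer(f[2L]), integer(1))
    end0 <- vapply(fields, function(f) as.integer(f[3L]), integer(1))
    lab <- vapply(fields, function(f) if (length(f) >= 4L) f[4L] else kind,
                  character(1))
    # BED is 0-based half-open on disk; in memory we use 1-based inclusive
    out <- data.frame(start = start0 + 1L, end = end0, label = lab,
                      stringsAsFactors = FALSE)
    out <- out[order(out$start), , drop = FALSE]
    rownames(out) <- NULL
  }
  new_track(kind, intervals = out)
}

read_site_track <- function(path, kind) {
  lines <- readLines(path)
  body <- which(!grepl("^#", lines) & nzchar(lines))
  if (length(body)) {
    fields <- strsplit(lines[body], "\t", fixed = TRUE)
    for (k in seq_along(fields)) {
      f <- fields[[k]]
      if (length(f) < 5L || is.na(suppressWarnings(as.integer(f[2L]))))
        stop(sprintf("malformed VCF line %d in %s", body[k], path))
    }
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    fx <- vcfR::getFIX(v)
    if (is.null(dim(fx))) fx <- matrix(fx, nrow = 1L, dimnames = list(NULL, names(fx)))
    sites <- data.frame(pos = as.integer(fx[, "POS"]),
                        ref = fx[, "REF"], alt = fx[, "ALT"],
                        stringsAsFactors = FALSE)
    sites <- sites[order(sites$pos), , drop = FALSE]
    rownames(sites) <- NULL
  } else {
    sites <- data.frame(pos = integer(0), ref = character(0),
                        alt = character(0), stringsAsFactors = FALSE)
  }
  new_track(kind, sites = sites)
}

#' Load annotation tracks from disk
#'
#' Interval kinds (HP, HV, HS, GENIC, DLOOP) are read from 4-column BED
#' (0-based half-open on disk, converted to 1-based inclusive in memory);
#' site kinds (NUMT, HG, DBSNP) from VCF-style site lists queried by
#' (position, ref, alt).
#'
#' @param paths named character vector or list mapping track kind to file.
#' @return named list of `mito_track` objects.
#' @export
load_region_tracks <- function(paths) {
  kinds <- toupper(names(paths))
  stopifnot(length(kinds) == length(paths), !anyNA(kinds))
  out <- vector("list", length(paths))
  names(out) <- kinds
  for (i in seq_along(paths)) {
    k <- kinds[i]
    out[[i]] <- if (k %in% track_kinds_site) read_site_track(paths[[i]], k)
                else read_bed_track(paths[[i]], k)
  }
  out
}

#' The bundled annotation tracks
#'
#' Small synthetic tracks matched to the bundled synthetic reference:
#' homopolymer (HP), hypervariable (HV), hotspot (HS), D-loop, coding genes
#' (GENIC), plus NUMT / haplogroup (HG) / dbSNP site lists.
#'
#' @return named list of `mito_track` objects.
#' @export
mito_tracks <- function() {
  dir <- system.file("extdata", "tracks", package = "mitovar", mustWork = TRUE)
  load_region_tracks(c(
    HP = file.path(dir, "hp.bed"),
    HV = file.path(dir, "hv.bed"),
    HS = file.path(dir, "hs.bed"),
    DLOOP = file.path(dir, "dloop.bed"),
    GENIC = file.path(dir, "genic.bed"),
    NUMT = file.path(dir, "numt_sites.vcf"),
    HG = file.path(dir, "hg_sites.vcf"),
    DBSNP = file.path(dir, "dbsnp_sites.vcf")))
}

#' Query track membership
#'
#' Interval tracks are queried by position; site tracks by the full
#' (position, ref, alt) triple.
#'
#' @param track a `mito_track`.
#' @param pos integer vector of 1-based positions.
#' @param ref,alt allele strings (site tracks only).
#' @return logical vector.
#' @export
track_membership <- function(track, pos, ref = NULL, alt = NULL) {
  stopifnot(inherits(track, "mito_track"))
  if (!is.null(track$intervals)) {
    iv <- track$intervals
    if (nrow(iv) == 0L) return(rep(FALSE, length(pos)))
    vapply(pos, function(p) any(p >= iv$start & p <= iv$end), logical(1))
  } else {
    s <- track$sites
    if (is.null(ref) || is.null(alt))
      stop("site tracks are queried by (pos, ref, alt)")
    key <- paste(s$pos, s$ref, s$alt)
    paste(pos, ref, alt) %in% key
  }
}

#' Interval label at a position (first match), or NA
#' @param track interval `mito_track`.
#' @param pos positions.
#' @return character vector of labels.
#' @export
track_label <- function(track, pos) {
  iv <- track$intervals
  vapply(pos, function(p) {
    hit <- which(p >= iv$start & p <= iv$end)
    if (length(hit)) iv$label[hit[1L]] else NA_character_
  }, character(1))
}

#' Write an interval track back to 4-column BED
#' @param track interval `mito_track`.
#' @param path output file.
#' @param chrom contig name for column 1.
#' @export
track_to_bed <- function(track, path, chrom = "chrM") {
  stopifnot(!is.null(track$intervals))
  iv <- track$intervals
  lines <- sprintf("%s\t%d\t%d\t%s", chrom, iv$start - 1L, iv$end, iv$label)
  writeLines(lines, path)
  invisible(path)
}
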