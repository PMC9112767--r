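#' Extraction regions: chrM plus NUMT read sinks
#'
#' Nuclear-embedded mitochondrial segments (NUMTs) on chr1 and chr17 act as
#' read sinks for true mitochondrial reads; reads landing there are pulled
#' back and remapped. Defaults are the hg38 sink intervals; other builds
#' must supply their own.
#'
#' @param chrm chrM contig name.
#' @param numt_sinks data.frame with chrom/start/end (1-based inclusive).
#' @export
extraction_regions <- function(chrm = "chrM",
                               numt_sinks = data.frame(
                                 chrom = c("chr1", "chr17"),
                                 start = c(629084L, 22521366L),
                                 end = c(634422L, 22521502L),
                                 stringsAsFactors = FALSE)) {
  structure(list(chrm = chrm, numt_sinks = numt_sinks),
            class = "mito_regions")
}

scan_fields <- c("qname", "flag", "rname", "strand", "pos", "cigar",
                 "mrnm", "mpos", "seq", "qual")

scan_to_df <- function(res) {
  data.frame(qname = res$qname, flag = res$flag,
             rname = as.character(res$rname), pos = res$pos,
             cigar = res$cigar, seq = as.character(res$seq),
             qual = as.character(res$qual),
             strand = as.character(res$strand),
             stringsAsFactors = FALSE)
}

bam_flag_param <- function() {
  Rsamtools::scanBamFlag(isSecondaryAlignment = FALSE,
                         isSupplementaryAlignment = FALSE)
}

#' Extract candidate mitochondrial reads from a whole-genome BAM
#'
#' Returns all reads mapped to chrM, all reads overlapping the NUMT sink
#' intervals, and unmapped reads whose mate maps to chrM; mates are
#' reunited and each read is emitted once, in its original (sequencing)
#' orientation, ready for FASTQ output and remapping.
#'
#' @param bam_path indexed BAM file.
#' @param regions an `extraction_regions()` object.
#' @return data.frame with read_id/seq1/qual1/seq2/qual2 (pairs) plus an
#'   `unpaired` attribute with any single-end leftovers.
#' @export
extract_candidate_reads <- function(bam_path, regions = extraction_regions()) {
  if (!file.exists(paste0(bam_path, ".bai")) &&
      !file.exists(sub("\\.bam$", ".bai", bam_path)))
    stop("BAM index not found for ", bam_path)
  hdr <- Rsamtools::scanBamHeader(bam_path)[[1L]]$targets
  if (!regions$chrm %in% names(hdr))
    stop("contig ", regions$chrm, " absent from ", bam_path)
  which <- GenomicRanges::GRanges(
    c(regions$chrm, regions$numt_sinks$chrom),
    IRanges::IRanges(c(1L, regions$numt_sinks$start),
                     c(hdr[[regions$chrm]], regions$numt_sinks$end)))
  keep <- names(hdr) %in% as.character(GenomicRanges::seqnames(which))
  which <- which[as.character(GenomicRanges::seqnames(which)) %in% names(hdr)]
  param <- Rsamtools::ScanBamParam(flag = bam_flag_param(), what = scan_fields,
                                   which = which)
  res <- Rsamtools::scanBam(bam_path, param = param)
  df <- do.call(rbind, lapply(res, scan_to_df))
  # scanBam(which=) returns mapped reads overlapping the regions plus
  # placed-unmapped reads (mates of chrM reads carry the mate's coordinates)
  df <- df[!duplicated(paste(df$qname, bitwAnd(df$flag, 192L))), , drop = FALSE]
  # drop NUMT-sink unmapped strays not anchored to chrM
  unmapped <- bitwAnd(df$flag, 4L) > 0L
  df <- df[!unmapped | df$rname == regions$chrm, , drop = FALSE]
  # back to sequencing orientation
  unmapped <- bitwAnd(df$flag, 4L) > 0L
  minus <- !unmapped & !is.na(df$strand) & df$strand == "-"
  if (any(minus)) {
    df$seq[minus] <- revcomp_str(df$seq[minus])
    df$qual[minus] <- rev_str(df$qual[minus])
  }
  first <- bitwAnd(df$flag, 64L) > 0L
  ids <- unique(df$qname)
  r1 <- df[first, , drop = FALSE]; r2 <- df[!first, , drop = FALSE]
  r1 <- r1[match(ids, r1$qname), , drop = FALSE]
  r2 <- r2[match(ids, r2$qname), , drop = FALSE]
  paired <- !is.na(r1$qname) & !is.na(r2$qname)
  out <- data.frame(read_id = ids[paired],
                    seq1 = r1$seq[paired], qual1 = r1$qual[paired],
                    seq2 = r2$seq[paired], qual2 = r2$qual[paired],
                    stringsAsFactors = FALSE)
  attr(out, "unpaired") <- ids[!paired]
  out
}

#' Collect per-contig read and base counts for copy-number estimation
#'
#' Counts primary, non-duplicate, mapped reads per contig and total mapped
#' bases (aligned cigar M/X/= bases) across the file.
#'
#' @param bam_path indexed BAM file.
#' @param regions an `extraction_regions()` object.
#' @param sex "F", "M" or NA.
#' @param metadata_cov externally provided genome coverage, if any.
#' @return a `mito_covstats` list: chrm_reads, read_len (mean aligned
#'   length on chrM), total_mapped_bases, per_contig counts, sex,
#'   metadata_cov.
#' @export
collect_coverage_stats <- function(bam_path, regions = extraction_regions(),
                                   sex = NA_character_, metadata_cov = NULL) {
  hdr <- Rsamtools::scanBamHeader(bam_path)[[1L]]$targets
  if (!regions$chrm %in% names(hdr))
    stop("contig ", regions$chrm, " absent from ", bam_path)
  flag <- Rsamtools::scanBamFlag(isSecondaryAlignment = FALSE,
                                 isSupplementaryAlignment = FALSE,
                                 isDuplicate = FALSE,
                                 isUnmappedQuery = FALSE)
  param <- Rsamtools::ScanBamParam(flag = flag,
                                   what = c("rname", "cigar"))
  res <- Rsamtools::scanBam(bam_path, param = param)[[1L]]
  alen <- cpp_cigar_ref_len(res$cigar)
  rn <- as.character(res$rname)
  per_contig <- tapply(rep(1L, length(rn)), rn, sum)
  chrm <- rn == regions$chrm
  structure(list(chrm_reads = sum(chrm),
                 read_len = if (any(chrm)) mean(alen[chrm]) else NA_real_,
                 total_mapped_bases = sum(as.numeric(alen)),
                 per_contig = per_contig,
                 sex = sex,
                 metadata_cov = metadata_cov),
            class = "mito_covstats")
}

#' Build coverage stats directly from known counts
#' @param chrm_reads mapped non-duplicate chrM read count.
#' @param read_len read length (bases).
#' @param total_mapped_bases genome-wide mapped bases.
#' @param sex "F", "M" or NA.
#' @param metadata_cov externally provided genome coverage or NULL.
#' @export
coverage_stats <- function(chrm_reads, read_len, total_mapped_bases = NA_real_,
                           sex = NA_character_, metadata_cov = NULL) {
  stopifnot(chrm_reads >= 0)
  structure(list(chrm_reads = chrm_reads, read_len = read_len,
                 total_mapped_bases = total_mapped_bases,
                 per_contig = NULL, sex = sex, metadata_cov = metadata_cov),
            class = "mito_covstats")
}
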