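# shared fixtures built in code; everything is deterministic

mref <- mitovar::mito_reference()
mtracks <- mitovar::mito_tracks()
mprofiles <- mitovar::haplogroup_profiles(mref)
mhp <- mitovar::find_homopolymer_regions(mref$seq)

# a small alignment table row, in the shape map_sample() produces
make_aln <- function(start, strand = "+", cigar = "150M",
                     seq = strrep("A", 150L), qual = strrep("?", nchar(seq)),
                     read_id = "r1", end = 1L, mapq = 60L, nm = 0L,
                     mate_start = NA_integer_, mate_strand = NA_character_) {
  data.frame(read_id = read_id, end = end, mapped = TRUE, start = start,
             strand = strand, cigar = cigar, score = nchar(seq), mapq = mapq,
             nm = nm, seq = seq, qual = qual, mate_start = mate_start,
             mate_strand = mate_strand, proper = TRUE, is_duplicate = FALSE,
             stringsAsFactors = FALSE)
}

# a pileup column in the shape pileup_column() produces
make_column <- function(pos, depth, alleles) {
  list(position = pos, depth = depth, spanning_deletions = 0L,
       alleles = alleles)
}

allele_df <- function(allele, fwd, rev) {
  data.frame(allele = allele, fwd = fwd, rev = rev, meanq = 30,
             stringsAsFactors = FALSE)
}

substr_circ <- function(seq, start, len) {
  doubled <- paste0(seq, seq)
  substr(doubled, start, start + len - 1L)
}

rc <- function(x) as.character(
  Biostrings::reverseComplement(Biostrings::DNAString(x)))
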