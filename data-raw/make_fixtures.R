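# Builds the bundled synthetic mitochondrial reference and annotation
# tracks under inst/extdata/. Run from the package root:
#   Rscript data-raw/make_fixtures.R
#
# The reference is a synthetic rCRS-like stand-in: canonical 16,569 bp
# length, the documented polycytosine tracts at chrM:300-320 and
# chrM:450-470, an N placeholder at 3107, rCRS alleles at the landmark
# sites used by the site-list tracks, and exactly nine C-homopolymer
# regions. It is NOT the GenBank NC_012920 sequence.

source("R/reference.R")
source("R/mitovar-package.R")
source("R/simulate.R")

set.seed(16569L)
L <- 16569L
bases <- c("A", "C", "G", "T")
s <- sample(bases, L, replace = TRUE, prob = c(0.309, 0.313, 0.131, 0.247))

# cap background C-runs at 2 so homopolymer content is fully designed
cap_c_runs <- function(s) {
  r <- rle(s == "C")
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  for (i in which(r$values & r$lengths > 2L)) {
    run <- starts[i]:ends[i]
    s[run[-(1:2)]] <- sample(c("A", "T"), length(run) - 2L, replace = TRUE)
  }
  s
}
s <- cap_c_runs(s)

# landmark single-base alleles (rCRS values at sites named in the bundled
# NUMT/dbSNP lists)
landmarks <- c(`73` = "A", `263` = "A", `750` = "A", `1438` = "A",
               `2706` = "A", `4769` = "A", `7028` = "C", `8701` = "A",
               `8860` = "A", `10398` = "A", `11719` = "G", `12612` = "G",
               `12705` = "C", `14766` = "C", `15326` = "A", `16093` = "T",
               `16189` = "T")
s[as.integer(names(landmarks))] <- landmarks

plant <- function(s, pos, str) {
  v <- strsplit(str, "")[[1L]]
  s[pos:(pos + length(v) - 1L)] <- v
  s
}
# documented polycytosine tracts
s <- plant(s, 300L, "AAACCCCCCCTCCCCCGCTTC")   # chrM:300-320
s <- plant(s, 450L, "TATTTTCCCCTCCCACTCCCA")   # chrM:450-470
s[3107L] <- "N"
# seven further designed C-tracts (nine total), flanked by non-C bases
hp_plants <- list(list(958L,  "ACCCCCA"),
                  list(2144L, "ACCCTCCCA"),
                  list(5893L, "ACCCCCCA"),
                  list(8274L, "ACCCCCTCCA"),
                  list(9538L, "ACCCCCA"),
                  list(12873L, "ACCCCTCCCCA"),
                  list(16183L, "ACCCCCTCCCCA"))
for (p in hp_plants) s <- plant(s, p[[1L]], p[[2L]])

designed <- rbind(
  data.frame(start = 300L, end = 320L),
  data.frame(start = 450L, end = 470L),
  do.call(rbind, lapply(hp_plants, function(p)
    data.frame(start = p[[1L]], end = p[[1L]] + nchar(p[[2L]]) - 1L))))
protected <- sort(unique(c(as.integer(names(landmarks)), 3107L,
                           unlist(mapply(seq, designed$start, designed$end)))))

# non-C flanks around each designed tract so background C's never extend them
flanks <- setdiff(c(designed$start - 1L, designed$end + 1L,
                    designed$start - 2L, designed$end + 2L), protected)
flanks <- flanks[flanks >= 1L & flanks <= L]
s[flanks][s[flanks] == "C"] <- "A"

# remove any stray homopolymer windows the random background produced
repeat {
  hp <- find_homopolymer_regions(paste(s, collapse = ""))
  stray <- which(!vapply(seq_len(nrow(hp)), function(i)
    any(hp$start[i] <= designed$end & hp$end[i] >= designed$start),
    logical(1)))
  if (!length(stray)) break
  for (i in stray) {
    cand <- setdiff(which(s == "C" & seq_along(s) >= hp$start[i] &
                            seq_along(s) <= hp$end[i]), protected)
    stopifnot(length(cand) > 0L)
    s[cand[1L]] <- "T"
  }
}
hp <- find_homopolymer_regions(paste(s, collapse = ""))
stopifnot(nrow(hp) == 9L)
seqstr <- paste(s, collapse = "")
stopifnot(nchar(seqstr) == L,
          substr(seqstr, 300, 320) == "AAACCCCCCCTCCCCCGCTTC",
          substr(seqstr, 450, 470) == "TATTTTCCCCTCCCACTCCCA")

dir.create("inst/extdata/tracks", recursive = TRUE, showWarnings = FALSE)
write_fasta(seqstr, "chrM synthetic rCRS-like stand-in (16569 bp)",
            "inst/extdata/chrM_synthetic.fa")

bed_line <- function(start, end, label) sprintf("chrM\t%d\t%d\t%s", start - 1L, end, label)

writeLines(bed_line(hp$start, hp$end, "HP"), "inst/extdata/tracks/hp.bed")
writeLines(c(bed_line(57L, 372L, "HV2"), bed_line(438L, 574L, "HV3"),
             bed_line(16024L, 16383L, "HV1")), "inst/extdata/tracks/hv.bed")
writeLines(c(bed_line(1L, 576L, "Dloop"), bed_line(16024L, 16569L, "Dloop")),
           "inst/extdata/tracks/dloop.bed")
hotspots <- c(64L, 152L, 195L, 247L, 16093L, 16129L, 16189L, 16362L)
writeLines(bed_line(hotspots, hotspots, "HS"), "inst/extdata/tracks/hs.bed")
genes <- data.frame(
  name = c("MT-ND1", "MT-ND2", "MT-CO1", "MT-CO2", "MT-ATP8", "MT-ATP6",
           "MT-CO3", "MT-ND3", "MT-ND4L", "MT-ND4", "MT-ND5", "MT-ND6",
           "MT-CYB"),
  start = c(3307L, 4470L, 5904L, 7586L, 8366L, 8527L, 9207L, 10059L,
            10470L, 10760L, 12337L, 14149L, 14747L),
  end = c(4262L, 5511L, 7445L, 8269L, 8572L, 9207L, 9990L, 10404L,
          10766L, 12137L, 14148L, 14673L, 15887L))
writeLines(bed_line(genes$start, genes$end, paste0("CDS:", genes$name)),
           "inst/extdata/tracks/genic.bed")

vcf_site_file <- function(path, pos, ref, alt, info = ".") {
  writeLines(c("##fileformat=VCFv4.2",
               sprintf("##contig=<ID=chrM,length=%d>", L),
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
               sprintf("chrM\t%d\t.\t%s\t%s\t.\t.\t%s", pos, ref, alt, info)),
             path)
}
numt <- data.frame(pos = c(2706L, 7028L, 8701L, 10398L, 11719L, 12612L,
                           12705L, 16093L),
                   alt = c("G", "T", "G", "G", "A", "A", "T", "C"))
numt$ref <- s[numt$pos]
vcf_site_file("inst/extdata/tracks/numt_sites.vcf", numt$pos, numt$ref, numt$alt)

dbsnp_pos <- c(73L, 263L, 750L, 1438L, 4769L, 8860L, 15326L, numt$pos)
dbsnp_alt <- c("G", "G", "G", "G", "G", "G", "G", numt$alt)
o <- order(dbsnp_pos)
vcf_site_file("inst/extdata/tracks/dbsnp_sites.vcf", dbsnp_pos[o],
              s[dbsnp_pos][o], dbsnp_alt[o])

# haplogroup-defining SNVs from the synthetic panel
ref <- reference_bundle("chrM", seqstr)
profiles <- haplogroup_profiles(ref)
hg <- do.call(rbind, lapply(profiles, function(p)
  cbind(p$snvs, hg = p$name)))
hg <- hg[order(hg$pos, hg$alt), , drop = FALSE]
hg <- hg[!duplicated(paste(hg$pos, hg$ref, hg$alt)), , drop = FALSE]
vcf_site_file("inst/extdata/tracks/hg_sites.vcf", hg$pos, hg$ref, hg$alt,
              paste0("HG=", hg$hg))

cat("wrote synthetic reference with", nrow(hp), "homopolymer regions\n")
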