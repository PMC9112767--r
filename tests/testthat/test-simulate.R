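test_that("haplogroup profiles are valid against the reference", {
  expect_length(mprofiles, 30L)
  sizes <- vapply(mprofiles, function(p) nrow(p$snvs), integer(1))
  expect_true(all(sizes >= 5L & sizes <= 40L))
  for (p in mprofiles) {
    expect_false(anyDuplicated(p$snvs$pos) > 0L)
    expect_equal(substring(mref$seq, p$snvs$pos, p$snvs$pos), p$snvs$ref)
  }
  # deterministic: regenerating gives the identical panel
  expect_identical(haplogroup_profiles(mref), mprofiles)
})

test_that("build_sample_genome applies profile SNVs and checks ref alleles", {
  empty <- structure(list(name = "ref", snvs = data.frame(
    pos = integer(0), ref = character(0), alt = character(0))),
    class = "mito_profile")
  expect_identical(build_sample_genome(mref, empty), mref$seq)

  p73 <- structure(list(name = "p", snvs = data.frame(
    pos = 73L, ref = "A", alt = "G")), class = "mito_profile")
  g <- build_sample_genome(mref, p73)
  diffs <- which(strsplit(g, "")[[1L]] != strsplit(mref$seq, "")[[1L]])
  expect_equal(diffs, 73L)

  bad <- structure(list(name = "b", snvs = data.frame(
    pos = 100L, ref = "X", alt = "G")), class = "mito_profile")
  expect_error(build_sample_genome(mref, bad), "position 100")
})

test_that("inject_heteroplasmies places the configured variant load", {
  cfg <- sim_config(coverage = 10, seed = 3L)
  inj <- inject_heteroplasmies(mref$seq, cfg, hp_track = mhp)
  expect_equal(nrow(inj$truth), 43L)
  expect_equal(sum(inj$truth$type == "SNV"), 35L)
  expect_equal(sum(inj$truth$type != "SNV"), 8L)
  expect_true(all(inj$truth$vaf >= 0.15 & inj$truth$vaf <= 0.20))
  expect_equal(mean(inj$truth$vaf), 0.18, tolerance = 1e-10)
  # injected sites avoid homopolymer tracts
  in_hp <- vapply(inj$truth$pos, function(p)
    any(p >= mhp$start & p <= mhp$end), logical(1))
  expect_false(any(in_hp))
  # truth alleles match the genome they were injected into
  expect_equal(substring(mref$seq, inj$truth$pos,
                         inj$truth$pos + nchar(inj$truth$ref) - 1L),
               inj$truth$ref)

  none <- inject_heteroplasmies(mref$seq, sim_config(coverage = 10, n_snv = 0,
                                                     n_indel = 0, seed = 3L))
  expect_equal(nrow(none$truth), 0L)
  expect_identical(none$alt_genome, mref$seq)

  again <- inject_heteroplasmies(mref$seq, cfg, hp_track = mhp)
  expect_identical(again$truth, inj$truth)
})

test_that("error-free reads are exact substrings of the circular genome", {
  cfg <- sim_config(coverage = 10, error_rate = 0, n_snv = 0, n_indel = 0,
                    seed = 5L)
  rd <- simulate_reads(mref$seq, cfg = cfg)
  expect_true(all(nchar(rd$seq1) == 150L))
  ok1 <- mapply(function(s, p) substr_circ(mref$seq, p, 150L) == s,
                rd$seq1, rd$pos1)
  ok2 <- mapply(function(s, p) rc(substr_circ(mref$seq, p, 150L)) == s,
                rd$seq2, rd$pos2)
  expect_true(all(ok1))
  expect_true(all(ok2))
})

test_that("total simulated bases hit the coverage target within 5%", {
  cfg <- sim_config(coverage = 100, seed = 6L)
  rd <- simulate_reads(mref$seq, cfg = cfg)
  total <- sum(nchar(rd$seq1)) + sum(nchar(rd$seq2))
  expect_lt(abs(total - 100 * 16569) / (100 * 16569), 0.05)
})

test_that("per-variant mixing recovers the intended allele fraction", {
  # one SNV at 18% VAF; with zero error the carrying fragments are counted
  # directly and must fall in the central 99% binomial interval
  pos <- 8000L
  refb <- substr(mref$seq, pos, pos)
  altb <- setdiff(c("A", "C", "G", "T"), refb)[1L]
  truth <- data.frame(pos = pos, ref = refb, alt = altb, vaf = 0.18)
  cfg <- sim_config(coverage = 2000, error_rate = 0, seed = 8L)
  rd <- simulate_reads(mref$seq, truth = truth, cfg = cfg)
  off1 <- (pos - rd$pos1) %% 16569L
  covering <- which(off1 < 150L)
  base <- substr(rd$seq1[covering], off1[covering] + 1L, off1[covering] + 1L)
  n <- length(covering)
  k <- sum(base == altb)
  expect_true(k >= qbinom(0.005, n, 0.18) && k <= qbinom(0.995, n, 0.18))
})

test_that("fragment starts are uniform over the circle", {
  cfg <- sim_config(coverage = 100, seed = 9L)
  rd <- simulate_reads(mref$seq, cfg = cfg)
  bins <- cut(rd$frag_start, breaks = seq(0, 16569, length.out = 11L))
  expect_gt(chisq.test(table(bins))$p.value, 0.001)
})

test_that("simulation output is byte-identical under a fixed seed", {
  cfg <- sim_config(coverage = 20, seed = 10L)
  ds1 <- simulate_dataset(mprofiles[[2L]], mref, cfg, hp_track = mhp)
  ds2 <- simulate_dataset(mprofiles[[2L]], mref, cfg, hp_track = mhp)
  expect_identical(ds1$reads, ds2$reads)
  expect_identical(ds1$truth, ds2$truth)

  d <- withr::local_tempdir()
  p1 <- file.path(d, "a"); p2 <- file.path(d, "b")
  write_reads_fastq(ds1$reads, p1)
  write_reads_fastq(ds2$reads, p2)
  expect_identical(readLines(paste0(p1, "_R1.fastq")),
                   readLines(paste0(p2, "_R1.fastq")))
  v1 <- file.path(d, "a.vcf"); v2 <- file.path(d, "b.vcf")
  write_truth(ds1$truth, v1)
  write_truth(ds2$truth, v2)
  expect_identical(readLines(v1), readLines(v2))

  back <- read_reads_fastq(p1)
  expect_equal(back$seq1, ds1$reads$seq1)
  expect_equal(back$qual2, ds1$reads$qual2)
})

test_that("truth sets round-trip through VCF", {
  cfg <- sim_config(coverage = 10, seed = 11L)
  inj <- inject_heteroplasmies(mref$seq, cfg, hp_track = mhp)
  f <- withr::local_tempfile(fileext = ".vcf")
  write_truth(inj$truth, f)
  expect_equal(sum(!grepl("^#", readLines(f))), 43L)
  back <- read_variant_vcf(f)
  ord <- order(inj$truth$pos, inj$truth$ref, inj$truth$alt)
  expect_equal(back$pos, inj$truth$pos[ord])
  expect_equal(back$ref, inj$truth$ref[ord])
  expect_equal(back$alt, inj$truth$alt[ord])
  expect_equal(back$vaf, inj$truth$vaf[ord], tolerance = 1e-5)

  empty <- inj$truth[0, ]
  write_truth(empty, f)
  expect_true(all(grepl("^#", readLines(f))))

  # an anchored insertion record, e.g. A > AC
  ins <- data.frame(pos = 302L, ref = substr(mref$seq, 302, 302),
                    alt = paste0(substr(mref$seq, 302, 302), "C"),
                    vaf = 0.06, type = "INS")
  write_truth(ins, f)
  rec <- read_variant_vcf(f)
  expect_equal(nchar(rec$alt) - nchar(rec$ref), 1L)
  expect_equal(rec$pos, 302L)
})
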