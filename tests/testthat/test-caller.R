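test_that("pileup counts depth, strands, deletions and insertions", {
  ref <- mref
  a <- make_aln(100L, seq = substr(ref$seq, 100, 249))
  pu <- build_pileup(a, ref)
  expect_equal(pu$depth[100:249], rep(1L, 150))
  expect_equal(pu$depth[99], 0L)
  expect_equal(pu$depth[250], 0L)

  # 1-base deletion at position 150: 50M then 1D then 99M from start 100
  b <- make_aln(100L, cigar = "50M1D99M", seq = substr(ref$seq, 100, 149),
                qual = strrep("?", 149L))
  b$seq <- paste0(substr(ref$seq, 100, 149), substr(ref$seq, 151, 249))
  pu <- build_pileup(b, ref)
  expect_equal(pu$del_span[150], 1L)
  expect_equal(pu$dels$anchor, 149L)
  expect_equal(pu$dels$dlen, 1L)
  expect_equal(pu$depth[150], 1L)

  # two reads, opposite strands, same base
  two <- rbind(make_aln(500L, "+", seq = substr(ref$seq, 500, 649)),
               make_aln(500L, "-", read_id = "r2",
                        seq = substr(ref$seq, 500, 649)))
  pu <- build_pileup(two, ref)
  col <- pileup_column(pu, 500L)
  base <- substr(ref$seq, 500, 500)
  row <- col$alleles[col$alleles$allele == base, ]
  expect_equal(c(row$fwd, row$rev), c(1L, 1L))

  # insertions key to their anchor
  d <- make_aln(100L, cigar = "50M2I100M",
                seq = paste0(substr(ref$seq, 100, 149), "GG",
                             substr(ref$seq, 150, 249)),
                qual = strrep("?", 152L))
  pu <- build_pileup(d, ref)
  expect_equal(pu$inss$anchor, 149L)
  expect_equal(pu$inss$seq, "GG")

  # alignments must stay inside the canonical reference
  e <- make_aln(16569L, cigar = "150M")
  expect_error(build_pileup(e, ref), "outside")
})

test_that("call_site applies the VAF and strand thresholds at the boundary", {
  cfg <- caller_config()
  col <- make_column(1000L, 2000L, allele_df(c("A", "G"), c(970, 30), c(970, 30)))
  out <- call_site(col, "A", cfg)
  expect_equal(nrow(out), 1L)
  expect_equal(out$allele, "G")
  expect_equal(out$vaf, 0.030)
  expect_equal(out$klass, "HETEROPLASMY")

  col59 <- make_column(1000L, 2000L, allele_df(c("A", "G"), c(971, 30), c(970, 29)))
  expect_equal(nrow(call_site(col59, "A", cfg)), 0L)  # 59/2000 < 3%

  onestrand <- make_column(1000L, 2000L, allele_df(c("A", "G"), c(920, 80), c(1000, 0)))
  expect_equal(nrow(call_site(onestrand, "A", cfg)), 0L)

  low <- make_column(1000L, 5L, allele_df("G", 3, 2))
  nc <- call_site(low, "A", cfg)
  expect_equal(nc$filters, "NO_CALL")
})

test_that("multiallelic sites report every passing allele", {
  col <- make_column(3666L, 1000L,
                     allele_df(c("G", "A", "C"), c(3, 380, 118), c(3, 379, 117)))
  out <- call_site(col, "G", caller_config())
  expect_equal(nrow(out), 2L)
  expect_equal(sort(out$allele), c("A", "C"))
  expect_equal(sum(out$vaf), 0.994, tolerance = 1e-9)
  expect_true(all(out$klass == "HETEROPLASMY"))
})

test_that("call_site matches a brute-force threshold oracle for depths <= 200", {
  cfg <- caller_config(min_depth = 1L)
  oracle <- function(col, ref_base) {
    hits <- list()
    for (i in seq_len(nrow(col$alleles))) {
      a <- col$alleles[i, ]
      if (a$allele == ref_base) next
      vaf <- (a$fwd + a$rev) / col$depth
      if (vaf >= cfg$vaf_min - 1e-12 && a$fwd >= cfg$min_reads_per_strand &&
          a$rev >= cfg$min_reads_per_strand)
        hits[[length(hits) + 1L]] <- data.frame(
          allele = a$allele, vaf = vaf,
          klass = if (vaf >= cfg$homoplasmy_vaf - 1e-12) "HOMOPLASMY"
                  else "HETEROPLASMY")
    }
    if (length(hits)) do.call(rbind, hits)
    else data.frame(allele = character(0), vaf = numeric(0),
                    klass = character(0))
  }
  set.seed(41)
  for (depth in 1:200) {
    counts <- as.vector(rmultinom(1, depth, prob = c(0.85, 0.06, 0.05, 0.04)))
    fwd <- rbinom(4, counts, 0.5)
    al <- allele_df(c("A", "C", "G", "T"), fwd, counts - fwd)
    al <- al[counts > 0, , drop = FALSE]
    col <- make_column(50L, depth, al)
    got <- call_site(col, "A", cfg)
    want <- oracle(col, "A")
    expect_equal(got$allele, want$allele)
    expect_equal(got$vaf, want$vaf)
    expect_equal(got$klass, want$klass)
  }
})

test_that("raising the VAF threshold never adds calls", {
  set.seed(42)
  for (i in 1:50) {
    depth <- sample(10:200, 1)
    counts <- as.vector(rmultinom(1, depth, prob = c(0.7, 0.1, 0.1, 0.1)))
    fwd <- rbinom(4, counts, 0.5)
    col <- make_column(1L, depth, allele_df(c("A", "C", "G", "T"), fwd,
                                            counts - fwd))
    lo <- call_site(col, "A", caller_config(vaf_min = 0.03, min_depth = 1L))
    hi <- call_site(col, "A", caller_config(vaf_min = 0.10, min_depth = 1L))
    expect_true(all(hi$allele %in% lo$allele))
    # allele fractions at a site never sum above 1
    expect_lte(sum(lo$vaf), 1 + 1e-9)
  }
})

test_that("homoplasmic alt classification leaves no reference-allele call", {
  col <- make_column(7L, 2000L, allele_df(c("A", "G"), c(10, 990), c(10, 990)))
  out <- call_site(col, "A", caller_config())
  expect_equal(out$allele, "G")
  expect_equal(out$klass, "HOMOPLASMY")
})

test_that("call_sample is clean on variant-free reads and recovers one SNV", {
  cfg <- sim_config(coverage = 60, error_rate = 0, n_snv = 0, n_indel = 0,
                    seed = 15L)
  rd <- simulate_reads(mref$seq, cfg = cfg)
  aln <- split_origin_spanning(map_sample(rd, build_index(mref)), mref$L)
  calls <- call_sample(aln, mref, caller_config())
  expect_equal(nrow(calls), 0L)

  pos <- 9000L
  refb <- substr(mref$seq, pos, pos)
  altb <- setdiff(c("A", "C", "G", "T"), refb)[1L]
  truth <- data.frame(pos = pos, ref = refb, alt = altb, vaf = 0.18)
  cfg2 <- sim_config(coverage = 1000, seed = 16L)
  rd2 <- simulate_reads(mref$seq, truth = truth, cfg = cfg2)
  aln2 <- split_origin_spanning(map_sample(rd2, build_index(mref)), mref$L)
  calls2 <- call_sample(aln2, mref, caller_config())
  het <- calls2[calls2$klass == "HETEROPLASMY", ]
  expect_equal(nrow(het), 1L)
  expect_equal(het$pos, pos)
  expect_equal(het$alt, altb)
  k <- round(het$vaf * het$depth)
  expect_true(k >= qbinom(0.005, het$depth, 0.18) &&
              k <= qbinom(0.995, het$depth, 0.18))

  expect_warning(empty <- call_sample(aln2[0, ], mref), "no mapped")
  expect_equal(nrow(empty), 0L)
})
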