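idx <- build_index(mref)

test_that("k-mer index covers the extended reference", {
  toy <- reference_bundle("toy", "ACGTACGTAAAGGTTTAAG", ext_len = 4L)
  ti <- build_index(toy, k = 11L)
  expect_gte(length(index_lookup(ti, substr(toy$ext_seq, 1, 11))), 1L)
  expect_error(build_index(toy, k = 5L), "k must be >= 11")

  # all offsets except k-mers crossing the N at 3107 are indexed
  n_kmers <- (mref$L + 300L) - 21L + 1L
  expect_equal(index_n_offsets(idx), n_kmers - 21L)
  expect_length(index_lookup(idx, strrep("A", 21L)), 0L)
})

test_that("exact reads map back to their origin", {
  pair <- data.frame(
    read_id = "p1",
    seq1 = substr(mref$ext_seq, 100, 249), qual1 = strrep("?", 150),
    seq2 = rc(substr(mref$ext_seq, 300, 449)), qual2 = strrep("?", 150),
    stringsAsFactors = FALSE)
  aln <- map_read_pair(pair, idx)
  expect_true(all(aln$mapped))
  expect_equal(aln$start[aln$end == 1L], 100)
  expect_equal(aln$cigar[aln$end == 1L], "150M")
  expect_equal(aln$strand, c("+", "-"))
  expect_true(all(aln$proper))
})

test_that("origin-spanning reads map across the junction and split in two", {
  pair <- data.frame(
    read_id = "junction",
    seq1 = substr(mref$ext_seq, 16500, 16649), qual1 = strrep("?", 150),
    seq2 = rc(substr(mref$ext_seq, 16700, 16849)), qual2 = strrep("?", 150),
    stringsAsFactors = FALSE)
  aln <- map_read_pair(pair, idx)
  expect_true(all(aln$mapped))
  expect_equal(sort(aln$start), c(131, 16500))
  sp <- split_origin_spanning(aln, mref$L)
  r1 <- sp[sp$end == 1L, ]
  expect_equal(nrow(r1), 2L)
  expect_equal(r1$start, c(1L, 16500L))
  expect_equal(r1$cigar, c("80M", "70M"))
  # base conservation
  expect_equal(sum(cpp_cigar_ref_len(r1$cigar)), 150L)
  expect_equal(paste0(r1$seq[2], r1$seq[1]), pair$seq1)
})

test_that("sequence sharing no k-mer with the reference stays unmapped", {
  set.seed(21)
  repeat {
    s <- paste(sample(c("A", "C", "G", "T"), 150, replace = TRUE), collapse = "")
    kmers <- substring(s, 1:130, 21:150)
    kmers <- c(kmers, substring(rc(s), 1:130, 21:150))
    if (all(vapply(kmers, function(k) length(index_lookup(idx, k)) == 0L,
                   logical(1)))) break
  }
  pair <- data.frame(read_id = "rnd", seq1 = s, qual1 = strrep("?", 150),
                     seq2 = s, qual2 = strrep("?", 150),
                     stringsAsFactors = FALSE)
  aln <- map_read_pair(pair, idx)
  expect_false(any(aln$mapped))
})

test_that("cigar splitting keeps junction insertions with their anchor", {
  a <- make_aln(start = 16569L, cigar = "1M1I149M",
                seq = strrep("A", 151L), qual = strrep("?", 151L))
  sp <- split_origin_spanning(a, 16569L)
  expect_equal(nrow(sp), 2L)
  expect_equal(sp$cigar[sp$start == 16569L], "1M1I")
  expect_equal(sp$cigar[sp$start == 1L], "149M")
  expect_equal(sum(cpp_cigar_read_len(sp$cigar)), 151L)
  expect_equal(sum(cpp_cigar_ref_len(sp$cigar)), 150L)

  # non-spanning alignments are untouched
  b <- make_aln(start = 100L)
  expect_identical(split_origin_spanning(b, 16569L), b)
})

test_that("split conserves reference and read bases for random alignments", {
  set.seed(31)
  for (i in 1:50) {
    n_ops <- sample(1:5, 1)
    ops <- sample(c("M", "I", "D"), n_ops, replace = TRUE, prob = c(.7, .15, .15))
    ops[1] <- "M"; ops[length(ops)] <- "M"
    lens <- sample(5:80, n_ops, replace = TRUE)
    cig <- paste0(lens, ops, collapse = "")
    rl <- sum(lens[ops != "D"])
    span <- sum(lens[ops != "I"])
    start <- sample((16569 - span + 2):16568, 1)
    a <- make_aln(start = start, cigar = cig, seq = strrep("A", rl),
                  qual = strrep("?", rl))
    sp <- split_origin_spanning(a, 16569L)
    expect_equal(sum(cpp_cigar_ref_len(sp$cigar)), span)
    expect_equal(sum(cpp_cigar_read_len(sp$cigar)), rl)
    expect_equal(paste(sp$seq[order(sp$start == 1L)], collapse = ""), a$seq)
  }
})

test_that("duplicate pairs are marked, keeping the best copy", {
  two <- rbind(
    make_aln(100L, read_id = "a", mate_start = 400L, mate_strand = "-"),
    make_aln(400L, "-", read_id = "a", end = 2L, mate_start = 100L,
             mate_strand = "+"),
    make_aln(100L, read_id = "b", qual = strrep("I", 150L),
             mate_start = 400L, mate_strand = "-"),
    make_aln(400L, "-", read_id = "b", end = 2L, qual = strrep("I", 150L),
             mate_start = 100L, mate_strand = "+"))
  md <- mark_duplicates(two)
  expect_equal(sort(unique(md$read_id[md$is_duplicate])), "a")  # b has higher quality

  distinct <- rbind(
    make_aln(100L, read_id = "a", mate_start = 400L, mate_strand = "-"),
    make_aln(400L, "-", read_id = "a", end = 2L, mate_start = 100L,
             mate_strand = "+"),
    make_aln(200L, read_id = "b", mate_start = 500L, mate_strand = "-"),
    make_aln(500L, "-", read_id = "b", end = 2L, mate_start = 200L,
             mate_strand = "+"))
  expect_false(any(mark_duplicates(distinct)$is_duplicate))

  five <- do.call(rbind, lapply(1:5, function(i) {
    s <- if (i <= 3L) 100L else 100L + i * 50L
    rbind(make_aln(s, read_id = paste0("r", i), mate_start = s + 300L,
                   mate_strand = "-"),
          make_aln(s + 300L, "-", read_id = paste0("r", i), end = 2L,
                   mate_start = s, mate_strand = "+"))
  }))
  md5 <- mark_duplicates(five)
  expect_equal(length(unique(md5$read_id[md5$is_duplicate])), 2L)
})

test_that("down-sampling approximates the target coverage and is seeded", {
  cfg <- sim_config(coverage = 60, error_rate = 0, n_snv = 0, n_indel = 0,
                    seed = 12L)
  rd <- simulate_reads(mref$seq, cfg = cfg)
  aln <- map_sample(rd, idx)
  ds <- downsample(aln, target_cov = 30, mref$L, seed = 1L)
  expect_true(all(ds$read_id %in% aln$read_id))
  cov <- alignment_coverage(ds, mref$L)
  expect_lt(abs(cov - 30) / 30, 0.05)
  ds2 <- downsample(aln, target_cov = 30, mref$L, seed = 1L)
  expect_identical(ds, ds2)
  # below-target input is returned unchanged
  expect_identical(downsample(aln, target_cov = 2000, mref$L, seed = 1L), aln)
})

test_that("error-free simulated reads recover their true origin", {
  cfg <- sim_config(coverage = 60, error_rate = 0, n_snv = 0, n_indel = 0,
                    seed = 13L)
  ds <- simulate_dataset(mprofiles[[5L]], mref, cfg, hp_track = mhp)
  aln <- map_sample(ds$reads, idx)
  a1 <- aln[aln$end == 1L, ]
  a2 <- aln[aln$end == 2L, ]
  hit1 <- a1$mapped & a1$start == ds$reads$pos1 & a1$strand == "+"
  hit2 <- a2$mapped & a2$start == ds$reads$pos2 & a2$strand == "-"
  expect_gte(mean(c(hit1, hit2)), 0.999)
})

test_that("circular remapping keeps D-loop coverage near the genome mean", {
  cfg <- sim_config(coverage = 80, seed = 14L)
  ds <- simulate_dataset(mprofiles[[8L]], mref, cfg, hp_track = mhp)
  aln <- map_sample(ds$reads, idx)
  aln <- split_origin_spanning(aln, mref$L)
  depth <- alignment_depth(aln, mref$L)
  dloop <- c(1:300, 16270:16569)
  expect_gte(mean(depth[dloop]) / mean(depth), 0.90)
})
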