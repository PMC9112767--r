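call_row <- function(pos, ref, alt, vaf, klass = NULL, type = NULL,
                     depth = 2000L) {
  if (is.null(type))
    type <- if (nchar(ref) == nchar(alt)) "SNV"
            else if (nchar(ref) < nchar(alt)) "INS" else "DEL"
  if (is.null(klass)) klass <- if (vaf >= 0.97) "HOMOPLASMY" else "HETEROPLASMY"
  data.frame(pos = pos, ref = ref, alt = alt, vaf = vaf, depth = depth,
             fwd = round(vaf * depth / 2), rev = round(vaf * depth / 2),
             meanq = 30, type = type, klass = klass, filters = "",
             iteration = 1L, stringsAsFactors = FALSE)
}

test_that("consensus applies homoplasmies and major alleles only", {
  cons0 <- build_consensus(mref, empty_calls())
  expect_identical(cons0$consensus_seq, mref$seq)
  expect_equal(consensus_forward(cons0, c(1L, 8000L, 16569L)),
               c(1L, 8000L, 16569L))

  c73 <- call_row(73L, "A", "G", 0.999)
  cons <- build_consensus(mref, c73)
  d <- which(strsplit(cons$consensus_seq, "")[[1L]] !=
               strsplit(mref$seq, "")[[1L]])
  expect_equal(d, 73L)

  minor <- call_row(73L, "A", "G", 0.40)
  expect_identical(build_consensus(mref, minor)$consensus_seq, mref$seq)
})

test_that("consensus insertions shift downstream coordinates", {
  rb <- substr(mref$seq, 302, 302)
  ins <- call_row(302L, rb, paste0(rb, "CC"), 0.74)
  cons <- build_consensus(mref, ins)
  expect_equal(cons$Lc, mref$L + 2L)
  expect_equal(consensus_forward(cons, 302L), 302L)
  expect_equal(consensus_forward(cons, 303L), 305L)
  inv <- consensus_inverse(cons, 5002L)
  expect_equal(inv$rcrs_pos, 5000L)
  expect_false(inv$in_insertion)
  # inserted bases map to the anchor
  inv2 <- consensus_inverse(cons, 303L)
  expect_equal(inv2$rcrs_pos, 302L)
  expect_true(inv2$in_insertion)

  over <- rbind(call_row(500L, substr(mref$seq, 500, 502), substr(mref$seq, 500, 500), 0.99),
                call_row(501L, substr(mref$seq, 501, 501), "A", 0.99))
  expect_error(build_consensus(mref, over), "overlapping")
})

test_that("forward/inverse mapping round-trips for random edit sets", {
  set.seed(51)
  for (rep in 1:3) {
    pos <- sort(sample(seq(100L, 16000L, by = 50L), 6L))
    edits <- do.call(rbind, lapply(seq_along(pos), function(i) {
      p <- pos[i]
      rb <- substr(mref$seq, p, p)
      kind <- sample(c("SNV", "INS", "DEL"), 1L)
      if (kind == "SNV") call_row(p, rb, setdiff(c("A","C","G","T"), rb)[1], 0.99)
      else if (kind == "INS") call_row(p, rb, paste0(rb, "TT"), 0.99)
      else call_row(p, substr(mref$seq, p, p + 2L), rb, 0.99)
    }))
    cons <- build_consensus(mref, edits)
    deleted <- unlist(mapply(
      function(s, e) seq(s, e), cons$deletions$rcrs_start,
      cons$deletions$rcrs_end, SIMPLIFY = FALSE))
    keep <- setdiff(seq_len(mref$L), deleted)
    fwd <- consensus_forward(cons, keep)
    expect_false(anyNA(fwd))
    inv <- consensus_inverse(cons, fwd)
    expect_equal(inv$rcrs_pos, keep)
    expect_false(any(inv$in_insertion))
    # deleted positions have no consensus image
    if (length(deleted))
      expect_true(all(is.na(consensus_forward(cons, deleted))))
    # consensus length accounting
    expect_equal(cons$Lc, mref$L + sum(nchar(edits$alt) - nchar(edits$ref)))
  }
})

test_that("liftover re-expresses alleles against the reference", {
  cons0 <- build_consensus(mref, empty_calls())
  c1 <- call_row(5000L, substr(mref$seq, 5000, 5000), "T", 0.10)
  lifted <- lift_to_reference(c1, cons0, mref)
  expect_equal(lifted$pos, 5000L)
  expect_equal(lifted$vaf, 0.10)

  # consensus carries G at 73 (edit A>G); a 4% G>A call flips roles
  cons <- build_consensus(mref, call_row(73L, "A", "G", 0.999))
  c2 <- call_row(73L, "G", "A", 0.04)
  c2$klass <- "HETEROPLASMY"
  lf <- lift_to_reference(c2, cons, mref)
  expect_equal(lf$ref, "A")
  expect_equal(lf$alt, "G")
  expect_equal(lf$vaf, 0.96)
  expect_equal(lf$minor_vaf, 0.04)
  expect_true(has_filter(lf$filters, "ALLELE_SWITCH"))
  expect_equal(lf$klass, "HETEROPLASMY")

  # a call inside a consensus insertion anchors to the insertion site
  rb <- substr(mref$seq, 302, 302)
  consI <- build_consensus(mref, call_row(302L, rb, paste0(rb, "CC"), 0.74))
  c3 <- call_row(303L, "C", "A", 0.05)
  c3$klass <- "HETEROPLASMY"
  lf3 <- lift_to_reference(c3, consI, mref)
  expect_equal(lf3$pos, 302L)
  expect_true(has_filter(lf3$filters, "IN_CONSENSUS_INS"))

  # downstream positions shift back through the insertion
  c4 <- call_row(5002L, substr(mref$seq, 5000, 5000), "T", 0.08)
  c4$klass <- "HETEROPLASMY"
  expect_equal(lift_to_reference(c4, consI, mref)$pos, 5000L)
})

test_that("exact-alignment validation merges with >= 5 base overlap", {
  tile <- function(starts, len = 150L) {
    do.call(rbind, lapply(seq_along(starts), function(i)
      make_aln(starts[i], read_id = paste0("t", i),
               seq = substr_circ(mref$seq, starts[i], len))))
  }
  # full tiling with 50-base overlaps covers the circle
  full <- tile(seq(1L, 16569L, by = 100L))
  v <- validate_consensus(full, mref$L)
  expect_true(v$fully_covered)
  expect_equal(nrow(v$uncovered), 0L)

  # remove the tiles over 1000-1100
  gap <- tile(setdiff(seq(1L, 16569L, by = 100L), c(901L, 1001L, 1101L)))
  vg <- validate_consensus(gap, mref$L)
  expect_false(vg$fully_covered)
  expect_true(any(vg$uncovered$start <= 1050 & vg$uncovered$end >= 1050))

  # two exact reads overlapping by 3 bases are not merged
  two <- tile(c(1000L, 1147L))
  vt <- validate_consensus(two, mref$L)
  expect_equal(nrow(vt$merged), 2L)
  # overlapping by 5 they merge
  three <- tile(c(1000L, 1145L))
  expect_equal(nrow(validate_consensus(three, mref$L)$merged), 1L)
})

test_that("second iteration absorbs homoplasmies for pure-profile samples", {
  # 400x: the 3% VAF floor (12 reads) is unreachable by 1% sequencing error,
  # so any residual call would be a genuine pipeline defect
  cfg <- sim_config(coverage = 400, n_snv = 0, n_indel = 0, seed = 17L)
  for (i in c(3L, 19L)) {  # one small and one large profile
    ds <- simulate_dataset(mprofiles[[i]], mref, cfg, hp_track = mhp)
    res <- mito_pipeline(ds$reads, mref, seed = 17L)
    # first iteration sees the profile SNVs as homoplasmies
    expect_gte(sum(res$calls1$klass == "HOMOPLASMY"),
               nrow(mprofiles[[i]]$snvs) - 1L)
    # the consensus absorbs them: no homoplasmy and no heteroplasmy left
    expect_equal(sum(res$calls2$klass == "HOMOPLASMY"), 0L)
    expect_equal(sum(res$calls2$klass == "HETEROPLASMY"), 0L)
    expect_true(res$validation$fully_covered)
  }
})
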