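#' Simulation configuration
#'
#' Holds the study conditions for the paired-end mitochondrial read
#' simulator: 150 bp read pairs with an independent per-base substitution
#' error of 0.01, and per sample 35 SNV + 8 INDEL heteroplasmies injected at
#' 15-20% variant allele fraction (mean 18%).
#'
#' @param coverage target fold coverage over the mitochondrial genome.
#' @param read_len read length in bases.
#' @param error_rate i.i.d. per-base substitution error probability.
#' @param vaf_low,vaf_high bounds of the injected VAF distribution.
#' @param n_snv,n_indel number of injected SNV / INDEL heteroplasmies.
#' @param frag_mean,frag_sd fragment length distribution (normal, truncated
#'   to `[2 * read_len, 1000]`).
#' @param seed integer seed; every draw the simulator makes is a pure
#'   function of the configuration, so identical configurations give
#'   byte-identical reads and truth sets.
#' @return a `mito_sim_config` list.
#' @export
sim_config <- function(coverage = 2000, read_len = 150L, error_rate = 0.01,
                       vaf_low = 0.15, vaf_high = 0.20, n_snv = 35L,
                       n_indel = 8L, frag_mean = 350, frag_sd = 50,
                       seed = 1L) {
  stopifnot(coverage > 0, read_len >= 30L,
            error_rate >= 0, error_rate < 0.5,
            vaf_low > 0, vaf_high < 1, vaf_low <= vaf_high,
            n_snv >= 0L, n_indel >= 0L, frag_mean >= 2 * read_len,
            seed == as.integer(seed), abs(seed) < 2^31 - 10)
  structure(list(coverage = coverage, read_len = as.integer(read_len),
                 error_rate = error_rate, vaf_low = vaf_low,
                 vaf_high = vaf_high, n_snv = as.integer(n_snv),
                 n_indel = as.integer(n_indel), frag_mean = frag_mean,
                 frag_sd = frag_sd, seed = as.integer(seed)),
            class = "mito_sim_config")
}

#' Synthetic haplogroup panel
#'
#' Thirty deterministic haplogroup profiles, each a set of homoplasmic SNVs
#' relative to the reference, labelled with macro-haplogroup letters. These
#' are synthetic stand-ins for phylogenetic haplogroups: each profile carries
#' 5-40 defining SNVs drawn (once, with a fixed internal constant) from
#' positions outside homopolymer tracts, so simulated samples built on
#' different profiles are distinguishable by their homoplasmies.
#'
#' @param ref a `mito_ref` bundle.
#' @param n_profiles number of profiles (max 30).
#' @return list of `mito_profile` objects with fields `name` and
#'   `snvs` (data.frame pos/ref/alt).
#' @export
haplogroup_profiles <- function(ref = mito_reference(), n_profiles = 30L) {
  labels <- c("A", "B", "C", "D", "E", "F", "G", "H", "HV", "I", "J", "K",
              "L0", "L1", "L2", "L3", "L4", "L5", "L6", "M", "N", "P", "Q",
              "R", "S", "T", "U", "V", "W", "X")
  stopifnot(n_profiles >= 1L, n_profiles <= length(labels))
  chars <- strsplit(ref$seq, "", fixed = TRUE)[[1L]]
  hp <- find_homopolymer_regions(ref$seq)
  blocked <- rep(FALSE, ref$L)
  if (nrow(hp)) for (i in seq_len(nrow(hp)))
    blocked[max(1L, hp$start[i] - 5L):min(ref$L, hp$end[i] + 5L)] <- TRUE
  blocked[chars == "N"] <- TRUE
  pool <- which(!blocked)
  bases <- c("A", "C", "G", "T")
  with_seed(20220517L, {
    lapply(seq_len(n_profiles), function(i) {
      k <- sample(5:40, 1L)
      pos <- sort(sample(pool, k))
      ref_al <- chars[pos]
      alt <- vapply(ref_al, function(b) sample(setdiff(bases, b), 1L),
                    character(1), USE.NAMES = FALSE)
      structure(list(name = labels[i],
                     snvs = data.frame(pos = pos, ref = ref_al, alt = alt,
                                       stringsAsFactors = FALSE)),
                class = "mito_profile")
    })
  })
}

#' Apply a haplogroup profile to the reference (homoplasmic backbone)
#'
#' @param ref a `mito_ref` bundle.
#' @param profile a `mito_profile`.
#' @return nucleotide string of the sample's homoplasmic genome.
#' @export
build_sample_genome <- function(ref, profile) {
  chars <- strsplit(ref$seq, "", fixed = TRUE)[[1L]]
  sn <- profile$snvs
  if (nrow(sn)) {
    if (anyDuplicated(sn$pos)) stop("duplicate profile positions")
    bad <- which(chars[sn$pos] != sn$ref)
    if (length(bad))
      stop("reference allele mismatch at position ", sn$pos[bad[1L]],
           ": expected ", sn$ref[bad[1L]], ", reference has ",
           chars[sn$pos[bad[1L]]])
    chars[sn$pos] <- sn$alt
  }
  paste(chars, collapse = "")
}

#' Left-align and trim a variant to its parsimonious representation
#'
#' @param genome nucleotide string the alleles are expressed against.
#' @param pos,ref,alt anchored VCF-style variant.
#' @return list(pos, ref, alt).
#' @export
normalize_variant <- function(genome, pos, ref, alt) {
  # trim identical trailing bases, shifting left through the genome
  repeat {
    lr <- nchar(ref); la <- nchar(alt)
    if (lr > 1L && la > 1L &&
        substr(ref, lr, lr) == substr(alt, la, la)) {
      ref <- substr(ref, 1L, lr - 1L)
      alt <- substr(alt, 1L, la - 1L)
    } else if ((lr == 1L || la == 1L) && lr != la && pos > 1L &&
               substr(ref, lr, lr) == substr(alt, la, la)) {
      prev <- substr(genome, pos - 1L, pos - 1L)
      ref <- paste0(prev, substr(ref, 1L, lr - 1L))
      alt <- paste0(prev, substr(alt, 1L, la - 1L))
      pos <- pos - 1L
    } else break
  }
  # trim identical leading bases while both alleles keep >= 1 base
  while (nchar(ref) > 1L && nchar(alt) > 1L &&
         substr(ref, 1L, 1L) == substr(alt, 1L, 1L)) {
    ref <- substr(ref, 2L, nchar(ref)); alt <- substr(alt, 2L, nchar(alt))
    pos <- pos + 1L
  }
  list(pos = pos, ref = ref, alt = alt)
}

#' Classify a variant as SNV, INS or DEL from its allele lengths
#' @param ref,alt allele strings.
#' @export
variant_type <- function(ref, alt) {
  ifelse(nchar(ref) == nchar(alt), "SNV",
         ifelse(nchar(ref) < nchar(alt), "INS", "DEL"))
}

#' Inject heteroplasmic variants into a sample genome
#'
#' Chooses `n_snv` SNV and `n_indel` INDEL sites uniformly at random
#' (outside homopolymer tracts by default, since slippage there is a known
#' error mode) and assigns each a VAF drawn uniformly on
#' `[vaf_low, vaf_high]`; under the default 15-20% range one site is nudged
#' so the sample mean is exactly 0.18.
#'
#' @param genome backbone nucleotide string.
#' @param cfg a `mito_sim_config`.
#' @param hp_track optional `mito_track` (or data.frame of intervals) of
#'   homopolymer regions to exclude.
#' @param exclude_pos additional positions to avoid (e.g. the haplogroup
#'   profile's own SNV sites), so truth alleles stay expressed against the
#'   canonical reference.
#' @param min_gap minimum distance between injected sites.
#' @return list with `alt_genome` (all variants applied) and `truth`
#'   (data.frame pos/ref/alt/vaf/type, left-aligned, sorted).
#' @export
inject_heteroplasmies <- function(genome, cfg, hp_track = NULL,
                                  exclude_pos = integer(0), min_gap = 25L) {
  Lg <- nchar(genome)
  n <- cfg$n_snv + cfg$n_indel
  if (n == 0L)
    return(list(alt_genome = genome,
                truth = data.frame(pos = integer(0), ref = character(0),
                                   alt = character(0), vaf = numeric(0),
                                   type = character(0), stringsAsFactors = FALSE)))
  chars <- strsplit(genome, "", fixed = TRUE)[[1L]]
  blocked <- rep(FALSE, Lg)
  iv <- if (inherits(hp_track, "mito_track")) hp_track$intervals else hp_track
  if (!is.null(iv) && nrow(iv))
    for (i in seq_len(nrow(iv)))
      blocked[max(1L, iv$start[i] - 5L):min(Lg, iv$end[i] + 5L)] <- TRUE
  for (p in exclude_pos)
    blocked[max(1L, p - 5L):min(Lg, p + 5L)] <- TRUE
  blocked[chars == "N"] <- TRUE
  blocked[c(1:10, (Lg - 10):Lg)] <- TRUE  # keep indel anchoring away from the origin
  bases <- c("A", "C", "G", "T")
  with_seed(cfg$seed, {
    pool <- which(!blocked)
    pos <- integer(0)
    pool <- sample(pool)
    for (p in pool) {
      if (length(pos) == n) break
      if (all(abs(pos - p) >= min_gap)) pos <- c(pos, p)
    }
    if (length(pos) < n)
      stop("could not place ", n, " variants with min_gap ", min_gap)
    pos <- sort(pos)
    is_indel <- rep(FALSE, n)
    is_indel[sample(n, cfg$n_indel)] <- TRUE
    ref <- alt <- character(n)
    for (i in seq_len(n)) {
      p <- pos[i]
      if (!is_indel[i]) {
        ref[i] <- chars[p]
        alt[i] <- sample(setdiff(bases, chars[p]), 1L)
      } else if (runif(1) < 0.5) {  # insertion after anchor
        ins <- paste(sample(bases, sample(1:3, 1L), replace = TRUE),
                     collapse = "")
        ref[i] <- chars[p]
        alt[i] <- paste0(chars[p], ins)
      } else {                      # deletion of 1-3 bases after anchor
        dl <- sample(1:3, 1L)
        ref[i] <- paste(chars[p:(p + dl)], collapse = "")
        alt[i] <- chars[p]
      }
    }
    vaf <- runif(n, cfg$vaf_low, cfg$vaf_high)
    if (isTRUE(all.equal(c(cfg$vaf_low, cfg$vaf_high), c(0.15, 0.20)))) {
      # uniform(0.15, 0.20) has mean 0.175; nudge sites (starting from the
      # last) until the sample mean is 0.18
      target <- 0.18
      for (i in rev(seq_len(n))) {
        delta <- (target - mean(vaf)) * n
        vaf[i] <- min(cfg$vaf_high, max(cfg$vaf_low, vaf[i] + delta))
        if (abs(mean(vaf) - target) < 1e-12) break
      }
    }
    truth <- data.frame(pos = pos, ref = ref, alt = alt, vaf = vaf,
                        type = variant_type(ref, alt),
                        stringsAsFactors = FALSE)
    for (i in seq_len(n)) {
      nv <- normalize_variant(genome, truth$pos[i], truth$ref[i], truth$alt[i])
      truth$pos[i] <- nv$pos; truth$ref[i] <- nv$ref; truth$alt[i] <- nv$alt
    }
    truth <- truth[order(truth$pos), , drop = FALSE]
    rownames(truth) <- NULL
    alt_genome <- apply_edits(genome, truth)
    list(alt_genome = alt_genome, truth = truth)
  })
}

# apply anchored edits (sorted by position, non-overlapping) to a sequence
apply_edits <- function(genome, edits) {
  if (nrow(edits) == 0L) return(genome)
  out <- character(0)
  cur <- 1L
  for (i in seq_len(nrow(edits))) {
    p <- edits$pos[i]
    stopifnot(substr(genome, p, p + nchar(edits$ref[i]) - 1L) == edits$ref[i])
    out <- c(out, substr(genome, cur, p - 1L), edits$alt[i])
    cur <- p + nchar(edits$ref[i])
  }
  paste0(paste(out, collapse = ""), substr(genome, cur, nchar(genome)))
}

#' Simulate paired-end reads from a circular mitochondrial genome
#'
#' Fragments are drawn uniformly on the circle (they may span the origin);
#' each fragment carries each overlapping truth variant independently with
#' probability equal to that variant's VAF, then i.i.d. substitution errors
#' are applied. Base qualities are constant Q30.
#'
#' @param backbone homoplasmic sample genome (string).
#' @param alt_genome genome with all truth variants applied (kept for
#'   interface symmetry; fragments are edited per variant from `truth`).
#' @param truth data.frame pos/ref/alt/vaf as from [inject_heteroplasmies()].
#' @param cfg a `mito_sim_config`.
#' @return data.frame with one row per pair: `read_id`, `seq1`, `qual1`,
#'   `seq2`, `qual2`, true origins `pos1`/`pos2` (canonical 1-based start of
#'   each read on the circle), `strand1`/`strand2`, `frag_start`, `frag_len`.
#' @export
simulate_reads <- function(backbone, alt_genome = NULL, truth = NULL, cfg) {
  Lg <- nchar(backbone)
  if (2L * cfg$read_len > min(1000L, Lg))
    stop("read length exceeds the maximum fragment length")
  if (is.null(truth))
    truth <- data.frame(pos = integer(0), ref = character(0),
                        alt = character(0), vaf = numeric(0))
  n_frag <- as.integer(round(cfg$coverage * Lg / (2 * cfg$read_len)))
  with_seed(cfg$seed + 1L, {
    frag_start <- sample.int(Lg, n_frag, replace = TRUE)
    frag_len <- as.integer(round(rnorm(n_frag, cfg$frag_mean, cfg$frag_sd)))
    frag_len <- pmin(pmax(frag_len, 2L * cfg$read_len), min(1000L, Lg))
    rd <- cpp_simulate_reads(backbone, frag_start, frag_len, cfg$read_len,
                             cfg$error_rate, as.integer(truth$pos),
                             as.character(truth$ref), as.character(truth$alt),
                             as.numeric(truth$vaf))
    qual <- strrep(rawToChar(as.raw(33L + 30L)), cfg$read_len)
    pos2 <- frag_start + frag_len - cfg$read_len
    pos2 <- ifelse(pos2 > Lg, pos2 - Lg, pos2)
    data.frame(read_id = sprintf("frag%06d", seq_len(n_frag)),
               seq1 = rd$r1, qual1 = qual, seq2 = rd$r2, qual2 = qual,
               pos1 = frag_start, strand1 = "+",
               pos2 = pos2, strand2 = "-",
               frag_start = frag_start, frag_len = frag_len,
               stringsAsFactors = FALSE)
  })
}

#' Simulate a complete sample dataset
#'
#' Convenience driver: builds the haplogroup backbone, injects
#' heteroplasmies (excluding homopolymer tracts and the profile's own
#' sites), and simulates reads.
#'
#' @param profile a `mito_profile`.
#' @param ref a `mito_ref`.
#' @param cfg a `mito_sim_config`.
#' @param hp_track homopolymer track (defaults to scanning `ref`).
#' @return list(profile, genome, truth, reads).
#' @export
simulate_dataset <- function(profile, ref = mito_reference(),
                             cfg = sim_config(), hp_track = NULL) {
  if (is.null(hp_track))
    hp_track <- new_track("HP", intervals = find_homopolymer_regions(ref$seq))
  genome <- build_sample_genome(ref, profile)
  inj <- inject_heteroplasmies(genome, cfg, hp_track = hp_track,
                               exclude_pos = profile$snvs$pos)
  reads <- simulate_reads(genome, inj$alt_genome, inj$truth, cfg)
  list(profile = profile, genome = genome, truth = inj$truth, reads = reads)
}

#' Write simulated read pairs as a FASTQ pair
#' @param reads data.frame from [simulate_reads()].
#' @param prefix output prefix; writes `<prefix>_R1.fastq`, `<prefix>_R2.fastq`.
#' @return the two file paths, invisibly.
#' @export
write_reads_fastq <- function(reads, prefix) {
  paths <- paste0(prefix, c("_R1.fastq", "_R2.fastq"))
  for (i in 1:2) {
    s <- Biostrings::DNAStringSet(reads[[paste0("seq", i)]])
    names(s) <- reads$read_id
    q <- Biostrings::PhredQuality(reads[[paste0("qual", i)]])
    qs <- Biostrings::QualityScaledDNAStringSet(s, q)
    Biostrings::writeQualityScaledXStringSet(qs, paths[i])
  }
  invisible(paths)
}

#' Read a FASTQ pair written by [write_reads_fastq()]
#' @param prefix prefix used when writing.
#' @return data.frame read_id/seq1/qual1/seq2/qual2.
#' @export
read_reads_fastq <- function(prefix) {
  paths <- paste0(prefix, c("_R1.fastq", "_R2.fastq"))
  # readQualityScaledDNAStringSet warns that FASTQ metadata columns are
  # dropped; nothing we need lives there
  r1 <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(paths[1]))
  r2 <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(paths[2]))
  data.frame(read_id = names(r1),
             seq1 = as.character(r1), qual1 = as.character(Biostrings::quality(r1)),
             seq2 = as.character(r2), qual2 = as.character(Biostrings::quality(r2)),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Write a truth set as VCF 4.2
#'
#' @param truth data.frame pos/ref/alt/vaf/type.
#' @param path output VCF path.
#' @param contig contig name.
#' @param L contig length for the header.
#' @export
write_truth <- function(truth, path, contig = "chrM", L = 16569L) {
  truth <- truth[order(truth$pos, truth$ref, truth$alt), , drop = FALSE]
  info <- sprintf("AF=%.6g;TYPE=%s", truth$vaf,
                  variant_type(truth$ref, truth$alt))
  write_vcf_body(path, contig, L, truth$pos, truth$ref, truth$alt,
                 filter = rep("PASS", nrow(truth)), info = info,
                 extra_header = c(
                   '##INFO=<ID=AF,Number=1,Type=Float,Description="Injected variant allele fraction">',
                   '##INFO=<ID=TYPE,Number=1,Type=String,Description="SNV, INS or DEL">'))
  invisible(path)
}
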