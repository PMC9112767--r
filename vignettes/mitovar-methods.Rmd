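---
title: "mitovar: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{mitovar: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Human cells carry hundreds to thousands of copies of the 16,569-bp circular
mitochondrial genome. Two quantities summarize its state in a whole-genome
sequencing (WGS) sample: **mtDNA copy number** (mtDNA-CN), the ratio of
mitochondrial to nuclear coverage times two, and **heteroplasmy**, the
fraction of mtDNA molecules carrying a variant allele at a site. Both are
hard to measure from standard alignments, for three reasons:

1. **Circularity.** Linear aligners leave a coverage crater at the
   artificial start/stop of chrM, exactly where the control region (D-loop)
   and its hypervariable segments lie.
2. **NUMTs.** Nuclear-embedded mitochondrial segments act as read sinks:
   true mitochondrial reads mis-map to chr1/chr17 look-alikes, and NUMT
   reads can leak back as false low-level heteroplasmies.
3. **Reference distance.** A sample whose haplogroup is far from the
   reference accumulates mismatches that depress mapping quality and
   coverage at its own variant sites, biasing heteroplasmy estimates.

`mitovar` addresses all three: it extracts candidate reads (chrM, the NUMT
sink intervals, unmapped mates), remaps them to a *circularized* reference
(the first 300 bases appended after position 16,569, with origin-spanning
alignments split back onto canonical coordinates), calls variants with
frequency/strand thresholds, then rebuilds each sample's *consensus*
mitochondrial genome and re-calls variants against it — the "second
iteration" — lifting the calls back to reference coordinates.

# The variant-calling model

Calling is deliberately threshold-based rather than likelihood-based. At a
site of depth $d$, a non-reference allele with $k$ supporting reads
($k_f$ forward, $k_r$ reverse) is called when

$$ k/d \ge 0.03, \qquad k_f \ge 2, \qquad k_r \ge 2, $$

with bases below Q20 excluded from allele counts (but not from depth) and
sites below depth 10 skipped. A call at VAF $\ge 0.97$ is classed
homoplasmic, otherwise heteroplasmic; the 0.97 boundary mirrors the 3%
floor symmetrically, since at high coverage a homoplasmy's residual error
reads would otherwise flip its class. All passing alleles at a site are
reported, preserving multiallelic records.

Why this model: at the working depth of ~2000x, a 3% threshold is 60 reads.
An independent 1% substitution error contributes Binomial(2000, 0.0033)
reads per specific alt allele — mean ~6.7, so 60 is unreachable and false
positives vanish; conversely a true 15–20% heteroplasmy has essentially
zero false-negative probability. The thresholds, not an error model, do
the work, and every decision is exactly reproducible and testable against
a brute-force oracle. The trade-off is sensitivity below 3% VAF and at low
coverage: at 100–200x the threshold is a handful of reads and error noise
*will* occasionally reach it (roughly one site per genome at 200x). That
behavior is intrinsic to the operating point, and is why down-sampling
targets 2000x rather than calling at raw coverage.

## Pileups and INDELs

Pileups are strand-aware cigar walks over deduplicated, uniquely-mapped
(mapq > 0) alignments. Insertions are keyed to their anchor base;
deletions appear both as spanning events at each deleted position and as an
anchored DEL allele. Calls are left-aligned to a parsimonious VCF
representation before any comparison. INDELs within 150 bases (one read
length) of a polycytosine homopolymer tract are flagged `HP_ADJACENT`:
polymerase slippage makes indel calls there unreliable, and they are kept
out of headline SNV summaries.

# The second iteration and coordinate liftover

The consensus genome applies every homoplasmic call and every heteroplasmic
call whose allele exceeds 50% VAF (highest-VAF allele at multiallelic
sites; a tie at exactly 0.5 keeps the reference, making the edit set
deterministic). Length-changing edits define a piecewise-linear, invertible
coordinate map; every consensus position outside an inserted block maps to
exactly one reference position and back.

Second-iteration calls are re-expressed against reference alleles so the
two iterations' VCFs are directly comparable. When a consensus edit makes
the reference base the *minor* allele (a 4% G>A call at a site whose
consensus is G because the sample is homoplasmic A>G), the record is
flipped to reference representation, its VAF becomes the major-allele
fraction, the minor fraction is kept in `minor_vaf`, and the record is
tagged `ALLELE_SWITCH`. Calls inside consensus insertions anchor to the
insertion site (`IN_CONSENSUS_INS`). Whether second-iteration VAFs should
be reported against consensus or reference alleles is genuinely open; we
chose reference re-expression because it keeps iteration-1 and iteration-2
call sets set-comparable, at the cost of a non-obvious VAF flip recorded
by the tag.

Consensus validation follows the exact-alignment rule: full-length,
100%-identity alignments are collected and merged when they overlap by at
least 5 bases (our reading of a negative-distance merge), and the circular
consensus must be fully covered by their union.

# The aligner

The built-in aligner is a seeded, banded, gap-affine mapper over the
extended reference: an exact 21-mer index, diagonal voting (seed step 5),
an ungapped fast path for reads within 5 mismatches of a diagonal, and a
banded (±16) fitting alignment with match +1, mismatch −4, gap open 6,
extend 1 for the rest. Ties between placements break to the smallest
canonical start; a read whose best two placements tie gets mapq 0 and is
excluded from pileups, as is the lower-scoring end of a pair that cannot
be placed in proper orientation within a 1000-bp circular insert. A
minimum score of 30 (configurable) rejects junk placements. These
constants mimic common short-read mapper defaults; the package's scope is
mitochondrial-scale references, not a general-purpose mapper.

# mtDNA copy number

$$ \mathrm{CN} = 2 \times \frac{\text{chrM coverage}}{\text{genome coverage}},
\qquad \text{chrM coverage} = \frac{\text{chrM reads} \times \text{read length}}{16{,}569}. $$

Genome coverage comes in three conventions: externally supplied metadata;
"recomputed" (total mapped bases / 3,031,865,587); and sex-adjusted
(female 3,054,815,472, male 3,008,915,703). Mapped bases are aligned
cigar bases of primary, non-duplicate reads; mean aligned length is used
when reads vary. Samples with CN < 100 are flagged: at low copy number
NUMT-derived reads form a larger share of apparent chrM coverage and can
masquerade as low-level heteroplasmies.

# The simulator

The simulator is the package's benchmark instrument and mirrors the
validation design end to end. Its defaults are the study conditions:
150-bp read pairs, i.i.d. substitution error 0.01, and per sample 35 SNVs
plus 8 INDELs injected at 15–20% VAF. A uniform draw on [0.15, 0.20] has
mean 0.175, so one site is nudged to bring the sample mean to exactly
0.18. Thirty synthetic haplogroup profiles (5–40 defining SNVs each,
drawn once with a fixed internal constant, labelled with macro-haplogroup
letters) provide homoplasmic backbones; they stand in for phylogenetic
haplogroups and are *not* Phylotree clades.

Fragments are drawn uniformly on the circle with length
Normal(350, 50) truncated to [300, 1000] (insert size is not specified by
the validation design; these are typical Illumina values), and may span
the origin. Each fragment carries each overlapping truth variant
*independently* with probability equal to that variant's VAF. Per-variant
mixing, rather than a single two-haplotype mixture, makes the binomial
oracle exact: the alt-read count at a site is Binomial(depth, VAF) by
construction, which the recovery tests exploit. Base qualities are
constant Q30. Injected sites avoid homopolymer tracts by default (the
validation design is silent on this; the exclusion is configurable), the
N placeholder, the profile's own sites, and each other (25-bp spacing),
so truth alleles stay expressed against the canonical reference.

What the simulator does *not* emulate: indel sequencing errors, PCR
duplicates, quality-score gradients, GC bias, NUMT contamination in the
read pool, and real phylogenetic structure among profiles. Passing the
benchmark therefore demonstrates the pipeline's bookkeeping (circular
mapping, thresholds, consensus/liftover round trip) under clean error
models — not robustness to every artifact of real libraries.

# The bundled reference

The package ships a **synthetic** rCRS-like reference
(`inst/extdata/chrM_synthetic.fa`), not the GenBank NC_012920 sequence:
canonical 16,569-bp length, the documented polycytosine tracts at
chrM:300–320 (`AAACCCCCCCTCCCCCGCTTC`) and chrM:450–470
(`TATTTTCCCCTCCCACTCCCA`), a further tract inside 16,178–16,193, an N
placeholder at 3107, rCRS alleles at the landmark sites used by the
bundled NUMT/dbSNP lists, and exactly nine C-homopolymer regions — the
documented count for the real rCRS — over a seeded-random background
whose C-runs are capped so the homopolymer content is fully designed.
All bundled tracks (HV/HP/HS/D-loop/genic intervals, NUMT/HG/dbSNP site
lists) are matched to this sequence. Analyses of real data must load the
true rCRS via `load_fasta()` and supply real annotation tracks; every
function takes the reference bundle and tracks as arguments.

The homopolymer definition: a window with ≥5 C's allowing one single-base
interior interruption (interruptions are interior only when flanked by
C's), padded by 1 base per side, overlaps merged. The scan runs on the
given strand's C-runs; `base = "G"` covers the opposite strand. How the
canonical count of nine regions arises from the prose definition (strand
handling, merge interactions) is not fully derivable, so the scan rule
was fixed first and the bundled sequence designed to carry nine tracts.

# Haplogroup assignment and contamination

Assignment scores each profile by (defining SNVs matched − defining SNVs
missed) / profile size over the sample's homoplasmic *and major-allele*
calls, tie-breaking by the unnormalized score and then label order. Major
alleles are included deliberately: in a 90/10 two-person mixture the
dominant haplogroup's variants sit near 90% VAF and are classed
heteroplasmic, and a homoplasmy-only rule would assign the wrong primary
haplogroup. With no informative calls the scoring reduces to preferring
the profile closest to the reference backbone.

The contamination screen is a simplified mixture check, not a
re-implementation of tree-walking contamination tools: among heteroplasmic
SNVs, the non-primary profile with the most matching defining alleles is
the candidate contaminant, the mixture level is the median VAF of the
matching calls, and the sample is flagged at level ≥ 3% with ≥ 3
supporting sites. The three-site floor keeps the false-flag rate at zero
on pure samples while a 10% read-level mixture is detected comfortably.

# Numerical choices and degenerate inputs

* VAF threshold comparisons use `count >= threshold * depth - 1e-9` so
  that exact boundaries (60/2000 at 3%) are stable against floating-point
  representation.
* Reference-N positions are never called; reads carry N through as a
  non-counting mismatch.
* Down-sampling keeps each pair independently with probability
  target/coverage (seeded), and is the identity below target.
* Duplicate marking keys on both ends' (start, strand); the pair with the
  highest summed base quality survives, ties broken by read id.
* Empty call sets, empty tracks, header-only VCFs, and zero-variant
  configurations are all defined and tested.

# Problem sizes used by the test-suite and benchmark

The bundled benchmark runs 10 of the 30 haplogroup datasets at 2000x
(the conditions under which the method's headline error rates are
defined), plus targeted simulations at 60–1000x where a property is
depth-independent; the CN cohort uses n = 1000 samples. These sizes keep
the whole suite in the minutes range on one CPU while leaving every
statistical check adequately powered.

# Known limitations

* The aligner is mitochondrial-scale: a dense exact k-mer index over a
  ~17-kb reference; it is not suitable for nuclear-genome mapping.
* No somatic-caller-style error model; VAFs below 3% are out of scope.
* INDEL calling near homopolymers is flagged rather than modeled.
* The synthetic reference and tracks support development and testing;
  biological conclusions require the real rCRS and curated annotation.
* CRAM input and real-data adapter/quality trimming are minimal
  (a trailing-quality trim flag covers clean data; a dedicated trimmer is
  out of scope).
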