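# mitovar

Mitochondrial DNA copy number and heteroplasmy from whole-genome
sequencing alignments, in R.

Human cells carry hundreds to thousands of copies of the 16,569-bp
circular mitochondrial genome, and its two summary quantities — **mtDNA
copy number** (mtDNA-CN) and **heteroplasmy**, the fraction of molecules
carrying a variant allele at a site — are both linked to aging and
disease. Measuring them from standard WGS alignments is error-prone: the
circular chromosome loses coverage at its artificial linear ends (exactly
where the hypervariable D-loop lies), nuclear-embedded mitochondrial
segments (NUMTs) siphon off true mitochondrial reads and leak false
low-level variants back, and samples from haplogroups far from the
reference lose coverage at their own variant sites.

`mitovar` is a self-contained toolkit for researchers analyzing
mitochondrial genetics in WGS cohorts. It:

* extracts candidate mitochondrial reads from whole-genome BAMs (chrM,
  the chr1/chr17 NUMT read-sink intervals, unmapped mates);
* remaps them to a **circularized** reference (first 300 bases appended
  after position 16,569) with a built-in seeded, banded gap-affine
  aligner, splitting origin-spanning alignments back onto canonical
  coordinates;
* calls SNVs and INDELs from strand-aware pileups with frequency
  thresholds — a non-reference allele is called when
  VAF ≥ 3% with ≥ 2 supporting reads per strand at ≥ Q20, classed
  homoplasmic at VAF ≥ 97% — after down-sampling to ~2000×;
* rebuilds each sample's **consensus** mitochondrial genome from its
  homoplasmies and major alleles, remaps and **re-calls against the
  sample's own genome** (the "second iteration"), and lifts calls back to
  reference coordinates through an invertible offset map, tagging
  allele-role inversions (`ALLELE_SWITCH`);
* annotates calls against hypervariable / homopolymer / hotspot / D-loop /
  genic interval tracks and NUMT / haplogroup / dbSNP site lists, assigns
  a haplogroup from a bundled 30-profile panel, and screens for
  cross-sample contamination (flag at ≥ 3% mixture with ≥ 3 supporting
  sites);
* computes mtDNA-CN = 2 × chrM coverage / genome coverage under three
  genome-coverage conventions (metadata, recomputed over 3,031,865,587
  bases, and sex-adjusted over 3,054,815,472 female / 3,008,915,703 male
  bases), flagging CN < 100;
* ships a paired-end **read simulator with truth sets** (150-bp pairs,
  1% base error, 35 SNV + 8 INDEL heteroplasmies per sample at 15–20%
  VAF over 30 haplogroup backbones) so every stage is benchmarkable
  without external data.

The bundled 16,569-bp reference is a clearly-labelled **synthetic**
rCRS-like stand-in (see `?mito_reference` and the methods vignette);
analyses of real data should load the true rCRS with `load_fasta()`.

## Worked example

Simulate one haplogroup-H sample under the benchmark conditions, run both
calling iterations, and score against the injected truth:

```r
library(mitovar)

ref      <- mito_reference()
profiles <- haplogroup_profiles(ref)

cfg <- sim_config(coverage = 2000, seed = 42)     # 150 bp PE, 1% error,
ds  <- simulate_dataset(profiles[[8]], ref, cfg)  # 35 SNVs + 8 INDELs @ 15-20%

res <- mito_pipeline(ds$reads, ref, seed = 42)    # iterations 1 and 2

compare_to_truth(res$calls1, ds$truth)
#> <mito_truthcmp> truth 43 | TP 43 FN 0 FP 0
compare_to_truth(res$calls2, ds$truth)
#> <mito_truthcmp> truth 43 | TP 43 FN 0 FP 0

hg <- assign_haplogroup(res$calls1, profiles)     # iteration 1: homoplasmies
hg$label
#> [1] "H"
contamination_screen(res$calls1, profiles, primary = hg$label)
#> <mito_mixture> primary H, secondary HV, level 0.156 (1 sites)
```

All 43 injected heteroplasmies are recovered with no false positives in
either iteration; the haplogroup comes back as the generating profile,
and the contamination screen stays unflagged (a single coincidental
profile match is far below the 3-site floor). Copy number from read
counts:

```r
st <- coverage_stats(chrm_reads = 182000, read_len = 150,
                     total_mapped_bases = 9.1e10, sex = "F")
cn_metrics(st)[, c("chrm_cov", "cn_recomputed", "cn_sex", "low_cn_flag")]
#>   chrm_cov cn_recomputed   cn_sex low_cn_flag
#> 1 1647.655      109.7905 110.6216       FALSE
```

A thin command-line wrapper over the same functions lives at
`inst/cli/mitovar.R` (`simulate`, `call`, `extract`, `cn`, `evaluate`
subcommands).

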