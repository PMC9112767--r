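# Minimal VCF 4.2 emission. Variant records here are simple site lists with
# INFO keys; reading always goes through vcfR so the writer is round-trip
# checked against an independent parser.

write_vcf_body <- function(path, contig, L, pos, ref, alt, filter, info,
                           extra_header = character(0)) {
  header <- c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s,length=%d>", contig, L),
    extra_header,
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  body <- if (length(pos))
    sprintf("%s\t%d\t.\t%s\t%s\t.\t%s\t%s", contig, pos, ref, alt, filter, info)
  else character(0)
  writeLines(c(header, body), path)
  invisible(path)
}

calls_header <- c(
  '##INFO=<ID=AF,Number=1,Type=Float,Description="Variant allele fraction (alt reads / depth)">',
  '##INFO=<ID=DP,Number=1,Type=Integer,Description="Read depth at the site">',
  '##INFO=<ID=SBF,Number=1,Type=Integer,Description="Alt-supporting reads, forward strand">',
  '##INFO=<ID=SBR,Number=1,Type=Integer,Description="Alt-supporting reads, reverse strand">',
  '##INFO=<ID=TYPE,Number=1,Type=String,Description="SNV, INS or DEL">',
  '##INFO=<ID=CLASS,Number=1,Type=String,Description="HETEROPLASMY or HOMOPLASMY">',
  '##INFO=<ID=ITER,Number=1,Type=Integer,Description="Variant-calling iteration (1: reference, 2: sample consensus)">',
  '##INFO=<ID=ANN,Number=.,Type=String,Description="Region/site annotations (HV,HP,HS,DLOOP,HG,NUMT,DBSNP,GENE:<name>)">',
  '##INFO=<ID=APOGEE,Number=1,Type=String,Description="Reserved for user-supplied pathogenicity scores">',
  '##FILTER=<ID=strand,Description="Fewer than the minimum alt reads on one strand">',
  '##FILTER=<ID=NO_CALL,Description="Site depth below the callable minimum">',
  '##FILTER=<ID=HP_ADJACENT,Description="INDEL within 150 bases of a homopolymer region">',
  '##FILTER=<ID=ALLELE_SWITCH,Description="Consensus edit made the reference allele the minor allele">',
  '##FILTER=<ID=IN_CONSENSUS_INS,Description="Call inside a consensus insertion; anchored to the insertion site">')

#' Write variant calls as an annotated VCF 4.2
#'
#' @param calls a calls data.frame (see [call_sample()]), optionally
#'   annotated by [annotate_call()].
#' @param path output path.
#' @param contig,L contig name and length for the header.
#' @export
write_calls_vcf <- function(calls, path, contig = "chrM", L = 16569L) {
  calls <- calls[order(calls$pos, calls$ref, calls$alt), , drop = FALSE]
  ann <- annotation_string(calls)
  info <- sprintf("AF=%.6g;DP=%d;SBF=%d;SBR=%d;TYPE=%s;CLASS=%s;ITER=%d%s",
                  calls$vaf, calls$depth, calls$fwd, calls$rev, calls$type,
                  calls$klass,
                  if ("iteration" %in% names(calls)) calls$iteration else 1L,
                  ifelse(nzchar(ann), paste0(";ANN=", ann), ""))
  filter <- if ("filters" %in% names(calls))
    ifelse(is.na(calls$filters) | !nzchar(calls$filters), "PASS", calls$filters)
  else rep("PASS", nrow(calls))
  write_vcf_body(path, contig, L, calls$pos, calls$ref, calls$alt,
                 filter = filter, info = info, extra_header = calls_header)
}

annotation_string <- function(calls) {
  flags <- c("HV", "HP", "HS", "DLOOP", "HG", "NUMT", "DBSNP")
  out <- rep("", nrow(calls))
  for (f in flags)
    if (f %in% names(calls))
      out <- ifelse(calls[[f]], paste0(out, ifelse(nzchar(out), ",", ""), f), out)
  if ("GENE" %in% names(calls)) {
    g <- calls$GENE
    out <- ifelse(!is.na(g) & nzchar(g),
                  paste0(out, ifelse(nzchar(out), ",", ""), "GENE:", g), out)
  }
  out
}

#' Read a variant VCF (truth sets or call sets) into a data.frame
#'
#' @param path VCF path.
#' @return data.frame with pos/ref/alt plus any of vaf, depth, type, klass,
#'   iteration present in INFO.
#' @export
read_variant_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fx <- vcfR::getFIX(v)
  if (is.null(dim(fx))) fx <- matrix(fx, nrow = 1L, dimnames = list(NULL, names(fx)))
  n <- nrow(fx)
  if (n == 0L)
    return(data.frame(pos = integer(0), ref = character(0), alt = character(0),
                      vaf = numeric(0), type = character(0),
                      stringsAsFactors = FALSE))
  out <- data.frame(pos = as.integer(fx[, "POS"]), ref = fx[, "REF"],
                    alt = fx[, "ALT"], stringsAsFactors = FALSE)
  info_field <- function(key) {
    x <- vcfR::extract.info(v, element = key)
    if (is.null(x)) rep(NA_character_, n) else x
  }
  out$vaf <- suppressWarnings(as.numeric(info_field("AF")))
  out$type <- info_field("TYPE")
  kl <- info_field("CLASS")
  if (!all(is.na(kl))) out$klass <- kl
  dp <- suppressWarnings(as.integer(info_field("DP")))
  if (!all(is.na(dp))) out$depth <- dp
  it <- suppressWarnings(as.integer(info_field("ITER")))
  if (!all(is.na(it))) out$iteration <- it
  out[order(out$pos, out$ref, out$alt), , drop = FALSE]
}
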