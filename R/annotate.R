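#' Annotate variant calls against region and site tracks
#'
#' Adds logical flags for interval membership (HV hypervariable, HP
#' homopolymer, HS hotspot, DLOOP) and site-list membership by
#' (position, ref, alt) triple (HG haplogroup-defining, NUMT nuclear
#' look-alike, DBSNP), plus a `GENE` column from the GENIC track.
#' Deterministic and idempotent.
#'
#' @param calls calls data.frame.
#' @param tracks named list of `mito_track` objects (see [mito_tracks()]).
#' @return calls with annotation columns added.
#' @export
annotate_call <- function(calls, tracks) {
  if (nrow(calls) == 0L) {
    for (f in c("HV", "HP", "HS", "DLOOP", "HG", "NUMT", "DBSNP"))
      calls[[f]] <- logical(0)
    calls$GENE <- character(0)
    return(calls)
  }
  for (f in c("HV", "HP", "HS", "DLOOP"))
    calls[[f]] <- if (!is.null(tracks[[f]]))
      track_membership(tracks[[f]], calls$pos) else FALSE
  for (f in c("HG", "NUMT", "DBSNP"))
    calls[[f]] <- if (!is.null(tracks[[f]]))
      track_membership(tracks[[f]], calls$pos, calls$ref, calls$alt) else FALSE
  calls$GENE <- if (!is.null(tracks$GENIC))
    sub("^CDS:", "", track_label(tracks$GENIC, calls$pos))
  else NA_character_
  calls
}

#' Assign the best-matching haplogroup profile
#'
#' Scores each profile by (defining SNVs matched among the sample's
#' homoplasmic / major-allele calls minus defining SNVs missed) / profile
#' size; ties are broken by the unnormalized score, then the
#' lexicographically smallest label (flagged AMBIGUOUS). Major alleles
#' (VAF > 0.5) count alongside homoplasmies so that a contaminated sample is
#' still assigned its dominant haplogroup.
#'
#' @param calls calls data.frame.
#' @param profiles list of `mito_profile` objects.
#' @return list(label, match_fraction, score, ambiguous).
#' @export
assign_haplogroup <- function(calls, profiles) {
  if (length(profiles) == 0L) stop("no haplogroup profiles supplied")
  hom <- calls[(calls$klass == "HOMOPLASMY" | calls$vaf > 0.5) &
                 calls$type == "SNV", , drop = FALSE]
  key <- paste(hom$pos, hom$ref, hom$alt)
  scores <- vapply(profiles, function(pr) {
    pk <- paste(pr$snvs$pos, pr$snvs$ref, pr$snvs$alt)
    m <- sum(pk %in% key)
    k <- length(pk)
    c(frac = (m - (k - m)) / k, raw = m - (k - m), match = m / k)
  }, numeric(3))
  labels <- vapply(profiles, `[[`, character(1), "name")
  ord <- order(-scores["frac", ], -scores["raw", ], labels)
  best <- ord[1L]
  amb <- sum(scores["frac", ] == scores["frac", best] &
               scores["raw", ] == scores["raw", best]) > 1L
  list(label = unname(labels[best]),
       match_fraction = unname(scores["match", best]),
       score = unname(scores["frac", best]), ambiguous = amb)
}

#' Screen for cross-sample contamination
#'
#' A contaminated sample shows the defining alleles of a *second* haplogroup
#' as consistent low-level heteroplasmies. Among heteroplasmic SNV calls,
#' the profile (other than the assigned one) with the most matching defining
#' alleles is the candidate contaminant; the mixture level is the median VAF
#' of the matching calls. Flagged when the level is >= `min_level` with at
#' least `min_sites` supporting sites.
#'
#' @param calls calls data.frame.
#' @param profiles list of `mito_profile` objects.
#' @param primary assigned haplogroup label (computed if missing).
#' @param min_level flagging threshold on the mixture level.
#' @param min_sites minimum supporting heteroplasmic sites.
#' @return a `mito_mixture` list: primary_hg, secondary_hg, mixture_level,
#'   n_support, flagged.
#' @export
contamination_screen <- function(calls, profiles, primary = NULL,
                                 min_level = 0.03, min_sites = 3L) {
  if (is.null(primary)) primary <- assign_haplogroup(calls, profiles)$label
  het <- calls[calls$klass == "HETEROPLASMY" & calls$type == "SNV", ,
               drop = FALSE]
  key <- paste(het$pos, het$ref, het$alt)
  best <- list(label = NULL, n = 0L, level = 0)
  for (pr in profiles) {
    if (pr$name == primary) next
    pk <- paste(pr$snvs$pos, pr$snvs$ref, pr$snvs$alt)
    hit <- key %in% pk
    n <- sum(hit)
    if (n > best$n) best <- list(label = pr$name, n = n,
                                 level = median(het$vaf[hit]))
  }
  level <- min(best$level, 0.5)
  structure(list(primary_hg = primary, secondary_hg = best$label,
                 mixture_level = level, n_support = best$n,
                 flagged = best$n >= min_sites && level >= min_level),
            class = "mito_mixture")
}

#' @export
print.mito_mixture <- function(x, ...) {
  cat(sprintf("<mito_mixture> primary %s, secondary %s, level %.3f (%d sites)%s\n",
              x$primary_hg, x$secondary_hg %||% "-", x$mixture_level,
              x$n_support, if (x$flagged) " FLAGGED" else ""))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
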