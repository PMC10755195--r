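#' Per-marker heterozygosity rate
#'
#' Fraction of non-missing individuals called heterozygous at each
#' marker. Markers with every call missing get `NA`.
#'
#' @param gm a [GenotypeMatrix-class].
#' @return named numeric vector, one rate per marker.
#' @export
markerHetRates <- function(gm) {
  cl <- genotypeCalls(gm)
  obs <- colSums(cl >= 0L)
  het <- colSums(cl == 1L)
  r <- ifelse(obs > 0L, het / obs, NA_real_)
  names(r) <- markerIds(gm)
  r
}

#' Classify a single marker for quality control
#'
#' Applies the allotetraploid marker rule: a marker with heterozygote
#' rate at or below the threshold is kept; above the threshold, a marker
#' showing only two genotype classes with one of them heterozygous
#' (`{0,1}` or `{1,2}`) is a subgenome-collapsed feature and is recoded;
#' above the threshold with all three classes present it is discarded.
#' Missing calls enter neither the rate denominator nor the class
#' census. Markers with all calls missing are discarded; monomorphic
#' markers are kept (polymorphism filtering is assumed upstream).
#'
#' @param calls integer vector of codes for one marker.
#' @param hetThreshold heterozygote-rate threshold (default 0.05); the
#'   high-heterozygosity branch triggers strictly above it.
#' @return one of `"keep"`, `"recode"`, `"discard"`.
#' @export
classifyMarker <- function(calls, hetThreshold = 0.05) {
  obs <- calls[calls >= 0L]
  if (length(obs) == 0L) return("discard")
  rate <- mean(obs == 1L)
  if (rate <= hetThreshold) return("keep")
  classes <- sort(unique(obs))
  # above threshold the het class is present, so a 2-class marker always
  # pairs it with one homozygous class; an all-het marker is the
  # degenerate fully-collapsed case
  if (length(classes) <= 2L) return("recode")
  "discard"
}

#' Recode a subgenome-collapsed marker
#'
#' Converts the spurious heterozygous class to the homozygous class
#' absent from the observed pair, reflecting the polymorphism of only
#' one subgenome: observed classes `{0,1}` send `1 -> 2`, `{1,2}` send
#' `1 -> 0`. Homozygous and missing calls are untouched; the operation
#' is idempotent.
#'
#' @param calls integer vector of codes for a marker classified
#'   `"recode"` (already-recoded markers pass through unchanged).
#' @return recoded integer vector.
#' @export
recodeCollapsedMarker <- function(calls) {
  obs <- sort(unique(calls[calls >= 0L]))
  if (!(1L %in% obs)) {
    if (all(obs %in% c(0L, 2L))) return(calls)  # idempotent re-entry
    stop("marker has no heterozygous class; recoding is undefined")
  }
  if (length(obs) > 2L)
    stop("marker shows three genotype classes; it must be discarded, ",
         "not recoded")
  target <- if (identical(obs, c(0L, 1L)) || identical(obs, 1L)) 2L else 0L
  calls[calls == 1L] <- target
  calls
}

#' Run the marker QC pipeline
#'
#' Classifies every marker (keep / recode / discard), recodes the
#' collapsed ones, drops the discarded ones, and reports per-marker
#' decisions. Kept and recoded markers preserve their input order.
#'
#' @param gm a [GenotypeMatrix-class].
#' @param hetThreshold heterozygote-rate threshold, default 0.05.
#' @return list with elements `gm` (filtered, recoded
#'   [GenotypeMatrix-class]) and `report` (data.frame with columns
#'   `marker`, `hetRate`, `nClasses`, `decision`, plus a `summary`
#'   attribute of per-decision counts).
#' @export
applyQC <- function(gm, hetThreshold = 0.05) {
  cl <- genotypeCalls(gm)
  rates <- markerHetRates(gm)
  decisions <- character(ncol(cl))
  nClasses <- integer(ncol(cl))
  for (j in seq_len(ncol(cl))) {
    obs <- cl[, j][cl[, j] >= 0L]
    nClasses[j] <- length(unique(obs))
    decisions[j] <- classifyMarker(cl[, j], hetThreshold)
  }
  report <- data.frame(marker = markerIds(gm), hetRate = unname(rates),
                       nClasses = nClasses, decision = decisions,
                       stringsAsFactors = FALSE)
  keepCols <- decisions != "discard"
  if (!any(keepCols))
    stop("QC discarded every marker; nothing left to analyse")
  out <- cl[, keepCols, drop = FALSE]
  rec <- which(decisions[keepCols] == "recode")
  for (j in rec) out[, j] <- recodeCollapsedMarker(out[, j])
  summary <- c(keep = sum(decisions == "keep"),
               recode = sum(decisions == "recode"),
               discard = sum(decisions == "discard"))
  stopifnot(sum(summary) == ncol(cl))
  attr(report, "summary") <- summary
  list(gm = GenotypeMatrix(out,
                           markerInfo(gm)[keepCols, , drop = FALSE]),
       report = report)
}
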