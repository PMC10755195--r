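#' Construct a GenotypeMatrix
#'
#' @param calls integer matrix of genotype codes (`0`/`1`/`2`/`-1`),
#'   samples in rows. Rownames are taken as sample ids; if absent,
#'   `S1..Sn` are generated.
#' @param markers optional data.frame with columns `id`, `chrom`, `pos`,
#'   `ref`, `alt`. Defaults to placeholder markers `M1..Mm` on a single
#'   chromosome with A/B alleles.
#' @return a [GenotypeMatrix-class].
#' @examples
#' gm <- GenotypeMatrix(rbind(a = c(0L, 1L), b = c(2L, -1L)))
#' genotypeCalls(gm)
#' @export
GenotypeMatrix <- function(calls, markers = NULL) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  if (is.null(rownames(calls)))
    rownames(calls) <- paste0("S", seq_len(nrow(calls)))
  if (is.null(markers)) {
    m <- ncol(calls)
    ids <- colnames(calls)
    if (is.null(ids)) ids <- paste0("M", seq_len(m))
    markers <- data.frame(id = ids, chrom = "chr1", pos = seq_len(m),
                          ref = "A", alt = "B", stringsAsFactors = FALSE)
  }
  colnames(calls) <- markers$id
  rownames(markers) <- NULL
  new("GenotypeMatrix", calls = calls, markers = markers)
}

#' @describeIn GenotypeMatrix genotype call matrix (samples x markers).
#' @param gm a [GenotypeMatrix-class].
#' @export
genotypeCalls <- function(gm) gm@calls

#' @describeIn GenotypeMatrix sample identifiers.
#' @export
sampleIds <- function(gm) rownames(gm@calls)

#' @describeIn GenotypeMatrix marker identifiers.
#' @export
markerIds <- function(gm) gm@markers$id

#' @describeIn GenotypeMatrix marker annotation table.
#' @export
markerInfo <- function(gm) gm@markers

#' @describeIn GenotypeMatrix number of samples.
#' @export
nSamples <- function(gm) nrow(gm@calls)

#' @describeIn GenotypeMatrix number of markers.
#' @export
nMarkers <- function(gm) ncol(gm@calls)

#' Allele dosage matrix
#'
#' Within-individual alternate-allele frequency `x = call / 2`
#' (0, 0.5, 1); missing calls become `NA`. This is the quantity the
#' Modified Rogers distance and expected heterozygosity operate on.
#'
#' @param gm a [GenotypeMatrix-class].
#' @return numeric matrix, samples x markers.
#' @export
dosageMatrix <- function(gm) {
  x <- gm@calls
  x[x < 0L] <- NA_integer_
  x / 2
}

#' Subset a GenotypeMatrix
#'
#' @param x a [GenotypeMatrix-class].
#' @param i sample index (integer, logical or sample ids).
#' @param j marker index (integer, logical or marker ids).
#' @param ... ignored.
#' @param drop ignored; subsetting never drops dimensions.
#' @export
setMethod("[", "GenotypeMatrix", function(x, i, j, ..., drop = FALSE) {
  if (missing(i)) i <- seq_len(nrow(x@calls))
  if (missing(j)) j <- seq_len(ncol(x@calls))
  if (is.character(j)) j <- match(j, x@markers$id)
  calls <- x@calls[i, j, drop = FALSE]
  new("GenotypeMatrix", calls = calls,
      markers = x@markers[match(colnames(calls), x@markers$id), ,
                          drop = FALSE])
})

setMethod("show", "GenotypeMatrix", function(object) {
  cl <- object@calls
  miss <- mean(cl < 0L)
  het <- mean(cl == 1L)
  cat(sprintf("GenotypeMatrix: %d samples x %d markers\n",
              nrow(cl), ncol(cl)))
  cat(sprintf("  missing: %.1f%%  heterozygous: %.1f%%\n",
              100 * miss, 100 * het))
})

setMethod("show", "CalibrationSet", function(object) {
  cat(sprintf("CalibrationSet: %d accessions, %d markers\n",
              nSamples(object@genotypes), nMarkers(object@genotypes)))
  print(table(object@labels))
})

setMethod("show", "DapcModel", function(object) {
  cat(sprintf(
    "DapcModel: %d markers, %d PCs, %d discriminant axes, %d subgroups\n",
    length(object@markerIds), object@nPca, ncol(object@discriminants),
    length(object@subgroupType)))
  cat("  subgroups:", paste(names(object@subgroupType), collapse = ", "),
      "\n")
})

setMethod("show", "AssignmentResult", function(object) {
  cat(sprintf("AssignmentResult: %d samples, %d subgroups\n",
              nrow(object@posterior), ncol(object@posterior)))
  if (!is.na(object@threshold)) {
    cat(sprintf("  threshold %.2f, excluded: %s\n", object@threshold,
                if (length(object@excluded))
                  paste(object@excluded, collapse = ", ") else "none"))
    print(table(object@final))
  }
})

setMethod("show", "AdmixtureFit", function(object) {
  cat(sprintf(
    "AdmixtureFit: K = %d, %d samples, %d markers (burn-in %d, reps %d)\n",
    object@K, nrow(object@Q), ncol(object@P), object@burnIn, object@reps))
  cat(sprintf("  alpha = %.3f, final logLik = %.1f\n", object@alpha,
              utils::tail(object@logLik, 1)))
})

setMethod("show", "RunEnsemble", function(object) {
  cat(sprintf("RunEnsemble: %d runs at K = %d, stability %.2f\n",
              length(object@fits), object@fits[[1]]@K, object@stability))
})

setMethod("show", "CoreResult", function(object) {
  cat(sprintf(
    "CoreResult: %d entries (%d breeder, %d diversity), AN = %.4f (%s)\n",
    length(object@selected), sum(object@provenance == "breeder"),
    sum(object@provenance == "diversity"), object@an, object@metric))
})

setMethod("show", "SimulatedCollection", function(object) {
  cat(sprintf(
    "SimulatedCollection: %d samples x %d markers, K_true = %d\n",
    nSamples(object@gm), nMarkers(object@gm), ncol(object@truthQ)))
  cat(sprintf("  collapsed markers: %d, related clusters: %d\n",
              length(object@collapsedMarkers),
              length(object@relatedClusters)))
})

#' @describeIn CoreResult-class selected entry ids.
#' @param core a [CoreResult-class].
#' @export
coreEntries <- function(core) core@selected

#' @describeIn CoreResult-class per-entry provenance (`breeder`/`diversity`).
#' @export
coreProvenance <- function(core) {
  stats::setNames(core@provenance, core@selected)
}

#' @describeIn CoreResult-class achieved AN objective value.
#' @export
coreObjective <- function(core) core@an

#' @describeIn AdmixtureFit-class ancestry proportion matrix Q.
#' @param fit an [AdmixtureFit-class].
#' @export
ancestryQ <- function(fit) fit@Q

#' @describeIn AdmixtureFit-class cluster allele-frequency matrix P.
#' @export
clusterFreqP <- function(fit) fit@P

#' @describeIn AssignmentResult-class posterior membership matrix.
#' @param x an [AssignmentResult-class].
#' @export
membershipPosterior <- function(x) x@posterior

#' @describeIn AssignmentResult-class final market-type calls.
#' @export
finalAssignment <- function(x) {
  stats::setNames(x@final, rownames(x@posterior))
}
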