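#' @import methods
NULL

VALID_CALLS <- c(-1L, 0L, 1L, 2L)
MARKET_TYPES <- c("Spanish", "Valencia", "Virginia")
SUBSPECIES_OF <- c(Spanish = "fastigiata", Valencia = "fastigiata",
                   Virginia = "hypogaea")
REGIONS <- c("East", "Southern", "West", "other")

#' GenotypeMatrix: integer-coded biallelic SNP genotypes
#'
#' The central container of the package: an `n x m` integer matrix of
#' genotype calls for `n` samples at `m` biallelic markers, coded
#' `0` (homozygous reference), `1` (heterozygous), `2` (homozygous
#' alternate) and `-1` (missing). The integer missing sentinel (rather
#' than `NA`) keeps equality tests and round-trips exact. Allele dosage,
#' used by the distance and heterozygosity machinery, is `call / 2`
#' (undefined for missing calls).
#'
#' @slot calls integer matrix, samples in rows (rownames = sample ids),
#'   markers in columns (colnames = marker ids).
#' @slot markers data.frame with columns `id`, `chrom`, `pos`, `ref`,
#'   `alt` describing each marker; `pos` is 1-based as in VCF.
#'
#' @seealso [GenotypeMatrix()] for the constructor, [readVCF()],
#'   [genotypeCalls()], [dosageMatrix()].
#' @export
setClass("GenotypeMatrix",
         representation(calls = "matrix", markers = "data.frame"))

setValidity("GenotypeMatrix", function(object) {
  msgs <- character()
  cl <- object@calls
  if (!is.integer(cl)) msgs <- c(msgs, "calls must be an integer matrix")
  if (nrow(cl) < 1L || ncol(cl) < 1L)
    msgs <- c(msgs, "need at least one sample and one marker")
  if (length(cl) && !all(cl %in% VALID_CALLS))
    msgs <- c(msgs, "calls must be coded in {0, 1, 2, -1}")
  sid <- rownames(cl)
  if (is.null(sid) || anyDuplicated(sid))
    msgs <- c(msgs, "sample ids (rownames) must be present and unique")
  mk <- object@markers
  need <- c("id", "chrom", "pos", "ref", "alt")
  if (!all(need %in% names(mk)))
    msgs <- c(msgs, sprintf("markers must have columns %s",
                            paste(need, collapse = ", ")))
  else {
    if (nrow(mk) != ncol(cl))
      msgs <- c(msgs, "markers table and call columns disagree in length")
    if (anyDuplicated(mk$id))
      msgs <- c(msgs, "marker ids must be unique")
    if (nrow(mk) && any(mk$pos < 1))
      msgs <- c(msgs, "marker positions must be >= 1")
    if (nrow(mk) && any(mk$ref == mk$alt))
      msgs <- c(msgs, "ref and alt alleles must differ")
  }
  if (length(msgs)) msgs else TRUE
})

#' CalibrationSet: reference genotypes with phenotype-derived labels
#'
#' Genotypes of reference accessions whose market type could be fixed
#' unambiguously from phenotype records (pod shape, main-axis flowering,
#' pod type), used to train the supervised DAPC classifier.
#'
#' @slot genotypes a [GenotypeMatrix-class] of the labelled accessions.
#' @slot labels named character vector (names = sample ids), values in
#'   `Spanish`, `Valencia`, `Virginia`.
#' @export
setClass("CalibrationSet",
         representation(genotypes = "GenotypeMatrix", labels = "character"))

setValidity("CalibrationSet", function(object) {
  msgs <- character()
  ids <- rownames(object@genotypes@calls)
  if (!identical(names(object@labels), ids))
    msgs <- c(msgs, "labels must be named by, and aligned with, sample ids")
  if (!all(object@labels %in% MARKET_TYPES))
    msgs <- c(msgs, "labels must be Spanish, Valencia or Virginia")
  if (length(msgs)) msgs else TRUE
})

#' DapcModel: a fitted supervised DAPC classifier
#'
#' Stores everything needed to project new samples: per-marker centering
#' means (also used for mean imputation of missing calls), retained PCA
#' loadings, discriminant axes scaled to unit pooled within-group
#' variance, and subgroup centroids in discriminant space. Subgroups are
#' market types split by k-means (e.g. `Spanish.1`..`Spanish.3`).
#'
#' @slot markerIds character, marker ids the model was trained on.
#' @slot center numeric, per-marker mean call used for centering/imputation.
#' @slot loadings matrix, markers x retained PCs.
#' @slot nPca integer, number of retained principal components.
#' @slot discriminants matrix, PCs x discriminant axes.
#' @slot centroids matrix, subgroups x discriminant axes.
#' @slot subgroupType named character, market type of each subgroup.
#' @slot config list of fitting parameters.
#' @export
setClass("DapcModel",
         representation(markerIds = "character", center = "numeric",
                        loadings = "matrix", nPca = "integer",
                        discriminants = "matrix", centroids = "matrix",
                        subgroupType = "character", config = "list"))

setValidity("DapcModel", function(object) {
  msgs <- character()
  if (nrow(object@centroids) != length(object@subgroupType))
    msgs <- c(msgs, "one centroid per subgroup required")
  if (ncol(object@discriminants) > max(1L, length(object@subgroupType) - 1L))
    msgs <- c(msgs, "cannot retain more discriminant axes than subgroups - 1")
  if (length(msgs)) msgs else TRUE
})

#' AssignmentResult: posterior memberships and final assignments
#'
#' Per-sample posterior membership over DAPC subgroups together with the
#' thresholded final market-type call. `final` is `unassigned` when the
#' best posterior falls below the membership threshold or the best
#' subgroup is on the exclusion list.
#'
#' @slot posterior matrix, samples x subgroups, rows sum to 1.
#' @slot bestSubgroup character, argmax subgroup per sample.
#' @slot bestPosterior numeric, the corresponding posterior.
#' @slot final character, market type or `"unassigned"`.
#' @slot subspecies character, `fastigiata`/`hypogaea`/`unassigned`.
#' @slot subgroupType named character, market type of each subgroup.
#' @slot threshold numeric, membership threshold used (NA before
#'   [assignFinal()] is applied).
#' @slot excluded character, excluded subgroups.
#' @export
setClass("AssignmentResult",
         representation(posterior = "matrix", bestSubgroup = "character",
                        bestPosterior = "numeric", final = "character",
                        subspecies = "character", subgroupType = "character",
                        threshold = "numeric", excluded = "character"))

setValidity("AssignmentResult", function(object) {
  msgs <- character()
  if (nrow(object@posterior) &&
      any(abs(rowSums(object@posterior) - 1) > 1e-9))
    msgs <- c(msgs, "posterior rows must sum to 1")
  n <- nrow(object@posterior)
  if (length(object@bestSubgroup) != n || length(object@final) != n)
    msgs <- c(msgs, "per-sample slots must match the posterior row count")
  if (length(msgs)) msgs else TRUE
})

#' AdmixtureFit: one Gibbs-sampler fit of the admixture model
#'
#' Posterior-mean ancestry proportions `Q` (samples x K) and cluster
#' allele frequencies `P` (K x markers) from a single MCMC run of the
#' standard admixture model, with the log-likelihood trace retained as a
#' convergence diagnostic.
#'
#' @slot K integer, number of ancestral clusters.
#' @slot Q matrix, samples x K; rows sum to 1.
#' @slot P matrix, K x markers; alternate-allele frequencies in (0, 1).
#' @slot alpha numeric, posterior-mean Dirichlet concentration.
#' @slot logLik numeric, observed-data log-likelihood at each stored sample.
#' @slot seed integer seed of the run.
#' @slot burnIn,reps integer iteration counts.
#' @export
setClass("AdmixtureFit",
         representation(K = "integer", Q = "matrix", P = "matrix",
                        alpha = "numeric", logLik = "numeric",
                        seed = "integer", burnIn = "integer",
                        reps = "integer"))

setValidity("AdmixtureFit", function(object) {
  msgs <- character()
  if (object@K < 1L) msgs <- c(msgs, "K must be >= 1")
  if (ncol(object@Q) != object@K || nrow(object@P) != object@K)
    msgs <- c(msgs, "Q / P dimensions must match K")
  if (nrow(object@Q) && any(abs(rowSums(object@Q) - 1) > 1e-6))
    msgs <- c(msgs, "Q rows must sum to 1")
  if (length(object@P) && (any(object@P <= 0) || any(object@P >= 1)))
    msgs <- c(msgs, "P entries must lie strictly in (0, 1)")
  if (length(msgs)) msgs else TRUE
})

#' RunEnsemble: label-aligned admixture runs at one K
#'
#' A set of [AdmixtureFit-class] runs at the same K whose cluster labels
#' have been aligned to a reference run, with the pairwise similarity
#' matrix (1 minus mean absolute Q difference) and the ensemble
#' stability score used for K selection.
#'
#' @slot fits list of aligned [AdmixtureFit-class] objects.
#' @slot similarity symmetric matrix of pairwise run similarities in \[0, 1\].
#' @slot stability numeric, fraction of runs concordant with the medoid run.
#' @slot medoid integer index of the medoid run.
#' @export
setClass("RunEnsemble",
         representation(fits = "list", similarity = "matrix",
                        stability = "numeric", medoid = "integer"))

setValidity("RunEnsemble", function(object) {
  msgs <- character()
  S <- object@similarity
  if (nrow(S) != length(object@fits))
    msgs <- c(msgs, "similarity dimension must match the number of runs")
  if (length(S) && (max(abs(S - t(S))) > 1e-12 || any(S < -1e-12 | S > 1 + 1e-12)))
    msgs <- c(msgs, "similarity must be symmetric with entries in [0, 1]")
  if (length(msgs)) msgs else TRUE
})

#' CoreResult: a constructed core collection
#'
#' The selected entry set with per-entry provenance (`breeder` for fixed
#' nominations, `diversity` for optimizer picks) and the achieved
#' average entry-to-nearest-entry (AN) objective value.
#'
#' @slot selected character, ids of the selected entries.
#' @slot provenance character, `breeder` or `diversity`, parallel to
#'   `selected`.
#' @slot an numeric, AN objective of the selection.
#' @slot anInitial numeric, AN of the initial (pre-local-search) selection.
#' @slot metric character, distance metric tag used.
#' @export
setClass("CoreResult",
         representation(selected = "character", provenance = "character",
                        an = "numeric", anInitial = "numeric",
                        metric = "character"))

setValidity("CoreResult", function(object) {
  msgs <- character()
  if (length(object@selected) != length(object@provenance))
    msgs <- c(msgs, "provenance must be parallel to selected")
  if (anyDuplicated(object@selected))
    msgs <- c(msgs, "selected entries must be unique")
  if (!all(object@provenance %in% c("breeder", "diversity")))
    msgs <- c(msgs, "provenance must be 'breeder' or 'diversity'")
  if (length(msgs)) msgs else TRUE
})

#' SimulatedCollection: a synthetic germplasm collection with truth
#'
#' Output of [simulateCollection()]: genotypes plus the latent truth
#' (ancestry matrix, market-type labels, injected collapsed markers and
#' related clusters) that downstream recovery tests compare against.
#'
#' @slot gm the [GenotypeMatrix-class].
#' @slot truthQ matrix, samples x K true ancestry proportions.
#' @slot truthP matrix, K x markers latent population allele frequencies.
#' @slot truthLabels character, nominal market type per sample.
#' @slot phenotypes data.frame of phenotype records.
#' @slot metadata data.frame of sample metadata.
#' @slot collapsedMarkers character, ids of subgenome-collapsed markers.
#' @slot relatedClusters list of character vectors (sample ids per cluster).
#' @slot config list, the generating configuration.
#' @export
setClass("SimulatedCollection",
         representation(gm = "GenotypeMatrix", truthQ = "matrix",
                        truthP = "matrix",
                        truthLabels = "character", phenotypes = "data.frame",
                        metadata = "data.frame", collapsedMarkers = "character",
                        relatedClusters = "list", config = "list"))

setValidity("SimulatedCollection", function(object) {
  msgs <- character()
  if (nrow(object@truthQ) != nrow(object@gm@calls))
    msgs <- c(msgs, "truthQ must have one row per sample")
  if (nrow(object@truthQ) && any(abs(rowSums(object@truthQ) - 1) > 1e-9))
    msgs <- c(msgs, "truthQ rows must sum to 1")
  if (length(msgs)) msgs else TRUE
})
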