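pairwiseCounts <- function(cl) {
  # indicator matrices per genotype class, 0 where missing
  I0 <- (cl == 0L) * 1; I1 <- (cl == 1L) * 1; I2 <- (cl == 2L) * 1
  M <- (cl >= 0L) * 1
  list(
    one = I0 %*% t(I1) + I1 %*% t(I0) + I1 %*% t(I2) + I2 %*% t(I1),
    two = I0 %*% t(I2) + I2 %*% t(I0),
    overlap = M %*% t(M))
}

finishDist <- function(D, overlap, ids, metric, noOverlap) {
  if (any(overlap[upper.tri(overlap)] == 0)) {
    if (noOverlap == "error")
      stop("sample pair(s) share no non-missing marker")
  }
  diag(D) <- 0
  dimnames(D) <- list(ids, ids)
  attr(D, "metric") <- metric
  D
}

#' Allele-sharing genetic distance
#'
#' `d(i, j)` is the mean, over markers non-missing in both samples, of
#' the absolute call difference divided by 2 — the per-allele mismatch
#' proportion between two individuals (0 for identical genotypes, 1 for
#' opposite homozygotes at every locus).
#'
#' @param gm a (post-QC) [GenotypeMatrix-class].
#' @param noOverlap `"error"` (default) or `"na"` for sample pairs with
#'   no shared non-missing marker.
#' @return symmetric numeric matrix with a `"metric"` attribute
#'   (`"allele_sharing"`).
#' @export
alleleSharingDist <- function(gm, noOverlap = c("error", "na")) {
  noOverlap <- match.arg(noOverlap)
  cl <- genotypeCalls(gm)
  pc <- pairwiseCounts(cl)
  D <- (pc$one + 2 * pc$two) / (2 * pc$overlap)
  finishDist(D, pc$overlap, sampleIds(gm), "allele_sharing", noOverlap)
}

#' Modified Rogers genetic distance
#'
#' Euclidean distance on within-individual allele frequencies
#' `x = call / 2`, scaled so opposite homozygotes at every locus give
#' distance 1: `d(i, j) = sqrt(sum_l (x_il - x_jl)^2 / m')` over the
#' `m'` markers non-missing in both samples. (The conventional
#' two-allele form with `1/(2m')` inside the root is identical for
#' biallelic loci, since ref and alt contribute the same squared term.)
#'
#' @inheritParams alleleSharingDist
#' @return symmetric numeric matrix with `"metric"` attribute
#'   (`"modified_rogers"`).
#' @export
modifiedRogersDist <- function(gm, noOverlap = c("error", "na")) {
  noOverlap <- match.arg(noOverlap)
  cl <- genotypeCalls(gm)
  pc <- pairwiseCounts(cl)
  sq <- 0.25 * pc$one + 1 * pc$two   # (x_i - x_j)^2 summed over loci
  D <- sqrt(sq / pc$overlap)
  finishDist(D, pc$overlap, sampleIds(gm), "modified_rogers", noOverlap)
}

#' Ward hierarchical clustering tree
#'
#' Agglomerates samples with Ward's minimum-variance criterion in its
#' squared-distance (ward.D2) form. Merge heights are non-decreasing, so
#' the dendrogram can be cut at any height and serialized to newick with
#' branch lengths derived from merge heights.
#'
#' @param d symmetric distance matrix (e.g. from
#'   [alleleSharingDist()]) or a `dist` object; needs >= 2 samples.
#' @return an `hclust` object (with the input metric tag carried in
#'   attribute `"metric"` when present).
#' @export
wardTree <- function(d) {
  metric <- attr(d, "metric")
  dd <- stats::as.dist(d)
  if (attr(dd, "Size") < 2L) stop("need at least 2 samples to cluster")
  hc <- stats::hclust(dd, method = "ward.D2")
  attr(hc, "metric") <- metric
  hc
}

#' Serialize a clustering tree to newick
#'
#' @param tree an `hclust` object (e.g. from [wardTree()]).
#' @param path optional output file; when `NULL` the newick string is
#'   returned.
#' @return the newick string (invisibly when written to `path`).
#' @export
treeNewick <- function(tree, path = NULL) {
  phy <- ape::as.phylo(tree)
  if (is.null(path)) return(ape::write.tree(phy))
  ape::write.tree(phy, file = path)
  invisible(ape::write.tree(phy))
}

#' Extract clusters of closely related samples from a tree
#'
#' Cuts the dendrogram at a height and keeps the resulting groups of at
#' least `minSize` members — the operational definition of "clusters of
#' very closely related material". The height can be given directly or
#' as a quantile of the pairwise distances (the package's distances are
#' proportions, so a portable default is a low quantile rather than an
#' absolute value tied to one dataset's scale).
#'
#' @param tree an `hclust` object.
#' @param height cut height on the tree's merge-height scale; ignored
#'   when `NULL` in favour of `quantile`.
#' @param d distance matrix, required when `quantile` is used.
#' @param quantile quantile of pairwise distances used as the cut height
#'   when `height` is `NULL` (default 0.02).
#' @param minSize minimum cluster size, default 10.
#' @return list of character vectors of sample ids, one per retained
#'   cluster, with the used cut height in attribute `"height"`.
#' @export
cutRelatedClusters <- function(tree, height = NULL, d = NULL,
                               quantile = 0.02, minSize = 10L) {
  if (is.null(height)) {
    if (is.null(d))
      stop("provide either a cut height or the distance matrix for the ",
           "quantile rule")
    dv <- as.matrix(d)[upper.tri(as.matrix(d))]
    height <- stats::quantile(dv, quantile, names = FALSE)
  }
  if (height < 0) stop("cut height must be >= 0")
  grp <- stats::cutree(tree, h = height)
  tab <- table(grp)
  keep <- names(tab)[tab >= minSize]
  out <- lapply(keep, function(g) names(grp)[grp == g])
  attr(out, "height") <- height
  out
}

#' PCA with supplementary individuals
#'
#' Fits a principal component analysis on the active samples (centered,
#' unscaled calls; missing calls mean-imputed from the active samples
#' only) and projects the supplementary samples with the active
#' centering and loadings — the standard treatment when clusters of
#' near-duplicates would otherwise dominate the axes: one
#' representative stays active, the rest are projected.
#'
#' @param gm a [GenotypeMatrix-class].
#' @param activeIds sample ids the PCA is fitted on (>= 2).
#' @param supplementaryIds sample ids projected afterwards (disjoint
#'   from `activeIds`).
#' @param nAxes number of axes to return, default 10 (capped by rank).
#' @return list with `scores` (data.frame: id, role, one column per
#'   axis) and `explainedVariance` (per-axis fractions).
#' @export
pcaProjection <- function(gm, activeIds, supplementaryIds = character(),
                          nAxes = 10L) {
  if (length(intersect(activeIds, supplementaryIds)))
    stop("active and supplementary sets must be disjoint")
  if (length(activeIds) < 2L) stop("need at least 2 active samples")
  cl <- genotypeCalls(gm)
  act <- cl[activeIds, , drop = FALSE]
  X <- act; storage.mode(X) <- "double"; X[X < 0] <- NA_real_
  center <- colMeans(X, na.rm = TRUE); center[is.nan(center)] <- 0
  Xc <- imputeCenter(act, center)
  pc <- stats::prcomp(Xc, center = FALSE, scale. = FALSE)
  ev <- pc$sdev^2 / sum(pc$sdev^2)
  nAxes <- min(as.integer(nAxes), ncol(pc$x))
  scoresA <- pc$x[, seq_len(nAxes), drop = FALSE]
  out <- data.frame(id = activeIds, role = "active",
                    stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(scoresA))
  if (length(supplementaryIds)) {
    sup <- cl[supplementaryIds, , drop = FALSE]
    Sc <- imputeCenter(sup, center)
    scoresS <- (Sc %*% pc$rotation)[, seq_len(nAxes), drop = FALSE]
    sup_df <- data.frame(id = supplementaryIds, role = "supplementary",
                         stringsAsFactors = FALSE)
    out <- rbind(out, cbind(sup_df, as.data.frame(scoresS)))
  }
  rownames(out) <- NULL
  list(scores = out, explainedVariance = ev[seq_len(nAxes)])
}

#' Expected heterozygosity (gene diversity)
#'
#' For each biallelic marker, `He = 1 - (p^2 + q^2)` with `p` the
#' alternate-allele frequency over the non-missing calls of the chosen
#' samples (`q = 1 - p`). The summary is the mean over markers with at
#' least one non-missing call; all-missing markers are excluded.
#'
#' @param gm a [GenotypeMatrix-class].
#' @param sampleSubset sample ids to use (default: all samples).
#' @return list with `perMarker` (named numeric, `NA` for all-missing
#'   markers) and `mean`.
#' @export
expectedHeterozygosity <- function(gm, sampleSubset = NULL) {
  cl <- genotypeCalls(gm)
  if (!is.null(sampleSubset)) {
    if (length(sampleSubset) == 0L) stop("sample subset is empty")
    cl <- cl[sampleSubset, , drop = FALSE]
  }
  obs <- cl >= 0L
  nObs <- colSums(obs)
  altSum <- colSums(cl * obs)   # missing contributes 0 after masking
  p <- ifelse(nObs > 0L, altSum / (2 * nObs), NA_real_)
  he <- 1 - (p^2 + (1 - p)^2)
  names(he) <- markerIds(gm)
  list(perMarker = he, mean = mean(he, na.rm = TRUE))
}

relatedRepresentatives <- function(gm, relatedClusters) {
  # one representative per cluster: least missing data, ties first by id
  cl <- genotypeCalls(gm)
  drop <- character()
  for (members in relatedClusters) {
    members <- sort(members)
    nMiss <- rowSums(cl[members, , drop = FALSE] < 0L)
    rep <- members[which.min(nMiss)]
    drop <- c(drop, setdiff(members, rep))
  }
  drop
}

#' Per-program diversity report
#'
#' Expected heterozygosity per breeding program across four germplasm
#' sets: all genotypes (`heAll`); all except the members of related
#' clusters other than one representative each (`heNoRelated`); the
#' no-related subset restricted to the fastigiata subspecies
#' (`heNoRelatedFastigiata`); and to the hypogaea subspecies
#' (`heNoRelatedHypogaea`). When core-collection entries are supplied
#' the same quantities are reported for the core as an extra row
#' (`program = "core"`). Empty strata are reported as `NA`, never as
#' zero; single-sample strata are computed but flagged.
#'
#' @param gm a [GenotypeMatrix-class].
#' @param metadata data.frame as from [readSampleMetadata()].
#' @param relatedClusters list of sample-id vectors (from
#'   [cutRelatedClusters()]); may be empty.
#' @param subspecies named character vector over samples with values
#'   `fastigiata` / `hypogaea` / `unassigned` (e.g. from the classifier
#'   final assignment).
#' @param coreIds optional core-collection entry ids.
#' @return data.frame, one row per program (plus `"core"`), columns
#'   `program`, `n`, `heAll`, `heNoRelated`, `heNoRelatedFastigiata`,
#'   `heNoRelatedHypogaea`, `lowN`.
#' @export
programDiversityReport <- function(gm, metadata, relatedClusters = list(),
                                   subspecies, coreIds = NULL) {
  dropIds <- relatedRepresentatives(gm, relatedClusters)
  heOf <- function(ids) {
    ids <- intersect(ids, sampleIds(gm))
    if (length(ids) == 0L) return(NA_real_)
    expectedHeterozygosity(gm, ids)$mean
  }
  rowFor <- function(ids, label) {
    noRel <- setdiff(ids, dropIds)
    fast <- noRel[subspecies[noRel] %in% "fastigiata"]
    hypo <- noRel[subspecies[noRel] %in% "hypogaea"]
    data.frame(program = label, n = length(ids),
               heAll = heOf(ids), heNoRelated = heOf(noRel),
               heNoRelatedFastigiata = heOf(fast),
               heNoRelatedHypogaea = heOf(hypo),
               lowN = length(ids) < 2L, stringsAsFactors = FALSE)
  }
  progs <- unique(metadata$program)
  rows <- lapply(progs, function(p)
    rowFor(metadata$id[metadata$program == p], p))
  if (!is.null(coreIds))
    rows <- c(rows, list(rowFor(coreIds, "core")))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Report duplicated display names
#'
#' Groups metadata display names after normalization and reports every
#' name carried by more than one sample, with the contributing
#' programs. The aggressive policy lowercases and strips all
#' non-alphanumeric characters, so `"Fleur 11"` and `"Fleur11"` merge;
#' the exact policy compares names verbatim.
#'
#' @param metadata data.frame as from [readSampleMetadata()].
#' @param policy `"aggressive"` (default) or `"exact"`.
#' @return data.frame with columns `name` (first-seen spelling),
#'   `count`, `programs` (comma-separated, in input order), sorted by
#'   decreasing count.
#' @export
detectNameDuplicates <- function(metadata,
                                 policy = c("aggressive", "exact")) {
  policy <- match.arg(policy)
  key <- if (policy == "aggressive")
    tolower(gsub("[^[:alnum:]]", "", metadata$name)) else metadata$name
  tab <- table(key)
  dup <- names(tab)[tab > 1L]
  rows <- lapply(dup, function(k) {
    idx <- which(key == k)
    data.frame(name = metadata$name[idx[1]], count = length(idx),
               programs = paste(metadata$program[idx], collapse = ","),
               stringsAsFactors = FALSE)
  })
  if (length(rows) == 0L)
    return(data.frame(name = character(), count = integer(),
                      programs = character(), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  out <- out[order(-out$count, out$name), ]
  rownames(out) <- NULL
  out
}
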