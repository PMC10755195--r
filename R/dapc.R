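#' Build a calibration set from phenotype congruence
#'
#' Retains only the accessions whose three phenotype descriptors agree
#' with a single market type: fastigiata-group pod shapes (Fastigiata,
#' Vulgaris or Peruviana) with flowers on the main axis and a Spanish or
#' Valencia pod type map to Spanish or Valencia respectively;
#' hypogaea-group shapes (Hypogaea, Hirsuta) without main-axis flowers
#' and a Virginia pod type map to Virginia. All other combinations are
#' dropped as incongruent.
#'
#' @param phenotypes data.frame with columns `id`, `pod_shape`,
#'   `main_axis_flower` (`"Yes"`/`"No"`), `pod_type`.
#' @param gm a [GenotypeMatrix-class] containing (at least) the
#'   phenotyped accessions.
#' @return a [CalibrationSet-class] of the congruent accessions.
#' @export
buildCalibrationSet <- function(phenotypes, gm) {
  need <- c("id", "pod_shape", "main_axis_flower", "pod_type")
  stopifnot(all(need %in% names(phenotypes)))
  lab <- rep(NA_character_, nrow(phenotypes))
  fast <- phenotypes$pod_shape %in% FASTIGIATA_SHAPES &
    phenotypes$main_axis_flower == "Yes"
  hypo <- phenotypes$pod_shape %in% HYPOGAEA_SHAPES &
    phenotypes$main_axis_flower == "No"
  lab[fast & phenotypes$pod_type == "Spanish"] <- "Spanish"
  lab[fast & phenotypes$pod_type == "Valencia"] <- "Valencia"
  lab[hypo & phenotypes$pod_type == "Virginia"] <- "Virginia"
  keep <- !is.na(lab) & phenotypes$id %in% sampleIds(gm)
  if (!any(keep))
    stop("no accession has congruent phenotype records")
  ids <- phenotypes$id[keep]
  new("CalibrationSet", genotypes = gm[ids, ],
      labels = stats::setNames(lab[keep], ids))
}

#' Split a calibration set into training and validation subsets
#'
#' @param cal a [CalibrationSet-class].
#' @param nTrain,nValid subset sizes; their sum must not exceed the
#'   calibration size.
#' @param seed integer seed.
#' @param stratify if `TRUE`, sample within market types proportionally.
#' @return list with [CalibrationSet-class] elements `train` and `valid`.
#' @export
splitCalibration <- function(cal, nTrain, nValid, seed, stratify = FALSE) {
  ids <- sampleIds(cal@genotypes)
  if (nTrain + nValid > length(ids))
    stop("calibration set too small for the requested split")
  set.seed(as.integer(seed))
  if (stratify) {
    byType <- split(ids, cal@labels[ids])
    tr <- unlist(lapply(byType, function(v) {
      k <- round(nTrain * length(v) / length(ids))
      sample(v, min(k, length(v)))
    }), use.names = FALSE)
    # top up / trim to the exact size
    if (length(tr) < nTrain)
      tr <- c(tr, sample(setdiff(ids, tr), nTrain - length(tr)))
    if (length(tr) > nTrain) tr <- sample(tr, nTrain)
    va <- sample(setdiff(ids, tr), nValid)
  } else {
    pick <- sample(ids, nTrain + nValid)
    tr <- pick[seq_len(nTrain)]
    va <- pick[nTrain + seq_len(nValid)]
  }
  subsetCal <- function(v)
    new("CalibrationSet", genotypes = cal@genotypes[v, ],
        labels = cal@labels[v])
  list(train = subsetCal(tr), valid = subsetCal(va))
}

imputeCenter <- function(calls, center = NULL) {
  X <- calls
  storage.mode(X) <- "double"
  X[X < 0] <- NA_real_
  if (is.null(center)) {
    center <- colMeans(X, na.rm = TRUE)
    center[is.nan(center)] <- 0
  }
  idx <- which(is.na(X), arr.ind = TRUE)
  if (nrow(idx)) X[idx] <- center[idx[, 2]]
  sweep(X, 2, center)
}

#' Fit a supervised DAPC model
#'
#' Discriminant analysis of principal components: per-marker mean
#' imputation of missing calls, centering, PCA, k-means subdivision of
#' each market type into `kSubgroups` subgroups in the retained PC
#' space, then linear discriminant axes from the between/within scatter
#' eigenproblem on PC scores with the subgroups as grouping factor.
#' Discriminant axes are scaled to unit pooled within-group variance, so
#' subsequent posteriors use an identity covariance.
#'
#' @param train a [CalibrationSet-class].
#' @param nPca number of principal components to retain, or `NULL`
#'   (default) for the smallest count explaining >= `varExplained` of
#'   the variance, capped at a third of the training size.
#' @param varExplained target cumulative variance fraction for the
#'   automatic PC rule (default 0.9).
#' @param kSubgroups k-means subgroups per market type (default 3; the
#'   trained groups are e.g. `Spanish.1`..`Spanish.3`).
#' @param nDa number of discriminant axes, default all
#'   (`subgroups - 1`).
#' @param seed integer seed (k-means restarts).
#' @param restarts k-means re-seeding attempts when a degenerate
#'   subgroup (fewer than 2 members) appears.
#' @return a [DapcModel-class].
#' @export
fitDapc <- function(train, nPca = NULL, varExplained = 0.9,
                    kSubgroups = 3L, nDa = NULL, seed = 1L,
                    restarts = 10L) {
  labels <- train@labels
  types <- sort(unique(labels))
  tab <- table(labels)
  if (any(tab < kSubgroups))
    stop("every market type needs at least kSubgroups members")
  cl <- genotypeCalls(train@genotypes)
  center <- {
    X <- cl; storage.mode(X) <- "double"; X[X < 0] <- NA_real_
    cm <- colMeans(X, na.rm = TRUE); cm[is.nan(cm)] <- 0; cm
  }
  Xc <- imputeCenter(cl, center)
  pc <- stats::prcomp(Xc, center = FALSE, scale. = FALSE)
  ev <- pc$sdev^2
  ev <- ev / sum(ev)
  if (is.null(nPca)) {
    nPca <- which(cumsum(ev) >= varExplained)[1]
    if (is.na(nPca)) nPca <- length(ev)
    nPca <- min(nPca, max(1L, floor(nrow(cl) / 3)))
  }
  nPca <- as.integer(min(nPca, sum(ev > 1e-12)))
  scores <- pc$x[, seq_len(nPca), drop = FALSE]
  loadings <- pc$rotation[, seq_len(nPca), drop = FALSE]

  # k-means subgroups within each market type
  set.seed(as.integer(seed))
  subgroup <- character(nrow(scores))
  names(subgroup) <- rownames(cl)
  for (ty in types) {
    idx <- which(labels == ty)
    k <- min(kSubgroups, length(idx))
    if (k == 1L) {
      subgroup[idx] <- paste0(ty, ".1")
      next
    }
    ok <- FALSE
    for (r in seq_len(restarts)) {
      km <- stats::kmeans(scores[idx, , drop = FALSE], centers = k,
                          nstart = 20L)
      if (min(table(km$cluster)) >= 2L) { ok <- TRUE; break }
    }
    if (!ok)
      stop("k-means produced a degenerate subgroup for ", ty,
           " after ", restarts, " restarts")
    subgroup[idx] <- paste0(ty, ".", km$cluster)
  }
  groups <- sort(unique(subgroup))
  subgroupType <- stats::setNames(sub("\\.[0-9]+$", "", groups), groups)

  da <- discriminantAxes(scores, factor(subgroup, levels = groups), nDa)
  Z <- scores %*% da
  centroids <- do.call(rbind, lapply(groups, function(g)
    colMeans(Z[subgroup == g, , drop = FALSE])))
  rownames(centroids) <- groups

  new("DapcModel", markerIds = markerIds(train@genotypes),
      center = center, loadings = loadings, nPca = nPca,
      discriminants = da, centroids = centroids,
      subgroupType = subgroupType,
      config = list(varExplained = varExplained,
                    kSubgroups = kSubgroups, seed = seed))
}

# Between/within scatter eigenproblem. Returns axes A with
# t(A) %*% Sw %*% A = I (Sw = pooled within-group covariance), so
# Euclidean distance in the projected space is Mahalanobis distance.
discriminantAxes <- function(scores, grouping, nDa = NULL) {
  g <- levels(grouping)
  p <- ncol(scores)
  mAll <- colMeans(scores)
  W <- matrix(0, p, p)
  B <- matrix(0, p, p)
  for (gg in g) {
    idx <- which(grouping == gg)
    mg <- colMeans(scores[idx, , drop = FALSE])
    Xg <- sweep(scores[idx, , drop = FALSE], 2, mg)
    W <- W + crossprod(Xg)
    B <- B + length(idx) * tcrossprod(mg - mAll)
  }
  Sw <- W / (nrow(scores) - length(g))
  es <- eigen(Sw, symmetric = TRUE)
  pos <- es$values > max(es$values) * 1e-8
  whiten <- es$vectors[, pos, drop = FALSE] %*%
    diag(1 / sqrt(es$values[pos]), sum(pos))
  M <- crossprod(whiten, B %*% whiten)
  eb <- eigen((M + t(M)) / 2, symmetric = TRUE)
  maxDa <- min(length(g) - 1L, sum(pos))
  nDa <- if (is.null(nDa)) maxDa else min(as.integer(nDa), maxDa)
  A <- whiten %*% eb$vectors[, seq_len(nDa), drop = FALSE]
  colnames(A) <- paste0("LD", seq_len(nDa))
  A
}

#' Posterior subgroup memberships for new samples
#'
#' Projects samples into the model's discriminant space (stored
#' centering, mean imputation of missing calls, PCA loadings,
#' discriminant axes) and computes Gaussian posteriors with identity
#' covariance and equal priors over the subgroup centroids:
#' `posterior_g proportional to exp(-d_g^2 / 2)`.
#'
#' @param model a [DapcModel-class].
#' @param gm a [GenotypeMatrix-class]; markers are intersected with and
#'   reordered to the model's marker set (with a warning when the
#'   overlap is partial).
#' @return an [AssignmentResult-class] with posteriors, best subgroup
#'   and best posterior filled in; apply [assignFinal()] for thresholded
#'   market-type calls.
#' @export
predictPosterior <- function(model, gm) {
  common <- intersect(model@markerIds, markerIds(gm))
  if (length(common) == 0L)
    stop("no overlap between model markers and the genotype matrix")
  if (length(common) < length(model@markerIds))
    warning("only ", length(common), "/", length(model@markerIds),
            " model markers present; projecting on the intersection")
  sel <- match(common, model@markerIds)
  cl <- genotypeCalls(gm)[, common, drop = FALSE]
  Xc <- imputeCenter(cl, model@center[sel])
  Z <- Xc %*% model@loadings[sel, , drop = FALSE] %*% model@discriminants
  d2 <- outer(rowSums(Z^2), rowSums(model@centroids^2), "+") -
    2 * Z %*% t(model@centroids)
  logp <- -d2 / 2
  logp <- logp - apply(logp, 1, max)
  post <- exp(logp)
  post <- post / rowSums(post)
  rownames(post) <- rownames(cl)
  colnames(post) <- rownames(model@centroids)
  best <- max.col(post, ties.method = "first")
  new("AssignmentResult", posterior = post,
      bestSubgroup = colnames(post)[best],
      bestPosterior = post[cbind(seq_len(nrow(post)), best)],
      final = rep(NA_character_, nrow(post)),
      subspecies = rep(NA_character_, nrow(post)),
      subgroupType = model@subgroupType,
      threshold = NA_real_, excluded = character())
}

#' Remove calibration outliers by self-prediction
#'
#' Fits a model on the calibration set, self-predicts, and drops
#' accessions that are misclassified at the market-type level or whose
#' best posterior falls below `threshold`. Mirrors the practice of
#' pruning reference accessions the model cannot explain before the
#' final fit.
#'
#' @param cal a [CalibrationSet-class].
#' @param fitFun function taking a [CalibrationSet-class] and returning
#'   a [DapcModel-class]; defaults to [fitDapc()] with its defaults.
#' @param threshold minimum self-prediction posterior (default 0, i.e.
#'   only misclassification drops an accession).
#' @return the pruned [CalibrationSet-class].
#' @export
removeCalibrationOutliers <- function(cal, fitFun = fitDapc,
                                      threshold = 0) {
  model <- fitFun(cal)
  res <- predictPosterior(model, cal@genotypes)
  predType <- unname(model@subgroupType[res@bestSubgroup])
  bad <- predType != unname(cal@labels) | res@bestPosterior < threshold
  if (mean(bad) > 0.5)
    stop("more than half of the calibration set is outlying; ",
         "the model looks mis-specified")
  ids <- sampleIds(cal@genotypes)[!bad]
  new("CalibrationSet", genotypes = cal@genotypes[ids, ],
      labels = cal@labels[ids])
}

#' Thresholded final market-type assignment
#'
#' A sample receives the market type of its best subgroup when the best
#' posterior reaches the membership threshold and the subgroup is not on
#' the exclusion list; otherwise it is `unassigned`. Subspecies follow
#' the fixed mapping Spanish/Valencia -> fastigiata, Virginia ->
#' hypogaea.
#'
#' @param result an [AssignmentResult-class] from [predictPosterior()].
#' @param threshold minimum posterior membership, default 0.8.
#' @param excludedSubgroups subgroups whose calls are treated as
#'   uncertain (e.g. subgroups poorly separated on the leading
#'   discriminant axes).
#' @return the [AssignmentResult-class] with `final` and `subspecies`
#'   filled in.
#' @export
assignFinal <- function(result, threshold = 0.8,
                        excludedSubgroups = character()) {
  ok <- unname(result@bestPosterior >= threshold &
                 !(result@bestSubgroup %in% excludedSubgroups))
  final <- ifelse(ok, unname(result@subgroupType[result@bestSubgroup]),
                  "unassigned")
  subsp <- unname(ifelse(final == "unassigned", "unassigned",
                         SUBSPECIES_OF[final]))
  methods::initialize(result, final = final, subspecies = subsp,
                      threshold = threshold,
                      excluded = as.character(excludedSubgroups))
}

#' Confusion matrix and accuracy
#'
#' @param predicted,truth character vectors of market types over the
#'   same samples; any label outside Spanish/Valencia/Virginia errors.
#' @return list with `confusion` (3x3 matrix, rows = predicted,
#'   columns = truth), `accuracy` (fraction, trace over total) and
#'   `accuracyPercent` (accuracy on the 0-100 scale).
#' @export
evaluateConfusion <- function(predicted, truth) {
  if (length(predicted) != length(truth))
    stop("predicted and truth must cover the same samples")
  if (!all(c(predicted, truth) %in% MARKET_TYPES))
    stop("labels must be Spanish, Valencia or Virginia")
  f <- function(x) factor(x, levels = MARKET_TYPES)
  confusion <- table(predicted = f(predicted), truth = f(truth))
  confusion <- unclass(confusion)
  acc <- sum(diag(confusion)) / sum(confusion)
  list(confusion = confusion, accuracy = acc,
       accuracyPercent = 100 * acc)
}

#' Round half up to a fixed number of digits
#'
#' Reported percentages use commercial (round-half-up) rounding, so an
#' accuracy of 92.8% prints as 93%.
#'
#' @param x numeric.
#' @param digits decimal digits, default 0.
#' @return rounded numeric.
#' @export
roundHalfUp <- function(x, digits = 0) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

#' @rdname roundHalfUp
#' @param suffix appended string, default `"%"`.
#' @export
formatPercent <- function(x, digits = 0, suffix = "%") {
  paste0(formatC(roundHalfUp(x, digits), format = "f", digits = digits),
         suffix)
}
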