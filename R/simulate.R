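#' Configuration for the synthetic collection generator
#'
#' Builds and validates the parameter list consumed by
#' [simulateCollection()]. Defaults describe a structured breeding
#' collection of three market-type populations under the Balding-Nichols
#' allele-frequency model, with a share of admixed individuals, a share
#' of subgenome-collapsed markers, occasional missing calls and
#' occasional duplicated display names.
#'
#' @param nSamples,nMarkers collection dimensions.
#' @param K number of ancestral populations (market types for K = 3).
#' @param fst per-population Balding-Nichols differentiation values in
#'   `[0, 1)`; recycled to length K. Defaults span 0.15-0.35, a typical
#'   range between crop market-type gene pools.
#' @param admixtureAlpha symmetric Dirichlet concentration for the
#'   ancestry of admixed individuals.
#' @param admixedFraction share of individuals drawn with mixed ancestry;
#'   the remainder are near-pure (one ancestry component >= 0.95).
#' @param collapsedFraction share of markers simulated as
#'   subgenome-collapsed (two observed classes, one called heterozygous).
#' @param selfing within-individual inbreeding coefficient in `[0, 1]`.
#'   Breeding lines of an autogamous crop are near-fully inbred, so
#'   ordinary markers show few heterozygotes; the default 0.95 puts
#'   background heterozygosity well under the 5% QC threshold. `0`
#'   recovers a plain `Binomial(2, theta)` (Hardy-Weinberg) draw.
#' @param relatedClusters list of `list(size =, mutationRate =)` specs for
#'   clusters of near-identical lines.
#' @param missingRate per-call missing probability.
#' @param nPrograms number of breeding programs sample metadata cycles
#'   through (max 10 named programs).
#' @param congruentFraction share of phenotype records congruent with the
#'   individual's true market type.
#' @param dupNameFraction share of samples given a display name already
#'   used by another sample.
#' @param seed mandatory integer seed; every generator draw flows from it.
#' @return a validated list of class `SimulationConfig`.
#' @export
simulationConfig <- function(nSamples = 200L, nMarkers = 500L, K = 3L,
                             fst = c(0.15, 0.25, 0.35),
                             admixtureAlpha = 0.5,
                             admixedFraction = 0.3,
                             collapsedFraction = 0.08,
                             selfing = 0.95,
                             relatedClusters = list(),
                             missingRate = 0.02, nPrograms = 10L,
                             congruentFraction = 0.8,
                             dupNameFraction = 0.05, seed) {
  if (missing(seed)) stop("a seed is mandatory for the generator")
  K <- as.integer(K)
  if (K < 1L) stop("K must be >= 1")
  fst <- rep_len(fst, K)
  if (any(fst < 0) || any(fst >= 1))
    stop("fst values must lie in [0, 1); F = 1 is degenerate")
  fr <- c(admixedFraction, collapsedFraction, missingRate,
          congruentFraction, dupNameFraction, selfing)
  if (any(fr < 0 | fr > 1)) stop("fractions and rates must lie in [0, 1]")
  for (rc in relatedClusters)
    if (is.null(rc$size) || rc$size < 2L)
      stop("related cluster sizes must be >= 2")
  cfg <- list(nSamples = as.integer(nSamples),
              nMarkers = as.integer(nMarkers), K = K, fst = fst,
              admixtureAlpha = admixtureAlpha,
              admixedFraction = admixedFraction,
              collapsedFraction = collapsedFraction,
              selfing = selfing,
              relatedClusters = relatedClusters,
              missingRate = missingRate,
              nPrograms = as.integer(nPrograms),
              congruentFraction = congruentFraction,
              dupNameFraction = dupNameFraction,
              seed = as.integer(seed))
  class(cfg) <- "SimulationConfig"
  cfg
}

popLabelNames <- function(K) {
  base <- MARKET_TYPES
  if (K <= 3L) base[seq_len(K)]
  else c(base, paste0("Pop", seq(4L, K)))
}

rdirichlet <- function(n, alpha) {
  K <- length(alpha)
  g <- matrix(stats::rgamma(n * K, shape = alpha), nrow = n, byrow = TRUE)
  g / rowSums(g)
}

#' Simulate a structured germplasm collection
#'
#' Generates genotypes under the Balding-Nichols model: ancestral
#' frequencies `p_anc ~ U(0.05, 0.95)`; population frequencies
#' `p_k ~ Beta(p_anc (1 - F_k) / F_k, (1 - p_anc)(1 - F_k) / F_k)`
#' (`p_k = p_anc` exactly when `F_k = 0`); individual `i` with ancestry
#' `q_i` draws each genotype as `Binomial(2, sum_k q_ik p_kl)`. On top of
#' the base genotypes the generator injects clusters of near-identical
#' lines, subgenome-collapsed markers and missing calls, then emits
#' sample metadata and phenotype records.
#'
#' Everything is deterministic under the config seed.
#'
#' @param cfg a [simulationConfig()].
#' @return a [SimulatedCollection-class].
#' @export
simulateCollection <- function(cfg) {
  stopifnot(inherits(cfg, "SimulationConfig"))
  set.seed(cfg$seed)
  n <- cfg$nSamples; m <- cfg$nMarkers; K <- cfg$K
  pAnc <- stats::runif(m, 0.05, 0.95)
  P <- matrix(0, K, m)
  for (k in seq_len(K)) {
    Fk <- cfg$fst[k]
    if (Fk == 0) P[k, ] <- pAnc
    else P[k, ] <- stats::rbeta(m, pAnc * (1 - Fk) / Fk,
                                (1 - pAnc) * (1 - Fk) / Fk)
  }
  # clamp away exact 0/1 so downstream likelihoods stay finite
  P <- pmin(pmax(P, 1e-6), 1 - 1e-6)

  Q <- matrix(0, n, K)
  if (K == 1L) {
    Q[, 1] <- 1
  } else {
    nAdmixed <- round(cfg$admixedFraction * n)
    admixed <- if (nAdmixed > 0) sort(sample.int(n, nAdmixed)) else integer()
    pure <- setdiff(seq_len(n), admixed)
    if (length(admixed))
      Q[admixed, ] <- rdirichlet(length(admixed),
                                 rep(cfg$admixtureAlpha, K))
    if (length(pure)) {
      comp <- rep_len(seq_len(K), length(pure))   # balanced populations
      main <- stats::runif(length(pure), 0.95, 1)
      rest <- rdirichlet(length(pure), rep(1, K - 1L))
      for (ii in seq_along(pure)) {
        row <- numeric(K)
        row[comp[ii]] <- main[ii]
        row[-comp[ii]] <- (1 - main[ii]) * rest[ii, ]
        Q[pure[ii], ] <- row
      }
    }
  }
  theta <- Q %*% P
  # genotype with inbreeding F: P(het) = 2 theta (1-theta) (1-F),
  # homozygotes absorb the remainder; F = 0 is Binomial(2, theta)
  Fis <- cfg$selfing
  pHet <- 2 * theta * (1 - theta) * (1 - Fis)
  pAlt2 <- theta^2 + theta * (1 - theta) * Fis
  u <- matrix(stats::runif(n * m), n, m)
  calls <- matrix(0L, n, m)
  calls[u < pAlt2] <- 2L
  calls[u >= pAlt2 & u < pAlt2 + pHet] <- 1L
  storage.mode(calls) <- "integer"
  rownames(calls) <- sprintf("S%04d", seq_len(n))
  colnames(calls) <- sprintf("M%05d", seq_len(m))
  rownames(Q) <- rownames(calls)
  mk <- data.frame(id = colnames(calls),
                   chrom = paste0("chr", 1L + (seq_len(m) - 1L) %% 10L),
                   pos = 1000L * (1L + (seq_len(m) - 1L) %/% 10L),
                   ref = "A", alt = "G", stringsAsFactors = FALSE)
  gm <- GenotypeMatrix(calls, mk)

  related <- list()
  if (length(cfg$relatedClusters)) {
    inj <- injectRelatedClusters(gm, cfg$relatedClusters,
                                 seed = cfg$seed + 1L)
    gm <- inj$gm
    related <- inj$clusters
  }

  collapsedIds <- character()
  if (cfg$collapsedFraction > 0) {
    nc <- round(cfg$collapsedFraction * m)
    if (nc > 0) {
      collapsedIds <- sort(sample(markerIds(gm), nc))
      gm <- injectCollapsedMarkers(gm, collapsedIds, seed = cfg$seed + 2L)
    }
  }

  if (cfg$missingRate > 0) {
    cl <- genotypeCalls(gm)
    mask <- matrix(stats::runif(n * m) < cfg$missingRate, n, m)
    cl[mask] <- -1L
    gm <- GenotypeMatrix(cl, markerInfo(gm))
  }

  labels <- popLabelNames(K)[max.col(Q)]
  names(labels) <- rownames(calls)

  progs <- names(PROGRAM_COUNTRY)[seq_len(min(cfg$nPrograms, 10L))]
  md <- data.frame(
    id = rownames(calls),
    name = sprintf("L%04d", seq_len(n)),
    program = rep_len(progs, n),
    stringsAsFactors = FALSE)
  md$country <- unname(PROGRAM_COUNTRY[md$program])
  md$region <- unname(COUNTRY_REGION[md$country])
  md$breeder_nominated <- FALSE
  nDup <- round(cfg$dupNameFraction * n)
  if (nDup > 0 && n > 1) {
    dupIdx <- sample.int(n, nDup)
    src <- sample(setdiff(seq_len(n), dupIdx), nDup, replace = TRUE)
    md$name[dupIdx] <- md$name[src]
  }

  phen <- emitPhenotypeRecords(labels, cfg$congruentFraction,
                               seed = cfg$seed + 3L)

  new("SimulatedCollection", gm = gm, truthQ = Q, truthP = P,
      truthLabels = labels,
      phenotypes = phen, metadata = md, collapsedMarkers = collapsedIds,
      relatedClusters = related, config = unclass(cfg))
}

#' Inject subgenome-collapsed markers
#'
#' Rewrites the targeted markers so that every observed call falls in
#' either `{0, 1}` or `{1, 2}` — two genotype classes with one of them
#' called heterozygous — emulating array features that interrogate
#' homeologous loci in both subgenomes of an allotetraploid, where fixed
#' inter-subgenome variation shows up as spurious heterozygosity.
#' Missing calls are left missing; untouched markers are unchanged.
#'
#' @param gm a [GenotypeMatrix-class].
#' @param ids ids of markers to rewrite (subset of `markerIds(gm)`).
#' @param seed integer seed.
#' @return the modified [GenotypeMatrix-class].
#' @export
injectCollapsedMarkers <- function(gm, ids, seed) {
  stopifnot(all(ids %in% markerIds(gm)))
  set.seed(as.integer(seed))
  cl <- genotypeCalls(gm)
  for (id in ids) {
    j <- match(id, colnames(cl))
    obs <- cl[, j] >= 0L
    pair <- if (stats::runif(1) < 0.5) c(0L, 1L) else c(1L, 2L)
    pHet <- stats::runif(1, 0.2, 0.8)
    het <- stats::runif(sum(obs)) < pHet
    cl[obs, j] <- ifelse(het, 1L, setdiff(pair, 1L))
  }
  GenotypeMatrix(cl, markerInfo(gm))
}

#' Inject clusters of near-identical lines
#'
#' For each spec, a founder sample is chosen and `size - 1` other
#' samples are overwritten with mutated copies of its row: each call
#' independently is replaced, with probability `mutationRate`, by a
#' uniform draw from `{0, 1, 2}`. The truth map of cluster membership is
#' returned alongside the matrix.
#'
#' @param gm a [GenotypeMatrix-class].
#' @param specs list of `list(size =, mutationRate =)`.
#' @param seed integer seed.
#' @return list with elements `gm` (modified matrix) and `clusters`
#'   (list of character id vectors; the founder is first in each).
#' @export
injectRelatedClusters <- function(gm, specs, seed) {
  set.seed(as.integer(seed))
  cl <- genotypeCalls(gm)
  n <- nrow(cl)
  pool <- seq_len(n)
  clusters <- list()
  for (s in specs) {
    size <- as.integer(s$size)
    mu <- if (is.null(s$mutationRate)) 0 else s$mutationRate
    if (size > length(pool))
      stop("not enough unassigned samples left for a cluster of size ", size)
    members <- sample(pool, size)
    pool <- setdiff(pool, members)
    founder <- members[1]
    for (i in members[-1]) {
      row <- cl[founder, ]
      if (mu > 0) {
        hit <- stats::runif(ncol(cl)) < mu
        row[hit] <- sample(c(0L, 1L, 2L), sum(hit), replace = TRUE)
      }
      cl[i, ] <- row
    }
    clusters[[length(clusters) + 1L]] <- rownames(cl)[members]
  }
  list(gm = GenotypeMatrix(cl, markerInfo(gm)), clusters = clusters)
}

PHENOTYPE_RULES <- data.frame(
  marketType = c("Valencia", "Spanish", "Virginia"),
  flower = c("Yes", "Yes", "No"),
  podType = c("Valencia", "Spanish", "Virginia"),
  stringsAsFactors = FALSE)

FASTIGIATA_SHAPES <- c("Fastigiata", "Vulgaris", "Peruviana")
HYPOGAEA_SHAPES <- c("Hypogaea", "Hirsuta")

#' Emit phenotype records for calibration accessions
#'
#' Generates the three descriptors used to fix market types from
#' phenotype: pod shape, presence of flowers on the main axis, and pod
#' type. A congruent record follows the rule table of the market type
#' exactly (fastigiata-group shapes + flowering main axis + matching pod
#' type for Spanish/Valencia; hypogaea-group shapes + no main-axis
#' flowers + Virginia pod type for Virginia). An incongruent record
#' violates at least one of the three variables.
#'
#' @param truthLabels named character vector of market types
#'   (`Spanish`/`Valencia`/`Virginia`), names = sample ids.
#' @param congruentFraction share of records drawn congruent.
#' @param seed integer seed.
#' @return data.frame with columns `id`, `pod_shape`, `main_axis_flower`,
#'   `pod_type`, `congruent`.
#' @export
emitPhenotypeRecords <- function(truthLabels, congruentFraction, seed) {
  if (!all(truthLabels %in% MARKET_TYPES))
    stop("labels must be Spanish, Valencia or Virginia")
  set.seed(as.integer(seed))
  n <- length(truthLabels)
  congr <- stats::runif(n) < congruentFraction
  shape <- character(n); flower <- character(n); pod <- character(n)
  for (i in seq_len(n)) {
    lab <- truthLabels[i]
    rule <- PHENOTYPE_RULES[PHENOTYPE_RULES$marketType == lab, ]
    shapes <- if (lab == "Virginia") HYPOGAEA_SHAPES else FASTIGIATA_SHAPES
    if (congr[i]) {
      shape[i] <- sample(shapes, 1)
      flower[i] <- rule$flower
      pod[i] <- rule$podType
    } else {
      # violate one to three of the variables, never zero
      repeat {
        viol <- stats::runif(3) < 0.5
        if (any(viol)) break
      }
      shape[i] <- if (viol[1])
        sample(setdiff(c(FASTIGIATA_SHAPES, HYPOGAEA_SHAPES), shapes), 1)
      else sample(shapes, 1)
      flower[i] <- if (viol[2]) setdiff(c("Yes", "No"), rule$flower)
      else rule$flower
      pod[i] <- if (viol[3]) sample(setdiff(MARKET_TYPES, rule$podType), 1)
      else rule$podType
    }
  }
  data.frame(id = names(truthLabels), pod_shape = shape,
             main_axis_flower = flower, pod_type = pod,
             congruent = congr, stringsAsFactors = FALSE,
             row.names = NULL)
}
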