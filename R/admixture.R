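#' Fit the admixture model by Gibbs sampling
#'
#' Standard model-based ancestry inference for unlinked biallelic
#' markers: each individual `i` carries ancestry proportions `q_i` over
#' `K` clusters, each cluster `k` carries allele frequencies `p_k`, and
#' every allele copy draws its cluster of origin from `q_i` and its
#' allele from the cluster's frequency. The sampler alternates
#' (1) cluster-of-origin draws `Z` for the two allele copies of every
#' non-missing call, (2) `P | Z ~ Dirichlet(lambda + allele counts)`
#' (Beta for biallelic markers, uniform prior `lambda = 1`),
#' (3) `Q | Z ~ Dirichlet(alpha + copy counts)` and (4) a Metropolis
#' update of the symmetric Dirichlet concentration `alpha` with a
#' log-normal proposal. `Q` and `P` are posterior means over thinned
#' post-burn-in samples; the observed-data log-likelihood is stored at
#' every thinning point as a convergence diagnostic.
#'
#' Missing calls contribute nothing to the likelihood or counts.
#'
#' @param gm a (post-QC) [GenotypeMatrix-class].
#' @param K number of ancestral clusters (>= 1, <= number of samples).
#' @param burnIn,reps burn-in sweeps and retained MCMC sweeps. Defaults
#'   (2000 / 5000) are desk-scale; production-scale chains
#'   (e.g. 50000 / 100000) are configured here.
#' @param seed integer seed.
#' @param thin store every `thin`-th post-burn-in sweep (default 10).
#' @param lambda Beta/Dirichlet prior mass on allele frequencies
#'   (default 1, uniform).
#' @param alphaInit,alphaMax,alphaPropSd initial value, upper bound and
#'   log-normal proposal scale of the Metropolis step for `alpha`.
#' @return an [AdmixtureFit-class].
#' @export
gibbsFit <- function(gm, K, burnIn = 2000L, reps = 5000L, seed,
                     thin = 10L, lambda = 1, alphaInit = 1,
                     alphaMax = 10, alphaPropSd = 0.3) {
  K <- as.integer(K)
  G <- genotypeCalls(gm)
  n <- nrow(G); m <- ncol(G)
  if (K > n) stop("K cannot exceed the number of samples")
  if (missing(seed)) stop("a seed is mandatory")
  set.seed(as.integer(seed))
  obs <- G >= 0L
  slotAlt <- list(G >= 1L & obs, G == 2L)   # allele of each copy slot
  nObsTotal <- sum(obs)

  Q <- rdirichlet(n, rep(1, K))
  P <- matrix(stats::runif(K * m, 0.1, 0.9), K, m)
  alpha <- alphaInit

  nStored <- reps %/% thin
  Qsum <- matrix(0, n, K); Psum <- matrix(0, K, m)
  alphaSum <- 0; ll <- numeric(0)
  total <- burnIn + reps

  for (it in seq_len(total)) {
    C <- matrix(0, n, K)
    altC <- matrix(0, K, m)
    refC <- matrix(0, K, m)
    Pm <- lapply(seq_len(K), function(k)
      matrix(P[k, ], n, m, byrow = TRUE))
    for (s in 1:2) {
      As <- slotAlt[[s]]
      W <- vector("list", K)
      Tot <- matrix(0, n, m)
      for (k in seq_len(K)) {
        Fk <- (1 - Pm[[k]]) + As * (2 * Pm[[k]] - 1)
        W[[k]] <- Q[, k] * Fk
        Tot <- Tot + W[[k]]
      }
      U <- matrix(stats::runif(n * m), n, m) * Tot
      z <- matrix(1L, n, m)
      if (K > 1L) {
        cs <- W[[1]]
        for (k in seq_len(K - 1L)) {
          z <- z + (U > cs)
          if (k < K - 1L) cs <- cs + W[[k + 1L]]
        }
      }
      for (k in seq_len(K)) {
        hit <- (z == k) & obs
        C[, k] <- C[, k] + rowSums(hit)
        isAlt <- hit & As
        altC[k, ] <- altC[k, ] + colSums(isAlt)
        refC[k, ] <- refC[k, ] + colSums(hit & !isAlt)
      }
    }
    P <- matrix(stats::rbeta(K * m, lambda + altC, lambda + refC), K, m)
    P <- pmin(pmax(P, 1e-9), 1 - 1e-9)
    gq <- matrix(stats::rgamma(n * K, shape = alpha + C), n, K)
    Q <- gq / rowSums(gq)
    Q <- pmax(Q, 1e-12); Q <- Q / rowSums(Q)

    if (K > 1L) {
      slq <- sum(log(Q))
      prop <- alpha * exp(stats::rnorm(1, 0, alphaPropSd))
      if (prop > 0 && prop < alphaMax) {
        logTarget <- function(a)
          n * (lgamma(K * a) - K * lgamma(a)) + (a - 1) * slq
        logAcc <- logTarget(prop) - logTarget(alpha) +
          log(prop) - log(alpha)   # log-normal proposal correction
        if (log(stats::runif(1)) < logAcc) alpha <- prop
      }
    }

    if (it > burnIn && (it - burnIn) %% thin == 0L) {
      Qsum <- Qsum + Q; Psum <- Psum + P; alphaSum <- alphaSum + alpha
      theta <- Q %*% P
      l <- stats::dbinom(G, 2L, theta, log = TRUE)
      ll <- c(ll, sum(l[obs]))
      if (!is.finite(ll[length(ll)]))
        stop("non-finite likelihood encountered")
    }
  }
  if (nStored == 0L) stop("reps/thin leaves no stored samples")
  Qhat <- Qsum / nStored
  Qhat <- Qhat / rowSums(Qhat)
  Phat <- pmin(pmax(Psum / nStored, 1e-9), 1 - 1e-9)
  rownames(Qhat) <- rownames(G)
  colnames(Phat) <- colnames(G)
  new("AdmixtureFit", K = K, Q = Qhat, P = Phat,
      alpha = alphaSum / nStored, logLik = ll, seed = as.integer(seed),
      burnIn = as.integer(burnIn), reps = as.integer(reps))
}

# Greedy assignment maximizing the score matrix (rows = reference
# clusters, cols = candidate clusters). Returns for each reference
# column the matched candidate column.
greedyMatch <- function(S) {
  K <- nrow(S)
  perm <- integer(K)
  Swork <- S
  for (step in seq_len(K)) {
    ij <- arrayInd(which.max(Swork), dim(Swork))
    perm[ij[1]] <- ij[2]
    Swork[ij[1], ] <- -Inf
    Swork[, ij[2]] <- -Inf
  }
  perm
}

alignOneRun <- function(ref, fit) {
  K <- ncol(ref)
  S <- matrix(0, K, K)
  for (a in seq_len(K)) for (b in seq_len(K)) {
    ra <- ref[, a]; fb <- fit@Q[, b]
    if (stats::sd(ra) < 1e-12 || stats::sd(fb) < 1e-12)
      S[a, b] <- -mean(abs(ra - fb))
    else S[a, b] <- stats::cor(ra, fb)
  }
  perm <- greedyMatch(S)
  methods::initialize(fit, Q = fit@Q[, perm, drop = FALSE],
                      P = fit@P[perm, , drop = FALSE])
}

#' Align admixture runs and score their concordance
#'
#' Fixes the label-switching ambiguity across runs at the same K by
#' greedily matching each run's Q columns to a reference run (first in
#' the list), maximizing the summed column correlation. Pairwise
#' similarity is `1 - mean|Q_a - Q_b|` after alignment; the ensemble
#' stability is the fraction of runs whose similarity to the medoid run
#' (the run most similar to all others) reaches `simThreshold`.
#'
#' @param fits list of [AdmixtureFit-class] objects at the same K over
#'   the same samples.
#' @param simThreshold concordance cutoff, default 0.95.
#' @return a [RunEnsemble-class].
#' @export
alignRuns <- function(fits, simThreshold = 0.95) {
  if (length(fits) == 0L) stop("no runs to align")
  Ks <- vapply(fits, function(f) f@K, integer(1))
  if (length(unique(Ks)) != 1L) stop("runs mix different K")
  ns <- vapply(fits, function(f) nrow(f@Q), integer(1))
  if (length(unique(ns)) != 1L) stop("runs mix different sample sets")
  ref <- fits[[1]]@Q
  aligned <- c(fits[1], lapply(fits[-1], function(f) alignOneRun(ref, f)))
  R <- length(aligned)
  S <- diag(1, R)
  for (a in seq_len(R - 1L)) for (b in seq(a + 1L, R)) {
    s <- 1 - mean(abs(aligned[[a]]@Q - aligned[[b]]@Q))
    S[a, b] <- S[b, a] <- s
  }
  medoid <- which.max(rowSums(S))
  stability <- mean(S[medoid, ] >= simThreshold)
  new("RunEnsemble", fits = aligned, similarity = S,
      stability = stability, medoid = as.integer(medoid))
}

#' Select K by multi-run stability
#'
#' Runs the Gibbs sampler `runsPerK` times for every K in `kRange`,
#' aligns each set of runs, and retains the K with the highest ensemble
#' stability — the selection rule suited to composite breeding
#' collections, where likelihood-based K criteria assume population
#' structure such material does not have. The thresholded stability
#' fraction saturates at 1 for every K with a single dominant posterior
#' mode (K below the true cluster count merges populations the same way
#' in every run), so exact ties are broken by the continuous mean
#' similarity to the medoid run, and only then by the smaller K.
#'
#' @param gm a (post-QC) [GenotypeMatrix-class].
#' @param kRange integer vector of candidate K values.
#' @param runsPerK runs per K, default 10.
#' @param burnIn,reps,thin passed to [gibbsFit()].
#' @param seed integer seed; run r at candidate K uses
#'   `seed + 97 * K + r`.
#' @param simThreshold concordance cutoff for [alignRuns()].
#' @return list with `K` (chosen), `stability` (named vector over
#'   `kRange`) and `ensembles` (list of [RunEnsemble-class]).
#' @export
selectKByStability <- function(gm, kRange, runsPerK = 10L,
                               burnIn = 500L, reps = 1500L, thin = 5L,
                               seed, simThreshold = 0.95) {
  if (length(kRange) == 0L) stop("kRange must be nonempty")
  if (missing(seed)) stop("a seed is mandatory")
  kRange <- sort(unique(as.integer(kRange)))
  ensembles <- list()
  stability <- meanSim <- numeric(length(kRange))
  names(stability) <- as.character(kRange)
  for (i in seq_along(kRange)) {
    K <- kRange[i]
    fits <- lapply(seq_len(runsPerK), function(r)
      gibbsFit(gm, K, burnIn = burnIn, reps = reps, thin = thin,
               seed = as.integer(seed + 97L * K + r)))
    ens <- alignRuns(fits, simThreshold = simThreshold)
    ensembles[[as.character(K)]] <- ens
    stability[i] <- ens@stability
    meanSim[i] <- mean(ens@similarity[ens@medoid, ])
  }
  ord <- order(-stability, -meanSim, kRange)
  best <- kRange[ord[1]]
  list(K = best, stability = stability, meanSimilarity = meanSim,
       ensembles = ensembles)
}

#' Assign samples to structure groups at a membership threshold
#'
#' @param fit an [AdmixtureFit-class].
#' @param threshold minimum membership, default 0.8. Samples whose
#'   maximum ancestry proportion falls below it form the `"Admixed"`
#'   group.
#' @return named character vector over samples with values `"1"`..`"K"`
#'   or `"Admixed"`.
#' @export
assignStructureGroups <- function(fit, threshold = 0.8) {
  best <- max.col(fit@Q, ties.method = "first")
  mx <- fit@Q[cbind(seq_len(nrow(fit@Q)), best)]
  out <- ifelse(mx >= threshold, as.character(best), "Admixed")
  names(out) <- rownames(fit@Q)
  out
}
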