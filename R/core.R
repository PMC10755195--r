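#' Prune closely related nominations
#'
#' Greedy scan in input order: an entry is dropped when it lies within
#' `threshold` of an already-kept entry. Automates the manual tree
#' inspection step in which only one of several closely related
#' nominated lines is retained.
#'
#' @param nominated character vector of nominated ids, in nomination
#'   order.
#' @param d distance matrix covering all nominated entries.
#' @param threshold distance below or at which two entries count as the
#'   same line; default 0.05 on the Modified Rogers scale.
#' @return the kept ids, in input order.
#' @export
dedupNominations <- function(nominated, d, threshold = 0.05) {
  if (threshold < 0) stop("threshold must be >= 0")
  d <- as.matrix(d)
  kept <- character()
  for (id in nominated) {
    if (length(kept) == 0L || all(d[id, kept] > threshold))
      kept <- c(kept, id)
  }
  kept
}

#' Average entry-to-nearest-entry distance (AN)
#'
#' The core-collection objective: the mean, over selected entries, of
#' each entry's distance to its nearest other selected entry.
#' Maximizing AN spreads the selection across the diversity space.
#'
#' @param selected character vector of >= 2 entry ids.
#' @param d distance matrix covering the entries.
#' @return the AN value.
#' @export
anObjective <- function(selected, d) {
  if (length(selected) < 2L)
    stop("AN is undefined for fewer than 2 entries")
  D <- as.matrix(d)[selected, selected]
  diag(D) <- Inf
  mean(apply(D, 1L, min))
}

anOfIndex <- function(idx, D) {
  S <- D[idx, idx]
  diag(S) <- Inf
  mean(apply(S, 1L, min))
}

#' Optimize a core collection under the AN objective
#'
#' Selects `N` entries containing all `fixed` entries and maximizing
#' the average entry-to-nearest-entry distance. Free slots are filled
#' by greedy furthest-point initialization (each new entry maximizes
#' its minimum distance to the current selection), then improved by
#' steepest-ascent single swaps: at each step the swap of one free
#' selected entry for one unselected candidate that most improves AN is
#' applied, until no swap improves or `maxSwaps` is reached. Additional
#' restarts start from random free slots; the best selection over all
#' restarts is kept. Deterministic under the seed; fixed entries are
#' never removed.
#'
#' @param candidates character vector of candidate ids.
#' @param fixed character vector of ids forced into the selection
#'   (subset of `candidates`).
#' @param N target size, `|fixed| <= N <= |candidates|`.
#' @param d distance matrix covering the candidates.
#' @param restarts number of searches (1 greedy + `restarts - 1`
#'   random initializations), default 3.
#' @param maxSwaps swap budget per search, default 1000.
#' @param seed integer seed.
#' @return a [CoreResult-class].
#' @export
optimizeCore <- function(candidates, fixed = character(), N, d,
                         restarts = 3L, maxSwaps = 1000L, seed = 1L) {
  if (!all(fixed %in% candidates))
    stop("fixed entries must be candidates")
  if (N < max(2L, length(fixed)) || N > length(candidates))
    stop("infeasible target size")
  D <- as.matrix(d)[candidates, candidates]
  metric <- attr(d, "metric")
  if (is.null(metric)) metric <- "unknown"
  fixedIdx <- match(fixed, candidates)
  nFree <- N - length(fixedIdx)
  all_idx <- seq_along(candidates)
  set.seed(as.integer(seed))

  greedyInit <- function() {
    sel <- fixedIdx
    if (length(sel) == 0L && nFree > 0L) {
      # seed with the globally furthest pair (or the single max-sum
      # point when only one slot is free)
      if (nFree >= 2L) {
        ij <- arrayInd(which.max(D), dim(D))
        sel <- as.integer(ij[1, ])
      } else sel <- which.max(rowSums(D))
    }
    while (length(sel) < N) {
      rest <- setdiff(all_idx, sel)
      minD <- apply(D[rest, sel, drop = FALSE], 1L, min)
      sel <- c(sel, rest[which.max(minD)])
    }
    sel
  }
  randomInit <- function() {
    free <- sample(setdiff(all_idx, fixedIdx), nFree)
    c(fixedIdx, free)
  }

  localSearch <- function(sel) {
    an <- anOfIndex(sel, D)
    anInit <- an
    swaps <- 0L
    repeat {
      freeSel <- setdiff(sel, fixedIdx)
      outside <- setdiff(all_idx, sel)
      if (length(freeSel) == 0L || length(outside) == 0L) break
      bestGain <- 0; bestSwap <- NULL
      for (r in freeSel) {
        base <- setdiff(sel, r)
        for (a in outside) {
          val <- anOfIndex(c(base, a), D)
          if (val - an > bestGain + 1e-12) {
            bestGain <- val - an
            bestSwap <- c(r, a)
          }
        }
      }
      if (is.null(bestSwap)) break
      sel <- c(setdiff(sel, bestSwap[1]), bestSwap[2])
      an <- an + bestGain
      swaps <- swaps + 1L
      if (swaps >= maxSwaps) break
    }
    list(sel = sel, an = an, anInit = anInit)
  }

  best <- NULL
  for (r in seq_len(restarts)) {
    init <- if (r == 1L) greedyInit() else randomInit()
    res <- localSearch(init)
    if (is.null(best) || res$an > best$an) best <- res
  }
  selIds <- candidates[best$sel]
  prov <- ifelse(selIds %in% fixed, "breeder", "diversity")
  ord <- order(prov != "breeder", match(selIds, candidates))
  new("CoreResult", selected = selIds[ord], provenance = prov[ord],
      an = best$an, anInitial = best$anInit, metric = metric)
}

#' Compose the core-collection report
#'
#' Per-program composition of a core collection: breeder-choice and
#' diversity-pick counts, market-type counts, each program's share of
#' the core, and the share of the program's own collection that made it
#' into the core, with a totals row. Percentages are printed with
#' round-half-up integer rounding alongside the raw values.
#'
#' @param core a [CoreResult-class].
#' @param metadata data.frame as from [readSampleMetadata()], covering
#'   the whole collection.
#' @param marketTypes named character vector over samples (market type
#'   or `"unassigned"`), e.g. from [finalAssignment()].
#' @return data.frame with one row per program plus a `"Total"` row;
#'   columns `program`, `breederChoice`, `diversity`, `Spanish`,
#'   `Valencia`, `Virginia`, `total`, `coreSharePct`,
#'   `coreShareRounded`, `programSharePct`, `programShareRounded`.
#' @export
composeCoreReport <- function(core, metadata, marketTypes) {
  sel <- core@selected
  prov <- stats::setNames(core@provenance, sel)
  mdSel <- metadata[match(sel, metadata$id), ]
  N <- length(sel)
  nColl <- nrow(metadata)
  progs <- unique(metadata$program)
  rowFor <- function(p) {
    ids <- sel[mdSel$program == p]
    nProg <- sum(metadata$program == p)
    mt <- marketTypes[ids]
    data.frame(
      program = p,
      breederChoice = sum(prov[ids] == "breeder"),
      diversity = sum(prov[ids] == "diversity"),
      Spanish = sum(mt %in% "Spanish"),
      Valencia = sum(mt %in% "Valencia"),
      Virginia = sum(mt %in% "Virginia"),
      total = length(ids),
      coreSharePct = 100 * length(ids) / N,
      programSharePct = 100 * length(ids) / nProg,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, lapply(progs, rowFor))
  totals <- data.frame(
    program = "Total",
    breederChoice = sum(out$breederChoice),
    diversity = sum(out$diversity),
    Spanish = sum(out$Spanish), Valencia = sum(out$Valencia),
    Virginia = sum(out$Virginia), total = N,
    coreSharePct = 100 * N / nColl,
    programSharePct = 100 * N / nColl,
    stringsAsFactors = FALSE)
  out <- rbind(out, totals)
  out$coreShareRounded <- roundHalfUp(out$coreSharePct)
  out$programShareRounded <- roundHalfUp(out$programSharePct)
  rownames(out) <- NULL
  out
}
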