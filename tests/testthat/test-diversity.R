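test_that("distance endpoints are exact", {
  calls <- rbind(a = rep(0L, 10), b = rep(0L, 10), c = rep(2L, 10))
  gm <- GenotypeMatrix(calls)
  das <- alleleSharingDist(gm)
  dmr <- modifiedRogersDist(gm)
  expect_equal(das["a", "b"], 0)
  expect_equal(dmr["a", "b"], 0)
  expect_equal(das["a", "c"], 1)   # opposite homozygotes everywhere
  expect_equal(dmr["a", "c"], 1)
  # het vs hom at a single locus: sqrt(0.25) = 0.5
  one <- GenotypeMatrix(rbind(x = 1L, y = 0L))
  expect_equal(modifiedRogersDist(one)["x", "y"], 0.5)
  expect_identical(attr(das, "metric"), "allele_sharing")
  expect_identical(attr(dmr, "metric"), "modified_rogers")
})

test_that("distances agree with brute-force loops under missingness", {
  gm <- randomGM(15, 60, missingRate = 0.15, seed = 71)
  cl <- genotypeCalls(gm)
  expect_equal(alleleSharingDist(gm), naiveAlleleSharing(cl),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(modifiedRogersDist(gm), naiveModifiedRogers(cl),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("no-overlap pairs follow the chosen policy", {
  calls <- rbind(a = c(0L, -1L), b = c(-1L, 2L))
  gm <- GenotypeMatrix(calls)
  expect_error(alleleSharingDist(gm), "no non-missing")
  d <- alleleSharingDist(gm, noOverlap = "na")
  expect_true(is.nan(d["a", "b"]))
})

test_that("both distances satisfy the triangle inequality", {
  for (seed in 1:3) {
    gm <- randomGM(12, 40, seed = 80 + seed)
    for (D in list(alleleSharingDist(gm), modifiedRogersDist(gm))) {
      n <- nrow(D)
      for (i in 1:(n - 2)) for (j in (i + 1):(n - 1)) for (k in (j + 1):n) {
        expect_lte(D[i, j], D[i, k] + D[k, j] + 1e-12)
        expect_lte(D[i, k], D[i, j] + D[j, k] + 1e-12)
        expect_lte(D[j, k], D[j, i] + D[i, k] + 1e-12)
      }
    }
  }
})

test_that("ward trees match a naive Lance-Williams agglomeration", {
  for (seed in 1:4) {
    n <- sample(5:8, 1)
    gm <- randomGM(n, 30, seed = 90 + seed)
    D <- alleleSharingDist(gm)
    hc <- wardTree(D)
    oracle <- naiveWardD2(D)
    expect_equal(hc$height, oracle$heights, tolerance = 1e-10)
    for (k in 2:(n - 1))
      expect_identical(hclustPartitionKey(hc, k),
                       partitionKey(oracle$partitions[[n - k]]))
  }
})

test_that("identical samples merge at height zero and heights increase", {
  calls <- rbind(a = c(0L, 1L, 2L, 0L), b = c(0L, 1L, 2L, 0L),
                 c = c(2L, 0L, 0L, 2L))
  hc <- wardTree(alleleSharingDist(GenotypeMatrix(calls)))
  expect_equal(hc$height[1], 0)
  expect_true(all(diff(hc$height) >= -1e-12))
  expect_error(wardTree(matrix(0, 1, 1)), "at least 2")
})

test_that("trees are invariant to input sample order", {
  # missingness varies the per-pair denominators so distances carry no
  # exact ties (tied merges make agglomeration order-dependent)
  gm <- randomGM(12, 151, missingRate = 0.25, seed = 97)
  perm <- sample(12)
  gmP <- GenotypeMatrix(genotypeCalls(gm)[perm, ], markerInfo(gm))
  hc <- wardTree(alleleSharingDist(gm))
  hcP <- wardTree(alleleSharingDist(gmP))
  expect_equal(hc$height, hcP$height, tolerance = 1e-10)
  for (k in c(2, 4)) {
    a <- split(names(cutree(hc, k = k)), cutree(hc, k = k))
    b <- split(names(cutree(hcP, k = k)), cutree(hcP, k = k))
    expect_identical(partitionKey(lapply(a, sort)),
                     partitionKey(lapply(b, sort)))
  }
  expect_match(treeNewick(hc), "^\\(.*\\);$")
})

test_that("cluster extraction recovers injected related material", {
  # related clusters are a small share of the collection, so their
  # pairs sit entirely below the low quantile of pairwise distances
  sim <- simulateCollection(simulationConfig(
    nSamples = 150, nMarkers = 400, K = 3, collapsedFraction = 0,
    missingRate = 0,
    relatedClusters = list(list(size = 12, mutationRate = 0.001),
                           list(size = 10, mutationRate = 0.001)),
    seed = 211))
  d <- alleleSharingDist(sim@gm)
  tree <- wardTree(d)
  found <- cutRelatedClusters(tree, d = d, quantile = 0.02, minSize = 10)
  expect_identical(length(found), 2L)
  foundSets <- lapply(found, sort)
  truthSets <- lapply(sim@relatedClusters, sort)
  expect_setequal(vapply(foundSets, paste, character(1), collapse = ","),
                  vapply(truthSets, paste, character(1), collapse = ","))
})

test_that("cluster extraction edge cases behave", {
  gm <- randomGM(10, 40, seed = 101)
  d <- alleleSharingDist(gm)
  tree <- wardTree(d)
  expect_length(cutRelatedClusters(tree, height = 0, minSize = 2), 0)
  expect_length(cutRelatedClusters(tree, height = 100, minSize = 11), 0)
  expect_error(cutRelatedClusters(tree, height = -1), ">= 0")
  expect_error(cutRelatedClusters(tree), "height")
})

test_that("supplementary projection reproduces active scores exactly", {
  gm <- randomGM(20, 60, missingRate = 0.05, seed = 103)
  # duplicate an active sample under a new id
  cl <- rbind(genotypeCalls(gm), copy = genotypeCalls(gm)["S3", ])
  gm2 <- GenotypeMatrix(cl, markerInfo(gm))
  pp <- pcaProjection(gm2, activeIds = paste0("S", 1:20),
                      supplementaryIds = "copy", nAxes = 5)
  sc <- pp$scores
  expect_equal(unlist(sc[sc$id == "copy", -(1:2)]),
               unlist(sc[sc$id == "S3", -(1:2)]), tolerance = 1e-10)
  expect_lte(sum(pp$explainedVariance), 1)
  expect_error(pcaProjection(gm2, paste0("S", 1:5), "S3"), "disjoint")
})

test_that("the leading axis separates diverged populations", {
  sim <- simulateCollection(simulationConfig(
    nSamples = 90, nMarkers = 300, K = 3, fst = c(0.3, 0.35, 0.4),
    admixedFraction = 0, collapsedFraction = 0, seed = 223))
  pp <- pcaProjection(sim@gm, activeIds = sampleIds(sim@gm), nAxes = 2)
  pc1 <- setNames(pp$scores$PC1, pp$scores$id)
  lab <- sim@truthLabels
  # silhouette of the truth labels on PC1
  sil <- vapply(names(pc1), function(id) {
    own <- mean(abs(pc1[id] - pc1[setdiff(names(lab)[lab == lab[id]], id)]))
    oth <- min(vapply(setdiff(unique(lab), lab[id]), function(l)
      mean(abs(pc1[id] - pc1[names(lab)[lab == l]])), numeric(1)))
    (oth - own) / max(oth, own)
  }, numeric(1))
  expect_gt(mean(sil), 0)
})

test_that("expected heterozygosity matches allele counting", {
  # p = 0.5 maximizes He at 0.5; monomorphic markers give 0
  gm <- GenotypeMatrix(cbind(c(0L, 2L, 0L, 2L), rep(0L, 4),
                             c(1L, 1L, -1L, 0L)))
  he <- expectedHeterozygosity(gm)
  expect_equal(unname(he$perMarker),
               c(0.5, 0, 1 - ((1 / 3)^2 + (2 / 3)^2)))
  gmR <- randomGM(25, 50, missingRate = 0.1, seed = 107)
  sub <- paste0("S", c(2, 5, 9, 11, 20))
  heR <- expectedHeterozygosity(gmR, sub)
  cl <- genotypeCalls(gmR)[sub, ]
  brute <- apply(cl, 2, function(v) {
    obs <- v[v >= 0]
    if (!length(obs)) return(NA_real_)
    p <- sum(obs) / (2 * length(obs))
    1 - p^2 - (1 - p)^2
  })
  expect_equal(unname(heR$perMarker), unname(brute))
  expect_equal(heR$mean, mean(brute, na.rm = TRUE))
  expect_true(all(heR$perMarker <= 0.5 + 1e-12, na.rm = TRUE))
  # allele-label swap invariance: flipping 0 <-> 2 preserves He
  flipped <- cl
  flipped[cl == 0L] <- 2L
  flipped[cl == 2L] <- 0L
  heF <- expectedHeterozygosity(GenotypeMatrix(flipped))
  expect_equal(unname(heF$perMarker), unname(brute))
})

test_that("the program diversity report stratifies and flags correctly", {
  sim <- simulateCollection(simulationConfig(
    nSamples = 60, nMarkers = 120, K = 3, nPrograms = 3,
    collapsedFraction = 0, seed = 227))
  md <- sim@metadata
  subspOf <- c(Spanish = "fastigiata", Valencia = "fastigiata",
               Virginia = "hypogaea")
  subsp <- setNames(unname(subspOf[sim@truthLabels]),
                    names(sim@truthLabels))
  # force one program to be fastigiata-only, like a program that
  # breeds no Virginia material
  prog1 <- md$id[md$program == md$program[1]]
  subsp[intersect(prog1, names(subsp))] <- "fastigiata"
  rep1 <- programDiversityReport(sim@gm, md, list(), subsp)
  row1 <- rep1[rep1$program == md$program[1], ]
  expect_true(is.na(row1$heNoRelatedHypogaea))
  expect_false(is.na(row1$heNoRelatedFastigiata))
  # single-sample program is computed but flagged
  mdX <- rbind(md, data.frame(id = "S0001x", name = "solo",
                              program = "Zam", country = "Zambia",
                              region = "Southern",
                              breeder_nominated = FALSE))
  gmX <- GenotypeMatrix(rbind(genotypeCalls(sim@gm),
                              S0001x = genotypeCalls(sim@gm)[1, ]),
                        markerInfo(sim@gm))
  repX <- programDiversityReport(gmX, mdX, list(), subsp)
  expect_true(repX$lowN[repX$program == "Zam"])
})

test_that("dropping related duplicates cannot deflate diversity", {
  # a program stuffed with copies of one line: He-all is dragged toward
  # the duplicated genotype, He-no-related recovers
  base <- randomGM(6, 200, seed = 109)
  cl <- genotypeCalls(base)
  dup <- do.call(rbind, c(list(cl), rep(list(cl[rep(1, 6), ]), 1)))
  rownames(dup) <- paste0("S", seq_len(nrow(dup)))
  gm <- GenotypeMatrix(dup, markerInfo(base))
  md <- data.frame(id = sampleIds(gm), name = sampleIds(gm),
                   program = "Ug", country = "Uganda", region = "East",
                   breeder_nominated = FALSE)
  cluster <- list(paste0("S", 7:12))  # the copies of S1
  subsp <- setNames(rep("fastigiata", nrow(dup)), sampleIds(gm))
  rep0 <- programDiversityReport(gm, md, cluster, subsp)
  expect_gte(rep0$heNoRelated, rep0$heAll)
  # with equal missingness the representative is the lexicographically
  # first id; the rest of the cluster is dropped
  keepId <- sort(cluster[[1]])[1]
  expect_setequal(germDiv:::relatedRepresentatives(gm, cluster),
                  setdiff(cluster[[1]], keepId))
})

test_that("duplicate names are detected under both policies", {
  md <- data.frame(
    id = paste0("S", 1:8),
    name = c("55-437", "55-437", "55-437", "55-437", "55-437",
             "Fleur 11", "Fleur11", "Unique"),
    program = c("Ng", "Sn", "Gh1", "Gh2", "Ml", "Sn", "Gh1", "Ug"),
    stringsAsFactors = FALSE)
  agg <- detectNameDuplicates(md)
  expect_identical(agg$count[agg$name == "55-437"], 5L)
  expect_true("Fleur 11" %in% agg$name)   # merged by normalization
  expect_identical(agg$programs[agg$name == "55-437"],
                   "Ng,Sn,Gh1,Gh2,Ml")
  exact <- detectNameDuplicates(md, policy = "exact")
  expect_false(any(grepl("Fleur", exact$name)))
  none <- detectNameDuplicates(md[md$name == "Unique", , drop = FALSE])
  expect_identical(nrow(none), 0L)
})
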