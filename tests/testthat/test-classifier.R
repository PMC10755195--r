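# A separable three-type collection used across classifier tests:
# strong differentiation, no admixture, congruent phenotypes.
separableSim <- function(n = 120, m = 300, seed = 101,
                         congruent = 1) {
  simulateCollection(simulationConfig(
    nSamples = n, nMarkers = m, K = 3, fst = c(0.35, 0.4, 0.45),
    admixedFraction = 0, collapsedFraction = 0, missingRate = 0.01,
    congruentFraction = congruent, seed = seed))
}

test_that("calibration retains exactly the congruent phenotype rows", {
  ph <- data.frame(
    id = paste0("S", 1:4),
    pod_shape = c("Vulgaris", "Hypogaea", "Fastigiata", "Hypogaea"),
    main_axis_flower = c("Yes", "Yes", "Yes", "No"),
    pod_type = c("Spanish", "Virginia", "Valencia", "Virginia"),
    stringsAsFactors = FALSE)
  gm <- randomGM(4, 10, seed = 1)
  cal <- buildCalibrationSet(ph, gm)
  # row 2 is incongruent (hypogaea shape with a flowering main axis)
  expect_identical(sort(sampleIds(cal@genotypes)), c("S1", "S3", "S4"))
  expect_identical(unname(cal@labels[c("S1", "S3", "S4")]),
                   c("Spanish", "Valencia", "Virginia"))
  allBad <- ph[2, , drop = FALSE]
  expect_error(buildCalibrationSet(allBad, gm), "congruent")
})

test_that("fully congruent synthetic phenotypes reproduce truth labels", {
  sim <- separableSim(n = 60, m = 80, seed = 103)
  cal <- buildCalibrationSet(sim@phenotypes, sim@gm)
  expect_identical(nSamples(cal@genotypes), 60L)
  expect_identical(unname(cal@labels), unname(sim@truthLabels))
})

test_that("calibration splits are exact, disjoint and seeded", {
  sim <- separableSim(n = 100, m = 60, seed = 107)
  cal <- buildCalibrationSet(sim@phenotypes, sim@gm)
  sp <- splitCalibration(cal, 70, 25, seed = 5)
  expect_identical(nSamples(sp$train@genotypes), 70L)
  expect_identical(nSamples(sp$valid@genotypes), 25L)
  expect_length(intersect(sampleIds(sp$train@genotypes),
                          sampleIds(sp$valid@genotypes)), 0)
  sp2 <- splitCalibration(cal, 70, 25, seed = 5)
  expect_identical(sampleIds(sp$train@genotypes),
                   sampleIds(sp2$train@genotypes))
  expect_error(splitCalibration(cal, 90, 25, seed = 5), "too small")
})

test_that("DAPC separates well-differentiated types perfectly", {
  sim <- separableSim(seed = 109)
  cal <- buildCalibrationSet(sim@phenotypes, sim@gm)
  model <- fitDapc(cal, kSubgroups = 1, seed = 7)
  expect_identical(length(model@subgroupType), 3L)
  res <- predictPosterior(model, cal@genotypes)
  predType <- unname(model@subgroupType[res@bestSubgroup])
  expect_identical(predType, unname(cal@labels))
  model9 <- fitDapc(cal, kSubgroups = 3, seed = 7)
  expect_identical(length(model9@subgroupType), 9L)
  expect_lte(ncol(model9@discriminants), 8L)
})

test_that("a duplicated training sample is recovered with high posterior", {
  sim <- separableSim(seed = 113)
  cal <- buildCalibrationSet(sim@phenotypes, sim@gm)
  model <- fitDapc(cal, kSubgroups = 3, seed = 7)
  resCal <- predictPosterior(model, cal@genotypes)
  dupId <- sampleIds(cal@genotypes)[1]
  dup <- GenotypeMatrix(genotypeCalls(cal@genotypes)[dupId, ,
                                                     drop = FALSE],
                        markerInfo(cal@genotypes))
  resDup <- predictPosterior(model, dup)
  expect_identical(resDup@bestSubgroup,
                   resCal@bestSubgroup[match(dupId,
                                             sampleIds(cal@genotypes))])
  expect_gt(resDup@bestPosterior, 0.99)
})

test_that("posteriors match closed-form Bayes on a 1-D two-group toy", {
  # hand-built model: 1 marker, identity projection, centroids at -1/+1
  model <- new("DapcModel", markerIds = "M1", center = 1,
               loadings = matrix(1, 1, 1), nPca = 1L,
               discriminants = matrix(1, 1, 1),
               centroids = matrix(c(-1, 1), 2, 1,
                                  dimnames = list(c("A.1", "B.1"), NULL)),
               subgroupType = c(A.1 = "A", B.1 = "B"),
               config = list())
  gm <- GenotypeMatrix(matrix(c(0L, 1L, 2L), 3, 1,
                              dimnames = list(c("a", "b", "c"), "M1")))
  res <- predictPosterior(model, gm)
  z <- c(-1, 0, 1)   # centered calls
  bayes <- exp(-(z + 1)^2 / 2) /
    (exp(-(z + 1)^2 / 2) + exp(-(z - 1)^2 / 2))
  expect_equal(unname(res@posterior[, "A.1"]), bayes, tolerance = 1e-12)
  # at the exact centroid the posterior argmax is that group;
  # equidistant gives the uniform posterior
  expect_identical(res@bestSubgroup[1], "A.1")
  expect_equal(unname(res@posterior[2, ]), c(0.5, 0.5))
  expect_true(all(abs(rowSums(res@posterior) - 1) < 1e-12))
})

test_that("discriminant projection agrees with an independent LDA", {
  sim <- separableSim(n = 90, m = 120, seed = 127)
  cal <- buildCalibrationSet(sim@phenotypes, sim@gm)
  model <- fitDapc(cal, kSubgroups = 1, nPca = 10, seed = 7)
  X <- germDiv:::imputeCenter(genotypeCalls(cal@genotypes), model@center)
  scores <- X %*% model@loadings
  ld <- MASS::lda(scores, grouping = factor(unname(cal@labels)))
  ours <- unname(model@subgroupType[
    predictPosterior(model, cal@genotypes)@bestSubgroup])
  theirs <- as.character(predict(ld, scores)$class)
  expect_identical(ours, theirs)
})

test_that("assignment is invariant to marker-order permutation", {
  sim <- separableSim(n = 50, m = 80, seed = 131)
  cal <- buildCalibrationSet(sim@phenotypes, sim@gm)
  model <- fitDapc(cal, kSubgroups = 1, seed = 7)
  perm <- sample(seq_len(nMarkers(sim@gm)))
  gmP <- sim@gm[, perm]
  resA <- predictPosterior(model, sim@gm)
  expect_warning(resB <- predictPosterior(model, gmP), NA)
  expect_equal(resA@posterior, resB@posterior, tolerance = 1e-9)
})

test_that("outlier removal drops a mislabeled accession and only it", {
  sim <- separableSim(seed = 137)
  cal <- buildCalibrationSet(sim@phenotypes, sim@gm)
  clean <- removeCalibrationOutliers(
    cal, fitFun = function(x) fitDapc(x, kSubgroups = 1, seed = 7))
  expect_identical(sampleIds(clean@genotypes), sampleIds(cal@genotypes))
  flipped <- cal@labels
  victim <- which(flipped == "Spanish")[1]
  flipped[victim] <- "Virginia"
  calBad <- new("CalibrationSet", genotypes = cal@genotypes,
                labels = flipped)
  pruned <- removeCalibrationOutliers(
    calBad, fitFun = function(x) fitDapc(x, kSubgroups = 1, seed = 7))
  expect_identical(setdiff(sampleIds(cal@genotypes),
                           sampleIds(pruned@genotypes)),
                   names(flipped)[victim])
})

test_that("final assignment applies threshold and exclusion list", {
  post <- rbind(c(0.85, 0.10, 0.05), c(0.5, 0.3, 0.2), c(0.1, 0.85, 0.05))
  rownames(post) <- paste0("s", 1:3)
  colnames(post) <- c("Spanish.1", "Spanish.2", "Virginia.1")
  res <- new("AssignmentResult", posterior = post,
             bestSubgroup = colnames(post)[max.col(post)],
             bestPosterior = apply(post, 1, max),
             final = rep(NA_character_, 3),
             subspecies = rep(NA_character_, 3),
             subgroupType = c(Spanish.1 = "Spanish", Spanish.2 = "Spanish",
                              Virginia.1 = "Virginia"),
             threshold = NA_real_, excluded = character())
  out <- assignFinal(res, threshold = 0.8)
  expect_identical(unname(finalAssignment(out)),
                   c("Spanish", "unassigned", "Spanish"))
  expect_identical(out@subspecies,
                   c("fastigiata", "unassigned", "fastigiata"))
  out2 <- assignFinal(res, threshold = 0.8,
                      excludedSubgroups = "Spanish.2")
  expect_identical(unname(finalAssignment(out2))[3], "unassigned")
  # threshold 0 with no exclusions assigns everyone
  all0 <- assignFinal(res, threshold = 0)
  expect_false(any(all0@final == "unassigned"))
  # excluding subgroups can only shrink the assigned count
  for (ex in list(character(), "Spanish.1", c("Spanish.1", "Spanish.2"))) {
    a <- sum(assignFinal(res, 0.8, ex)@final != "unassigned")
    b <- sum(assignFinal(res, 0.8, c(ex, "Virginia.1"))@final !=
               "unassigned")
    expect_gte(a, b)
  }
})

test_that("confusion matrices count correctly", {
  pred <- c("Spanish", "Spanish", "Valencia", "Virginia")
  truth <- c("Spanish", "Virginia", "Valencia", "Virginia")
  ev <- evaluateConfusion(pred, truth)
  expect_identical(sum(ev$confusion), 4L)
  expect_equal(ev$accuracy, 0.75)
  expect_identical(unname(ev$confusion["Spanish", "Virginia"]), 1L)
  expect_error(evaluateConfusion(c("Spanish", "Runner"),
                                 c("Spanish", "Spanish")), "labels")
  set.seed(5)
  p <- sample(c("Spanish", "Valencia", "Virginia"), 30, replace = TRUE)
  t <- sample(c("Spanish", "Valencia", "Virginia"), 30, replace = TRUE)
  expect_equal(evaluateConfusion(p, t)$accuracy, sum(p == t) / 30)
})

test_that("percentages round half up to the printed precision", {
  expect_equal(roundHalfUp(92.8), 93)
  expect_equal(roundHalfUp(28.5), 29)   # banker's rounding would give 28
  expect_equal(roundHalfUp(43.52, 1), 43.5)
  expect_identical(formatPercent(92.8), "93%")
})
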