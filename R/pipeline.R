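pipelineDefaults <- function() {
  list(
    stages = list(qc = TRUE, classify = TRUE, structure = TRUE,
                  diversity = TRUE, core = TRUE),
    hetThreshold = 0.05,
    kSubgroups = 3L,
    assignThreshold = 0.8,
    excludedSubgroups = character(),
    structureThreshold = 0.8,
    kRange = 2:5,
    runsPerK = 3L,
    burnIn = 500L,
    reps = 1500L,
    thin = 5L,
    cutQuantile = 0.02,
    minClusterSize = 10L,
    coreSize = 30L,
    dedupThreshold = 0.05,
    coreRestarts = 2L,
    seed = 1L)
}

#' Read a pipeline configuration file
#'
#' YAML file with keys `vcf`, `metadata`, `phenotypes` (paths),
#' optionally `nominations` (path to a one-id-per-line file), a
#' `stages` map of logical toggles, and any of the stage parameters
#' (see [runPipeline()]); unspecified entries take the defaults.
#'
#' @param path YAML file path.
#' @return a config list for [runPipeline()].
#' @export
readPipelineConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  def <- pipelineDefaults()
  if (!is.null(cfg$stages))
    def$stages[names(cfg$stages)] <- cfg$stages
  cfg$stages <- NULL
  def[names(cfg)] <- cfg
  def$kRange <- as.integer(def$kRange)
  def
}

writeCsv <- function(x, dir, name) {
  p <- file.path(dir, name)
  utils::write.csv(x, p, row.names = FALSE)
  p
}

#' Run the full germplasm analysis pipeline
#'
#' Orchestrates QC, market-type classification, admixture structure
#' inference, diversity analytics and core-collection construction from
#' a single configuration, writing every artifact plus a JSON manifest
#' (inputs, parameters, seeds, package version) to `outDir`. Stages run
#' in dependency order; a failing stage aborts with its name while the
#' artifacts already written are retained. Reruns with the same
#' configuration produce identical outputs.
#'
#' @param config list as produced by [readPipelineConfig()], or
#'   assembled directly; must contain paths `vcf`, `metadata`,
#'   `phenotypes` (and optionally `nominations`) plus any parameter
#'   overrides over the defaults.
#' @param outDir output directory (created if needed).
#' @return invisibly, a list with the in-memory stage results and the
#'   manifest.
#' @export
runPipeline <- function(config, outDir) {
  def <- pipelineDefaults()
  if (!is.null(config$stages)) def$stages[names(config$stages)] <- config$stages
  cfg <- def
  cfg[setdiff(names(config), "stages")] <-
    config[setdiff(names(config), "stages")]
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  artifacts <- character()
  results <- list()
  stage <- function(name, enabled, fn) {
    if (!enabled) return(NULL)
    tryCatch(fn(), error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  gm <- readVCF(cfg$vcf)
  metadata <- readSampleMetadata(cfg$metadata)

  results$qc <- stage("qc", cfg$stages$qc, function() {
    qc <- applyQC(gm, cfg$hetThreshold)
    artifacts <<- c(artifacts, writeCsv(qc$report, outDir, "qc_report.csv"))
    writeVCF(qc$gm, file.path(outDir, "genotypes_qc.vcf"))
    artifacts <<- c(artifacts, file.path(outDir, "genotypes_qc.vcf"))
    qc
  })
  gmQC <- if (!is.null(results$qc)) results$qc$gm else gm

  results$classify <- stage("classify", cfg$stages$classify, function() {
    phen <- utils::read.csv(cfg$phenotypes, stringsAsFactors = FALSE)
    cal <- buildCalibrationSet(phen, gmQC)
    model <- fitDapc(cal, kSubgroups = cfg$kSubgroups,
                     seed = cfg$seed + 10L)
    res <- predictPosterior(model, gmQC)
    res <- assignFinal(res, threshold = cfg$assignThreshold,
                       excludedSubgroups = cfg$excludedSubgroups)
    tab <- data.frame(id = rownames(res@posterior),
                      subgroup = res@bestSubgroup,
                      posterior = res@bestPosterior,
                      marketType = res@final,
                      subspecies = res@subspecies,
                      stringsAsFactors = FALSE)
    artifacts <<- c(artifacts, writeCsv(tab, outDir, "assignments.csv"))
    list(model = model, result = res, table = tab)
  })

  results$structure <- stage("structure", cfg$stages$structure, function() {
    sel <- selectKByStability(gmQC, cfg$kRange, runsPerK = cfg$runsPerK,
                              burnIn = cfg$burnIn, reps = cfg$reps,
                              thin = cfg$thin, seed = cfg$seed + 20L)
    ens <- sel$ensembles[[as.character(sel$K)]]
    fit <- ens@fits[[ens@medoid]]
    groups <- assignStructureGroups(fit, cfg$structureThreshold)
    Q <- as.data.frame(fit@Q)
    names(Q) <- paste0("Q", seq_len(fit@K))
    qtab <- cbind(data.frame(id = rownames(fit@Q),
                             stringsAsFactors = FALSE),
                  Q, data.frame(group = unname(groups)))
    artifacts <<- c(artifacts, writeCsv(qtab, outDir, "structure_Q.csv"))
    stab <- data.frame(K = as.integer(names(sel$stability)),
                       stability = unname(sel$stability))
    artifacts <<- c(artifacts, writeCsv(stab, outDir,
                                        "structure_stability.csv"))
    list(selection = sel, fit = fit, groups = groups)
  })

  results$diversity <- stage("diversity", cfg$stages$diversity, function() {
    dAS <- alleleSharingDist(gmQC, noOverlap = "na")
    tree <- wardTree(dAS)
    treeNewick(tree, file.path(outDir, "tree.newick"))
    artifacts <<- c(artifacts, file.path(outDir, "tree.newick"))
    related <- cutRelatedClusters(tree, d = dAS,
                                  quantile = cfg$cutQuantile,
                                  minSize = cfg$minClusterSize)
    subsp <- if (!is.null(results$classify))
      stats::setNames(results$classify$result@subspecies,
                      rownames(results$classify$result@posterior))
    else stats::setNames(rep("unassigned", nSamples(gmQC)),
                         sampleIds(gmQC))
    heTab <- programDiversityReport(gmQC, metadata, related, subsp)
    artifacts <<- c(artifacts, writeCsv(heTab, outDir, "he_report.csv"))
    dups <- detectNameDuplicates(metadata)
    artifacts <<- c(artifacts, writeCsv(dups, outDir,
                                        "name_duplicates.csv"))
    list(distance = dAS, tree = tree, related = related, he = heTab,
         duplicates = dups, subspecies = subsp)
  })

  results$core <- stage("core", cfg$stages$core, function() {
    dMR <- modifiedRogersDist(gmQC, noOverlap = "na")
    nominated <- if (!is.null(cfg$nominations))
      readLines(cfg$nominations)
    else metadata$id[metadata$breeder_nominated]
    nominated <- intersect(nominated, sampleIds(gmQC))
    fixed <- dedupNominations(nominated, dMR, cfg$dedupThreshold)
    core <- optimizeCore(sampleIds(gmQC), fixed, cfg$coreSize, dMR,
                         restarts = cfg$coreRestarts,
                         seed = cfg$seed + 30L)
    mt <- if (!is.null(results$classify))
      stats::setNames(results$classify$result@final,
                      rownames(results$classify$result@posterior))
    else stats::setNames(rep("unassigned", nSamples(gmQC)),
                         sampleIds(gmQC))
    report <- composeCoreReport(core, metadata, mt)
    selTab <- data.frame(id = core@selected,
                         provenance = core@provenance,
                         stringsAsFactors = FALSE)
    artifacts <<- c(artifacts, writeCsv(selTab, outDir,
                                        "core_selection.csv"))
    artifacts <<- c(artifacts, writeCsv(report, outDir,
                                        "core_report.csv"))
    if (!is.null(results$diversity)) {
      heCore <- programDiversityReport(gmQC, metadata,
                                       results$diversity$related,
                                       results$diversity$subspecies,
                                       coreIds = core@selected)
      artifacts <<- c(artifacts, writeCsv(heCore, outDir,
                                          "he_report_core.csv"))
    }
    list(core = core, report = report, fixed = fixed)
  })

  manifest <- list(
    package = "germDiv",
    version = as.character(utils::packageVersion("germDiv")),
    inputs = list(vcf = cfg$vcf, metadata = cfg$metadata,
                  phenotypes = cfg$phenotypes,
                  nominations = cfg$nominations),
    stages = cfg$stages[vapply(cfg$stages, isTRUE, logical(1))],
    parameters = cfg[setdiff(names(cfg),
                             c("stages", "vcf", "metadata", "phenotypes",
                               "nominations"))],
    seed = cfg$seed,
    artifacts = basename(artifacts))
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  results$manifest <- manifest
  invisible(results)
}

#' Run a bundled end-to-end demonstration
#'
#' Generates a small synthetic collection, writes its VCF/CSV inputs,
#' runs the full pipeline with desk-scale parameters and prints the
#' headline tables: final assignment counts, per-program expected
#' heterozygosity and the core-collection composition.
#'
#' @param outDir output directory, default a fresh temporary directory.
#' @param seed integer seed, default 42.
#' @param nSamples,nMarkers size of the demonstration collection.
#' @return invisibly, the [runPipeline()] result list.
#' @export
runDemo <- function(outDir = tempfile("germDiv_demo_"), seed = 42L,
                    nSamples = 100L, nMarkers = 200L) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  sim <- simulateCollection(simulationConfig(
    nSamples = nSamples, nMarkers = nMarkers, K = 3L,
    admixedFraction = 0.25, collapsedFraction = 0.08,
    missingRate = 0.02, congruentFraction = 0.9, seed = seed))
  vcf <- file.path(outDir, "collection.vcf")
  writeVCF(sim@gm, vcf)
  md <- file.path(outDir, "metadata.csv")
  meta <- sim@metadata
  set.seed(seed + 99L)
  meta$breeder_nominated <- seq_len(nrow(meta)) %in%
    sample.int(nrow(meta), max(6L, nrow(meta) %/% 20L))
  utils::write.csv(meta, md, row.names = FALSE)
  ph <- file.path(outDir, "phenotypes.csv")
  utils::write.csv(sim@phenotypes, ph, row.names = FALSE)
  cfg <- list(vcf = vcf, metadata = md, phenotypes = ph,
              kRange = 2:4, runsPerK = 2L, burnIn = 150L, reps = 450L,
              thin = 3L, coreSize = max(10L, nSamples %/% 5L),
              minClusterSize = 5L, seed = seed)
  res <- runPipeline(cfg, file.path(outDir, "run"))
  cat("== Final market-type assignment ==\n")
  print(table(res$classify$table$marketType))
  cat(sprintf("\n== Structure: selected K = %d ==\n",
              res$structure$selection$K))
  print(table(res$structure$groups))
  cat("\n== Per-program expected heterozygosity ==\n")
  print(res$diversity$he, digits = 3)
  cat("\n== Core collection composition ==\n")
  print(res$core$report, digits = 3)
  invisible(res)
}
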