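#' Study configuration
#'
#' Builds (and validates) the configuration consumed by [runStudy()].
#' Unknown keys are rejected. A configuration can also be loaded from a
#' YAML file with [readStudyConfig()]; all randomness flows from the single
#' `seed` field.
#'
#' @param synthetic generate the input ensembles with [generateStudy()]
#'   (`TRUE`, default) or read them from `inputPaths`.
#' @param inputPaths named list of multi-model PDB paths per state
#'   (`ff`, `fd`, `cf`, `cd`); states may be missing, in which case stages
#'   needing them are skipped.
#' @param s2Path optional path to an experimental S2 TSV
#'   ([readS2Table()] format); for synthetic studies the generated table is
#'   used when `NULL`.
#' @param pcaResidues residues analysed by PCA (`NULL` = all).
#' @param fitAtoms atom names of the fit group.
#' @param temperature entropy temperature, K.
#' @param thresholds state-partition thresholds along modes 1 and 2,
#'   Angstrom.
#' @param contactMetric `"soft_sphere"` or `"precomputed"`.
#' @param contactAreasPaths named list of per-state contact-area TSVs when
#'   `contactMetric = "precomputed"`.
#' @param contactStride evaluate contact areas on every `contactStride`-th
#'   model.
#' @param estimator entropy estimator, `"schlitter"` or `"quasiharmonic"`.
#' @param schedule convergence-trace schedule for the entropy ratio.
#' @param seed integer seed.
#' @param spec optional [syntheticSpec()] overriding the default synthetic
#'   study (its own seed is replaced by `seed`).
#' @param outputDir optional directory for the JSON report and TSV outputs.
#' @return list of class `StudyConfig`.
#' @export
studyConfig <- function(synthetic = TRUE, inputPaths = NULL, s2Path = NULL,
                        pcaResidues = NULL, fitAtoms = c("N", "CA"),
                        temperature = 300, thresholds = c(0, 0),
                        contactMetric = "soft_sphere",
                        contactAreasPaths = NULL, contactStride = 1,
                        estimator = "schlitter",
                        schedule = seq(0.1, 1, by = 0.1), seed = 1,
                        spec = NULL, outputDir = NULL) {
  cfg <- list(synthetic = synthetic, inputPaths = inputPaths,
              s2Path = s2Path, pcaResidues = pcaResidues,
              fitAtoms = fitAtoms, temperature = temperature,
              thresholds = thresholds, contactMetric = contactMetric,
              contactAreasPaths = contactAreasPaths,
              contactStride = as.integer(contactStride),
              estimator = estimator, schedule = schedule,
              seed = as.integer(seed), spec = spec, outputDir = outputDir)
  class(cfg) <- "StudyConfig"
  cfg
}

#' @rdname studyConfig
#' @param path YAML file with a subset of the `studyConfig()` fields.
#' @export
readStudyConfig <- function(path) {
  y <- yaml::read_yaml(path)
  known <- names(formals(studyConfig))
  bad <- setdiff(names(y), known)
  if (length(bad))
    stop("unknown configuration key(s): ", paste(bad, collapse = ", "))
  do.call(studyConfig, y)
}

#' Run the full ensemble-comparison study
#'
#' Orchestrates the pipeline end to end: obtain the four state ensembles
#' (synthetic or from disk), back-calculate and correlate S2 order
#' parameters, estimate the binding-entropy ratio with its convergence
#' trace, run combined-ensemble PCA with state partitioning (occupancies,
#' co-occurrence, per-replica visiting), compute discriminative contacts
#' and the contact network, and report per-state versus combined mode
#' overlaps (RMSIP). Stages whose inputs are missing are skipped with a
#' logged reason; the remaining stages still run.
#'
#' The returned report is deterministic given the configuration (including
#' its seed) and contains every numerical convention used (normalization,
#' temperature, thresholds, tie-breaks) for provenance.
#'
#' @param config a [studyConfig()] (or a YAML path understood by
#'   [readStudyConfig()]).
#' @param verbose log stage progress with `message()`.
#' @return A list of class `StudyReport`; also written as
#'   `report.json` under `config$outputDir` when set.
#' @export
runStudy <- function(config = studyConfig(), verbose = TRUE) {
  if (is.character(config)) config <- readStudyConfig(config)
  stopifnot(inherits(config, "StudyConfig"))
  say <- function(...) if (verbose) message("[runStudy] ", ...)
  report <- list(
    schemaVersion = "1.0",
    parameters = list(
      seed = config$seed, temperature = config$temperature,
      thresholds = config$thresholds, estimator = config$estimator,
      contactMetric = config$contactMetric,
      contactStride = config$contactStride,
      fitAtoms = config$fitAtoms,
      covarianceNormalization = "population (1/N)",
      tieBreak = "projections at the threshold go to the negative side",
      coOccurrence = "max[P(++)+P(--), P(+-)+P(-+)] along modes 1 and 2"
    ),
    skipped = list()
  )

  manifest <- NULL
  observedS2 <- NULL
  if (isTRUE(config$synthetic)) {
    say("generating synthetic study (seed ", config$seed, ")")
    spec <- config$spec %||% syntheticSpec()
    spec$seed <- config$seed
    study <- generateStudy(spec)
    ensembles <- study$ensembles
    observedS2 <- study$observedS2
    manifest <- study$manifest
  } else {
    say("reading ensembles from disk")
    ensembles <- lapply(config$inputPaths, readEnsemble)
    for (nm in names(ensembles))
      if (stateLabel(ensembles[[nm]]) == "unlabelled")
        ensembles[[nm]]@stateLabel <- nm
  }
  if (!is.null(config$s2Path)) observedS2 <- readS2Table(config$s2Path)
  states <- names(ensembles)
  fitSel <- atomSelection(atomNames = config$fitAtoms)

  # --- S2 stage ------------------------------------------------------------
  say("back-calculating S2 order parameters")
  fitted <- lapply(ensembles, fitEnsemble, fitSelection = fitSel)
  s2calc <- lapply(fitted, function(e) backCalculateS2(e))
  report$s2 <- list(calculated = s2calc)
  if (!is.null(observedS2)) {
    report$s2$correlations <- lapply(s2calc, function(tab) {
      lapply(correlateS2(tab, observedS2), function(x)
        x[c("r", "rmsd", "n")])
    })
  } else {
    report$skipped$s2Correlation <- "no experimental S2 table supplied"
  }

  # --- entropy stage -------------------------------------------------------
  need <- c("ff", "fd", "cf", "cd")
  if (all(need %in% states)) {
    say("estimating conformational entropies (", config$estimator, ")")
    ber <- bindingEntropyRatio(
      ensembles[need], fitSelection = fitSel,
      analysisSelection = atomSelection(heavyOnly = TRUE),
      temperature = config$temperature, estimator = config$estimator,
      schedule = config$schedule)
    report$entropy <- list(
      perState = c(ff = ber$s_ff, fd = ber$s_fd, cf = ber$s_cf,
                   cd = ber$s_cd),
      ratio = ber$ratio, convergence = ber$convergence,
      temperature = ber$temperature, estimator = ber$estimator)
  } else {
    report$skipped$entropy <- paste("missing state(s):",
                                    paste(setdiff(need, states),
                                          collapse = ", "))
    say("entropy stage skipped: ", report$skipped$entropy)
  }

  # --- modes stage ---------------------------------------------------------
  say("combined-ensemble PCA and state partition")
  pcaSel <- if (is.null(config$pcaResidues)) {
    atomSelection(atomNames = "CA")
  } else atomSelection(resno = config$pcaResidues, atomNames = "CA")
  ms <- combinedPCA(unname(ensembles), selection = pcaSel)
  cov10 <- varianceCoverage(ms, k = 10)
  part <- partitionStates(ms, thresholds = config$thresholds)
  report$modes <- list(
    eigenvalues = head(ms@values, 20),
    totalVariance = ms@totalVariance,
    pc1ShareFirst10 = cov10$leadingShare,
    first10Fraction = cov10$cumulativeFraction,
    occupancy = part$occupancy,
    coOccurrence = as.list(part$coOccurrence),
    replicaOccupancy = part$replicaOccupancy,
    joint = lapply(part$joint, function(m) as.data.frame(as.table(m)))
  )

  say("per-state versus combined mode overlap")
  report$overlap <- lapply(setNames(states, states), function(nm) {
    msI <- combinedPCA(ensembles[[nm]], selection = pcaSel)
    ov <- modeOverlap(msI, ms, k = 10)
    list(rmsip = ov$rmsip, k = ov$k)
  })

  # --- contacts stage ------------------------------------------------------
  if (config$contactMetric == "precomputed" &&
      is.null(config$contactAreasPaths)) {
    report$skipped$contacts <- "precomputed metric without contactAreasPaths"
    say("contacts stage skipped: ", report$skipped$contacts)
  } else {
    say("contact areas and discriminative-contact network")
    areas <- if (config$contactMetric == "precomputed") {
      lapply(config$contactAreasPaths, readContactAreas)
    } else {
      lapply(ensembles, function(e)
        contactAreas(e, models = seq(1, nModels(e),
                                     by = config$contactStride)))
    }
    stats <- contactStatistics(areas)
    disc <- discriminativeContacts(stats)
    net <- buildContactNetwork(disc)
    report$contacts <- list(
      nPairsObserved = nrow(unique(stats[, c("resI", "resJ")])),
      nDiscriminative = nrow(disc),
      discriminative = disc,
      componentSizes = net@componentSizes,
      nNodes = nrow(net@nodes),
      nNonzeroBetweenness = sum(net@nodes$betweenness > 0),
      nodes = net@nodes)
  }

  if (!is.null(manifest)) report$manifest <- manifest

  if (!is.null(config$outputDir)) {
    dir.create(config$outputDir, recursive = TRUE, showWarnings = FALSE)
    out <- report
    out$manifest$modeVectorsCA <- NULL     # bulky; PDBs carry the data
    jsonlite::write_json(out, file.path(config$outputDir, "report.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
    say("report written to ", file.path(config$outputDir, "report.json"))
  }
  class(report) <- "StudyReport"
  report
}

#' @export
print.StudyReport <- function(x, ...) {
  cat("StudyReport (schema", x$schemaVersion, ")\n")
  if (!is.null(x$entropy))
    cat(sprintf("  binding-entropy ratio: %.3f (%s)\n", x$entropy$ratio,
                x$entropy$estimator))
  if (!is.null(x$modes)) {
    cat(sprintf("  PC1 share of first 10 modes: %.1f%%\n",
                100 * x$modes$pc1ShareFirst10))
    print(x$modes$occupancy, row.names = FALSE)
  }
  if (!is.null(x$contacts))
    cat(sprintf("  discriminative contacts: %d; components: %s; nonzero betweenness: %d\n",
                x$contacts$nDiscriminative,
                paste(x$contacts$componentSizes, collapse = ","),
                x$contacts$nNonzeroBetweenness))
  for (nm in names(x$skipped))
    cat("  skipped ", nm, ": ", x$skipped[[nm]], "\n", sep = "")
  invisible(x)
}
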