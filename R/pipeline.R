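#' Build the absorbance matrix of a simulated study
#'
#' @param sim a \code{SyntheticATeem}.
#' @param range optional wavelength interval (nm) to crop to (closed on both
#'   ends), e.g. \code{c(240, 350)} for the UV block.
#' @return samples x wavelengths matrix with a \code{wavelength_nm} attribute.
#' @export
absorbanceMatrix <- function(sim, range = NULL) {
  g <- sim$config$absGrid
  keep <- if (is.null(range)) seq_along(g) else which(g >= min(range) & g <= max(range))
  if (!length(keep)) stop("absorbance crop leaves no wavelengths")
  m <- t(vapply(sim$absorbance, function(a) a@absorbance[keep], numeric(length(keep))))
  dimnames(m) <- list(sim$sampleIds, sprintf("a%g", g[keep]))
  attr(m, "wavelength_nm") <- g[keep]
  m
}

#' Fit and evaluate one classification block
#'
#' Chooses the latent-variable count by cross-validation (parsimony rule),
#' fits the PLS-DA model on the full block, and reports calibration
#' (fitted-model) confusion counts and Eq-style metrics for both possible
#' "class 1" conventions, alongside the cross-validation table.
#'
#' @param Xmat samples x variables matrix for the block.
#' @param labels class labels.
#' @param block block name for reporting.
#' @param maxLV largest LV count scanned.
#' @param scheme cross-validation scheme, see \code{\link{crossValidatePLSDA}}.
#' @return list with the model, chosen LV, confusion matrices and metrics.
#' @export
classifyBlock <- function(Xmat, labels, block = "block", maxLV = 8L,
                          scheme = "leave_one_out") {
  enc <- classEncoding(labels)
  cv <- crossValidatePLSDA(Xmat, enc, maxLV = maxLV, scheme = scheme)
  model <- fitPLSDA(Xmat, enc, cv$nLV)
  pred <- predictPLSDA(model, Xmat)$class
  metricsFor <- function(positive) {
    cm <- confusionMatrix(truth = enc$labels, predicted = pred, positive = positive)
    list(
      cm = cm, sensitivity = sensitivity(cm), specificity = specificity(cm),
      misclassification = misclassificationError(cm)
    )
  }
  list(
    block = block, nLV = model@nLV, model = model, cvTable = cv$cvTable,
    predicted = pred,
    class1_direct = metricsFor("direct"),
    class1_processed = metricsFor("processed")
  )
}

#' Summarise classification blocks as a performance table
#'
#' One row per block: latent variables, misclassification error, and the
#' class-1 sensitivity/specificity under both class-1 conventions (which
#' class is "positive" is a reporting choice, so both are given).
#'
#' @param blocks list of \code{\link{classifyBlock}} results.
#' @return data.frame (empty with headers for empty input).
#' @export
makeTable2 <- function(blocks) {
  cols <- c(
    "block", "nLV", "misclassification", "sensitivity_class1_direct",
    "specificity_class1_direct", "sensitivity_class1_processed",
    "specificity_class1_processed"
  )
  if (!length(blocks)) {
    df <- as.data.frame(setNames(rep(list(numeric(0)), length(cols)), cols))
    df$block <- character(0)
    return(df)
  }
  do.call(rbind, lapply(blocks, function(b) {
    data.frame(
      block = b$block, nLV = b$nLV,
      misclassification = round(b$class1_direct$misclassification, 3),
      sensitivity_class1_direct = round(b$class1_direct$sensitivity, 2),
      specificity_class1_direct = round(b$class1_direct$specificity, 2),
      sensitivity_class1_processed = round(b$class1_processed$sensitivity, 2),
      specificity_class1_processed = round(b$class1_processed$specificity, 2)
    )
  }))
}

#' Run the full A-TEEM analysis pipeline on simulated data
#'
#' Executes, in fixed order: simulation; preprocessing (inner-filter
#' correction, Rayleigh excision, replicate averaging) with a masked dataset
#' for PARAFAC and an emission-interpolated dataset for PCA/PLS-DA; PARAFAC
#' component-number scan with CORCONDIA, split-half validation at the chosen
#' F, and class-wise score t-tests; PCA of the absorbance matrix and of the
#' unfolded EEMs; PLS-DA for the six standard input blocks (full UV-vis, UV,
#' vis, unfolded EEMs, PARAFAC scores, emission slices at 275/305/365 nm);
#' and a consolidated report. All randomness (simulation, ALS starts,
#' split-half partition) derives from the configuration's master seed.
#'
#' @param config a \code{SyntheticConfig}.
#' @param outdir optional directory; when given, the report JSON, the
#'   performance table, score/loading CSVs and the simulated study are
#'   persisted there.
#' @param candidates PARAFAC component counts to scan.
#' @param parafacControl list of arguments passed to \code{\link{fitParafac}}
#'   (e.g. \code{nStarts}, \code{tol}, \code{maxIter}).
#' @param maxLV largest PLS-DA latent-variable count scanned per block.
#' @param emissionSlices excitation wavelengths (nm) of the emission-slice
#'   block.
#' @return list of class \code{RunReport}.
#' @export
runPipeline <- function(config = defaultSyntheticConfig(), outdir = NULL,
                        candidates = 3:5, parafacControl = list(),
                        maxLV = 8L, emissionSlices = c(275, 305, 365)) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
        call. = FALSE)
    })
  }
  set.seed(config$seed)
  stageSeeds <- sample.int(2^31 - 1L, 3L)

  sim <- stage("simulate", simulateDataset(config))
  # generous excision for PARAFAC: scatter is non-trilinear and masked cells
  # are free under the weighted ALS; classification keeps the narrower bands
  dsMask <- stage("preprocess",
    preprocessSimulated(sim, scatterSpec(
      order1Halfwidth = 14, order2Halfwidth = 21, fillPolicy = "mask"
    )))
  dsInterp <- stage("preprocess",
    preprocessSimulated(sim, scatterSpec(fillPolicy = "interpolate_emission")))
  nExcised <- sum(is.na(dsMask@array))

  pf <- function(X, f, seed) {
    do.call(fitParafac, c(list(X = X, nComponents = f, seed = seed), parafacControl))
  }
  sel <- stage("parafac", {
    models <- lapply(candidates, function(f) pf(dsMask, f, stageSeeds[1L]))
    tab <- data.frame(
      nComponents = candidates,
      fitPercent = vapply(models, function(m) m@fitPercent, 0),
      corcondia = vapply(models, function(m) m@corcondia, 0)
    )
    pass <- which(tab$corcondia >= 80)
    best <- if (length(pass)) candidates[max(pass)] else candidates[1L]
    list(nComponents = best, diagnostics = tab,
      model = models[[match(best, candidates)]])
  })
  sh <- stage("parafac", do.call(splitHalf, c(
    list(X = dsMask, nComponents = sel$nComponents, seed = stageSeeds[2L]),
    parafacControl
  )))
  scoreTests <- stage("parafac",
    compareClassScores(parafacScores(sel$model), sampleLabels(dsMask)))

  absMat <- absorbanceMatrix(sim)
  ueem <- unfoldDataset(dsInterp)
  pcaAbs <- stage("pca", fitPCA(absMat))
  pcaUeem <- stage("pca", fitPCA(ueem))

  blocks <- stage("plsda", list(
    classifyBlock(absMat, sim$labels, "uvvis", maxLV),
    classifyBlock(absorbanceMatrix(sim, c(240, 350)), sim$labels, "uv", maxLV),
    classifyBlock(absorbanceMatrix(sim, c(350, 600)), sim$labels, "vis", maxLV),
    classifyBlock(ueem, sim$labels, "ueem", maxLV),
    classifyBlock(parafacScores(sel$model), sim$labels, "parafac_scores",
      min(maxLV, sel$nComponents)),
    classifyBlock(extractEmissionSlices(dsInterp, emissionSlices), sim$labels,
      sprintf("emslices:%s", paste(emissionSlices, collapse = ",")), maxLV)
  ))
  table2 <- makeTable2(blocks)

  report <- structure(
    list(
      config = config,
      seeds = list(master = config$seed, parafac = stageSeeds[1L],
        splitHalf = stageSeeds[2L]),
      preprocessing = list(
        nCellsExcised = nExcised,
        order = c("ife_correct", "remove_rayleigh", "average_replicates")
      ),
      parafac = list(
        nComponents = sel$nComponents, diagnostics = sel$diagnostics,
        model = sel$model, splitHalfSimilarity = sh$similarity,
        scoreTests = scoreTests
      ),
      pca = list(
        absorbance = pcaAbs@explainedVariance,
        ueem = pcaUeem@explainedVariance
      ),
      classification = table2,
      blocks = blocks,
      version = as.character(utils::packageVersion("ateem"))
    ),
    class = "RunReport"
  )
  if (!is.null(outdir)) .persistReport(report, sim, outdir)
  report
}

.persistReport <- function(report, sim, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  writeSimulated(sim, file.path(outdir, "simulated"))
  m <- report$parafac$model
  write.csv(
    data.frame(sample = sim$sampleIds, parafacScores(m)),
    file.path(outdir, "parafac_scores.csv"), row.names = FALSE
  )
  write.csv(
    data.frame(em_nm = m@em, parafacLoadings(m, "em")),
    file.path(outdir, "parafac_em_loadings.csv"), row.names = FALSE
  )
  write.csv(
    data.frame(ex_nm = m@ex, parafacLoadings(m, "ex")),
    file.path(outdir, "parafac_ex_loadings.csv"), row.names = FALSE
  )
  write.csv(report$classification, file.path(outdir, "classification_table.csv"),
    row.names = FALSE)
  jsonlite::write_json(
    list(
      seeds = report$seeds,
      preprocessing = report$preprocessing,
      parafacDiagnostics = report$parafac$diagnostics,
      nComponents = report$parafac$nComponents,
      splitHalfSimilarity = report$parafac$splitHalfSimilarity,
      scoreTests = report$parafac$scoreTests,
      pcaExplainedVariance = report$pca,
      classification = report$classification,
      version = report$version
    ),
    file.path(outdir, "report.json"),
    auto_unbox = TRUE, digits = NA, dataframe = "rows"
  )
  invisible(outdir)
}

#' @export
print.RunReport <- function(x, ...) {
  cat("A-TEEM pipeline report\n")
  cat(sprintf("  master seed: %d\n", x$seeds$master))
  cat(sprintf("  preprocessing: %s; %d cells excised\n",
    paste(x$preprocessing$order, collapse = " -> "), x$preprocessing$nCellsExcised))
  cat(sprintf("  PARAFAC: F = %d, CORCONDIA = %.1f%%, split-half = %.1f%%\n",
    x$parafac$nComponents,
    x$parafac$diagnostics$corcondia[
      x$parafac$diagnostics$nComponents == x$parafac$nComponents],
    x$parafac$splitHalfSimilarity))
  cat(sprintf("  PCA variance (absorbance): %s\n",
    paste(sprintf("%.2f%%", head(x$pca$absorbance, 2)), collapse = ", ")))
  cat(sprintf("  PCA variance (uEEM): %s\n",
    paste(sprintf("%.2f%%", head(x$pca$ueem, 2)), collapse = ", ")))
  cat("  classification:\n")
  print(x$classification, row.names = FALSE)
  invisible(x)
}
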