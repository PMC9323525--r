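#' @importFrom methods new validObject setClass setValidity setMethod setGeneric
#'   is slot show
#' @importFrom stats sd qnorm pnorm dnorm runif rnorm optim t.test approx
#'   median setNames
#' @importFrom utils read.csv write.csv head
NULL

setClassUnion("matrixOrNULL", c("matrix", "NULL"))

#' EEM: a single excitation-emission matrix
#'
#' Fluorescence landscape of one sample on an excitation x emission wavelength
#' grid. Rows of \code{intensity} follow the emission grid, columns the
#' excitation grid. Cells excised during preprocessing (e.g. Rayleigh scatter)
#' are \code{NA} in \code{intensity} and \code{TRUE} in \code{mask}; masked
#' cells are excluded from all downstream fits.
#'
#' @slot ex numeric, excitation wavelengths (nm), strictly increasing.
#' @slot em numeric, emission wavelengths (nm), strictly increasing.
#' @slot intensity numeric matrix, \code{length(em)} x \code{length(ex)}.
#' @slot sampleId character scalar.
#' @slot mask logical matrix of the same shape, or NULL (no cells excised).
#' @export
setClass("EEM",
  representation(
    ex = "numeric", em = "numeric", intensity = "matrix",
    sampleId = "character", mask = "matrixOrNULL"
  ),
  prototype(mask = NULL)
)

.checkGrid <- function(g, what) {
  if (length(g) < 2L) return(sprintf("%s grid needs >= 2 wavelengths", what))
  if (any(!is.finite(g)) || any(g <= 0)) {
    return(sprintf("%s grid must be finite and positive", what))
  }
  if (any(diff(g) <= 0)) return(sprintf("%s grid must be strictly increasing", what))
  NULL
}

setValidity("EEM", function(object) {
  msgs <- c(.checkGrid(object@ex, "excitation"), .checkGrid(object@em, "emission"))
  d <- dim(object@intensity)
  if (d[1L] != length(object@em) || d[2L] != length(object@ex)) {
    msgs <- c(msgs, sprintf(
      "intensity is %d x %d but grids imply %d x %d",
      d[1L], d[2L], length(object@em), length(object@ex)
    ))
  }
  if (!is.null(object@mask)) {
    if (!identical(dim(object@mask), d)) msgs <- c(msgs, "mask shape differs from intensity")
    if (!is.logical(object@mask)) msgs <- c(msgs, "mask must be logical")
  }
  bad <- !is.finite(object@intensity)
  if (!is.null(object@mask)) bad <- bad & !object@mask else if (any(bad)) {
    msgs <- c(msgs, "non-finite intensities outside mask")
    bad <- FALSE
  }
  if (any(bad)) msgs <- c(msgs, "non-finite intensities outside mask")
  if (length(object@sampleId) != 1L) msgs <- c(msgs, "sampleId must be a single string")
  if (length(msgs)) msgs else TRUE
})

#' Construct an EEM object
#'
#' @param intensity numeric matrix (emission x excitation).
#' @param em,ex wavelength grids in nm.
#' @param sampleId sample identifier.
#' @param mask optional logical matrix of excised cells; inferred from
#'   \code{NA} intensities when omitted.
#' @return An \linkS4class{EEM}.
#' @export
EEM <- function(intensity, em, ex, sampleId = "sample", mask = NULL) {
  intensity <- as.matrix(intensity)
  storage.mode(intensity) <- "double"
  if (is.null(mask) && anyNA(intensity)) mask <- is.na(intensity)
  if (!is.null(mask)) intensity[mask] <- NA_real_
  new("EEM",
    ex = as.numeric(ex), em = as.numeric(em), intensity = intensity,
    sampleId = as.character(sampleId), mask = mask
  )
}

setMethod("show", "EEM", function(object) {
  n_mask <- if (is.null(object@mask)) 0L else sum(object@mask)
  cat(sprintf(
    "EEM '%s': %d em x %d ex (em %.1f-%.1f nm, ex %.1f-%.1f nm), %d masked cells\n",
    object@sampleId, length(object@em), length(object@ex),
    min(object@em), max(object@em), min(object@ex), max(object@ex), n_mask
  ))
})

#' AbsorbanceSpectrum: a UV-vis absorbance spectrum
#'
#' @slot wavelength numeric, nm, strictly increasing.
#' @slot absorbance numeric, AU, aligned to \code{wavelength}. Negative values
#'   are tolerated (baseline artifacts) but flagged by the constructor.
#' @slot sampleId character scalar.
#' @export
setClass("AbsorbanceSpectrum",
  representation(wavelength = "numeric", absorbance = "numeric", sampleId = "character")
)

setValidity("AbsorbanceSpectrum", function(object) {
  msgs <- .checkGrid(object@wavelength, "absorbance")
  if (length(object@absorbance) != length(object@wavelength)) {
    msgs <- c(msgs, "absorbance and wavelength lengths differ")
  }
  if (any(!is.finite(object@absorbance))) msgs <- c(msgs, "absorbance must be finite")
  if (length(msgs)) msgs else TRUE
})

#' Construct an AbsorbanceSpectrum
#'
#' @param wavelength nm grid.
#' @param absorbance AU values.
#' @param sampleId sample identifier.
#' @return An \linkS4class{AbsorbanceSpectrum}.
#' @export
AbsorbanceSpectrum <- function(wavelength, absorbance, sampleId = "sample") {
  obj <- new("AbsorbanceSpectrum",
    wavelength = as.numeric(wavelength),
    absorbance = as.numeric(absorbance), sampleId = as.character(sampleId)
  )
  if (any(obj@absorbance < 0)) {
    warning(sprintf(
      "negative absorbance in '%s' (baseline artifact?)", obj@sampleId
    ), call. = FALSE)
  }
  obj
}

setMethod("show", "AbsorbanceSpectrum", function(object) {
  cat(sprintf(
    "AbsorbanceSpectrum '%s': %d points, %.0f-%.0f nm, max A = %.3f\n",
    object@sampleId, length(object@wavelength),
    min(object@wavelength), max(object@wavelength), max(object@absorbance)
  ))
})

#' EEMDataset: aligned three-way EEM array with class labels
#'
#' Samples x emission x excitation intensity array on shared grids, with one
#' class label per sample (two classes, e.g. direct vs processed).
#'
#' @slot array numeric 3-way array (samples x em x ex); \code{NA} = masked.
#' @slot samples character, sample ids in array order.
#' @slot labels factor with exactly two levels.
#' @slot em,ex shared wavelength grids (nm).
#' @export
setClass("EEMDataset",
  representation(
    array = "array", samples = "character", labels = "factor",
    em = "numeric", ex = "numeric"
  )
)

setValidity("EEMDataset", function(object) {
  msgs <- c(.checkGrid(object@ex, "excitation"), .checkGrid(object@em, "emission"))
  d <- dim(object@array)
  if (length(d) != 3L) msgs <- c(msgs, "array must be 3-way")
  else {
    if (d[1L] != length(object@samples)) msgs <- c(msgs, "sample count mismatch")
    if (d[2L] != length(object@em) || d[3L] != length(object@ex)) {
      msgs <- c(msgs, "array em/ex dimensions do not match grids")
    }
  }
  if (length(object@labels) != length(object@samples)) {
    msgs <- c(msgs, "one label per sample required")
  }
  if (nlevels(object@labels) != 2L) msgs <- c(msgs, "labels must have exactly two classes")
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "EEMDataset", function(object) {
  d <- dim(object@array)
  cat(sprintf(
    "EEMDataset: %d samples x %d em x %d ex; classes: %s; %d masked cells\n",
    d[1L], d[2L], d[3L],
    paste(sprintf("%s (%d)", levels(object@labels), table(object@labels)), collapse = ", "),
    sum(is.na(object@array))
  ))
})

#' Number of samples in an EEMDataset
#' @param ds an \linkS4class{EEMDataset}.
#' @return integer.
#' @export
nSamples <- function(ds) dim(ds@array)[1L]

#' Class labels of an EEMDataset
#' @param ds an \linkS4class{EEMDataset}.
#' @return factor of per-sample labels.
#' @export
sampleLabels <- function(ds) ds@labels

#' Emission / excitation grids
#' @param x an object with wavelength grids (EEM or EEMDataset).
#' @return numeric vector of wavelengths (nm).
#' @export
emGrid <- function(x) x@em

#' @rdname emGrid
#' @export
exGrid <- function(x) x@ex

#' ParafacModel: fitted trilinear decomposition
#'
#' Holds the trilinear model X[i,j,k] = sum_f A[i,f] B[j,f] C[k,f] with
#' emission (B) and excitation (C) loadings normalised to unit Euclidean norm,
#' so the sample scores A carry the intensity scale.
#'
#' @slot nComponents integer.
#' @slot scores samples x F matrix (intensity-scaled).
#' @slot emLoadings |em| x F, unit-norm columns.
#' @slot exLoadings |ex| x F, unit-norm columns.
#' @slot fitPercent percent of observed sum of squares explained.
#' @slot corcondia core consistency diagnostic, percent (NA until computed).
#' @slot nIter ALS iterations used.
#' @slot converged logical.
#' @slot em,ex wavelength grids the loadings refer to.
#' @export
setClass("ParafacModel",
  representation(
    nComponents = "integer", scores = "matrix", emLoadings = "matrix",
    exLoadings = "matrix", fitPercent = "numeric", corcondia = "numeric",
    nIter = "integer", converged = "logical", em = "numeric", ex = "numeric"
  )
)

setValidity("ParafacModel", function(object) {
  f <- object@nComponents
  msgs <- character()
  if (ncol(object@scores) != f || ncol(object@emLoadings) != f ||
    ncol(object@exLoadings) != f) {
    msgs <- c(msgs, "factor matrices must all have nComponents columns")
  }
  nrmB <- sqrt(colSums(object@emLoadings^2))
  nrmC <- sqrt(colSums(object@exLoadings^2))
  if (any(abs(nrmB - 1) > 1e-6) || any(abs(nrmC - 1) > 1e-6)) {
    msgs <- c(msgs, "em/ex loading columns must have unit norm")
  }
  if (object@fitPercent > 100 + 1e-8) msgs <- c(msgs, "fitPercent cannot exceed 100")
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "ParafacModel", function(object) {
  cat(sprintf(
    "ParafacModel: %d components, fit = %.2f%%, CORCONDIA = %s, %d iterations%s\n",
    object@nComponents, object@fitPercent,
    if (is.na(object@corcondia)) "not computed" else sprintf("%.1f%%", object@corcondia),
    object@nIter, if (object@converged) "" else " (NOT converged)"
  ))
  pk <- function(L, g) g[apply(L, 2L, which.max)]
  cat("  loading maxima (ex/em nm): ",
    paste(sprintf(
      "%.0f/%.0f", pk(object@exLoadings, object@ex), pk(object@emLoadings, object@em)
    ), collapse = ", "), "\n",
    sep = ""
  )
})

#' Extract PARAFAC sample scores
#' @param model a \linkS4class{ParafacModel}.
#' @return samples x F numeric matrix.
#' @export
parafacScores <- function(model) model@scores

#' Extract PARAFAC spectral loadings
#' @param model a \linkS4class{ParafacModel}.
#' @param mode \code{"em"} or \code{"ex"}.
#' @return wavelengths x F matrix with unit-norm columns.
#' @export
parafacLoadings <- function(model, mode = c("em", "ex")) {
  switch(match.arg(mode), em = model@emLoadings, ex = model@exLoadings)
}

#' PCAModel: principal component decomposition
#'
#' @slot loadings variables x components, orthonormal columns.
#' @slot scores samples x components.
#' @slot explainedVariance percent per component, non-increasing.
#' @slot center,scale preprocessing vectors applied to the data.
#' @slot preprocessing "mean_center" or "autoscale".
#' @export
setClass("PCAModel",
  representation(
    loadings = "matrix", scores = "matrix", explainedVariance = "numeric",
    center = "numeric", scale = "numeric", preprocessing = "character"
  )
)

setValidity("PCAModel", function(object) {
  msgs <- character()
  ev <- object@explainedVariance
  if (any(diff(ev) > 1e-8)) msgs <- c(msgs, "explained variance must be non-increasing")
  if (any(ev < -1e-8 | ev > 100 + 1e-8) || sum(ev) > 100 + 1e-6) {
    msgs <- c(msgs, "explained variances must lie in [0,100] and sum to <= 100")
  }
  G <- crossprod(object@loadings)
  if (max(abs(G - diag(ncol(G)))) > 1e-6) msgs <- c(msgs, "loadings must be orthonormal")
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "PCAModel", function(object) {
  cat(sprintf(
    "PCAModel (%s): %d components; explained variance: %s\n",
    object@preprocessing, ncol(object@loadings),
    paste(sprintf("%.2f%%", object@explainedVariance), collapse = ", ")
  ))
})

#' PLSDAModel: two-class PLS discriminant analysis
#'
#' PLS2 regression of a two-column 0/1 class membership matrix on
#' mean-centered spectra; class assignment by argmax of the predicted
#' dummy columns.
#'
#' @slot nLV latent variables retained.
#' @slot weights,xLoadings variables x LV (NIPALS W and P).
#' @slot yLoadings 2 x LV (Q).
#' @slot coefficients variables x 2 regression coefficients.
#' @slot xCenter,yCenter centering vectors.
#' @slot classes the two class labels, column order of Y.
#' @slot vip per-variable importance in projection (mean squared VIP = 1).
#' @slot ssyPerLV Y sum of squares explained per latent variable.
#' @slot cvTable data.frame of cross-validated misclassification per LV
#'   (empty until cross-validation is run).
#' @export
setClass("PLSDAModel",
  representation(
    nLV = "integer", weights = "matrix", xLoadings = "matrix",
    yLoadings = "matrix", coefficients = "matrix", xCenter = "numeric",
    yCenter = "numeric", classes = "character", vip = "numeric",
    ssyPerLV = "numeric", cvTable = "data.frame"
  )
)

setValidity("PLSDAModel", function(object) {
  msgs <- character()
  if (length(object@classes) != 2L) msgs <- c(msgs, "exactly two classes required")
  if (length(object@vip) != nrow(object@weights)) {
    msgs <- c(msgs, "vip length must equal number of X variables")
  }
  if (abs(mean(object@vip^2) - 1) > 1e-6) msgs <- c(msgs, "mean squared VIP must equal 1")
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "PLSDAModel", function(object) {
  cat(sprintf(
    "PLSDAModel: %d latent variables, classes (%s), %d variables\n",
    object@nLV, paste(object@classes, collapse = " vs "), nrow(object@weights)
  ))
})

#' ConfusionMatrix: 2x2 classification counts
#'
#' Counts are relative to a designated positive class: TP and FN count
#' positive-class samples, TN and FP negative-class samples.
#'
#' @slot TP,TN,FP,FN non-negative integer counts.
#' @slot positive label of the positive class ("class 1").
#' @export
setClass("ConfusionMatrix",
  representation(
    TP = "integer", TN = "integer", FP = "integer", FN = "integer",
    positive = "character"
  )
)

setValidity("ConfusionMatrix", function(object) {
  v <- c(object@TP, object@TN, object@FP, object@FN)
  if (any(v < 0)) return("counts must be non-negative")
  if (sum(v) < 1L) return("total count must be >= 1")
  TRUE
})

setMethod("show", "ConfusionMatrix", function(object) {
  cat(sprintf(
    "ConfusionMatrix (positive = '%s'): TP=%d TN=%d FP=%d FN=%d\n",
    object@positive, object@TP, object@TN, object@FP, object@FN
  ))
})

#' Construct a ConfusionMatrix
#'
#' Either give the four counts directly, or truth/predicted label vectors.
#'
#' @param TP,TN,FP,FN counts.
#' @param truth,predicted label vectors (used when counts are missing).
#' @param positive label treated as the positive class.
#' @return A \linkS4class{ConfusionMatrix}.
#' @export
confusionMatrix <- function(TP = NULL, TN = NULL, FP = NULL, FN = NULL,
                            truth = NULL, predicted = NULL, positive = "direct") {
  if (is.null(TP)) {
    stopifnot(!is.null(truth), !is.null(predicted), length(truth) == length(predicted))
    truth <- as.character(truth)
    predicted <- as.character(predicted)
    pos <- truth == positive
    TP <- sum(pos & predicted == positive)
    FN <- sum(pos & predicted != positive)
    TN <- sum(!pos & predicted != positive)
    FP <- sum(!pos & predicted == positive)
  }
  new("ConfusionMatrix",
    TP = as.integer(TP), TN = as.integer(TN), FP = as.integer(FP),
    FN = as.integer(FN), positive = as.character(positive)
  )
}
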