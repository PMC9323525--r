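#' Stack EEMs into a three-way dataset
#'
#' Assembles aligned per-sample EEMs into a samples x emission x excitation
#' array, preserving the input order and every intensity value bit-exactly.
#'
#' @param eems list of \linkS4class{EEM} objects on identical grids.
#' @param labels class label per sample (two classes).
#' @return An \linkS4class{EEMDataset}.
#' @export
stackDataset <- function(eems, labels) {
  if (length(eems) < 2L) stop("need at least 2 samples to stack")
  if (length(labels) != length(eems)) stop("one label per sample required")
  ref <- eems[[1L]]
  for (e in eems) {
    if (!isTRUE(all.equal(e@ex, ref@ex)) || !isTRUE(all.equal(e@em, ref@em))) {
      stop(sprintf("grid mismatch: sample '%s' is not aligned with '%s'",
        e@sampleId, ref@sampleId))
    }
  }
  arr <- array(NA_real_, c(length(eems), length(ref@em), length(ref@ex)))
  for (i in seq_along(eems)) arr[i, , ] <- eems[[i]]@intensity
  new("EEMDataset",
    array = arr,
    samples = vapply(eems, function(e) e@sampleId, ""),
    labels = factor(labels), em = ref@em, ex = ref@ex
  )
}

#' Crop a dataset to wavelength ranges
#'
#' Keeps grid points with \code{range[1] <= lambda <= range[2]} (closed
#' interval on both ends) in each mode and subsets the intensities
#' accordingly. Cropping twice with the same ranges is a no-op.
#'
#' @param ds an \linkS4class{EEMDataset}.
#' @param exRange,emRange length-2 numeric intervals (nm); NULL keeps the
#'   full grid.
#' @return The cropped \linkS4class{EEMDataset}.
#' @export
cropDataset <- function(ds, exRange = NULL, emRange = NULL) {
  keep <- function(g, r, what) {
    if (is.null(r)) return(seq_along(g))
    idx <- which(g >= min(r) & g <= max(r))
    if (!length(idx)) {
      stop(sprintf("%s crop [%g, %g] leaves no grid points", what, min(r), max(r)))
    }
    idx
  }
  ie <- keep(ds@ex, exRange, "excitation")
  im <- keep(ds@em, emRange, "emission")
  new("EEMDataset",
    array = ds@array[, im, ie, drop = FALSE], samples = ds@samples,
    labels = ds@labels, em = ds@em[im], ex = ds@ex[ie]
  )
}

#' Unfold a dataset along the sample mode
#'
#' Produces the samples x (emission * excitation) matrix ("uEEM"). Column
#' ordering is fixed: the emission index varies fastest, the excitation
#' index slowest, i.e. column (k-1)*|em| + j holds emission j at excitation
#' k. The per-column wavelength tags are attached as attributes
#' \code{em_nm} and \code{ex_nm} and as column names \code{"em<j>_ex<k>"}.
#'
#' @param ds an \linkS4class{EEMDataset}.
#' @return numeric matrix with wavelength-tag attributes.
#' @export
unfoldDataset <- function(ds) {
  d <- dim(ds@array)
  m <- matrix(ds@array, nrow = d[1L])  # array major order = em fastest
  em_tag <- rep(ds@em, times = d[3L])
  ex_tag <- rep(ds@ex, each = d[2L])
  dimnames(m) <- list(ds@samples, sprintf("em%g_ex%g", em_tag, ex_tag))
  attr(m, "em_nm") <- em_tag
  attr(m, "ex_nm") <- ex_tag
  m
}

#' Refold an unfolded variable vector into an em x ex matrix
#'
#' Inverse of the column ordering of \code{\link{unfoldDataset}} applied to a
#' single unfolded row (e.g. a VIP vector or one sample's spectrum).
#'
#' @param v numeric vector of length |em| * |ex|.
#' @param em,ex the wavelength grids defining the target shape.
#' @return |em| x |ex| numeric matrix with wavelength dimnames.
#' @export
refoldVector <- function(v, em, ex) {
  if (length(v) != length(em) * length(ex)) {
    stop(sprintf(
      "vector length %d does not match |em| * |ex| = %d",
      length(v), length(em) * length(ex)
    ))
  }
  matrix(as.numeric(v), nrow = length(em), ncol = length(ex),
    dimnames = list(em, ex))
}
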