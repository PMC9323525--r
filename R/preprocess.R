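#' Inner-filter-effect correction
#'
#' Multiplicative absorbance-based correction for primary (excitation) and
#' secondary (emission) inner filtering in a 1 cm cuvette:
#' \deqn{F_{corr}(\lambda_{ex}, \lambda_{em}) =
#'   F_{obs} \cdot 10^{(A(\lambda_{ex}) + A(\lambda_{em})) / 2}.}
#' Absorbance is interpolated linearly onto the EEM grids, which the
#' absorbance grid must cover. Since the factor is \eqn{\ge 1} whenever
#' \eqn{A \ge 0}, correction never decreases an intensity for non-negative
#' absorbance. Masked cells pass through untouched.
#'
#' @param eem an \linkS4class{EEM}.
#' @param absSpec the sample's \linkS4class{AbsorbanceSpectrum}.
#' @return The corrected \linkS4class{EEM}, with the per-cell correction
#'   factors attached as attribute \code{ifeFactors}.
#' @export
ifeCorrect <- function(eem, absSpec) {
  stopifnot(is(eem, "EEM"), is(absSpec, "AbsorbanceSpectrum"))
  wl <- absSpec@wavelength
  need <- range(c(eem@ex, eem@em))
  if (need[1L] < min(wl) || need[2L] > max(wl)) {
    stop(sprintf(
      "absorbance grid (%g-%g nm) does not cover EEM wavelengths (%g-%g nm)",
      min(wl), max(wl), need[1L], need[2L]
    ))
  }
  if (max(absSpec@absorbance) > 2.0) {
    warning(sprintf(
      "absorbance exceeds 2.0 AU for '%s'; IFE correction unreliable at high optical density",
      absSpec@sampleId
    ), call. = FALSE)
  }
  Aex <- approx(wl, absSpec@absorbance, xout = eem@ex)$y
  Aem <- approx(wl, absSpec@absorbance, xout = eem@em)$y
  factors <- 10^(outer(Aem, Aex, `+`) / 2)
  out <- eem
  out@intensity <- eem@intensity * factors
  if (!is.null(eem@mask)) out@intensity[eem@mask] <- eem@intensity[eem@mask]
  attr(out@intensity, "ifeFactors") <- factors
  out
}

#' Rayleigh scatter excision specification
#'
#' @param order1Halfwidth nm half-width of the first-order band
#'   (\eqn{|\lambda_{em} - \lambda_{ex}|}).
#' @param order2Halfwidth nm half-width of the second-order band
#'   (\eqn{|\lambda_{em} - 2\lambda_{ex}|}).
#' @param fillPolicy what to put in excised cells: \code{"mask"} (NA, excluded
#'   from fits; appropriate for missing-data PARAFAC), \code{"interpolate_emission"}
#'   (linear interpolation along the emission axis; needed by PCA/PLS-DA which
#'   require complete matrices), or \code{"zero"}.
#' @return A list of class \code{ScatterSpec}.
#' @export
scatterSpec <- function(order1Halfwidth = 10, order2Halfwidth = 15,
                        fillPolicy = c("mask", "interpolate_emission", "zero")) {
  if (order1Halfwidth <= 0 || order2Halfwidth <= 0) stop("halfwidths must be > 0")
  structure(
    list(
      order1Halfwidth = order1Halfwidth, order2Halfwidth = order2Halfwidth,
      fillPolicy = match.arg(fillPolicy)
    ),
    class = "ScatterSpec"
  )
}

#' Remove Rayleigh scatter ridges
#'
#' Excises cells within the first-order (\eqn{\lambda_{em} \approx
#' \lambda_{ex}}) and second-order (\eqn{\lambda_{em} \approx 2\lambda_{ex}})
#' scatter bands and fills them per the spec's policy. Applying the same spec
#' twice is idempotent.
#'
#' @param eem an \linkS4class{EEM}.
#' @param spec a \code{\link{scatterSpec}}.
#' @return The scatter-free \linkS4class{EEM}; the number of affected cells is
#'   attached as attribute \code{nExcised}.
#' @export
removeRayleigh <- function(eem, spec = scatterSpec()) {
  stopifnot(is(eem, "EEM"), inherits(spec, "ScatterSpec"))
  d1 <- abs(outer(eem@em, eem@ex, `-`))
  d2 <- abs(outer(eem@em, 2 * eem@ex, `-`))
  band <- d1 <= spec$order1Halfwidth | d2 <= spec$order2Halfwidth
  out <- eem
  n_exc <- sum(band)
  if (n_exc > 0L) {
    if (spec$fillPolicy == "zero") {
      out@intensity[band] <- 0
    } else if (spec$fillPolicy == "mask") {
      out@intensity[band] <- NA_real_
      out@mask <- if (is.null(eem@mask)) band else eem@mask | band
    } else { # interpolate along emission within each excitation column
      for (k in seq_along(eem@ex)) {
        bk <- band[, k]
        if (!any(bk)) next
        if (all(bk)) {
          warning(sprintf(
            "all emission points excised at ex = %g nm; falling back to mask",
            eem@ex[k]
          ), call. = FALSE)
          out@intensity[bk, k] <- NA_real_
          out@mask <- if (is.null(out@mask)) {
            m <- matrix(FALSE, nrow(band), ncol(band)); m[, k] <- TRUE; m
          } else { out@mask[, k] <- TRUE; out@mask }
          next
        }
        good <- which(!bk & !is.na(eem@intensity[, k]))
        if (length(good) >= 2L) {
          out@intensity[bk, k] <- approx(
            eem@em[good], eem@intensity[good, k],
            xout = eem@em[bk], rule = 2
          )$y
        } else if (length(good) == 1L) {
          out@intensity[bk, k] <- eem@intensity[good, k]
        }
      }
    }
  }
  attr(out@intensity, "nExcised") <- n_exc
  out
}

#' Average replicate EEM measurements
#'
#' Cell-wise arithmetic mean of replicate measurements of one sample. A cell
#' masked in any replicate is masked in the result.
#'
#' @param eems list of \linkS4class{EEM} replicates on identical grids with a
#'   common sample id.
#' @return The averaged \linkS4class{EEM}.
#' @export
averageReplicates <- function(eems) {
  if (!length(eems)) stop("need at least one replicate")
  ref <- eems[[1L]]
  for (e in eems) {
    if (!isTRUE(all.equal(e@ex, ref@ex)) || !isTRUE(all.equal(e@em, ref@em))) {
      stop(sprintf("grid mismatch among replicates of '%s'", ref@sampleId))
    }
    if (e@sampleId != ref@sampleId) {
      stop(sprintf(
        "replicates mix sample ids '%s' and '%s'", ref@sampleId, e@sampleId
      ))
    }
  }
  acc <- Reduce(`+`, lapply(eems, function(e) e@intensity))
  mean_int <- acc / length(eems)
  masks <- lapply(eems, function(e) e@mask)
  mask <- NULL
  if (any(!vapply(masks, is.null, TRUE))) {
    mask <- Reduce(`|`, lapply(masks, function(m) {
      if (is.null(m)) matrix(FALSE, nrow(mean_int), ncol(mean_int)) else m
    }))
    mean_int[mask] <- NA_real_
  }
  EEM(mean_int, em = ref@em, ex = ref@ex, sampleId = ref@sampleId, mask = mask)
}

#' Extract emission spectra at selected excitation wavelengths
#'
#' Concatenates, sample by sample, the emission spectra measured at the
#' requested excitation wavelengths into a samples x (|em| * n_ex) matrix,
#' column-tagged like \code{\link{unfoldDataset}}. Requested wavelengths are
#' snapped to the nearest grid point when within half a grid step; farther
#' requests are an error.
#'
#' @param ds an \linkS4class{EEMDataset}.
#' @param exWavelengths numeric, requested excitation wavelengths (nm).
#' @return numeric matrix with \code{em_nm}/\code{ex_nm} attributes; snapped
#'   wavelengths are reported via a message.
#' @export
extractEmissionSlices <- function(ds, exWavelengths) {
  step <- median(diff(ds@ex))
  idx <- vapply(exWavelengths, function(w) {
    k <- which.min(abs(ds@ex - w))
    if (abs(ds@ex[k] - w) > step / 2 + 1e-9) {
      stop(sprintf(
        "excitation %g nm is farther than half a grid step (%g nm) from the grid",
        w, step
      ))
    }
    if (abs(ds@ex[k] - w) > 1e-9) {
      message(sprintf("excitation %g nm snapped to grid point %g nm", w, ds@ex[k]))
    }
    k
  }, 1L)
  blocks <- lapply(idx, function(k) ds@array[, , k, drop = TRUE])
  m <- do.call(cbind, blocks)
  em_tag <- rep(ds@em, times = length(idx))
  ex_tag <- rep(ds@ex[idx], each = length(ds@em))
  dimnames(m) <- list(ds@samples, sprintf("em%g_ex%g", em_tag, ex_tag))
  attr(m, "em_nm") <- em_tag
  attr(m, "ex_nm") <- ex_tag
  m
}

#' Preprocess a set of replicate A-TEEM measurements
#'
#' Fixed pipeline order: inner-filter correction of each replicate, Rayleigh
#' scatter excision, then replicate averaging.
#'
#' @param replicates list of \linkS4class{EEM} replicates for one sample.
#' @param absSpec the sample's \linkS4class{AbsorbanceSpectrum}.
#' @param spec a \code{\link{scatterSpec}}.
#' @param applyIfe logical; skip IFE correction when the instrument already
#'   applied it.
#' @return The preprocessed, averaged \linkS4class{EEM}.
#' @export
preprocessSample <- function(replicates, absSpec, spec = scatterSpec(),
                             applyIfe = TRUE) {
  if (applyIfe) replicates <- lapply(replicates, ifeCorrect, absSpec = absSpec)
  replicates <- lapply(replicates, removeRayleigh, spec = spec)
  averageReplicates(replicates)
}
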