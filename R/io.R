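#' Read an EEM from CSV
#'
#' Expected layout: first row is \code{em_nm} followed by the excitation
#' wavelengths; every following row starts with the emission wavelength and
#' continues with the intensities for that emission at each excitation.
#' The token \code{NA} marks masked (excised) cells.
#'
#' @param path file path.
#' @param sampleId sample id to attach; defaults to the file name sans ".csv".
#' @return An \linkS4class{EEM}.
#' @export
readEEM <- function(path, sampleId = NULL) {
  lines <- readLines(path)
  if (length(lines) < 2L) stop("EEM CSV needs a header and at least one emission row")
  cells <- strsplit(lines, ",", fixed = TRUE)
  ncols <- lengths(cells)
  if (length(unique(ncols)) != 1L) {
    stop(sprintf(
      "non-rectangular EEM CSV: rows have %s columns",
      paste(sort(unique(ncols)), collapse = "/")
    ))
  }
  parseNum <- function(x, row, col, allowNA = FALSE) {
    v <- suppressWarnings(as.numeric(x))
    bad <- is.na(v) & !(allowNA & trimws(x) %in% c("NA", ""))
    if (any(bad)) {
      i <- which(bad)[1L]
      stop(sprintf(
        "non-numeric cell '%s' at row %d, column %d", x[i], row[i], col[i]
      ))
    }
    v
  }
  ex <- parseNum(cells[[1L]][-1L], rep(1L, ncols[1L] - 1L), seq_len(ncols[1L] - 1L))
  body <- cells[-1L]
  em <- parseNum(
    vapply(body, `[[`, "", 1L), seq_along(body) + 1L, rep(1L, length(body))
  )
  inten <- matrix(NA_real_, length(em), length(ex))
  for (r in seq_along(body)) {
    inten[r, ] <- parseNum(body[[r]][-1L],
      rep(r + 1L, length(ex)), seq_along(ex) + 1L,
      allowNA = TRUE
    )
  }
  if (any(diff(ex) <= 0) || any(diff(em) <= 0)) {
    stop("EEM CSV grids must be strictly increasing")
  }
  if (is.null(sampleId)) sampleId <- sub("\\.csv$", "", basename(path))
  EEM(inten, em = em, ex = ex, sampleId = sampleId)
}

#' Write an EEM to CSV
#'
#' Inverse of \code{\link{readEEM}}; masked cells are written as \code{NA}.
#' Numbers are written with full double precision so a round trip is
#' numerically exact.
#'
#' @param eem an \linkS4class{EEM}.
#' @param path output file path.
#' @return Invisibly, \code{path}.
#' @export
writeEEM <- function(eem, path) {
  stopifnot(is(eem, "EEM"))
  validObject(eem)
  fmt <- function(x) formatC(x, format = ".17g", flag = "")
  num <- function(x) {
    out <- sprintf("%.17g", x)
    out[is.na(x)] <- "NA"
    out
  }
  header <- paste(c("em_nm", num(eem@ex)), collapse = ",")
  rows <- vapply(seq_along(eem@em), function(r) {
    paste(c(num(eem@em[r]), num(eem@intensity[r, ])), collapse = ",")
  }, "")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(header, rows), con)
  invisible(path)
}

#' Read an absorbance spectrum from CSV
#'
#' Two columns: \code{wavelength_nm}, \code{absorbance_au}.
#'
#' @param path file path.
#' @param sampleId sample id; defaults to the file name sans ".csv".
#' @return An \linkS4class{AbsorbanceSpectrum}.
#' @export
readAbsorbance <- function(path, sampleId = NULL) {
  df <- read.csv(path)
  if (!all(c("wavelength_nm", "absorbance_au") %in% names(df))) {
    stop("absorbance CSV must have columns wavelength_nm, absorbance_au")
  }
  if (is.null(sampleId)) sampleId <- sub("\\.csv$", "", basename(path))
  suppressWarnings(
    AbsorbanceSpectrum(df$wavelength_nm, df$absorbance_au, sampleId = sampleId)
  )
}

#' Write an absorbance spectrum to CSV
#'
#' @param spec an \linkS4class{AbsorbanceSpectrum}.
#' @param path output file path.
#' @return Invisibly, \code{path}.
#' @export
writeAbsorbance <- function(spec, path) {
  stopifnot(is(spec, "AbsorbanceSpectrum"))
  df <- data.frame(wavelength_nm = spec@wavelength, absorbance_au = spec@absorbance)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a sample manifest
#'
#' Columns: \code{sample_id}, \code{class}, \code{eem_path},
#' \code{absorbance_path}. Paths are resolved relative to the manifest's
#' directory unless absolute.
#'
#' @param path manifest CSV path.
#' @return data.frame with resolved paths.
#' @export
readManifest <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "class", "eem_path", "absorbance_path")
  if (!all(need %in% names(df))) {
    stop("manifest must have columns: ", paste(need, collapse = ", "))
  }
  base <- dirname(normalizePath(path))
  resolve <- function(p) ifelse(grepl("^(/|[A-Za-z]:)", p), p, file.path(base, p))
  df$eem_path <- resolve(df$eem_path)
  df$absorbance_path <- resolve(df$absorbance_path)
  df
}
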