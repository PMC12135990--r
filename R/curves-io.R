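## Readers for the de-facto small-angle scattering text dialect:
## whitespace- or comma-delimited columns (abscissa, value, optional SD),
## '#' comment lines skipped.

.read_sas_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  fields <- strsplit(gsub(",", " ", lines), "[[:space:]]+")
  ## drop header/footer lines that are not fully numeric (GNOM-style files)
  num <- lapply(fields, function(f) suppressWarnings(as.numeric(f)))
  ok <- vapply(num, function(v) length(v) >= 2 && !anyNA(v), logical(1))
  num <- num[ok]
  if (!length(num)) stop("no numeric data rows in ", path)
  ncol <- min(vapply(num, length, integer(1)))
  mat <- t(vapply(num, function(v) v[seq_len(ncol)], numeric(ncol)))
  mat
}

#' Read an experimental I(q) curve
#'
#' Accepts the common 2- or 3-column SAXS text format (q, I, optional SD),
#' with \code{#} comments.  q is converted to inverse Angstrom immediately
#' when declared in inverse nm.
#'
#' @param path text file.
#' @param qUnit \code{"inv_angstrom"} or \code{"inv_nm"}.
#' @return A [ScatteringCurve-class] in inverse Angstrom.
#' @export
readScatteringCurve <- function(path, qUnit = c("inv_angstrom", "inv_nm")) {
  qUnit <- match.arg(qUnit)
  mat <- .read_sas_table(path)
  sd <- if (ncol(mat) >= 3) mat[, 3] else numeric()
  if (length(sd) && any(sd <= 0)) {
    warning("non-positive SDs in ", path, "; SD column dropped")
    sd <- numeric()
  }
  cv <- new("ScatteringCurve", q = mat[, 1], intensity = mat[, 2], sd = sd)
  convertUnits(cv, unit = qUnit)
}

#' Read an experimentally derived P(r)
#'
#' 2- or 3-column text (r, P, optional SD); r converted to Angstrom when
#' declared in nm (frequencies rescaled so the area is conserved).  The
#' grid must be uniform; a missing leading r = 0 bin is prepended with
#' P = 0 (GNOM output usually includes it).
#'
#' @param path text file.
#' @param rUnit \code{"angstrom"} or \code{"nm"}.
#' @return A [PofR-class] (normalization NA: experimental curves are kept
#'   on their own scale).
#' @export
readPofR <- function(path, rUnit = c("angstrom", "nm")) {
  rUnit <- match.arg(rUnit)
  mat <- .read_sas_table(path)
  r <- mat[, 1]; p <- mat[, 2]
  sd <- if (ncol(mat) >= 3) mat[, 3] else numeric()
  if (length(sd) && any(sd <= 0)) sd <- numeric()
  dr <- if (length(r) > 1) r[2] - r[1] else 1
  if (r[1] > dr / 2) {
    ## prepend missing bins down to r = 0
    nmiss <- round(r[1] / dr)
    r <- c(seq(0, by = dr, length.out = nmiss), r)
    p <- c(rep(0, nmiss), p)
    if (length(sd)) sd <- c(rep(min(sd), nmiss), sd)
  } else {
    r <- r - r[1]
  }
  pr <- new("PofR", r = r, p = pmax(p, 0), sd = sd,
            normalization = NA_real_)
  convertUnits(pr, unit = rUnit)
}
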