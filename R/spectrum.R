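# MS/MS spectrum container: the annotation substrate.

#' Construct an MS/MS spectrum
#'
#' A negative-mode product-ion spectrum: precursor m/z plus a peak list.
#' Peaks are stored sorted by ascending m/z; fragments above the precursor
#' (beyond a small tolerance) are rejected.
#'
#' @param precursor_mz precursor m/z (Da, > 0).
#' @param mz fragment m/z values (Da, > 0).
#' @param intensity non-negative intensities (arbitrary units), recycled to
#'   `length(mz)` if scalar.
#' @param rt retention time in minutes (optional).
#' @param sample_id label carried through annotation tables.
#' @param tol slack allowed above the precursor for isotope/calibration
#'   effects (Da).
#' @return object of class `msms_spectrum`: list with `precursor_mz`, `rt`,
#'   `sample_id`, `peaks` (data.frame `mz`, `intensity`).
#' @export
msms_spectrum <- function(precursor_mz, mz, intensity = 1, rt = NA_real_,
                          sample_id = "", tol = 0.5) {
  stopifnot(is.numeric(precursor_mz), length(precursor_mz) == 1L,
            precursor_mz > 0)
  if (length(intensity) == 1L) intensity <- rep(intensity, length(mz))
  stopifnot(length(mz) == length(intensity), all(intensity >= 0))
  if (length(mz) && any(mz <= 0)) stop("fragment m/z must be positive")
  if (length(mz) && any(mz > precursor_mz + tol)) {
    stop("fragment m/z above precursor + tolerance")
  }
  ord <- order(mz)
  structure(
    list(precursor_mz = precursor_mz, rt = rt, sample_id = sample_id,
         peaks = data.frame(mz = mz[ord], intensity = intensity[ord])),
    class = "msms_spectrum"
  )
}

#' @export
print.msms_spectrum <- function(x, ...) {
  cat(sprintf("<msms_spectrum> %s  precursor m/z %.4f  rt %s min  %d peaks\n",
              x$sample_id, x$precursor_mz,
              if (is.na(x$rt)) "NA" else sprintf("%.2f", x$rt),
              nrow(x$peaks)))
  invisible(x)
}

# Peaks at or above `floor` (fraction of base peak); low-intensity noise is
# ignored by the class cascade.
.filtered_peaks <- function(s, floor = 0.01) {
  pk <- s$peaks
  if (!nrow(pk)) return(pk)
  pk[pk$intensity >= floor * max(pk$intensity), , drop = FALSE]
}
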