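# The built-in compound library: a faithful transcription of the 42
# tentatively identified tea metabolites (retention time, formula, printed
# calc/found m/z, printed ppm error and RDB, fragment list, compound class).

#' Load the tea compound library
#'
#' Returns the 42-entry reference library shipped with the package. Printed
#' table values are transcribed verbatim; `calc_mz` and `rdb` are recomputed
#' from the formula, and `calc_consistent` flags rows whose printed calc m/z
#' agrees with the recomputed value at 4 decimals (a handful of printed rows
#' carry transcription errata, e.g. swapped calc/found columns).
#'
#' @param path optional path to an alternative library CSV with the same
#'   columns.
#' @return data.frame with one row per compound; `fragments` is a list-column
#'   of numeric fragment m/z vectors.
#' @export
tea_compound_library <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "tea_compound_library.csv",
                        package = "teaphenolics", mustWork = TRUE)
  }
  lib <- utils::read.csv(path, stringsAsFactors = FALSE)
  lib$fragments <- lapply(strsplit(lib$fragments, ";", fixed = TRUE),
                          as.numeric)
  lib$calc_mz <- vapply(lib$formula, deprotonated_mz, numeric(1))
  lib$calc_mz_exact <- vapply(lib$formula, deprotonated_mz, numeric(1),
                              digits = NA)
  lib$rdb <- vapply(lib$formula, rdb, numeric(1))
  lib$calc_consistent <- lib$printed_calc_mz == lib$calc_mz
  lib$aglycone[lib$aglycone == ""] <- NA_character_
  lib$base_peak_mz[is.na(lib$base_peak_mz)] <- NA_real_
  lib
}
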