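# File readers/writers and the end-to-end pipeline driver.

#' Read MS/MS spectra from MGF or CSV
#'
#' MGF follows the `BEGIN IONS` / `PEPMASS` / `RTINSECONDS` dialect; the CSV
#' form is long format with columns `spectrum_id`, `precursor_mz`, `rt_min`,
#' `mz`, `intensity`. Malformed records are skipped with a warning; spectra
#' come back sorted by retention time then precursor m/z.
#'
#' @param path input file.
#' @param format `"mgf"` or `"csv"` (default guessed from the extension).
#' @return list of [msms_spectrum] objects.
#' @export
read_spectra <- function(path, format = c("auto", "mgf", "csv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("cannot read spectra file: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.mgf$", path, ignore.case = TRUE)) "mgf" else "csv"
  }
  spectra <- if (format == "mgf") .read_mgf(path) else .read_spectra_csv(path)
  if (!length(spectra)) stop("zero parsable spectra in ", path)
  ord <- order(vapply(spectra, function(s) {
    if (is.na(s$rt)) Inf else s$rt
  }, numeric(1)),
  vapply(spectra, `[[`, numeric(1), "precursor_mz"))
  spectra[ord]
}

.read_mgf <- function(path) {
  lines <- readLines(path, warn = FALSE)
  starts <- which(lines == "BEGIN IONS")
  ends <- which(lines == "END IONS")
  if (length(starts) != length(ends)) {
    warning("unbalanced BEGIN/END IONS blocks in ", path)
  }
  n_bad <- 0L
  out <- list()
  for (k in seq_len(min(length(starts), length(ends)))) {
    block <- lines[(starts[k] + 1L):(ends[k] - 1L)]
    hdr <- grepl("=", block, fixed = TRUE)
    fields <- strsplit(block[hdr], "=", fixed = TRUE)
    keys <- toupper(vapply(fields, `[`, character(1), 1))
    vals <- vapply(fields, function(f) paste(f[-1], collapse = "="),
                   character(1))
    pep <- vals[match("PEPMASS", keys)]
    prec <- suppressWarnings(as.numeric(strsplit(trimws(pep), "\\s+")[[1]][1]))
    rt_s <- suppressWarnings(as.numeric(vals[match("RTINSECONDS", keys)]))
    title <- vals[match("TITLE", keys)]
    peak_lines <- trimws(block[!hdr])
    peak_lines <- peak_lines[nzchar(peak_lines)]
    pk <- do.call(rbind, lapply(strsplit(peak_lines, "\\s+"), function(x) {
      suppressWarnings(as.numeric(x[1:2]))
    }))
    if (is.na(prec) || is.null(pk) || anyNA(pk)) {
      n_bad <- n_bad + 1L
      next
    }
    out[[length(out) + 1L]] <- msms_spectrum(
      prec, pk[, 1], pk[, 2],
      rt = if (is.na(rt_s)) NA_real_ else rt_s / 60,
      sample_id = if (is.na(title)) sprintf("scan%04d", k) else title)
  }
  if (n_bad) warning(n_bad, " malformed MGF block(s) skipped")
  out
}

.read_spectra_csv <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("spectrum_id", "precursor_mz", "mz", "intensity")
  missing <- setdiff(need, names(tab))
  if (length(missing)) {
    stop("spectra CSV is missing column(s): ", paste(missing, collapse = ", "))
  }
  lapply(split(tab, tab$spectrum_id), function(d) {
    msms_spectrum(d$precursor_mz[1], d$mz, d$intensity,
                  rt = if ("rt_min" %in% names(d)) d$rt_min[1] else NA_real_,
                  sample_id = as.character(d$spectrum_id[1]))
  })
}

#' Write spectra to an MGF file
#'
#' @param spectra list of [msms_spectrum] objects.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_mgf <- function(spectra, path) {
  blocks <- vapply(spectra, function(s) {
    paste(c("BEGIN IONS",
            paste0("TITLE=", s$sample_id),
            sprintf("PEPMASS=%.6f", s$precursor_mz),
            if (!is.na(s$rt)) sprintf("RTINSECONDS=%.3f", s$rt * 60),
            sprintf("%.6f %.6f", s$peaks$mz, s$peaks$intensity),
            "END IONS", ""),
          collapse = "\n")
  }, character(1))
  writeLines(blocks, path)
  invisible(path)
}

#' Read a long-format dose-response CSV
#'
#' Expects columns `sample`, `assay`, `dose`, `response` (optionally `sd`);
#' returns one [dose_response] per sample/assay combination.
#'
#' @param path CSV file.
#' @return named list of [dose_response] records.
#' @export
read_dose_response_csv <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample", "assay", "dose", "response")
  missing <- setdiff(need, names(tab))
  if (length(missing)) {
    stop("dose-response CSV is missing column(s): ",
         paste(missing, collapse = ", "))
  }
  groups <- split(tab, paste(tab$sample, tab$assay, sep = "/"))
  lapply(groups, function(d) {
    d <- d[order(d$dose), ]
    dose_response(d$sample[1], d$assay[1], d$dose, d$response,
                  sds = if ("sd" %in% names(d)) d$sd)
  })
}

#' Read an ORAC time-series CSV
#'
#' Expects columns `sample`, `conc`, `time_min`, `fluorescence`; returns one
#' [orac_curve] per sample/concentration.
#'
#' @param path CSV file.
#' @return named list of [orac_curve] objects.
#' @export
read_orac_csv <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample", "conc", "time_min", "fluorescence")
  missing <- setdiff(need, names(tab))
  if (length(missing)) {
    stop("ORAC CSV is missing column(s): ", paste(missing, collapse = ", "))
  }
  groups <- split(tab, paste(tab$sample, tab$conc, sep = "/"))
  lapply(groups, function(d) {
    d <- d[order(d$time_min), ]
    orac_curve(d$sample[1], d$conc[1], d$time_min, d$fluorescence)
  })
}

#' Run the full annotation + activity pipeline
#'
#' Chains annotation, class relative abundance, assay metrics, RACI and
#' clustering over file inputs and writes the artifact set (annotation CSV,
#' class-abundance CSV, panel CSV, RACI CSV, newick dendrogram, run log)
#' into `out_dir`. Stages whose inputs are absent are skipped. Output is
#' deterministic given identical inputs.
#'
#' @param spectra_path MGF or CSV peak-list file (optional).
#' @param dose_response_path long-format dose-response CSV (optional).
#' @param orac_path ORAC time-series CSV (optional; the blank must be named
#'   `"blank"`, the standard `"trolox"`).
#' @param out_dir output directory, created if needed.
#' @param library compound library (see [tea_compound_library()]).
#' @param precursor_tol_ppm,fragment_tol_da matching tolerances.
#' @param id50_method `"interp"` or `"4pl"`.
#' @param seed recorded in the run log (the pipeline itself is
#'   deterministic).
#' @return invisible character vector of files written.
#' @export
run_pipeline <- function(spectra_path = NULL, dose_response_path = NULL,
                         orac_path = NULL, out_dir = "pipeline_out",
                         library = tea_compound_library(),
                         precursor_tol_ppm = 10, fragment_tol_da = 0.02,
                         id50_method = "interp", seed = NA_integer_) {
  stopifnot(precursor_tol_ppm > 0, fragment_tol_da > 0)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  emit <- function(df, name) {
    f <- file.path(out_dir, name)
    utils::write.csv(df, f, row.names = FALSE)
    written <<- c(written, f)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE)
    })
  }

  panel_cols <- list()
  if (!is.null(spectra_path)) {
    stage("annotate", {
      spectra <- read_spectra(spectra_path)
      ann <- annotate_library(spectra, library,
                              precursor_tol_ppm = precursor_tol_ppm,
                              tol = fragment_tol_da)
      emit(ann, "annotation.csv")
      inten <- vapply(spectra, function(s) sum(s$peaks$intensity),
                      numeric(1))
      emit(class_relative_abundance(ann$class, inten),
           "class_abundance.csv")
    })
  }
  if (!is.null(dose_response_path)) {
    stage("assay", {
      drs <- read_dose_response_csv(dose_response_path)
      rows <- lapply(drs, function(dr) {
        est <- estimate_id50(dr, method = id50_method)
        data.frame(sample = dr$sample_id, assay = dr$assay,
                   id50 = est$value, bracketed = est$bracketed,
                   stringsAsFactors = FALSE)
      })
      id50s <- do.call(rbind, rows)
      rownames(id50s) <- NULL
      trolox <- id50s[id50s$sample == "trolox", c("assay", "id50")]
      if (nrow(trolox)) {
        id50s$teac <- NA_real_
        hit <- match(id50s$assay, trolox$assay)
        ok <- !is.na(hit) & id50s$sample != "trolox"
        id50s$teac[ok] <- teac(trolox$id50[hit[ok]], id50s$id50[ok])
      }
      emit(id50s, "id50_teac.csv")
      panel_cols$id50 <- id50s
    })
  }
  if (!is.null(orac_path)) {
    stage("orac", {
      curves <- read_orac_csv(orac_path)
      ids <- vapply(curves, `[[`, character(1), "sample_id")
      blank <- curves[[which(ids == "blank")[1]]]
      auc_blank <- orac_auc(blank)
      net <- lapply(split(curves[ids != "blank"], ids[ids != "blank"]),
                    function(cl) {
        data.frame(
          conc = vapply(cl, `[[`, numeric(1), "concentration"),
          net_auc = vapply(cl, function(cu) {
            orac_auc(orac_normalize(cu, blank)) - auc_blank
          }, numeric(1)))
      })
      if (!"trolox" %in% names(net)) stop("no 'trolox' standard curves")
      rows <- lapply(setdiff(names(net), "trolox"), function(id) {
        te <- orac_trolox_equivalents(net[[id]], net[["trolox"]])
        data.frame(sample = id, orac_te = te$trolox_eq,
                   slope = te$slope_sample, stringsAsFactors = FALSE)
      })
      emit(do.call(rbind, rows), "orac_te.csv")
    })
  }

  # activity ranking whenever a complete panel can be assembled
  id50s <- panel_cols$id50
  if (!is.null(id50s)) {
    stage("raci", {
      samples <- setdiff(unique(id50s$sample), "trolox")
      assays <- unique(id50s$assay)
      wide <- sapply(assays, function(a) {
        id50s$id50[match(paste(samples, a), paste(id50s$sample, id50s$assay))]
      })
      wide <- matrix(wide, nrow = length(samples),
                     dimnames = list(samples, paste0("id50_", tolower(assays))))
      if (!anyNA(wide) && nrow(wide) >= 2) {
        m <- activity_matrix(wide, rep("lower-better", ncol(wide)))
        rr <- raci(m)
        emit(data.frame(sample = samples, raci = rr$raci, rr$z),
             "raci.csv")
        if (nrow(wide) >= 3 && ncol(wide) >= 2) {
          hc <- average_linkage(correlation_distance(scale(wide)))
          dendrogram_newick(hc, file.path(out_dir, "samples.nwk"))
          written <<- c(written, file.path(out_dir, "samples.nwk"))
        }
      }
    })
  }

  log_file <- file.path(out_dir, "run_log.txt")
  writeLines(c(
    sprintf("teaphenolics %s",
            as.character(utils::packageVersion("teaphenolics"))),
    sprintf("seed: %s", seed),
    sprintf("precursor_tol_ppm: %g", precursor_tol_ppm),
    sprintf("fragment_tol_da: %g", fragment_tol_da),
    sprintf("id50_method: %s", id50_method),
    sprintf("outputs: %s", paste(basename(written), collapse = ", "))
  ), log_file)
  invisible(c(written, log_file))
}
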