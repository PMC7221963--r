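#!/usr/bin/env Rscript
# Generate the synthetic study inputs: MS/MS spectra for all 42 library
# compounds (measurement-like noise), dose-response curves for six extracts
# plus the Trolox standard, and ORAC fluorescence decays. Everything is
# seeded, so reruns are byte-identical.

suppressPackageStartupMessages(library(teaphenolics))

out <- "results/fixtures"
dir.create(out, showWarnings = FALSE, recursive = TRUE)
cfg <- sim_config(seed = 20)

lib <- tea_compound_library()
spectra <- lapply(seq_len(nrow(lib)), function(i) simulate_spectrum(lib[i, ], cfg))
write_mgf(spectra, file.path(out, "spectra.mgf"))
cat(sprintf("wrote %d simulated spectra (5 ppm precursor, 10 mDa fragment noise, 5 decoys each)\n",
            length(spectra)))

# planted ID50s (ug/mL) loosely spanning the printed activity range
samples <- c(teaA = 2.0, teaB = 6.0, teaC = 15.0, teaD = 30.0, trolox = 9.0)
dr_rows <- do.call(rbind, lapply(names(samples), function(s) {
  dr <- simulate_dose_response(samples[[s]], cfg, sample_id = s, assay = "DPPH")
  data.frame(sample = s, assay = "DPPH", dose = dr$doses,
             response = dr$responses, sd = dr$sds)
}))
write.csv(dr_rows, file.path(out, "dose_response.csv"), row.names = FALSE)
cat("wrote dose-response curves, planted ID50s:",
    paste(sprintf("%s=%.1f", names(samples), samples), collapse = ", "), "\n")

# ORAC: planted Trolox equivalents per extract, Trolox standard at TE = 1
tes <- c(teaA = 3.5, teaB = 2.5, trolox = 1)
grids <- list(teaA = c(0.78, 1.56, 3.125), teaB = c(0.78, 1.56, 3.125),
              trolox = c(1, 2, 4, 8))
orac_rows <- list()
for (s in names(tes)) {
  sim <- simulate_orac_decay(tes[[s]], grids[[s]], cfg, sample_id = s)
  for (cu in sim$curves) {
    orac_rows[[length(orac_rows) + 1L]] <- data.frame(
      sample = s, conc = cu$concentration, time_min = cu$times,
      fluorescence = cu$fluorescence)
  }
  if (s == "trolox") {
    orac_rows[[length(orac_rows) + 1L]] <- data.frame(
      sample = "blank", conc = 0, time_min = sim$blank$times,
      fluorescence = sim$blank$fluorescence)
  }
}
write.csv(do.call(rbind, orac_rows), file.path(out, "orac.csv"),
          row.names = FALSE)
cat("wrote ORAC decays, planted TE:",
    paste(sprintf("%s=%.1f", names(tes), tes), collapse = ", "), "\n")
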