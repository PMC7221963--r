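# Deterministic synthetic-data generator: QqTOF-like MS/MS spectra from the
# compound library, Hill dose-response curves, ORAC fluorescence decays and
# activity panels with planted ground truth.

# Stable 31-bit string hash; sub-streams are derived from the master seed
# plus a hash of operation name + entry id, so adding entries does not
# reshuffle existing outputs.
.stable_hash <- function(text) {
  h <- 0
  for (c in utf8ToInt(text)) h <- (h * 31 + c) %% 2147483647
  as.integer(h)
}

.substream_seed <- function(cfg, key) {
  as.integer((as.numeric(cfg$seed) + .stable_hash(key)) %% 2147483647)
}

# Evaluate expr under a sub-stream seed, restoring the caller's RNG state.
.with_substream <- function(cfg, key, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(.substream_seed(cfg, key))
  force(expr)
}

#' Simulation configuration
#'
#' Bundles every tunable of the synthetic-data generator. Defaults emulate
#' the acquisition and assay designs the pipeline targets: negative-mode
#' QqTOF spectra with ppm-scale precursor error and mDa-scale fragment
#' error plus a handful of low-level chemical-noise peaks, the five-point
#' two-fold dose grid 0.78-12.5 ug/mL, and fluorescence read every 15 min
#' for 120 min (9 readings).
#'
#' @param seed master integer seed; all outputs are bit-reproducible given
#'   the seed.
#' @param precursor_ppm_sd SD of the precursor mass error (ppm).
#' @param fragment_mda_sd SD of fragment mass error (mDa).
#' @param n_decoy_peaks decoy (noise) peaks appended per spectrum.
#' @param decoy_intensity_max decoy intensity ceiling, fraction of base peak.
#' @param dose_grid assay dose levels (ug/mL).
#' @param hill_slope Hill coefficient of simulated dose-response curves.
#' @param response_noise_sd multiplicative response noise (percent of the
#'   reading).
#' @param n_replicates replicate measurements averaged per dose point
#'   (assays are run in triplicate).
#' @param orac_times ORAC reading grid (minutes).
#' @param orac_mid,orac_tau logistic fluorescence-decay midpoint and
#'   steepness of the blank (minutes).
#' @param orac_shift_per_unit midpoint delay (minutes) per unit of
#'   Trolox-equivalent x concentration.
#' @param orac_noise_sd multiplicative fluorescence noise (percent).
#' @param panel_noise_sd multiplicative noise of simulated activity panels
#'   (fraction).
#' @return list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       precursor_ppm_sd = 5,
                       fragment_mda_sd = 10,
                       n_decoy_peaks = 5L,
                       decoy_intensity_max = 0.2,
                       dose_grid = c(0.78, 1.56, 3.125, 6.25, 12.5),
                       hill_slope = 1,
                       response_noise_sd = 2,
                       n_replicates = 3L,
                       orac_times = seq(0, 120, by = 15),
                       orac_mid = 45,
                       orac_tau = 8,
                       orac_shift_per_unit = 2,
                       orac_noise_sd = 2,
                       panel_noise_sd = 0.05) {
  stopifnot(precursor_ppm_sd >= 0, fragment_mda_sd >= 0, n_decoy_peaks >= 0,
            hill_slope > 0, response_noise_sd >= 0, all(dose_grid > 0))
  structure(as.list(environment()), class = "sim_config")
}

#' Simulate an MS/MS spectrum from a library entry
#'
#' Precursor m/z is the calculated `[M - H]-` value plus Gaussian ppm error;
#' fragments are the library fragment list plus Gaussian mDa error.
#' Intensities are drawn log-uniform over `[0.05, 1]` of the base peak; the
#' library's stated base-peak identity (e.g. the radical aglycone of
#' 3-O-glycosides) is preserved. Decoy peaks are appended at uniform random
#' m/z. With zero noise SDs and no decoys the peaks equal the library values
#' exactly.
#'
#' @param entry one row of [tea_compound_library()] (data.frame or list).
#' @param cfg a [sim_config()].
#' @return an [msms_spectrum].
#' @export
simulate_spectrum <- function(entry, cfg = sim_config()) {
  frags <- if (is.list(entry$fragments)) entry$fragments[[1]] else
    entry$fragments
  if (!length(frags)) stop("library entry has no expected fragments")
  .with_substream(cfg, paste0("spectrum/", entry$peak_no), {
    calc <- deprotonated_mz(entry$formula, digits = NA)
    prec <- calc * (1 + stats::rnorm(1) * cfg$precursor_ppm_sd * 1e-6)
    mz <- frags + stats::rnorm(length(frags)) * cfg$fragment_mda_sd / 1000
    inten <- 10^stats::runif(length(frags), log10(0.05), log10(0.95))
    base_mz <- entry$base_peak_mz
    base_i <- if (!is.null(base_mz) && !is.na(base_mz)) {
      which.min(abs(frags - base_mz))
    } else which.max(inten)
    inten[base_i] <- 1
    if (cfg$n_decoy_peaks > 0) {
      dmz <- stats::runif(cfg$n_decoy_peaks, 50, max(prec - 1, 60))
      dint <- stats::runif(cfg$n_decoy_peaks, 0, cfg$decoy_intensity_max)
      mz <- c(mz, dmz)
      inten <- c(inten, dint)
    }
    msms_spectrum(prec, mz, inten, rt = entry$rt_min,
                  sample_id = paste0("sim_peak_", entry$peak_no))
  })
}

#' Simulate a Hill-shaped dose-response record
#'
#' `response(d) = 100 d^h / (d^h + ID50^h)` with multiplicative Gaussian
#' noise per replicate, averaged over `n_replicates` as in the assay
#' protocol; at zero noise the response at `d = ID50` is exactly 50.
#'
#' @param id50_true planted ID50 (ug/mL, > 0).
#' @param cfg a [sim_config()]; uses `dose_grid`, `hill_slope`,
#'   `response_noise_sd`, `n_replicates`.
#' @param sample_id,assay labels for the record.
#' @param rep_id replicate tag entering the random sub-stream.
#' @return a [dose_response].
#' @export
simulate_dose_response <- function(id50_true, cfg = sim_config(),
                                   sample_id = "sim", assay = "DPPH",
                                   rep_id = 1L) {
  stopifnot(id50_true > 0)
  if (cfg$hill_slope <= 0) stop("Hill slope must be positive")
  .with_substream(cfg, paste0("dose/", sample_id, "/", assay, "/", rep_id, "/",
                              signif(id50_true, 8), "/", cfg$hill_slope), {
    d <- cfg$dose_grid
    h <- cfg$hill_slope
    true <- 100 * d^h / (d^h + id50_true^h)
    reps <- replicate(cfg$n_replicates,
                      true * (1 + stats::rnorm(length(d)) *
                                cfg$response_noise_sd / 100))
    reps <- matrix(reps, nrow = length(d))
    dose_response(sample_id, assay, d, rowMeans(reps),
                  sds = apply(reps, 1, stats::sd))
  })
}

#' Simulate ORAC fluorescence decays with a planted Trolox equivalent
#'
#' The blank decays as a logistic sigmoid; antioxidant delays the decay by
#' shifting the midpoint proportionally to `te_true x concentration`. A
#' planted `te_true = 0` reproduces the blank curve.
#'
#' @param te_true planted Trolox equivalent (>= 0).
#' @param conc_grid antioxidant concentrations (>= 0).
#' @param cfg a [sim_config()].
#' @param sample_id label.
#' @return list with `curves` (list of [orac_curve], one per concentration)
#'   and `blank` (an [orac_curve]).
#' @export
simulate_orac_decay <- function(te_true, conc_grid, cfg = sim_config(),
                                sample_id = "sim") {
  stopifnot(te_true >= 0)
  if (any(conc_grid < 0)) stop("negative concentration")
  decay <- function(t, mid) {
    raw <- 1 / (1 + exp((t - mid) / cfg$orac_tau))
    raw / raw[1]  # anchor f(0) = 1
  }
  .with_substream(cfg, paste0("orac/", sample_id, "/", signif(te_true, 8)), {
    t <- cfg$orac_times
    f0 <- 1000
    noisy <- function(f) {
      pmax(f * (1 + stats::rnorm(length(f)) * cfg$orac_noise_sd / 100),
           f0 * 1e-6)
    }
    blank <- orac_curve("blank", 0, t, noisy(f0 * decay(t, cfg$orac_mid)))
    curves <- lapply(conc_grid, function(cc) {
      mid <- cfg$orac_mid + cfg$orac_shift_per_unit * te_true * cc
      orac_curve(sample_id, cc, t, noisy(f0 * decay(t, mid)))
    })
    list(curves = curves, blank = blank)
  })
}

#' Simulate an activity panel with a planted ranking
#'
#' Produces a four-metric activity matrix (three ID50-style lower-better
#' columns, one ORAC-style higher-better column) whose oriented quality
#' follows the planted ranking, with multiplicative log-scale noise. At zero
#' noise the RACI ordering equals the planted ranking exactly.
#'
#' @param n_samples number of samples (>= 2).
#' @param planted_ranking permutation of `1:n_samples` listing samples from
#'   most to least active (default identity).
#' @param cfg a [sim_config()]; uses `panel_noise_sd`.
#' @return an [activity_matrix] with planted ranking in
#'   `attr(, "planted_ranking")`.
#' @export
simulate_panel <- function(n_samples, planted_ranking = seq_len(n_samples),
                           cfg = sim_config()) {
  stopifnot(n_samples >= 2,
            setequal(planted_ranking, seq_len(n_samples)))
  .with_substream(cfg, paste0("panel/", n_samples), {
    quality <- numeric(n_samples)
    quality[planted_ranking] <- seq(n_samples - 1, 0)  # best gets most
    noise <- function() {
      exp(stats::rnorm(n_samples) * cfg$panel_noise_sd)
    }
    vals <- cbind(
      id50_dpph = 40 * exp(-0.6 * quality) * noise(),
      id50_abts = 5 * exp(-0.5 * quality) * noise(),
      id50_tbars = 2 * exp(-0.7 * quality) * noise(),
      orac_te = 2 * (1 + 0.3 * quality) * noise()
    )
    rownames(vals) <- sprintf("sample%02d", seq_len(n_samples))
    m <- activity_matrix(vals, c("lower-better", "lower-better",
                                 "lower-better", "higher-better"))
    attr(m, "planted_ranking") <- planted_ranking
    m
  })
}
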