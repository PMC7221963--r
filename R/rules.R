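# Diagnostic neutral-loss rules and marker ions for negative-mode ESI
# fragmentation of tea polyphenols. All masses derive from the formula
# arithmetic in formula_mass.R, never from hard-coded numbers.

#' Neutral-loss rule set
#'
#' The diagnostic neutral losses used by the annotation engine, grouped by
#' category: glycosyl residues (hexose, deoxyhexose, pentose), acyl residues
#' (galloyl, coumaroyl and their acid forms, methylgalloyl), small molecules
#' (water, carbon dioxide, ethenone, formaldehyde, formic acid) and
#' ring-fission losses (the flavanol A-ring released by heterocyclic ring
#' fission, plus the 60/90/120 Da cross-ring cleavages of C-glycosides).
#'
#' @return data.frame with columns `name`, `formula`, `category`,
#'   `exact_mass` (Da, monoisotopic).
#' @export
neutral_loss_rules <- function() {
  spec <- rbind(
    c("hexose",        "C6H10O5", "glycosyl"),
    c("deoxyhexose",   "C6H10O4", "glycosyl"),
    c("pentose",       "C5H8O4",  "glycosyl"),
    c("galloyl",       "C7H4O4",  "acyl"),
    c("coumaroyl",     "C9H6O2",  "acyl"),
    c("coumaric acid", "C9H8O3",  "acyl"),
    c("gallic acid",   "C7H6O5",  "acyl"),
    c("methylgalloyl", "C8H6O4",  "acyl"),
    c("H2O",           "H2O",     "small"),
    c("CO2",           "CO2",     "small"),
    c("C2H2O",         "C2H2O",   "small"),
    c("CH2O",          "CH2O",    "small"),
    c("CH2O2",         "CH2O2",   "small"),
    c("HRF A-ring",    "C6H6O3",  "ring-fission"),
    c("cross-ring 60", "C2H4O2",  "ring-fission"),
    c("cross-ring 90", "C3H6O3",  "ring-fission"),
    c("cross-ring 120","C4H8O4",  "ring-fission")
  )
  out <- data.frame(name = spec[, 1], formula = spec[, 2],
                    category = spec[, 3], stringsAsFactors = FALSE)
  out$exact_mass <- vapply(out$formula, monoisotopic_mass, numeric(1))
  out
}

#' Flavonol and flavone aglycone marker ions
#'
#' For each aglycone, the even-electron `[A - H]-` and odd-electron radical
#' `[A - 2H].-` m/z. Radical dominance over the even-electron ion is the
#' evidence for 3-O-glycosylation. Apigenin is observed in C-glycosides only,
#' where no free radical aglycone forms.
#'
#' @return data.frame with columns `aglycone`, `formula`, `even_mz`,
#'   `radical_mz` (NA where the radical channel is not diagnostic).
#' @export
aglycone_ions <- function() {
  out <- data.frame(
    aglycone = c("quercetin", "kaempferol", "myricetin", "apigenin"),
    formula  = c("C15H10O7", "C15H10O6", "C15H10O8", "C15H10O5"),
    stringsAsFactors = FALSE
  )
  out$even_mz <- vapply(out$formula, deprotonated_mz, numeric(1), digits = NA)
  out$radical_mz <- vapply(out$formula, radical_anion_mz, numeric(1),
                           digits = NA)
  out$radical_mz[out$aglycone == "apigenin"] <- NA_real_
  out
}

#' Low-mass diagnostic ions
#'
#' Marker fragments used by the class cascade: the flavanol A-ring HRF ion at
#' m/z 125.02, the retro Diels-Alder pair 137.02/151.04, the catechol B-ring
#' ion, deprotonated gallate and quinate, and the methylgallate radical ion.
#'
#' @return data.frame with columns `name`, `mz`, `meaning`.
#' @export
diagnostic_ions <- function() {
  data.frame(
    name = c("flavanol A-ring", "RDA 137", "RDA 151", "catechol B-ring",
             "gallate", "methylgallate radical", "quinate"),
    mz = c(deprotonated_mz("C6H6O3", digits = NA),
           deprotonated_mz("C7H6O3", digits = NA),
           deprotonated_mz("C8H8O3", digits = NA),
           deprotonated_mz("C6H6O2", digits = NA),
           deprotonated_mz("C7H6O5", digits = NA),
           monoisotopic_mass("C7H4O5"),
           deprotonated_mz("C7H12O6", digits = NA)),
    meaning = c("flavan-3-ol HRF", "RDA pair", "RDA pair", "catechol B-ring",
                "galloylation", "methylgalloylation", "quinate ester"),
    stringsAsFactors = FALSE
  )
}
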