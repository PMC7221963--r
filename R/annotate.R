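# The tentative-identification rule engine: neutral-loss detection,
# aglycone identification, C-glycoside diagnosis and the compound-class
# decision cascade.

# nearest-match helper: index of the peak m/z closest to `target` within
# `tol`, or NA.
.match_mz <- function(mz, target, tol) {
  if (!length(mz)) return(NA_integer_)
  d <- abs(mz - target)
  i <- which.min(d)
  if (d[i] <= tol) i else NA_integer_
}

#' Detect diagnostic neutral losses in a spectrum
#'
#' Scans every ordered peak pair (including precursor to peak) for a mass
#' difference matching a neutral-loss rule within `tol`.
#'
#' @param s an [msms_spectrum].
#' @param rules rule table as from [neutral_loss_rules()].
#' @param tol fragment tolerance in Da (default 0.02; observed fragment m/z
#'   on QqTOF data deviate up to ~15 mDa from exact values).
#' @param floor intensity floor as a fraction of the base peak.
#' @return data.frame with columns `rule`, `category`, `from_mz`, `to_mz`,
#'   `delta` (observed), `exact_mass` (rule), sorted by `from_mz` descending.
#' @export
detect_neutral_losses <- function(s, rules = neutral_loss_rules(), tol = 0.02,
                                  floor = 0) {
  stopifnot(inherits(s, "msms_spectrum"), tol > 0)
  if (!nrow(rules)) stop("empty rule set")
  pk <- .filtered_peaks(s, floor)
  froms <- c(s$precursor_mz, pk$mz)
  out <- list()
  for (fm in froms) {
    to <- pk$mz[pk$mz < fm - min(rules$exact_mass) + tol]
    if (!length(to)) next
    delta <- fm - to
    for (r in seq_len(nrow(rules))) {
      hit <- abs(delta - rules$exact_mass[r]) <= tol
      if (any(hit)) {
        out[[length(out) + 1L]] <- data.frame(
          rule = rules$name[r], category = rules$category[r],
          from_mz = fm, to_mz = to[hit], delta = delta[hit],
          exact_mass = rules$exact_mass[r], stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(rule = character(), category = character(),
                      from_mz = numeric(), to_mz = numeric(),
                      delta = numeric(), exact_mass = numeric()))
  }
  res <- do.call(rbind, out)
  res <- res[order(-res$from_mz, -res$to_mz, res$rule), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Identify the flavonoid aglycone and glycosylation-position evidence
#'
#' Matches the low-mass region against the aglycone marker-ion pairs of
#' [aglycone_ions()]. When the odd-electron radical ion `[A - 2H].-` is
#' strictly more intense than the even-electron `[A - H]-`, the saccharide is
#' localized at the 3-O position; an even-electron ion alone (or an intensity
#' tie) is indeterminate. Confirmatory CH2O / CH2O2 sub-losses from the
#' even-electron aglycone raise a `confirmed` flag.
#'
#' @inheritParams detect_neutral_losses
#' @return `NULL` if no aglycone ion is found, else a list with elements
#'   `aglycone`, `evidence` (`"3-O"` or `"indeterminate"`), `even_mz`,
#'   `radical_mz` (observed, NA when absent) and `confirmed`.
#' @export
identify_aglycone <- function(s, tol = 0.02, floor = 0.01) {
  stopifnot(inherits(s, "msms_spectrum"), tol > 0)
  pk <- .filtered_peaks(s, floor)
  if (!nrow(pk)) return(NULL)
  agly <- aglycone_ions()
  best <- NULL
  for (i in seq_len(nrow(agly))) {
    ie <- .match_mz(pk$mz, agly$even_mz[i], tol)
    ir <- if (is.na(agly$radical_mz[i])) NA_integer_ else
      .match_mz(pk$mz, agly$radical_mz[i], tol)
    if (is.na(ie) && is.na(ir)) next
    n_hits <- sum(!is.na(c(ie, ir)))
    inten <- sum(pk$intensity[c(ie, ir)], na.rm = TRUE)
    cand <- list(i = i, ie = ie, ir = ir, n_hits = n_hits, inten = inten)
    if (is.null(best) || cand$n_hits > best$n_hits ||
        (cand$n_hits == best$n_hits && cand$inten > best$inten)) {
      best <- cand
    }
  }
  if (is.null(best)) return(NULL)
  i <- best$i
  even_int <- if (is.na(best$ie)) 0 else pk$intensity[best$ie]
  rad_int <- if (is.na(best$ir)) 0 else pk$intensity[best$ir]
  evidence <- if (!is.na(best$ir) && rad_int > even_int) "3-O" else
    "indeterminate"
  # confirmatory sub-losses from the even-electron aglycone
  confirmed <- FALSE
  if (!is.na(best$ie)) {
    base <- pk$mz[best$ie]
    ch2o <- monoisotopic_mass("CH2O")
    ch2o2 <- monoisotopic_mass("CH2O2")
    confirmed <- !is.na(.match_mz(pk$mz, base - ch2o, tol)) &&
      !is.na(.match_mz(pk$mz, base - ch2o2, tol))
  }
  list(aglycone = agly$aglycone[i], evidence = evidence,
       even_mz = if (is.na(best$ie)) NA_real_ else pk$mz[best$ie],
       radical_mz = if (is.na(best$ir)) NA_real_ else pk$mz[best$ir],
       confirmed = confirmed)
}

# sums of 1..3 glycosyl residues (hexose/deoxyhexose/pentose); the whole
# saccharide part of di/tri-glycosides is often lost in a single step.
.glycosyl_combos <- function() {
  res <- vapply(c("C6H10O5", "C6H10O4", "C5H8O4"), monoisotopic_mass,
                numeric(1))
  sums <- res
  for (k in 2:3) {
    grid <- expand.grid(rep(list(res), k))
    sums <- c(sums, rowSums(grid))
  }
  sort(unique(round(sums, 6)))
}

#' Diagnose C-glycosylation from cross-ring losses
#'
#' Sugars attached by a C-C bond cannot leave as whole residues; instead the
#' sugar ring itself cleaves, giving losses of 60, 90 and 120 Da from the
#' precursor. The call requires at least two distinct cross-ring losses (a
#' single 120 Da loss also occurs in O-glycoside spectra) and the absence of
#' a full glycosyl-residue loss down to a free aglycone ion.
#'
#' @inheritParams detect_neutral_losses
#' @return list with `is_c_glycoside` (logical) and `evidence` (data.frame of
#'   matched cross-ring losses).
#' @export
detect_c_glycoside <- function(s, tol = 0.02, floor = 0.01) {
  stopifnot(inherits(s, "msms_spectrum"), tol > 0)
  pk <- .filtered_peaks(s, floor)
  losses <- vapply(c("C2H4O2", "C3H6O3", "C4H8O4"), monoisotopic_mass,
                   numeric(1))
  hits <- list()
  for (j in seq_along(losses)) {
    i <- .match_mz(pk$mz, s$precursor_mz - losses[j], tol)
    if (!is.na(i)) {
      hits[[length(hits) + 1L]] <- data.frame(
        loss = names(losses)[j], exact_mass = losses[j],
        fragment_mz = pk$mz[i], delta = s$precursor_mz - pk$mz[i])
    }
  }
  evidence <- if (length(hits)) do.call(rbind, hits) else
    data.frame(loss = character(), exact_mass = numeric(),
               fragment_mz = numeric(), delta = numeric())
  # O-glycoside counter-evidence: aglycone ion reachable by whole-residue loss
  o_glyc <- FALSE
  ag <- identify_aglycone(s, tol, floor)
  if (!is.null(ag)) {
    combos <- .glycosyl_combos()
    for (obs in c(ag$even_mz, ag$radical_mz + monoisotopic_mass("H"))) {
      if (is.na(obs)) next
      if (any(abs((s$precursor_mz - obs) - combos) <= 2 * tol)) o_glyc <- TRUE
    }
  }
  list(is_c_glycoside = nrow(evidence) >= 2 && !o_glyc, evidence = evidence)
}

# Bounded depth-first search for the neutral-loss chain explaining the
# spectrum: start at the precursor, follow rule-matching losses, never reuse
# a peak, depth capped. Among complete chains prefer one ending at a
# recognized aglycone/diagnostic ion, then highest explained intensity.
.best_loss_chain <- function(s, losses, pk, tol, max_depth = 5) {
  diag_mz <- c(diagnostic_ions()$mz, aglycone_ions()$even_mz,
               stats::na.omit(aglycone_ions()$radical_mz))
  is_terminal <- function(mz) any(abs(mz - diag_mz) <= tol)
  best <- list(chain = NULL, key = c(-1, -1))
  walk <- function(from, used, chain) {
    nxt <- losses[abs(losses$from_mz - from) <= 1e-9 &
                    !(round(losses$to_mz, 6) %in% used), , drop = FALSE]
    if (nrow(nxt) && length(chain) < max_depth) {
      # larger-mass rule preferred at ties on the same destination peak
      nxt <- nxt[order(-nxt$to_mz, -nxt$exact_mass), , drop = FALSE]
      nxt <- nxt[!duplicated(nxt$to_mz), , drop = FALSE]
      for (k in seq_len(nrow(nxt))) {
        walk(nxt$to_mz[k], c(used, round(nxt$to_mz[k], 6)),
             c(chain, list(nxt[k, ])))
      }
    } else {
      if (!length(chain)) return()
      expl <- sum(pk$intensity[round(pk$mz, 6) %in% used])
      key <- c(as.numeric(is_terminal(from)), expl)
      if (key[1] > best$key[1] ||
          (key[1] == best$key[1] && key[2] > best$key[2])) {
        best <<- list(chain = do.call(rbind, chain), key = key)
      }
    }
  }
  walk(s$precursor_mz, numeric(0), list())
  best$chain
}

#' Classify a spectrum into a polyphenol compound class
#'
#' The decision cascade mirrors the fragmentation reasoning used for tea
#' extracts: (1) flavan-3-ols by the A-ring HRF ion at m/z 125.02 or the
#' retro Diels-Alder pair 137/151, refined to proanthocyanidin dimers
#' (quinone-methide monomer ion plus HRF loss) or galloylated flavanols
#' (galloyl/methylgalloyl losses or gallate ions); (2) acylated flavonol
#' glycosides by coumaroyl + coumaric-acid loss pairs or a single acyl loss
#' co-occurring with an identified flavonol aglycone; (3) flavone
#' C-glycosides via [detect_c_glycoside()]; (4) flavonol O-glycosides when a
#' glycosyl-residue loss (or residue-sum) connects the precursor to an
#' aglycone ion; (5) phenolic acids / quinate esters by quinate or gallate
#' ions; (6) saccharides when only glycosyl/cross-ring/small losses and no
#' aromatic marker ions are seen. A nitrogen-containing precursor formula
#' with no aromatic evidence is called an amino acid. Anything else is
#' unclassified.
#'
#' @param s an [msms_spectrum].
#' @param precursor_formula optional neutral [elemental formula][parse_formula]
#'   of the precursor (used only for the amino-acid call).
#' @param tol fragment tolerance in Da.
#' @param floor intensity floor as a fraction of the base peak.
#' @return object of class `annotation_result`: list with `compound_class`,
#'   `aglycone`, `position_evidence`, `loss_chain`, `diagnostic_hits`,
#'   `acyl_inner_sugar` and `score` (explained-intensity fraction in
#'   `[0, 1]`).
#' @export
classify_compound <- function(s, precursor_formula = NULL, tol = 0.02,
                              floor = 0.01) {
  stopifnot(inherits(s, "msms_spectrum"), tol > 0)
  if (!nrow(s$peaks)) stop("cannot classify an empty spectrum")
  pk <- .filtered_peaks(s, floor)
  result <- function(class, aglycone = NA_character_,
                     position = "indeterminate") {
    losses <- detect_neutral_losses(s, tol = tol, floor = floor)
    di <- diagnostic_ions()
    hit_idx <- vapply(di$mz, function(m) .match_mz(pk$mz, m, tol),
                      integer(1))
    hits <- di[!is.na(hit_idx), , drop = FALSE]
    hits$observed_mz <- pk$mz[hit_idx[!is.na(hit_idx)]]
    chain <- .best_loss_chain(s, losses, pk, tol)
    explained <- unique(c(
      if (!is.null(chain)) round(chain$to_mz, 6),
      round(hits$observed_mz, 6)))
    tot <- sum(pk$intensity)
    score <- if (tot > 0) {
      sum(pk$intensity[round(pk$mz, 6) %in% explained]) / tot
    } else 0
    acid <- c("coumaric acid", "gallic acid")
    acid_h2o <- c("coumaroyl", "galloyl")
    prec <- losses[abs(losses$from_mz - s$precursor_mz) <= 1e-9, ]
    structure(list(
      compound_class = class, aglycone = aglycone,
      position_evidence = position, loss_chain = chain,
      diagnostic_hits = hits,
      acyl_inner_sugar = any(prec$rule %in% acid) &&
        any(prec$rule %in% acid_h2o),
      score = score), class = "annotation_result")
  }
  if (!nrow(pk)) return(result("unclassified"))

  di <- diagnostic_ions()
  dmz <- stats::setNames(di$mz, di$name)
  present <- function(target) !is.na(.match_mz(pk$mz, target, tol))
  losses <- detect_neutral_losses(s, tol = tol, floor = floor)
  prec_losses <- losses[abs(losses$from_mz - s$precursor_mz) <= 1e-9, ]
  ag <- identify_aglycone(s, tol, floor)
  aromatic <- any(vapply(dmz[c("flavanol A-ring", "RDA 137", "RDA 151",
                               "catechol B-ring", "gallate",
                               "methylgallate radical")],
                         present, logical(1))) || !is.null(ag)

  # precursor itself a small phenolic acid anion
  if (abs(s$precursor_mz - dmz[["gallate"]]) <= tol ||
      abs(s$precursor_mz - dmz[["quinate"]]) <= tol) {
    return(result("phenolic acid/quinate ester"))
  }

  # (1) flavan-3-ol family (precursor floor keeps gallic acid's 125.0242
  # [M-H-CO2]- fragment from mimicking the A-ring HRF diagnostic)
  rda_pair <- present(dmz[["RDA 137"]]) && present(dmz[["RDA 151"]])
  if (s$precursor_mz > 270 &&
      (present(dmz[["flavanol A-ring"]]) || rda_pair)) {
    monomer <- vapply(c("C15H12O7", "C15H12O6"), monoisotopic_mass,
                      numeric(1))  # quinone-methide fission complements
    qm <- any(vapply(s$precursor_mz - monomer, function(m) {
      m > 250 && present(m)
    }, logical(1)))
    hrf <- any(prec_losses$rule == "HRF A-ring")
    if (qm && hrf) return(result("proanthocyanidin dimer"))
    # acyl-loss evidence must leave a flavanol-sized product: A/B-ring
    # fragment mass differences coincide with acyl masses below ~250 Da
    gall_loss <- prec_losses$rule %in%
      c("galloyl", "methylgalloyl", "gallic acid") & prec_losses$to_mz >= 250
    gall <- present(dmz[["gallate"]]) ||
      present(dmz[["methylgallate radical"]]) || any(gall_loss)
    if (gall) return(result("galloylated flavan-3-ol"))
    return(result("flavan-3-ol"))
  }

  # (2) acylated flavonol glycoside
  acyl_rules <- c("coumaroyl", "coumaric acid", "galloyl", "methylgalloyl",
                  "gallic acid")
  acyl_losses <- prec_losses$rule[prec_losses$rule %in% acyl_rules]
  flavonol_ag <- !is.null(ag) && ag$aglycone != "apigenin"
  # an identified flavonol aglycone is required: coumaroyl/coumaric-acid
  # loss pairs also occur from hydroxycinnamoyl quinate esters
  if (length(acyl_losses) && flavonol_ag) {
    return(result("acylated flavonol glycoside",
                  aglycone = if (is.null(ag)) NA_character_ else ag$aglycone,
                  position = if (is.null(ag)) "indeterminate" else
                    ag$evidence))
  }

  # (3) flavone C-glycoside
  cg <- detect_c_glycoside(s, tol, floor)
  if (cg$is_c_glycoside) {
    return(result("flavone C-glycoside",
                  aglycone = if (is.null(ag)) NA_character_ else ag$aglycone,
                  position = "C-C"))
  }

  # (4) flavonol O-glycoside: glycosyl losses connect precursor to aglycone
  if (flavonol_ag) {
    combos <- .glycosyl_combos()
    deltas <- c(s$precursor_mz - ag$even_mz,
                s$precursor_mz - ag$radical_mz - monoisotopic_mass("H"))
    reach <- any(vapply(deltas[!is.na(deltas)], function(d) {
      any(abs(d - combos) <= 2 * tol)
    }, logical(1)))
    if (reach) {
      return(result("flavonol O-glycoside", aglycone = ag$aglycone,
                    position = ag$evidence))
    }
  }

  # (5) phenolic acid / quinate ester
  if (present(dmz[["quinate"]]) || present(dmz[["gallate"]])) {
    return(result("phenolic acid/quinate ester"))
  }

  # amino acid: needs the precursor formula (nitrogen, no aromatic evidence)
  if (!is.null(precursor_formula)) {
    f <- .as_formula(precursor_formula)
    if ("N" %in% names(f) && f[["N"]] > 0 && !aromatic) {
      return(result("amino acid"))
    }
  }

  # (6) saccharide: only glycosyl/cross-ring/small losses, no aromatics
  if (nrow(losses) && !aromatic &&
      all(losses$category %in% c("glycosyl", "ring-fission", "small")) &&
      any(losses$category %in% c("glycosyl", "ring-fission"))) {
    return(result("saccharide"))
  }

  result("unclassified")
}

#' @export
print.annotation_result <- function(x, ...) {
  cat(sprintf("<annotation_result> class: %s", x$compound_class))
  if (!is.na(x$aglycone)) {
    cat(sprintf("  aglycone: %s (%s)", x$aglycone, x$position_evidence))
  }
  cat(sprintf("  score: %.2f\n", x$score))
  if (!is.null(x$loss_chain)) {
    cat("loss chain:\n")
    print(x$loss_chain[, c("rule", "from_mz", "to_mz", "delta")])
  }
  invisible(x)
}

.chain_string <- function(chain) {
  if (is.null(chain) || !nrow(chain)) return("")
  paste(sprintf("%s(%.4f->%.4f)", chain$rule, chain$from_mz, chain$to_mz),
        collapse = ";")
}

#' Annotate spectra against the compound library
#'
#' Each spectrum is matched to the closest library entry by precursor ppm
#' error (retention time proximity breaks ties), then classified de novo by
#' [classify_compound()]; unmatched spectra keep the class-only annotation.
#'
#' @param spectra list of [msms_spectrum] objects.
#' @param library compound library as from [tea_compound_library()].
#' @param precursor_tol_ppm precursor match tolerance (ppm).
#' @param rt_tol_min retention-time window for tie-breaking (minutes).
#' @param tol fragment tolerance in Da for classification.
#' @return data.frame with one row per spectrum: `peak_id`, `precursor_mz`,
#'   `rt`, `matched_peak_no`, `matched_name`, `formula`, `calc_mz`, `ppm`,
#'   `rdb`, `class`, `aglycone`, `position_evidence`, `loss_chain`, `score`.
#' @export
annotate_library <- function(spectra, library = tea_compound_library(),
                             precursor_tol_ppm = 10, rt_tol_min = 0.5,
                             tol = 0.02) {
  stopifnot(length(spectra) > 0, nrow(library) > 0)
  rows <- lapply(seq_along(spectra), function(i) {
    s <- spectra[[i]]
    calc_ref <- if ("calc_mz_exact" %in% names(library)) {
      library$calc_mz_exact
    } else library$calc_mz
    ppm <- ppm_error(s$precursor_mz, calc_ref, digits = NA)
    cand <- which(abs(ppm) <= precursor_tol_ppm)
    match_i <- NA_integer_
    if (length(cand)) {
      ord <- order(abs(ppm[cand]),
                   if (is.na(s$rt)) rep(0, length(cand)) else
                     abs(library$rt_min[cand] - s$rt))
      best <- cand[ord[1]]
      # rt only breaks near-ties within the ppm tolerance
      if (!is.na(s$rt)) {
        near <- cand[abs(abs(ppm[cand]) - abs(ppm[best])) < 0.5]
        if (length(near) > 1) {
          drt <- abs(library$rt_min[near] - s$rt)
          best <- near[which.min(drt)]
          if (min(drt) > rt_tol_min) best <- cand[ord[1]]
        }
      }
      match_i <- best
    }
    f <- if (!is.na(match_i)) library$formula[match_i] else NULL
    ann <- classify_compound(s, precursor_formula = f, tol = tol)
    data.frame(
      peak_id = if (nzchar(s$sample_id)) s$sample_id else sprintf("spec%03d", i),
      precursor_mz = round_half_up(s$precursor_mz, 4),
      rt = s$rt,
      matched_peak_no = if (is.na(match_i)) NA_integer_ else
        library$peak_no[match_i],
      matched_name = if (is.na(match_i)) NA_character_ else
        library$name[match_i],
      formula = if (is.na(match_i)) NA_character_ else library$formula[match_i],
      calc_mz = if (is.na(match_i)) NA_real_ else library$calc_mz[match_i],
      ppm = if (is.na(match_i)) NA_real_ else
        ppm_error(s$precursor_mz, calc_ref[match_i]),
      rdb = if (is.na(match_i)) NA_real_ else library$rdb[match_i],
      class = ann$compound_class,
      aglycone = ann$aglycone,
      position_evidence = ann$position_evidence,
      loss_chain = .chain_string(ann$loss_chain),
      score = ann$score,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Relative abundance per compound class
#'
#' @param class character vector of class calls per annotated feature.
#' @param abundance non-negative abundances (same length).
#' @return data.frame with `class` and `percent`, percentages summing to 100.
#' @export
class_relative_abundance <- function(class, abundance) {
  stopifnot(length(class) == length(abundance), all(abundance >= 0))
  tot <- sum(abundance)
  if (tot <= 0) stop("zero total abundance")
  agg <- tapply(abundance, class, sum)
  out <- data.frame(class = names(agg),
                    percent = as.numeric(agg) / tot * 100,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$percent), , drop = FALSE]
  rownames(out) <- NULL
  out
}
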