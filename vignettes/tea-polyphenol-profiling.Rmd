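---
title: "Profiling tea polyphenols and scoring antioxidant activity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiling tea polyphenols and scoring antioxidant activity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(teaphenolics)
```

## Scope

`teaphenolics` implements the computational chain behind a comparative study
of green tea extracts: tentative identification of polyphenols from
negative-mode QqTOF MS/MS peak lists, and scoring of antioxidant activity
from radical-scavenging, lipid-peroxidation and ORAC assays. Everything is
testable offline because a seeded generator can synthesize all inputs with
planted ground truth.

## Formula and mass arithmetic

All calculated m/z values derive from elemental formulas and a pinned table
of monoisotopic atomic masses (C 12 exactly, H 1.0078250, N 14.0030740,
O 15.9949146; `inst/extdata/atomic_masses.tsv`). The deprotonated molecular
ion is

$$ m/z\,[\mathrm{M-H}]^- = M_\text{mono} - m_p, \qquad m_p = 1.007276\ \mathrm{Da}, $$

neglecting the electron mass; this convention reproduces the printed
4-decimal calc columns of the reference tables. The odd-electron radical
anion $[\mathrm{M-2H}]^{\bullet-}$ sits one hydrogen *atom* below the
even-electron ion. Ring double bond equivalents are
$\mathrm{RDB} = C - H/2 + N/2 + 1$ on the neutral formula, and mass errors
are reported as $(found - calc)/calc \times 10^6$ ppm. Reported values are
rounded half away from zero (4 decimals for m/z, 1 for ppm), matching table
formatting; ppm errors are computed against the *unrounded* calc value,
which is how the reference tables' error column behaves.

The transcribed 42-compound library (`tea_compound_library()`) keeps the
printed calc/found/error/RDB columns verbatim and recomputes calc m/z and
RDB from the formula. Eight printed rows (peaks 12, 13, 22, 23, 28, 32, 34,
35) carry calc values inconsistent with their own formula — mostly apparent
calc/found column swaps — and are flagged `calc_consistent = FALSE`; tests
reproduce the printed columns on the self-consistent rows only.

## The annotation rule engine

Class calls follow the fragmentation logic used for tea polyphenols in
negative ESI:

1. **Flavan-3-ols** show the A-ring ion at m/z 125.0244 from heterocyclic
   ring fission (HRF) or the retro Diels–Alder pair 137.0244/151.0401.
   Within this family, a quinone-methide monomer ion plus an HRF loss of
   126.0317 Da from the precursor marks a **proanthocyanidin dimer**, and
   galloyl/methylgalloyl losses or gallate-type ions mark **galloylated**
   flavanols. Two guards matter in practice: the flavanol branch requires a
   precursor above 270 Da (gallic acid's $[\mathrm{M-H-CO_2}]^-$ fragment at
   125.0242 is otherwise indistinguishable from the HRF diagnostic), and
   acyl-loss evidence must leave a product above 250 Da, because A/B-ring
   fragment differences of plain catechins coincide numerically with acyl
   masses (e.g. 305 → 139 is 166.026 Da, the methylgalloyl mass).
2. **Acylated flavonol glycosides** lose coumaroyl (146.0368) and/or
   coumaric acid (164.0473), or galloyl residues, from the precursor. The
   call additionally requires an identified flavonol aglycone ion:
   hydroxycinnamoyl quinate esters also show the coumaroyl/coumaric-acid
   loss pair, so the loss pair alone is not specific.
3. **Flavone C-glycosides** cannot lose their sugar as a whole residue;
   instead the sugar ring cleaves, giving losses of 60/90/120 Da from the
   precursor. The call requires at least two distinct cross-ring losses (a
   lone 120 Da loss occurs in O-glycoside spectra too) and no
   whole-residue route to a free aglycone; this makes C- and O-glycoside
   calls mutually exclusive by construction.
4. **Flavonol O-glycosides** connect the precursor to an aglycone ion
   through glycosyl residues. Because di- and tri-glycosides often shed the
   entire saccharide part in one step, the engine accepts any sum of one to
   three hexose/deoxyhexose/pentose residues (even-electron channel), or
   that sum plus one hydrogen (radical channel), within tolerance, in
   addition to stepwise loss chains.
5. **Phenolic acids / quinate esters** are called when the precursor is
   itself the gallate or quinate anion, or when those ions appear among the
   fragments and no glycoside/flavanol evidence preempted them.
6. **Saccharides** show only glycosyl/cross-ring/small losses and no
   aromatic marker ions. A nitrogen-containing precursor formula with no
   aromatic evidence is called an **amino acid** (theanine); this is the one
   call that needs the optional formula argument.

Aglycone identification matches the low-mass region against
$[\mathrm{A-H}]^-$ / $[\mathrm{A-2H}]^{\bullet-}$ pairs for quercetin,
kaempferol, myricetin and apigenin. Strict radical dominance
($I_{rad} > I_{even}$) is read as 3-O-glycosylation; a tie or an
even-electron ion alone stays indeterminate. Confirmatory
CH$_2$O/CH$_2$O$_2$ sub-losses from the even-electron aglycone raise a
`confirmed` flag. When two aglycones match (e.g. methylated flavonols whose
fragments include a demethylated pair), the one with both ions present and
the larger summed intensity wins.

Loss chains are found by bounded depth-first search from the precursor
(depth ≤ 5, each peak consumed once, larger-mass rule preferred at ties);
among complete chains the engine prefers one terminating at a recognized
diagnostic/aglycone ion, then the highest explained-intensity fraction,
which is also the reported `score`. The default fragment tolerance is
±0.02 Da — printed fragment m/z values deviate up to ~15 mDa from exact
residue arithmetic — and the precursor match tolerance is ±10 ppm. Peaks
below 1% of the base peak are ignored (`floor`), which keeps decoy noise
from entering the cascade. Co-occurrence of an acid and its dehydrated
(acyl) loss is recorded as an `acyl_inner_sugar` flag, evidence that the
acyl group sits on the sugar bonded to the aglycone, without asserting a
structure.

Known limitations: no combinatorial bond-breaking enumeration, no
stereochemistry (catechin vs epicatechin is retention-time-based), no
isotope envelopes, and retention time is used only to break library-match
ties, never for class logic.

## Assay mathematics

Percent inhibition is $(1 - S/S_0)\times 100$ against the blank. The ID50
is, by default, linear interpolation of response against $\log_{10}$ dose
between the bracketing pair around 50% — exact for a Hill curve with unit
slope whose midpoint is log-centred between two doses — with a
four-parameter logistic fit (`method = "4pl"`) as the alternative; the
five-point printed dose grid (0.78–12.5 µg/mL) is too sparse for the 4PL to
be the default. Non-monotone responses are isotonically projected when the
violation is ≤ 5% of the response range, otherwise rejected: this prevents
spurious multiple 50% crossings. If 50% is never crossed, the estimate is
extrapolated from the two nearest points and flagged `bracketed = FALSE`.

TEAC is the ratio $ID50_{Trolox}/ID50_{sample}$. The printed activity panel
satisfies $ID50_i \times TEAC_i \approx const$ per assay within 5%, which is
how the package validates this definition against the reference table.

ORAC curves are normalized to the blank by the factor
$f_{blank}(0)/f_{sample}(0)$, and the area under the decay is
$\mathrm{AUC} = \sum_i f_i/f_0$ over all readings *including* t = 0 (the
index runs over readings, so the first term contributes exactly 1 and a flat
nine-reading curve yields 9). Net AUC is $\mathrm{AUC} -
\mathrm{AUC}_{blank}$; Trolox equivalents are the ratio of ordinary
least-squares slopes (with intercept) of net AUC against concentration for
the sample and the Trolox standard.

## Activity ranking

Standard scores use the sample standard deviation (n − 1); with six samples
this is the convention under which the scored column has SD exactly 1.
Metrics where lower raw values mean more activity (all ID50 columns) are
negated after scoring so that "more antioxidant" always maps to a larger
score; the relative antioxidant capacity index (RACI) is the per-sample mean
of these oriented scores and sums to zero over samples. The printed RACI
magnitudes (up to 9.96) exceed the largest mean z-score attainable with six
samples (≈ 2.04 with n − 1 scaling), so they cannot arise from the stated
formula; the package therefore reproduces — and tests — only the sample
*ordering*, which matches the printed column exactly.

Clustering uses Pearson correlation distance ($1 - r$) and unweighted
average linkage (UPGMA), computed via `stats::hclust` behind the
`average_linkage()` surface and cross-checked in the tests against an
independent brute-force $O(n^3)$ UPGMA implementation; tie-breaking follows
`hclust` order (ties have probability zero for the continuous matrices
used). Heatmap preparation centres and unit-scales rows before ordering
both axes by their dendrograms, and dendrograms serialize to newick through
`ape` with branch lengths equal to merge-height differences.

## What the generator emulates — and what it does not

`sim_config()` fixes the study conditions:

* **Spectra**: precursor m/z = calculated $[\mathrm{M-H}]^-$ with Gaussian
  5 ppm error; fragments = the library's printed fragment lists with
  Gaussian 10 mDa error; intensities log-uniform over [0.05, 1] of the base
  peak with stated base-peak identities preserved (the radical aglycone for
  3-O-glycosides, the gallate ion for gallate esters, ...); five decoy peaks
  up to 20% of the base peak. Zero noise reduces every value to the exact
  library number.
* **Dose–response**: Hill curves $100\,d^h/(d^h + ID50^h)$ on the
  0.78–12.5 µg/mL grid with 2% multiplicative noise per replicate, averaged
  over three replicates as in the assay protocol (means are analyzed, SDs
  carried for reporting).
* **ORAC**: logistic fluorescence decay whose midpoint (blank: 45 min,
  steepness 8 min) is delayed proportionally to TE × concentration. The
  midpoint/steepness were chosen so the transition lies fully inside the
  0–120 min window; a transition touching t = 0 truncates the curve and
  visibly biases net-AUC linearity. The true decay kinetics are not
  tabulated anywhere, so only this qualitative delayed-decay behaviour is
  matched.
* **Panels**: four metrics (three lower-better, one higher-better) whose
  oriented quality follows a planted ranking with 5% log-normal noise.

Determinism: one master seed; each operation derives a sub-stream by stable
hashing of the operation name plus entry id, so adding entries never
reshuffles existing outputs, and the caller's RNG state is restored.

What passing these tests does *not* show about real data: the generator
re-emits the library's own fragment lists, so recovery rates measure the
rule engine's robustness to mass error and decoys, not its coverage of
fragmentation pathways absent from the library; co-eluting isomers,
chimeric spectra, chromatographic peak shapes and detector saturation are
all outside the model.

## Problem sizes used by the test suite

The recovery experiments run the full 42-compound library per condition,
100 dose–response curves per Hill slope in {0.5, 1, 2, 3}, 100 ORAC
replicate pairs, and 1,000 random 6-leaf distance matrices against the
brute-force clustering oracle — sizes at which every experiment is exact or
statistically stable while the whole suite stays fast.
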