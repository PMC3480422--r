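---
title: "Monitoring soil nematode assemblages with taxon-specific qPCR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Monitoring soil nematode assemblages with taxon-specific qPCR}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nemaquant)
```

## The measurement model

`nemaquant` treats a soil nematode community as a panel of monitored
taxa (families, or genera where a family cannot carry one DNA
signature), each detected by a specific primer pair on the small-subunit
(18S) ribosomal RNA gene. The quantitative core is the per-assay linear
calibration

$$C_t = a \cdot \log_{10} N + b,$$

where $C_t$ is the threshold cycle, $N$ the number of target nematodes
in the extract, $a < 0$ the slope in cycles per tenfold change (perfect
per-cycle doubling corresponds to $a = -1/\log_{10} 2 \approx -3.32$;
the derived amplification efficiency is $10^{-1/a} - 1$), and $b$ the
expected $C_t$ of a single nematode. The model is deliberately
log-scale: nematode life stages differ in somatic cell number by less
than a factor of two, so the unknown stage distribution perturbs
$\log_{10} N$ by far less than the order-of-magnitude differences the
monitoring aims to resolve. This assumption is adopted, not modelled.

Inverting the line gives densities, $N = 10^{(C_t - b)/a}$, reported as
individuals per 100 ml elutriated soil. Three corrections sit between a
raw plate and a community profile:

* **No-signal censoring.** The protocol runs 60 cycles; a $C_t$ at or
  beyond 60 (or an instrument "no signal") is a censored zero. The
  censoring flag propagates into profiles rather than being dropped, so
  downstream sums can distinguish "absent" from "below detection".
* **Extraction correction.** A fixed spike of mammalian DNA is carried
  through lysis and purification and quantified with its own assay.
  With per-cycle efficiency $E$ (default 1), recovery relative to a
  complete-recovery reference is $(1+E)^{\Delta C_t}$; one cycle of
  delay doubles all densities. Published protocols of this kind state
  the purpose of the internal standard but not its arithmetic, so the
  formula and the efficiency exponent are explicit, configurable
  package choices.
* **Dilution bookkeeping.** Calibration lysates and environmental
  lysates are assayed at different template dilutions (1000× vs 50× in
  the emulated protocol), giving a default multiplicative adjustment of
  20. Because this arithmetic is protocol-dependent, it is an exposed
  argument recorded in every profile, never a hidden constant.

## Deciding assay rank: monophyly on the reference tree

A family-level signature motif can only exist if the family is a clade
of the reference phylogeny. `check_monophyly()` takes the smallest
clade (MRCA subtree) spanning the family's reference sequences and
reports any non-member leaves inside it as intruders; single-leaf taxa
are monophyletic by convention. Trees are evaluated as rooted, exactly
as written in the Newick source — for an unrooted basal multifurcation a
warning marks the verdict rooting-dependent. `resolve_assay_targets()`
then keeps monophyletic families at family rank, replaces
non-monophyletic families by their monophyletic constituent genera (the
pattern seen in fungivorous families that split into two genus assays),
and flags families with no monophyletic representation as un-assayable
rather than silently dropping them — large para/polyphyletic groups
admit no comprehensive barcode at family level.

## Assay design choices

**Signature windows.** A window is a run of alignment columns, mapped to
ungapped coordinates of a representative target sequence (0-based
half-open internally, 1-based inclusive in everything user-facing), in
which all target members agree and every non-target differs by at least
a configured mismatch count (default 2). IUPAC ambiguity codes are kept
throughout; two bases match when their ambiguity sets intersect, which
is conservative for specificity claims (an ambiguous reference position
is never counted as a mismatch). A gap in a member breaks conservation;
a gap in a non-target counts as a mismatch. Ranking weights worst-case
non-target mismatches in the 3′-terminal five positions first, because
polymerase extension is most sensitive to 3′ mismatches.

**Melting temperature.** All primers target one annealing temperature
(63 °C, default tolerance ±1 °C) so a whole community panel runs on one
plate program. $T_m$ uses the unified nearest-neighbor ΔH/ΔS parameter
set with the entropic monovalent-salt correction
$\Delta S[\mathrm{Na^+}] = \Delta S[1\,\mathrm{M}] + 0.368\,(L-1)\ln[\mathrm{Na^+}]$
and the $C_T/4$ concentration convention, at defaults of 50 mM
Na⁺-equivalent and 200 nM primer. The parameter table ships as a
versioned data file so golden values remain stable. The published
protocol's stated primer concentration of 200 µg/µl is dimensionally
implausible (almost certainly nM was intended), so the thermodynamic
defaults here are package decisions, not transcribed values. Degenerate
primers are expanded (capped at 64 realisations) and the minimum — i.e.
weakest-binding, worst-case — $T_m$ is reported.

**Specificity and selection.** Empirically, specificity is the ΔCt gap
between the latest target and the earliest non-target; assays with a
numeric gap below 12 cycles are discarded. In silico, no published rule
exists, so the package uses a labelled heuristic: a non-target is
predicted non-amplifiable if either primer has ≥2 mismatches in its 3′
pentamer or ≥4 total mismatches, and otherwise contributes a proxy gap
of 3.3 cycles per mismatch; empirical measurements always override the
proxy. "No non-target signal at all" ranks above any numeric gap, ties
break by the lowest Ct per unit of template and finally by primer
sequence, making selection invariant under permutation of candidates.
The annealing-temperature profile check demands a sharp optimum:
Ct rising at ≥1 cycle/°C above 63 °C (the threshold that separates a
sharply peaked profile from a flat one) with the 63 °C point within 0.5
cycles of the profile minimum.

## Calibration choices

Fits are ordinary least squares of $C_t$ on $\log_{10} N$ (base-10
throughout, matching the slope's cycles-per-decade interpretation). $R^2$
is defined as the squared Pearson correlation between observed and
fitted $C_t$, which stays meaningful under replicated counts. A
non-negative slope flags the curve invalid with a warning — it is
returned for inspection but refuses to estimate densities. Family-level
assays pool genus dilution series by refitting on the union of raw
points, not by averaging slopes: genera within one family can differ
several-fold in body size and DNA content, so the pooled $R^2$ honestly
reflects that spread, and only genera actually observed in the
monitored samples are pooled. Both per-genus and pooled statistics are
available since the original description does not say which was
reported for multi-genus families.

## Coverage diagnostics

If the panel covered every taxon present, summed qPCR densities would
equal microscopic total counts. `coverage_check()` regresses
$\log_{10}(\text{qPCR total})$ on $\log_{10}(\text{microscopy total})$
and reports the slope with its standard error, externally Studentized
residuals (flag threshold $|2|$), and the fraction of samples within
±0.5 log₁₀ units — half an order of magnitude — of the fitted trend,
measured as vertical distance (the band runs parallel to the trend, not
to the identity line). One property worth knowing: when true totals
vary little between samples relative to the observation error of the
regressor, errors-in-variables attenuation pulls the fitted slope well
below one while shrinking residuals, so the in-band fraction can exceed
the naive Gaussian-tail expectation. The band fraction is a diagnostic
of scatter around the trend, not a test of slope unity; the slope and
its SE carry that information.

## Survey statistics

* **Trend lines.** The moving average follows the plotting convention
  of the emulated survey's figures: output element $i$ averages raw
  points $i+1 \ldots i+\text{window}$, with the final window truncated
  at the series end (so 18 occasions give 16 trend points, and a window
  equal to the series length yields the mean of points $2 \ldots n$).
  That convention discards the first raw point; the conventional
  trailing alignment is available behind `align = "trailing"`.
* **Site comparisons.** Mann–Whitney U uses the exact distribution for
  $n + m \le 12$ without ties and the tie-corrected normal
  approximation (with continuity correction) otherwise, reporting which
  path was taken. Total densities are compared by Welch's t on
  $\log_{10}$ totals with Welch–Satterthwaite degrees of freedom.
* **Mantel tests.** The observed statistic is the classical Mantel
  $Z = \sum_{i<j} X_{ij} Y_{ij}$ (the normalized correlation $r$ is
  reported alongside); the partial form correlates residuals of $X|Z$
  and $Y|Z$. Significance permutes rows and columns of $X$
  simultaneously, with the add-one convention
  $p = (\#\{Z_\pi \ge Z_{obs}\} + 1)/(M + 1)$ — $p$ can never be zero —
  and defaults to 9,999 seeded permutations; for small matrices all
  $n! - 1$ non-identity permutations are enumerated instead. The
  control matrix of a partial Mantel must be supplied explicitly: the
  emulated analysis describes only two community matrices, so the
  default reproduction is the simple Mantel on two sites'
  squared-Euclidean community time-profiles.
* **Covariates.** Environmental drivers are summarised as look-back
  sums (e.g. cumulative rainfall over the 21 days strictly before a
  sampling day) and only juxtaposed with density series — no
  density-on-weather regression is fitted, by design.

## The synthetic world

The generators exist so that every pipeline stage can be validated
against planted truth.

* `generate_reference_set()` builds a gapped alignment in which each
  taxon carries two planted signature motifs (a forward and a reverse
  primer site, one amplicon apart) that differ from the shared template
  at every position, members carry private substitutions outside the
  motif slots, and a short insertion in alternating taxa keeps the
  alignment genuinely gapped. A polyphyly switch interleaves one
  family's two genera with the other families in the reference tree.
  Uniqueness of planted signatures is guaranteed by construction and
  infeasible geometries error out.
* `generate_calibration_series()` draws Ct values on the true line at
  the 1/5/10/50/100 protocol counts with Gaussian Ct noise (default
  σ = 0.3 cycles).
* `generate_survey()` emulates the monitored design: 18 occasions over
  weeks 1–40, four field and two forest composites each, 15 taxa with
  the packaged calibration parameters as true curves where names match.
  Per-taxon seasonal means follow
  $\text{base} \cdot \exp(\text{amp} \cdot \sin(2\pi(w - \text{phase})/40))$
  with site-specific parameters; sampled densities are log-normal
  around those means (sdlog 0.3) times a community-wide per-sample
  factor (sd 0.15 log₁₀) that reproduces the realistic ~50% coefficient
  of variation of total densities; microscopy totals get independent
  log-normal observation error (sd 0.2 log₁₀). Panel Cts are emitted at
  calibration dilution with a complete-recovery internal standard, so
  quantification with `dilution_adjustment = 1` recovers truth exactly
  when all noise terms are zero.

Everything is driven by one master seed through fixed child-seed
derivation, so outputs are byte-identical across runs and platforms.

What passing these synthetic tests does **not** show: the generators
plant perfectly conserved motifs, independent Gaussian Ct noise and
log-normal abundances; real reference sets contain within-taxon
sequence variation, PCR inhibitors, rDNA copy-number differences
between life stages and taxa, and non-independent replicate structure.
The synthetic closure validates the arithmetic and the software
contracts, not the field performance of any particular primer set.

## Problem sizes and numerical conventions

The test suite runs the oracle-agreement checks at exhaustively
enumerable sizes (trees ≤ 8 leaves against full clade enumeration, rank
tests at $n+m \le 12$ against all labelings, Mantel at ≤ 5 entities
against all permutations), estimator-calibration checks at 500
replicated dilution series, and null-calibration checks at 2,000
Mann–Whitney and 500 Mantel simulations — sizes chosen to make
Monte-Carlo error small relative to the asserted tolerances while the
whole suite stays interactive. Ties in assay selection break
deterministically (gap, then unit-template Ct, then primer sequence);
fits are plain `lm`; p-value conventions (two-sided doubling for the
exact rank test, add-one for permutations) are stated on each function.

## Known limitations

Obligate plant parasites are excluded from coverage accounting by
design, as in the emulated study. The genus-level coverage rule
reproduces the published forest figure (72%, 13/18) exactly but yields
65% (20/31) for the field where 59% was printed with an unrecoverable
denominator; both numbers are reported, not reconciled. The in-silico
ΔCt proxy is a labelled heuristic with no claim of cycle-level accuracy.
Marine assemblages, melting-curve analysis, probe-based chemistry,
primer-dimer/hairpin screening and soil-food-web maturity indices are
out of scope.
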