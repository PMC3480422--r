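# nemaquant

Quantitative PCR monitoring of soil nematode assemblages from
taxon-specific SSU rDNA assays.

Soil nematodes are a standard indicator group for biological soil
quality, but classical community analysis requires slow microscopic
identification by specialists. An alternative is a panel of
taxon-specific quantitative PCR (qPCR) assays on the small-subunit (18S)
ribosomal RNA gene: one primer pair per monitored family or genus, all
running at a single annealing temperature, calibrated against hand-picked
nematode dilution series so that threshold cycles translate directly into
densities. `nemaquant` implements that workflow end to end for ecologists
and molecular soil biologists:

1. **Reference framework** — validate a gapped SSU rDNA alignment,
   taxonomy and reference phylogeny; test each candidate family for
   monophyly (a family can only carry one DNA signature if its members
   form a clade) and decide family- versus genus-rank assay targets
   (`load_framework()`, `check_monophyly()`, `resolve_assay_targets()`).
2. **Assay design** — discover taxon-specific sequence motifs in the
   alignment, enumerate primer pairs at a uniform annealing temperature
   of 63 °C using nearest-neighbor melting-temperature thermodynamics,
   score specificity as the Ct gap (ΔCt) between the latest target and
   the earliest non-target signal, and select one assay per taxon,
   discarding any candidate with ΔCt < 12 cycles
   (`find_signature_windows()`, `enumerate_primer_pairs()`,
   `compute_tm()`, `score_specificity()`, `select_assay()`).
3. **Calibration** — fit the linear relation

   `Ct = a · log10(N) + b`

   per assay by ordinary least squares on dilution series of 1, 5, 10,
   50 and 100 hand-picked nematodes; pool genus series into family
   curves; invert the relation to estimate densities
   (`fit_calibration()`, `predict_ct()`, `estimate_density()`,
   `pool_family_curve()`).
4. **Quantification** — convert an environmental sample's Ct panel into
   individuals per 100 ml soil with internal-standard extraction
   correction and dilution bookkeeping, aggregate feeding guilds, and
   check coverage against microscopic total counts on the log–log scale
   (`quantify_sample()`, `aggregate_guilds()`, `coverage_check()`).
5. **Survey statistics** — the seasonal-survey toolbox: trend-line
   moving averages, coefficients of variation, Mann–Whitney U site
   comparisons, Welch t on log totals, simple/partial Mantel tests with
   permutation p-values, and rainfall look-back windows.
6. **Synthetic data** — seeded generators (`synthetic_spec()`,
   `generate_reference_set()`, `generate_calibration_series()`,
   `generate_survey()`) reproduce the statistical structure of a
   two-site, 18-occasion seasonal survey with known ground truth, so the
   whole pipeline is testable without laboratory data.

The package ships two plain-text fixtures: the genus occurrence
inventory of a monitored former arable field and adjacent beech forest
(45 genera) and the 15-assay calibration table (guild, ΔCt, slope,
intercept, R²).

## Worked example

```r
library(nemaquant)

# a packaged family curve, and a density estimate from an observed Ct
cv <- fixture_curves()[["Metateratocephalidae"]]
cv
#> <calibration> Metateratocephalidae: Ct = -5.090 log10(N) + 24.400 (R2 0.954, eff 57%)
round(as.numeric(estimate_density(cv, 18.7)), 1)
#> [1] 13.2   (individuals; Ct 5.7 cycles before the single-nematode
#>             intercept on a -5.09 slope is ~13 nematodes)

# a synthetic survey with known truth, quantified end to end
sp <- synthetic_spec(seed = 42)
sv <- generate_survey(sp)
d  <- subset(sv$panels, sample_id == "field_w01_r1")
prof <- quantify_sample(
  list(sample_id = "field_w01_r1", site = "field", week = 1,
       cts = setNames(d$ct, d$assay), internal_standard_ct = 20),
  sv$curves, reference_standard_ct = 20, dilution_adjustment = 1)
prof
#> <community profile> field_w01_r1 (field, week 1): 15 taxa, total 696.2 per 100 ml
round(aggregate_guilds(prof, sp$guilds), 1)
#>     B     F     O     P
#> 534.2  62.3  77.3  22.3

# assay coverage of the forest's free-living genera
coverage_fraction(occurrence_fixture(), "forest")
#> [1] 72        (13 of 18 free-living genera carry an assay)
```

The guild codes are B bacterivore, F fungivore, O omnivore, P predator;
totals are individuals per 100 ml elutriated soil.

A thin command-line front end is installed as `inst/exec/nemaquant`
(subcommands `targets`, `calibrate`, `quantify`, `coverage`,
`simulate`); it delegates to the exported functions above.

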