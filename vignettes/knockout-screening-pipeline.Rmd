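---
title: "Designing, screening and mining a transposon knockout collection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing, screening and mining a transposon knockout collection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(koscreen)
```

## The problem

Acid-producing bacteria such as *Gluconobacter oxydans* leach rare-earth
elements (REEs) from solid substrates by secreting a gluconic-acid-rich
biolixiviant, and the endpoint pH of that biolixiviant is a strong predictor
of leaching efficiency. Finding the genes that control acidification
genome-wide calls for a whole-genome knockout collection: tens of thousands
of mariner-transposon mutants, arrayed, located, condensed to one-to-few
mutants per gene, screened with cheap colorimetric pH assays, and confirmed
with proper statistics. `koscreen` implements the computational chain behind
every one of those steps, together with a seeded synthetic-data generator
that emulates all of the pipeline's inputs so each stage can be exercised
and tested without any external data.

## Insertion-site model

Mariner-family transposons insert at TA dinucleotides. We index sites by
scanning the forward strand of each contig for the words `TA` and `AT`,
counting overlapping occurrences, and addressing a site by the 1-based
position of its first base; a site belongs to a gene when that base lies in
`[start, end - 1]` (coordinates are GFF3-style 1-based inclusive
throughout). Scanning a single strand is a deliberate choice: the word pair
`{TA, AT}` already captures both orientations of the palindromic target, so
adding the reverse strand would double-count every site. Whether published
per-gene site counts used one or both strands is generally ambiguous; the
single-strand convention at least makes the count well defined, and the
reverse-complement invariance of the pair is enforced by a property test.
`N` bases never match, which under-counts rather than over-counts sites in
ambiguous sequence. An insertion that falls where genes overlap is charged
to every overlapping gene - the conservative reading for a knockout
catalog.

## Saturation design

The number of genes carrying at least one disruption after `N` picks is
estimated two ways. The Monte Carlo route draws insertions i.i.d.
site-uniformly (each of the `S` genome sites equally likely; picks landing
outside genes consume a draw and cover nothing, which is what happens when
colonies are picked blind) and reports the mean and standard deviation of
the unique-gene count over replicates, with a mean ± 2 sd band; 1000
replicates is the default. The closed form for the same expectation is

$$\mathbb{E}[\text{unique genes}] = \sum_i \left(1 - (1 - p_i)^N\right),
\qquad p_i = s_i / S,$$

with `s_i` the gene's site count. `min_picks_for_coverage()` inverts the
closed form by doubling-then-bisection; the Monte Carlo and the closed form
are required to agree within 3 standard errors in the test suite. A
gene-weights mode accepts explicit `p_i` for reproducing curves when only
per-gene counts are published, and a without-replacement mode draws from a
sequenced progenitor catalog to show whether an already-picked collection
is saturated (its curve must dominate the with-replacement curve at matched
`n`; at the full catalog size it is exact with zero variance).

## Pooling and curation

Plates are arranged row-major on a 20 x 27 virtual grid and pooled along
four axes - grid row (20 pools), grid column (27), well row (8), well
column (12), 67 pools in total, each well in exactly one pool per axis. The
paper trail for real collections uses Bayesian inference over sequencing
read counts to resolve addresses; that is out of scope here. The naive
deconvolution provided instead intersects the Cartesian product of a
strain's observed axis coordinates with occupied grid cells: a single-well
strain resolves uniquely, a strain in two wells sharing no axis value
yields 16 candidates, and a strain missing an axis is flagged unlocatable
rather than guessed. Round-trip exactness on collision-free catalogs is an
acceptance property.

Curation of the condensed collection ranks each gene's candidate strains by
insertion proximity to the translation start (disruptions early in the ORF
are more reliably null) and then by address probability, selects up to two
strains, adds a third when both selections have probability below the
`ambiguity_threshold` (default 0.5 - the source protocol says only that
some locations were "ambiguous", so the threshold is a configuration key,
not a claim), and requests `min(10, 2 x predicted well occupancy)` colonies
per pick.

## Dye screens and hit calling

Endpoint acidity is scored as the thymol blue A435/A545 ratio, which is
linear in pH between 2.0 and 3.4; the calibration is an ordinary
least-squares line `pH = slope x ratio + intercept` and conversions outside
the window are returned but flagged extrapolated. Because the ratio and any
positive-slope calibration of it are affinely related, outlier flags are
identical whether raw ratios or calibrated pH enter the quartile
computation; the pipeline flags on the raw ratio. Acidification rate is the
negated least-squares slope of seven one-minute A600 reads (bromophenol
blue's absorbance falls as acid forms, so positive `V` means faster
acidification), normalized by OD590. Rate wells are discarded when the
kinetic fit's R^2 is below 0.5; wells are additionally discarded below a
growth floor of OD 0.1 - the source protocol does not state how failed
wells were excluded, so the floor is explicit and configurable.

Hits are called per plate: quartiles of the valid scores by the inclusive
linear-interpolation convention (`quantile` type 7, the spreadsheet
default, exposed as a parameter because the convention moves hit
boundaries), bounds at 1.5 IQR beyond them, and a strain is a hit when more
than half of its wells (or 1 of 2) are outliers on a consistent side.
Mixed-direction outliers are never hits - a strain that is "high" on one
plate and "low" on another is noise, not biology. Control wells B2 and E7
never enter the quartiles. Plates with fewer than four valid scores are
skipped with a warning.

## Confirmation statistics

Confirmed phenotypes come from two-tailed pooled-variance t-tests against
proxy wild-type (pWT) strains - mutants with intergenic insertions, so the
antibiotic cassette is controlled for - with Bonferroni threshold
`0.05 / N` for a family of `N` comparisons. Two mating-batch backgrounds
with different saturated densities run through the collection, so endpoint
comparisons use pWT set A for plates 1-76, 110-129 and 160-185 and set B
for 77-109 and 130-159; plate 130 appears in both printed ranges and is
assigned to B (overridable). Zero-pooled-variance cases are resolved
deterministically (equal means: p = 1; unequal: significant, flagged
degenerate). A strain only keeps a headline acidity/rate label when its
growth comparison is non-significant; the growth filter is operationalized
as the same Bonferroni-corrected t-test on saturated OD, since the source
describes the outcome but not the test. Family-wise error control under a
global null is verified by simulation in the acceptance suite.

## Enrichment

GO enrichment of any gene set against the annotated background uses the
one-sided hypergeometric upper tail `P(X >= k)` - classic Fisher - with
significance at raw `p < 0.05` and no multiplicity correction by default,
mirroring common practice for this screen type (an adjusted mode exists but
is off). The annotation map is used as given: no GO-graph propagation, no
term decorrelation. Decorrelating algorithms ("weight"/"elim") redistribute
p-values on correlated terms and would give systematically different
results; that difference is documented, not reconciled. Terms with `k = 0`
are skipped, ties in p sort by term id for stability, and the
implementation is checked against full combinatorial enumeration for all
backgrounds up to N = 60.

## Bioleaching quantification

Leachate concentrations arrive as-measured in ppb after 1/200 dilution
(1/20 for low-leaching samples, routed automatically below a quantitation
threshold). Undiluted concentration is measured x dilution; extracted mass
is concentration (ug/L) x leachate volume (0.5 mL); efficiency is extracted
mass over available mass (solids mass in grams x substrate REE content in
ug/g) x 100. The content table is a required configuration input - the
pipeline ships no substrate reference values, and the synthetic generator's
table is a placeholder. Totals are mass sums over the 16-element panel (Sc,
Y, La-Lu with their ICP-MS m/z); whether published totals are molar or mass
sums is often unstated, and mass is used here. Strain comparisons reuse the
pooled t-test plus a percent-change estimate; the pH-extraction relation is
a straight OLS of total REE on pH with its Pearson correlation, expected
negative on realistic data.

## The synthetic-data generator

Every input the pipeline consumes can be generated from a `sim_config()`
and a seed, with ground truth emitted alongside and never read by the
pipeline itself:

* **Genome**: 3283 genes by default on 62 contigs at GC 0.61, log-normal
  gene lengths (median ~900 bp, sdlog 0.55 - the real length distribution
  is not published, and log-normal with a plausible spread reproduces the
  slow saturation tail caused by short, site-poor genes), ~13% intergenic
  sequence. Every gene is guaranteed >= 7 TA/AT sites by rejection
  resampling, so all genes are disruptable. GC >= 0.9 is rejected outright.
* **Progenitor catalog**: 49,256 site-uniform picks into 94-well plates
  (B2/E7 reserved), 5% cross-contamination duplicating strains into extra
  wells, address probabilities with an ambiguous tail.
* **Plate readouts**: per well, true pH = batch baseline 2.3 + planted
  shift + N(0, 0.03); the true thymol blue line (slope 1, intercept 1.8)
  maps pH to the A435/A545 ratio with absorbance noise sd 0.01 on each
  channel; A600 declines at `0.05 x rate multiplier x OD` per minute with
  per-read noise; OD is the batch mean (1.3 for set A, 0.9 for set B - the
  two backgrounds differ only in density) times the growth multiplier.
  Controls carry blank signatures.
* **Bioleach tables**: total REE = 7600 - 2000 x pH ppb (floored at 100),
  split by a fixed Y/Eu-rich composition vector summing to 1, replicate
  noise sd 120 ppb. At the baseline pH this leaches ~3000 ppb; near pH 4.7
  the floor engages and samples route to the 1/20 dilution.

What the generator does **not** emulate: transposition hot/cold spots
beyond TA density, selection bias, read-level sequencing noise (and hence
the Bayesian location problem), plate-position or edge effects, growth-curve
dynamics, instrument drift, and inter-element ICP-MS interference. Passing
tests therefore demonstrate that the *computational chain* is correct under
its stated assumptions, not that those assumptions hold for any particular
real data set.

## Numerical choices and problem sizes

Quartiles use inclusive interpolation (type 7); switching conventions is a
one-argument change and shifts hit boundaries, which is exactly why it is
exposed. Degenerate inputs are resolved rather than propagated: zero
variance in a t-test, zero A545 in a ratio, constant kinetic series (V = 0,
R^2 = 0), IQR = 0 plates (only values different from the common value can
flag). Seeds are mandatory wherever randomness exists and every generator
is a pure function of (config, seed).

The shipped tests and the acceptance script run the saturation check on a
300-gene genome at 1000 replicates and the full-scale screens on the
185-plate default with 300-replicate coverage curves - sizes chosen so the
whole suite re-runs in a few minutes while still exercising the pipeline at
the collection's real plate count. The analysis scripts under `analysis/`
run the same chain at the full 3283-gene, 49,256-pick scale.

## Known limitations

* The naive deconvolution is intentionally weaker than Bayesian address
  inference; with cross-contamination it returns candidate sets, not
  posterior probabilities.
* Enrichment p-values on correlated GO terms differ from decorrelating
  algorithms by construction.
* Extraction efficiency is only as good as the substrate content table;
  efficiencies above 100% are flagged rather than clamped.
* The growth filter and the OD floor are this pipeline's explicit
  operationalizations of steps that wet-lab protocols usually leave
  implicit; both are configurable.
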