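---
title: "Methods: humpback song structure, similarity and support"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: humpback song structure, similarity and support}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(whalesong)
```

## The analysis problem

Passive acoustic recorders moored across a polar feeding ground log
humpback whale sound year-round, but a single hydrophone cannot identify
individuals, and no audio survives desk-scale reanalysis — what travels is
the *annotation*: which hours held song, and, for high-quality hours, the
unit/phrase/theme transcription of what was sung. This package turns such
annotations into the quantities that support population-level inference:
how song presence is distributed in space and season, how elaborate songs
are, and — the core question — whether the singers fall into distinct song
groups, as breeding-population theory predicts.

The package is organised around that flow: hour classification →
singer attribution and segmentation → elaborateness → similarity →
clustering with bootstrap support, with sea-ice context and a unit-type
validation check alongside, and a synthetic generator standing in for the
recordings.

## Hour categories

An annotated hour is classified by a fixed precedence:

1. `HWS1` (complex song) if at least two distinct themes occur;
2. `HWS2` (preliminary song) if at least three *consecutive* phrases of
   one phrase type occur;
3. `SOCIAL` if any vocalization is present;
4. `ABSENT` otherwise.

"Repeated phrases" is read as contiguous repetition — i.e. a theme —
because that is what the category's schematic depicts; two non-adjacent
renditions of a phrase type do not make a preliminary song. Monthly
proportions divide category counts by *classified* hours, so absence
contributes to the denominator but no numerator; months without usable
recordings are omitted rather than reported as zero.

## Singers, sessions, songs

Operational singer identity uses two rules: distinct stations (over 200 km
apart, implausible to cross in a day at a 4 km/h swim speed and 17–75
km/day travel rates) host distinct singers; and within a station, a gap of
more than 24 h between song-bearing hours starts a new singer. The gap is
measured between consecutive hours, not calendar days, and the singer id is
the station plus the date of the singer's first hour. Increasing the gap
parameter can only merge singers, never split them (tested as a
monotonicity property).

Sessions split where the silence between consecutive units (end-to-start)
strictly exceeds 60 s. Song delineation scans a session's theme tokens left
to right and closes a song each time the set of theme types seen since the
last boundary equals the session's *own* full theme-type set — a
deterministic reading of "complete rendition of all unique theme types".
The session's set, not a global catalogue, is the reference, because a
global reference would mark nearly every field recording partial. A
trailing incomplete segment is kept, flagged `partial`, so unit counts are
conserved; partials feed length statistics but are excluded from set-median
input by callers that follow the same convention.

Quality filtering keeps sequences with SNR ≥ 10 dB and at least two
distinct themes. Where a recording spans adjacent analysed hours the
package concatenates contiguous hours before session splitting; the
even-hour subsampling helper and the odd-neighbour extension mimic the
manual revision schedule that produced such data.

## Elaborateness

Two lengths and three complexities, all per song and then averaged per
singer: length is the number of units per sequence; unit complexity is
unique unit types / total units; phrase complexity is unique phrase types /
total phrases; song complexity is their product. All complexities live in
(0, 1] and are invariant to relabelling of types. Associations with day of
year and latitude are plain Pearson product-moment correlations, reported
with n and without significance tests.

## Similarity indices

Repertoire similarity is the Dice Coincidence Index over phrase-type
*sets*, `DCI = 2A/(B + C)`. Sequence similarity is
`LSI(a, b) = 1 − d(a, b) / max(L(a), L(b))` where `d` is the Levenshtein
distance computed over *theme tokens*: `"Cb"` is one symbol, because
comparing letters would spuriously reward phrase codes that happen to share
characters. Both indices are symmetric, bounded in [0, 1], equal 1 exactly
on identical inputs, and are invariant to any bijective relabelling of
tokens (all tested, with the edit distance additionally checked against an
exhaustive-recursion oracle over every pair of length ≤ 4 sequences on a
3-token alphabet).

The set-median string of a singer's songs (one 24-h window at one station)
is the member sequence with maximal *sum* of LSI to the other members —
equivalent to the maximal mean; self-similarity is excluded. Ties break to
the earliest song in input order, so callers should order songs
deterministically (the pipeline sorts by singer id, then song start).

When only the printed set-median table is available, a singer's repertoire
for DCI is proxied by the token set of their printed set-median sequence.
Every output built on that proxy carries
`repertoire_source = "set_median_proxy"`, because repertoires from full
quality-filtered recordings could be larger.

## Clustering and AU support

Similarities become distances `d = 1 − s` and are clustered by single
linkage. Merge ties break to the pair whose smallest leaf labels sort
lexicographically first, which makes trees reproducible even on degenerate
matrices (identical repertoires are common within a year).

Support comes from a multiscale bootstrap. What to resample is a design
decision the source material leaves open; the package resamples the **raw
observations beneath the similarity**, never the matrix itself:

* for DCI, singers' repertoires form a binary singer × phrase-type matrix,
  and phrase-type columns are resampled with replacement —
  `round(r * m)` columns at scale `r`; duplicated columns count multiply
  in the 2A/(B + C) arithmetic, and a singer left with no sampled types
  gets similarity 0 to everyone (conservative);
* for LSI, each singer's song set is resampled with replacement
  (`round(r * n)` songs, at least one) and the set median recomputed.

Scales default to 0.5, 0.6, ..., 1.4 with 1000 replicates per scale and a
mandatory seed. For each internal division of the observed tree, the
bootstrap proportion `BP_r` is the fraction of replicate trees containing
the identical leaf set (replicate trees use the same lexicographic
tie-break, so tie-created divisions are counted consistently). The
approximately unbiased probability comes from the multiscale fit: regress
`qnorm(1 − BP_r)` on `(sqrt(r), 1/sqrt(r))` by ordinary least squares to
estimate a signed distance `v` and curvature `c`, then
`AU = 1 − pnorm(v − c)`. Scales with BP exactly 0 or 1 carry no quantile
information and are dropped from the fit; if BP is 1 (or 0) at *every*
scale the division is reported as AU = 1 (or 0) with a `degenerate_*`
flag, and with a single scale the fit is impossible, so BP is reported and
AU flagged `insufficient_scales`. AU > 0.95 marks divisions likely to be
supported by the data.

Newick export writes branch lengths as merge-height differences and AU × 100
as internal node labels; labels with spaces or slashes are single-quoted.

## Sea ice

Station series average, per day, all grid cells whose haversine
(R = 6371 km) distance to the station is at most 50 km, treating cells as
points at their centres — the simplest defensible reading of "within a 50 km
radius"; no area weighting is applied. Interior gaps of at most 5 days are
linearly interpolated; longer gaps stay missing and crossings skip them.
The ice edge is the 15% contour: a retreat event is the first day strictly
below the threshold after a day at or above it, an advance the mirror
image. Song/ice lags measure first song minus the most recent prior
retreat, and last song minus the most recent prior advance; if a song
precedes every event of the right kind, the lag to the next event is
returned (negative) with an explicit flag rather than silently undefined.

## Unit-type validation

The robustness of a manual unit catalogue is scored by the out-of-bag
misclassification rate of a bagged ensemble of CART-style trees grown on a
numeric acoustic-feature table (nominally 44 metrics per unit exemplar).
Trees use Gini impurity with `floor(sqrt(p))` features sampled *per split*
and grow to purity by default; 500 trees is the default ensemble size and
is configurable, not hard-coded. Rows are canonically reordered before any
random draw, so the rate is bit-identical for a seed and invariant to input
row order. One caution established while testing: on data with *no* signal,
OOB majority votes anti-correlate with the true labels (a held-out row's
class is underrepresented in its trees' bootstraps), so the rate lands
above the naive chance level — about 0.9 for two balanced classes with
constant features. The estimator is reported as-is; the published 16% OOB
rate of the original 436-exemplar table is a property of that dataset, not
a target the synthetic benchmarks reproduce.

## The synthetic world

The generator states, once, the world the analysis assumes, and the test
suite treats it as ground truth:

* **Two song groups.** Disjoint phrase catalogues by default (overlap is a
  config knob); the widespread group sings at the Greenwich-meridian and
  central Weddell stations in all study years, the western group only at
  the Elephant Island station in 2013. Catalogue sizes default to 12 and 8
  phrase types.
* **Repertoire convergence.** Within a group-year, every singer carries the
  catalogue's core half and draws the rest from one of 3 shared song
  variants — singers converge on the same rendition, so with more singers
  than variants some pairs share repertoires 100%, and within-group DCI is
  never below the core fraction (0.5).
* **Era drift.** Between the 2011–2013 and 2017–2018 eras, half the
  catalogue (the `era_drift` fraction) is replaced. Replacement types
  occupy the core positions and only old tail types survive, which bounds
  cross-era repertoire DCI at `1 − era_drift` (0.5 at defaults) — the
  "at least 50% different" era contrast.
* **Songs.** Theme sequences of length 2–7 (the bulk of printed set-median
  lengths) from a first-order process with no immediate repeats; each theme
  expands into 1–4 phrases, phrases into units via the type's template with
  1–3 repetitions per template unit; unit SNRs sit above the 10 dB filter.
  Sessions group about 3 songs with > 60 s gaps between sessions.
* **Season and ice.** Hour categories peak in May (Gaussian month weights);
  the southernmost station (the most ice-bound) emits social calls only.
  Ice concentration is `clip(50 + 45·cos(2π(doy − 260)/365.25) + ε, 0, 100)`
  with ε ~ N(0, 3²): a mid-September maximum, a late-February minimum below
  the 15% edge, hence exactly one retreat and one advance per year, with
  the closed form retrievable for tests.
* **Unit features.** 21 classes × 20 exemplars (echoing ~436 exemplars at
  ≥ 20 per type) × 44 features; class means have per-feature offsets drawn
  from N(0, separation²) in units of the within-class standard deviation,
  default separation 6.

Everything is a pure function of (config, seed). What a green synthetic
test establishes is that the *estimators* behave as designed under the
stated world; it cannot establish anything about real recordings — the
generator has no masking noise, no detector misses, no annotation error,
and its group structure is cleaner than nature's.

## Numerical choices and edge cases

* Timestamps are seconds from recording start over half-open intervals;
  dates are UTC calendar dates with no time-zone arithmetic.
* The session gap uses strict `> 60 s`; ice-edge crossings use strict
  inequalities on the 15% threshold ("dropped below" / "exceeded").
* Phrase repetition counts serialize as comma-separated integers in their
  own column — appending them to the code string would be ambiguous to
  parse back.
* The singer-id parser accepts both printed dialects (with and without a
  space before the date); the formatter always emits the spaced form, so
  format→parse is the identity.
* The set-median table fixture is checksummed (md5) on load; the printed
  table lists 77 singer rows and 44 distinct phrase-type codes, and the
  reader enforces both.
* Similarity matrices are validated symmetric with unit diagonal before
  clustering; non-symmetric input is an error, not a warning.

## Known limitations

* Sea-ice input is long-format CSV only; no NetCDF reader is bundled.
* The AU resampling units (phrase-type columns for DCI, songs for LSI) are
  one reasonable choice among several; outputs carry enough metadata to
  recompute under another convention, but no alternative is implemented.
* Only single linkage is provided, matching the analysis this package
  reimplements; no other linkage, and no gap-scored sequence alignment
  beyond unit-cost edit operations.
* LSI bootstrap replicates recompute set medians per singer and are an
  order of magnitude slower than DCI replicates; plan n_boot accordingly.
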