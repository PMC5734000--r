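---
title: "Mining care-pathway spectra and clustering provider networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining care-pathway spectra and clustering provider networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(careflow)
library(dplyr)
```

## The problem

Administrative claims registers record, for every patient, a time-stamped
stream of diagnostic and therapeutic events. For chronic ischemic heart
disease (stable angina; acute myocardial infarction excluded), the work-up
escalates through three care levels:

* **E** — non-invasive, non-imaging testing: stress electrocardiography;
* **NI** — non-invasive imaging: stress echocardiography, SPECT;
* **I** — invasive procedures: coronary angiography (CA), percutaneous
  coronary intervention (PCI), coronary artery bypass grafting (CABG).

Clinical guidelines prescribe the escalation E → NI → I, but physicians
may skip or reorder steps. `careflow` quantifies this practice variation:
it extracts care episodes from the event stream, labels each episode by
the order in which the three categories first appear, profiles de facto
care centers by the resulting 15-component *pathway spectrum*, and
clusters the centers by the Pearson correlation of their spectra. Cluster
membership can then be confronted with costs, revascularization intensity
and 365-day mortality.

## From events to episodes

An *event series* is the unit of analysis. Its rules, all day-granular:

1. **Phantom merging.** Same-procedure events of one patient that fall
   within a per-procedure window are collapsed into the earliest one,
   greedily left to right. The default merges only SPECT rows up to 2 days
   apart (the two-day acquisition protocol is billed as two events); all
   other windows default to 0. `merge_phantom_events()` exposes the
   windows, so richer rule sets can be supplied when they are known.
2. **Index qualification.** An event opens a series iff the patient had no
   event in the preceding 180 days *and* the event falls at least 180 days
   after observation start. The second condition is the conservative
   reading of an unverifiable run-in: for an event on day 10 we cannot
   know whether the patient was event-free before the window began, so it
   cannot be an index event and pre-index events are discarded.
3. **Termination.** The series runs until the next >180-day event-free
   stretch, a death event, or the end of observation.
4. **Classification.** The label is the hyphen-join of the categories in
   order of first appearance; repeats never re-enter. The label space is
   therefore the 15 non-empty ordered selections of distinct elements of
   {E, NI, I}. Same-day ties are ordered E < NI < I, then alphabetically
   by procedure code — the register is silent on intra-day order, and a
   deterministic convention is required for reproducible labels.

Death markers carry no care category: they terminate series and feed the
mortality statistic, but never the label.

## Centers, spectra, outcomes

Each ZIP area is assigned one dominant de facto center per care level by
majority vote: every resident patient with at least one event of the level
casts one vote, for the provider of their chronologically first such
event. Ties break to the lexicographically smallest provider id (the data
cannot distinguish tied providers; determinism is required).
Series are attributed to the dominant center of the patient's ZIP — the
spectrum describes the population served, not the operator of each
procedure. Departments of one institution should be merged beforehand
with `aggregate_departments()`.

A center's spectrum is its relative-frequency vector over the 15 types.
Cluster-level percentages pool raw series counts across member centers
(never unweighted means of center ratios), which makes the
whole-population column an exact series-count-weighted mean of the cluster
columns — an identity the test suite checks and the acceptance script
recomputes from the published table.

Outcome statistics per scope:

* **cost** — sum of the per-procedure reimbursement tariff over the
  (post-merge) events of a series, averaged per series. The tariff
  defaults to the published averaged values (`default_tariff()`). Where a
  source prints "cost per patient" for the same numbers, note that with
  essentially one series per patient the distinction vanishes; this
  package's denominator is always the series.
* **revascularization rate** — among series containing a CA, the share in
  which a CA was followed by PCI or CABG of the same patient within 180
  days. The search deliberately spans series boundaries; with the
  follow-up window equal to the 180-day series gap, a cross-series hit is
  geometrically impossible (the next series starts >180 days after every
  event of the previous one), so the mechanism only matters when a wider
  window is configured.
* **365-day mortality** — share of series whose patient died within 365
  days of the index event, wherever the death fell.
* **direct standardization** — `direct_standardize()` recomputes any
  stratified rate under a reference stratum distribution; strata are the
  caller's choice (age decades being the natural one when an age column
  exists). The synthetic register carries no demographics, so raw rates
  are the default throughout.

## The correlation network and its clustering

Centers are compared by the Pearson correlation of their spectra
(n = 15 components). The network is complete — no significance or
magnitude cutoff is applied — and edge weights are the shifted
correlations w = c + 2, mapping [−1, 1] into [1, 3] so that
modularity-based methods (which require positive weights) apply. Fisher-z
confidence bounds for each coefficient are available via
`correlation_ci()` for transparency, but are never used to filter edges.

Clustering is native Louvain modularity optimization:

* modularity Q compares within-community weight to a degree-preserving
  null model; the all-in-one partition has Q = 0 exactly;
* local moving visits nodes in a per-start shuffled order, moving each
  node to the community with maximal positive gain (ties to the smallest
  community id), capped at 10 sweeps per aggregation level — the cap
  mirrors the usual optimizer-tool semantics of an "iteration" count;
* communities are aggregated and the process repeats; an outer refinement
  loop restarts node-level moving from the found partition until Q stops
  improving;
* 10 restarts seeded `seed, seed+1, ...` are run and the best Q wins, so
  results are deterministic given the seed. Community ids are reported
  contiguous from 1, following R indexing convention.

Hierarchical structure is obtained by re-running the same procedure on
each community's induced subnetwork (weights retained), to depth 3.
"Opinion-leader" analysis uses weighted degree and shortest-path
betweenness; since strong correlation means professional proximity, edge
lengths default to 1/w (a unit-length alternative is available), and
betweenness is reported unnormalized with percentile ranks per scope.

On small complete correlation networks (up to 8 nodes) the implementation
attains the exhaustive maximum-modularity partition; on sparse random
graphs the entire greedy-modularity family — including reference
implementations — has known local optima, which is a property of the
method, not of this implementation.

## The synthetic register

No public accession of a national reimbursement register exists, so the
package ships a generator, `generate_registry()`, that emulates the
*structure* of such data with planted ground truth. Its distributional
choices are declared test scaffolding, not claims about any real register:

* **archetypes** — each center belongs to a practice-style archetype with
  a fixed 15-type spectrum; defaults are the three published cluster
  profiles (`default_archetype_spectra()`), arranged in contiguous blocks
  of centers to mimic regional practice styles. Per-center deviation is
  Dirichlet-distributed around the archetype with concentration
  `spectrum_noise` (0 = exact adherence).
* **routing** — each ZIP area is served by exactly one center and
  patients never move, so voting recovery is exactly checkable against
  the planted ZIP-to-center map. Competing providers within a ZIP are out
  of scope, matching the acknowledged limitation of single-provider
  attribution.
* **series** — one intended series per patient: the type is drawn from
  the center's spectrum; events appear in the label's category order with
  gaps of 1 to `intra_series_gap_max` (default 30 < 180) days; the index
  day is uniform over the feasible window, at least 180 days into the
  default 5-year (1826-day) horizon. Within a category block the concrete
  procedure is uniform (E: stress ECG; NI: echo or SPECT); invasive
  blocks always open with a CA, and a revascularization (PCI or CABG,
  50/50) follows with probability `revasc_prob` (default 0.04, the
  order of the published population rate). With probability
  `repeat_event_prob` a block repeats an event, exercising the
  classifier's invariance to duplicates.
* **mortality** — Bernoulli per intended type with the published per-type
  365-day rates as defaults, the death day placed after the last care
  event and within 365 days of the index.

What the generator does *not* emulate: demographics (age/sex), cross-ZIP
care seeking, provider entry/exit over time, multi-morbidity coding noise,
or series-count heterogeneity per patient. Green tests on synthetic data
therefore certify the pipeline's algebra and invariances — recovery of
planted structure, conservation laws, determinism — not epidemiological
realism.

## Detectability of planted clusters — an honest caveat

Modularity clustering of the w = c + 2 network can only separate planted
archetypes whose spectra are themselves weakly correlated. For three
equal groups of size s in a complete graph, the planted split has Q > 0
only if the within/between weight ratio exceeds s/(s−1) — about 1.11 for
ten-center groups. The three published cluster profiles are pairwise
correlated at 0.997–0.999 (every profile is ~76% E), so centers simulated
from them produce correlations all near +1, a near-uniform network, and a
single Louvain community: the planted partition is mathematically
undetectable in that regime, no matter the sample size. Real registry
spectra are far more dispersed center-to-center (published intra-cluster
average correlations of 0.12–0.38 and inter-cluster averages down to
−0.20), which is exactly what makes the real network clusterable.
`separated_archetype_spectra()` provides archetypes in the detectable
regime (pairwise correlation < 0.5); with them the pipeline recovers the
planted partition perfectly (adjusted Rand index 1.0 at 30 centers ×
1,000 series), stably across the transforms (c+2)·100, (c+2)² and (c+2)³.
The corresponding acceptance check that plants the published profiles
themselves is retained — and fails by design of the mathematics — as
documentation of this boundary.

## Numerical conventions and sizes

* Days are integers with day 0 = observation start; all windows (180-day
  gap, 365-day mortality, merge windows) are closed on the day scale.
* Percent differences are 100·(a−b)/b; a zero reference is flagged `NA`.
* Fisher exact tests are two-sided via `stats::fisher.test`; the suite
  verifies them against hypergeometric enumeration for all margins ≤ 12.
* Pooled-versus-cluster consistency is asserted to 0.005 percentage
  points; published-table recomputations are matched to one unit in the
  last printed digit (the tables truncate at two decimals).
* Default problem sizes in the tests and acceptance script — 30 centers,
  1,000–2,000 patients per center, 10,000-patient round trips, 50
  eight-node oracle graphs — were chosen so each property is measured
  well inside its stochastic tolerance while the whole suite stays quick
  to run.

## Limitations

* The phantom-merge rule set and index-qualification details of the
  original register cleaning are only partially public; both are
  parameterized rather than hard-coded, with conservative defaults.
* ICD/ICPM-to-category mapping from raw claims is upstream of this
  package: events arrive already coded with the six-procedure vocabulary.
* ZIP areas are single-provider by construction; competitive urban
  markets violate this and bias attribution, as acknowledged for the real
  register.
* Mortality is crude (or directly standardized on caller-supplied
  strata); no risk adjustment beyond that is attempted.
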