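---
title: "Screening split-intein orthogonality and planning intein-mediated assembly"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening split-intein orthogonality and planning intein-mediated assembly}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(inteinscreen)
library(dplyr)
```

## The measurement platform

Split inteins are protein segments expressed as two fragments (an N-half
and a C-half) that associate, excise themselves, and ligate their flanking
sequences with a native peptide bond. A panel of split inteins is only
useful for multiplexed protein engineering if its members are *mutually
orthogonal*: each N-half must react with its own C-half (the cognate pair)
and with nothing else.

The screen quantified here uses a split fluorescent reporter: an intein is
inserted into (or split across) mCherry, so fluorescence is reconstituted
only by successful splicing. Each sample is a bacterial culture measured in
a plate reader, giving fluorescence and OD600 per well. The per-sample
signal is

$$\text{Fluo.}/\text{OD}_{600} =
  \frac{F_\text{well} - \bar F_\text{blank}}{A_\text{well} - \bar A_\text{blank}}
  \; - \; \overline{\left(\text{Fluo.}/\text{OD}_{600}\right)}_\text{neg.\ ctrl},$$

i.e. medium background is subtracted from both channels, fluorescence is
normalized to cell density, and the negative-control level is removed
before replicates (three biological replicates throughout) are aggregated
into mean, sd and n. Design choices worth stating:

* **Negative values are retained, not clamped.** Clamping at zero would
  bias upward the medians on which the orthogonality criterion operates.
  Downstream, ratios floor negative signals at zero instead.
* **Blank aggregation is the arithmetic mean** of the blank wells per
  plate, channel and (by default) time point. For kinetic runs with a
  single pre-read blank, `blank_correct(per_time = FALSE)` applies one
  time-averaged blank instead.
* **Low-density wells are flagged, not dropped.** OD600 below 0.01 (after
  blank correction) makes the ratio unreliable; the `low_od` flag leaves
  the decision with the analyst.

## The two-threshold orthogonality criterion

For a panel of $k$ split pairs, all $k^2$ N$\times$C combinations are
measured (576 for the 24-pair in vivo panel, 144 for the 12-pair in vitro
panel). For pair $p$ the non-cognate values are its row and column cells
excluding the diagonal — $2(k-1)$ values, 46 for $k = 24$ — each divided by
$p$'s cognate signal. Pair $p$ is *orthogonal* when

$$\max_i r_i < 0.2 \quad\text{and}\quad \operatorname{median}_i r_i < 0.05,$$

with both inequalities strict ("below"). The criterion is scale-free:
multiplying the whole matrix by a constant changes nothing. Two collection
policies are implemented, because split variants of the *same* parent
intein share sequence and are expected to cross-react: `"all"` (every
non-cognate cell counts, reproducing the 46) and `"exclude_same_intein"`
(same-parent cells are exempt). The default is `"all"`; neither policy is
asserted to be the only defensible one, and both are exported.

### Why pruning is blame-based

`prune_mutually_orthogonal()` removes pairs one at a time, re-applying the
criterion inside the reduced matrix after each removal, until everything
remaining is mutually orthogonal. The obvious removal rule — drop the pair
with the worst `max_rel` — fails in exactly the situation the screen is
designed to catch: one promiscuous pair contaminates the row and column of
*every other pair*, so nearly all pairs share essentially the same
`max_rel`, and replicate noise in the cognate denominators decides the
order. The victims then get removed before the offender and the panel
collapses. The implemented rule therefore assigns *blame*: each relative
value breaching the max threshold implicates both pairs that generated it,
and the pair implicated most often is removed first (ties broken by
`median_rel`, then `max_rel`, then pair id — fully deterministic). A pair
failing only the median rule blames itself. Note the most-blamed pair may
itself classify orthogonal (a strong binder with a large cognate
denominator); it is still the right removal.

Re-evaluation at each step matters for a second reason: the criterion is
**not monotone under matrix restriction**. The max can only drop when
pairs are removed, but the *median* of the surviving values can rise —
removing a member whose cells sat below a pair's median pushes that median
up, possibly past 0.05. So orthogonality within a subset must always be
judged within that subset. This is also why the exact subset search below
can prune branches only on the max rule.

After pruning, a parent intein surviving with several split variants is
represented by the variant with the highest cognate signal (the natural
choice: it is the variant with the most dynamic range); both the pair-level
and intein-level sets are reported.

### Exact maximum orthogonal subsets

`max_orthogonal_subset(mode = "exact")` finds the provably largest subset
in which every member classifies orthogonal. It is a branch-and-bound over
include/exclude decisions whose result equals exhaustive enumeration over
all $2^k$ subsets: branches are cut only when (a) the optimistic size bound
cannot beat the incumbent, or (b) two included pairs already violate the
max rule against each other — a condition that is monotone (adding members
never removes values), unlike the median rule, which is checked only on
complete candidate subsets. Exact mode accepts up to $k = 25$; greedy mode
returns the pruning result and is never larger than the exact answer.

## Splicing efficiency from band intensities

Western blots are probed with two antibodies (anti-mCherry-N and anti-His
against the C-terminal tag) on two membranes, giving $n = 4$ band-signal
quantifications per sample. Efficiency per quantification is defined as

$$e = \frac{I_\text{spliced}}{\sum_{s \in \text{visible}(c)} I_s},$$

the spliced band over the summed intensity of all species visible to that
channel's antibody; the estimate is the mean (and sd) over the four
quantifications. The denominator definition is an explicit assumption of
this package: the source screens never print a formula, and this is the
simplest definition consistent with dual-antibody averaging. The default
epitope map includes cleavage by-products in the denominator
(`default_epitope_map()`); a precursor-plus-spliced-only map is a one-line
alternative. Zero total signal in *any* quantification reports the
efficiency as absent ("not detected") rather than extrapolating from the
remaining channels. The estimator is invariant to per-quantification
exposure rescaling, which is what makes cross-membrane averaging
meaningful.

## Activity calls and kinetic classes

All activity calls are strict threshold decisions, read as "above":

* **cis, in vivo**: normalized fluorescence > 2000 a.u.
* **in vitro**: end-point fluorescence > 4000 a.u. *and* spliced product
  > 10% of the cohort maximum (the most efficient pair defines 100%). The
  end-point, not a fitted plateau, is used — the screen classifies
  measured curves.
* **fast kinetics**: the signal at 1 h (linear interpolation between
  samples) exceeds 75% of the plateau, with plateau taken as the observed
  series maximum. The class is invariant to rescaling the series.

`fit_first_order()` fits $A\,(1 - e^{-k\,(t-d)_+})$ by Levenberg–Marquardt
least squares, where the onset delay $d$ absorbs the lag between splicing
and fluorophore maturation. Starting values come from the observed
maximum, the first crossing of 5% of it (delay) and the half-rise time
(rate); constant series are rejected as unidentifiable rather than
returned with a meaningless rate.

## Choosing one common reaction condition

The condition screen covers pH {8, 9} × NaCl {100, 300, 500 mM} ×
temperature {4, 21, 30, 37, 42 °C} per intein. The screen's goal is a
*single* condition under which any intein combination works, so the
default aggregate is max–min: each intein's signals are rescaled to its
own maximum (removing per-intein magnitude), each condition is scored by
its worst-performing intein, and the best worst case wins. No selection
statistic is claimed to be the original study's — the rule is attached to
the result (`median` and `mean` aggregates are available), and ties break
by median score then lexicographically. DTT is treated as a fixed protocol
constant, not a screened axis.

## Assembly planning and the incomplete-splicing ladder

Two schemes assemble $n$ repetitive units (default composition: the
SasG5³E² block, 3 G5 + 2 E domains per unit):

* **One pot** splices everything simultaneously: $n-1$ *distinct*
  orthogonal inteins, $n$ unit designs, terminal units tagged H6 and
  Strep for tandem purification.
* **Recursive solid phase** grows a resin-bound chain with two alternating
  inteins: at most 4 unit designs for any $n \ge 4$, and $n-1$
  wash-and-incubate cycles.

`product_composition()` sums domains ($n$ uniform units give
SasG5$^{3n}$E$^{2n}$) and, given sequences, the average-isotopic mass of
the spliced chain in kDa (residue masses + one water; inteins excise and
are excluded). Average rather than monoisotopic masses match gel-scale
reporting; the anomalous gel migration of SasG-like proteins is explicitly
not modelled. `check_junction_compatibility()` compares the realized
−3..+3 junction residues against each intein's preference by exact match —
junction sequence strongly affects splicing efficiency, but scoring
partial matches would imply a model nobody has calibrated.

`simulate_yield()` predicts the by-product ladder from per-junction
splicing probabilities:

* **Solid phase**: a failed cycle leaves the resin-bound chain permanently
  truncated (the simplest reading of a ladder that persists across
  cycles — later cycles could in principle rescue a stalled chain through
  the same missing junction, but that is not modelled). Full-length
  abundance is $\prod_j p_j$ ($p^{n-1}$ for a common $p$); a species of
  $m < n$ units has abundance $(\prod_{j<m} p_j)(1-p_m)$.
* **One pot**: the $n-1$ junctions succeed independently; all $2^{n-1}$
  outcomes are enumerated exactly (feasible to $n = 20$) and each outcome
  is represented by its principal product, the largest contiguous block of
  spliced units. Ladder masses for truncated one-pot species use the first
  $m$ units, which is exact for uniform units.

Both modes return proper distributions (abundances sum to 1); a seeded
stochastic mode estimates the same distributions by simulation and agrees
with the exact mode within Monte-Carlo error, which the test suite asserts
at three standard errors.

## Logic circuits

An intein-split transcription factor is a two-input AND gate: each input
drives one chimeric half, and only splicing reconstitutes the factor.
`truth_table()` enumerates all $2^{|inputs|}$ states in binary order with
each reporter reading the OR over its gates. `circuit_three_input()` wires
the canonical three-input, three-output design (blue ← rha ∧ AHL, green ←
ara ∧ rha, red ← ara ∧ AHL): every two-input state lights exactly one
reporter, the all-on state lights all three, and 4 of the 8 states produce
output. The model is purely Boolean — leakiness, dynamic range and
promoter strength are not modelled, because no quantitative model is
available to calibrate them.

## What the synthetic data emulate — and what they do not

`sim_config()` fixes the generative truth: cognate signal 20,000 a.u./OD
with 10% replicate CV (lognormal, since plate and blot signals are
positive with roughly constant CV), OD600 0.5 ± 5% (Gaussian), blank 100
a.u., negative-control background 200 a.u./OD, three replicates,
non-cognate relative levels drawn from an exponential with mean 0.01 (so
matrices are sparse-cross-talking, with optional planted violators),
first-order kinetics with a 20 min maturation delay at 1.4 h⁻¹, and band
tables at 5% multiplicative noise. These defaults are realistic for the
platform being emulated and are not tuned per analysis.

The generators reproduce the *statistical structure* the pipeline assumes:
replicate noise, blank and control offsets, density variation,
cross-talk sparsity, onset-delayed kinetics. They do not emulate plate
position effects, growth differences between constructs, expression or
solubility failures of individual chimeras, antibody cross-reactivity, or
saturation of either detector. Passing recovery tests therefore shows the
analysis chain is correct and unbiased under its own assumptions — not
that those assumptions hold for any particular instrument.

Determinism: every generator is seeded through `withr::with_seed()`, so an
identical configuration yields an identical dataset, byte for byte.

## Problem sizes and numerical choices

The test suite and the acceptance script run at the scales the analyses
are designed for: full 24-pair (576-combination) panels through the
plate-level pipeline, 200 seeded 24-pair matrices for classification
accuracy, 1000-draw densitometry recovery, exact-vs-enumeration subset
checks on 8-pair panels (50 instances), and exact ladder enumeration to 10
units. Exact subset search is capped at $k = 25$ and exact one-pot
enumeration at $n = 20$; beyond that, greedy pruning and the stochastic
ladder mode are the intended tools. Medians of even-length value sets are
the mean of the two central values. All tie-breaks (pruning order,
branch-and-bound, condition ranking) are lexicographic and deterministic.

## Known limitations

* The efficiency denominator and the solid-phase truncation model are
  explicit assumptions, stated above, not measured facts.
* The orthogonality criterion operates on replicate means; a
  per-replicate uncertainty propagation is available through the
  `replicates` column of `cross_matrix()` cells but is not part of the
  default calls.
* The one-pot ladder identifies species by size of the largest assembled
  block, which ignores which block carries the purification tags;
  tag-aware purification yields would need a block-identity model.
* Boolean circuit evaluation cannot reproduce graded leakiness or the
  background reduction seen with particular split transcription factors.
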