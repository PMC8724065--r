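---
title: "ONEST: models, defaults and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ONEST: models, defaults and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(onest)
```

## The problem

Many diagnostic tests in pathology reduce to a subjective quantitative
estimate — the fraction of tumour-cell nuclei staining for ER, PR or Ki67
under the microscope — that is then binned into a small number of
categories with therapeutic consequences. Agreement between observers is
conventionally summarized by a kappa statistic or an intraclass
correlation, both computed from whichever panel of observers happened to be
available. ONEST (Observers Needed to Evaluate Subjective Tests) asks a
complementary question: *how does the agreement estimate itself depend on
how many observers you used, and how many would have been enough?*

## OPA, OPA curves and the ONEST plot

For a set $S$ of observers rating $n$ cases, the **overall percent
agreement** is

$$\mathrm{OPA}(S) = \frac{\#\{\text{cases on which all observers in } S
\text{ agree}\}}{n} \in [0, 1].$$

Fix an ordering $\pi$ of all $N$ observers and plot
$\mathrm{OPA}(\{\pi_1,\dots,\pi_k\})$ against $k = 2,\dots,N$: this is an
**OPA curve** (OPAC). Adding an observer can only shrink the set of fully
agreed cases, so every OPAC is non-increasing, and all OPACs terminate at
the same point, the OPA of the full panel. The ONEST plot overlays the
OPACs of many random orderings (100 by default, drawn uniformly *without
replacement* from the $N!$ possibilities — duplicated orderings add no
information to envelopes). Three summaries characterize a categorization:

* **bandwidth** — the gap between the best and worst two-observer OPA.
  `onest()` computes this exactly over all $\binom{N}{2}$ pairs by default
  (the pair count is small and the quantity concerns the extremes, which a
  100-ordering sample may miss); `bandwidth = "sampled"` gives the
  envelope-based variant.
* **plateau** — the observer count at which the curve stops materially
  decreasing. No closed-form rule exists in the ONEST literature, so the
  package uses an explicit terminal-gap rule: the smallest $k$ with
  $\mathrm{curve}(k) - \mathrm{curve}(N) \le \varepsilon$, with
  $\varepsilon = 0.02$ (one case in fifty) on the *mean* envelope by
  default. Both $\varepsilon$ and the target envelope (`mean` or `min`)
  are arguments, because a visual reading of a plateau is inherently a
  judgement call.
* **OPA for all observers** — the common terminal value, also available
  per category through `category_consensus_counts()`.

### Envelopes, exhaustively

The pointwise min/max/mean over *all* $N!$ orderings is computable at
panel scale: the OPA of a length-$k$ prefix depends only on the prefix
*set*, every size-$k$ subset is some ordering's prefix, and each size-$k$
subset prefixes equally many orderings. So `exhaustive_envelope()`
enumerates $\sum_k \binom{N}{k}$ subsets — 501 OPA evaluations for
$N = 9$ instead of 362,880 curves — and is oracle-tested against literal
brute force over all orderings for $N \le 5$. A guard (default
$N \le 12$) keeps the subset count bounded.

One subtlety the package makes explicit rather than assuming: the
pointwise minimum envelope over all orderings need *not* be attained by
any single ordering (the worst pair may not extend to the worst triple).
`onest()` therefore reports `min_realized`; the test suite carries a
concrete 11-case, 5-observer counterexample.

## Agreement statistics

**ICC(2,1)** — two-way random effects, absolute agreement, single rater —
is computed from the ANOVA mean squares of the cases-by-raters grid:

$$\mathrm{ICC} = \frac{MS_R - MS_E}{MS_R + (k-1)MS_E + \frac{k}{n}(MS_C - MS_E)}$$

with the standard F-based 95% confidence interval
(Satterthwaite-approximated denominator degrees of freedom). It is
implemented from the sums of squares directly and verified in the tests
against `stats::aov` mean squares, an independent sums-of-squares oracle,
and a reference value from an external implementation. Categorical
matrices are accepted by encoding the ordered labels as consecutive
integers $0, 1, 2, \dots$ in label-set order; ICC on the raw percentages
is equally available by passing the percent matrix. Reliability grading
follows the usual bands (poor $\le 0.5$ < moderate $\le 0.75$ < good
$\le 0.9$ < excellent) applied to the point estimate, with a straddling
label ("good to excellent") when the two CI bounds fall into different
bands. The degenerate grids behave deliberately: identical raters on
non-constant cases give exactly 1; a constant grid has no between-case
variance, so the ICC is undefined and the function errors rather than
returning 0/0.

**Kruskal–Wallis** comparisons of minimum OPA curves treat the $k = 2..N$
curve values of each panel as observations (mid-ranks, standard tie
correction, $\chi^2$ approximation via `stats::kruskal.test`). Two caveats
are part of the method's honest description rather than bugs: the points
of one curve are statistically dependent (each is a refinement of the
previous prefix), so the p value is a descriptive comparison of curve
levels; and when every value is identical the statistic is defined as
$H = 0$, $p = 1$ (no rank variation, no evidence), where the raw
tie-correction divisor would be 0/0.

`compare_sampled_vs_exhaustive()` packages the internal sanity check that
100 random orderings already pin down the worst-case curve: on synthetic
50-case, 9-observer panels its p values sit well above 0.05 (typically
0.6–1), which is what licenses using a 100-ordering sample in practice.

## Categorization schemes

Percentage cut-offs are represented as explicit bins partitioning
$[0, 100]$ with stated boundary inclusivity, validated at construction
(no gaps, no overlaps, unique labels):

* ER/PR/Ki67 three-tier: negative $< 1$, low positive $[1, 10]$,
  positive $> 10$. "1–10%" is read as including both endpoints, so
  negative is strictly below 1 and positive strictly above 10.
* St Gallen Ki67 tiers: 2009 low $\le 15$ / intermediate $(15, 30]$ /
  high $> 30$; 2011 low $\le 13$; 2013 low $\le 20$; 2015 relative to the
  median labelling $m$ of ER+ cases (default parameter 15%): low
  $\le m - 10$, high $\ge m + 10$, intermediate strictly between. With
  5%-rounded inputs only the $m \pm 10$ boundaries can ever be hit.
* Allred quick score: intensity subscore (validated as an integer 0–3;
  non-integer "average intensity" inputs are rejected rather than
  silently rounded) plus the standard proportion subscore bins
  (0; $(0,1)$; $[1,10]$; $(10,33]$; $(33,66]$; $(66,100]$ — lower
  boundaries aligned with the 1%/10% reporting convention), grouped for
  reporting as 0,2 / 3–4 / 5–6 / 7–8. A quick score of 1 is impossible
  and rejected.

Score-valued "schemes" (intensity 0–3, Allred groups) are dedicated
converters (`intensity_ratings()`, `allred_ratings()`) rather than
percentage bins; the CLI dispatches on the scheme name.

Missing cells are a hard error by default — OPA is undefined for a
partially rated case — with explicit listwise deletion
(`drop_incomplete = TRUE`) that warns with the dropped count.

## The synthetic rater-panel generator

Real multi-rater datasets of this kind are rarely deposited, so the
package ships a generator with the structure such data exhibit, making
every other module testable end to end.

**Case mix.** A latent true staining percentage per case is drawn from a
named `marker_profile`: a mixture of logit-normal components on the 0–100
scale plus an atom of truly negative (0%) cases; a zero-spread component
is a point mass, used for the 100% extreme. The six built-in profiles
(ER/PR/Ki67 × biopsy/excision) were calibrated by Monte Carlo — once, at
$2\times10^5$ draws — to the marker-typical median (IQR) pairs reported
for multi-rater breast panels: ER 95 (30) / 95 (15), PR 60 (89) / 73
(95), Ki67 20 (85) / 10 (20). Nothing beyond that level is fitted; the
profiles live in a versioned YAML file
(`inst/extdata/marker_profiles.yaml`).

**Observers.** A reading is
$\mathrm{logit}^{-1}(\mathrm{logit}(p) + b_j + e_{ij})$, rounded to the
reporting grid and clamped. Noise on the logit scale makes reading spread
shrink near 0% and 100%, matching the empirical ease of scoring the
extremes. Defaults: per-read noise SD 0.5 and per-observer bias SD 0.15
on the logit scale — order-of-magnitude choices (no published
per-observer bias magnitudes exist to calibrate against), marked as such
in the config; reporting grid 5% for Ki67 (eyeballing convention), 1%
otherwise. Exact 0% and 100% cases are fixed points — a truly negative
case is read negative — unless an explicit `extreme_leak` probability is
set, in which case a leaked read is re-scored as a borderline 1%/99% case
plus noise.

**What the generator does and does not show.** Zero-noise panels recover
OPA ≡ 1, bandwidth 0 and plateau at $k = 2$ for every scheme; mean
agreement decreases monotonically in the noise scale; and an ER-like
extreme-heavy case mix yields systematically higher full-panel OPA than a
Ki67-like mid-range mix under the same cut-offs and noise — the
distribution of values near vs away from the 0%/100% extremes, not the
cut-off labels themselves, drives reproducibility. Passing these tests
shows the machinery is correct and the qualitative mechanisms are
reproduced; it does not certify quantitative agreement levels for any
real panel, which depend on case selection, staining quality and observer
training that the generator does not model (nor does it model correlated
errors between observers, case-difficulty heterogeneity beyond the latent
value, or intensity/percentage correlation).

## Numerical and design notes

* Permutation sampling: for $N! \le 8!$ the orderings are enumerated
  lexicographically and subsampled; for larger $N$, rejection sampling
  with explicit de-duplication (collisions are negligible at
  $100/362{,}880$ but are removed regardless). Requesting
  `n_perm >= N!` returns all orderings in deterministic order, making the
  result seed-independent.
* All randomness flows from a single integer seed, stored in the result;
  runs are reproducible from (input, configuration, seed), and a
  fixed-seed panel exports byte-identical CSV.
* Problem sizes in the test suite — matrices up to 15 cases and 6
  observers for oracle equivalence, 20 seeds per condition for
  Monte-Carlo trends, ten 50 × 9 panels for the sampled-vs-exhaustive
  comparison — were chosen so the full suite exercises every property at
  panel-realistic scale while remaining quick to run routinely.
* Limitations: no confidence bands on OPA curves (OPA is all-or-nothing;
  inference on dependent curve points would be misleading), no weighted
  or partial agreement, no kappa statistics, and no attempt to
  reconstruct any particular study's rating data.
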