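---
title: "Band width selection and optimality certification for long-read alignment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Band width selection and optimality certification for long-read alignment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(banddp)
```

## The model

Two long reads drawn from the same molecule differ by per-base sequencing
errors described by an error profile $(p_u, p_m, p_i, p_d)$: each base is
left unchanged with probability $p_u$, substituted with $p_m$, followed by
an inserted base with $p_i$, or deleted with $p_d$.  In the alignment
lattice of such a pair (rows $i = 0..l_2$ for the shorter read, columns
$j = 0..l_1$ for the longer), every insertion or deletion moves the
optimal path one cell off the diagonal.  The diagonal offset therefore
performs a one-dimensional random walk.  For a walk of $N$ steps that
moves right with probability $p_r$, left with $p_l$ and stays put
otherwise, the multinomial moments give

$$\mathrm{Var}(d) = N p_r (1 - p_r) + N p_l (1 - p_l) + 2 N p_r p_l,$$

which reduces, for the symmetric case $p_r = p_l = p$, to
$\mathrm{Var}(d) = 2Np$ (implemented as `walk_displacement_variance()`
and cross-checked in the tests against direct multinomial sampling).
The per-column step probability is taken to be

$$p = 2\,(p_d + p_i - p_d^2 - p_i^2),$$

counting indels accumulated by *both* reads of the pair and removing
exact same-position cancellations.  Higher-order cancellations — an
insertion in one read absorbed by a nearby deletion in the other, which
the scoring scheme prefers to render as a mismatch — are deliberately not
modelled: they are hard to enumerate, and dropping them only makes
$\sigma_d = \sqrt{2Np}$ a slight overestimate, i.e. a conservative band.
The simulation harness `run_table1()` quantifies exactly this effect: the
measured spread of the path deviation sits a few percent *below*
$\sigma_d$ at every length and error rate we test.

A band of half-width $w = 3\sigma_d$ then contains the path with
probability $2\Phi(3) - 1 > 99.7\%$, so fewer than $0.3\%$ of alignments
need a restart, and the aligner runs in $O(\sigma_d N) = O(N^{3/2})$
time and memory.

## Measuring the deviation

The quantity the walk models is exposed as `path_deviation_stat()`: over
the traceback nodes $(i_k, j_k)$ it returns the signed offset
$s_k = i_k - j_k$ at the index maximising $|s_k|$ (the earliest on ties).
Alternatives exist — the net end-to-end displacement, or the longest
single gap run — but the maximal signed excursion is the quantity that
decides whether a band of half-width $w$ was wide enough, which is what
the band model is for.  Its spread is close to, and dominated by the
same scaling as, $\sqrt{2Np}$; the simulations below confirm the match.
By symmetry its mean is zero, and swapping the two reads negates it.

## Band geometries

Two band shapes are supported by `dp_band()`:

* the **corridor** band (`extend = TRUE`, the default):
  $-w-(l_1-l_2) \le i-j \le +w$.  It always reaches the corner cell
  $(l_2, l_1)$, which global alignments need, and it is the geometry the
  `best_out` bound is written for.
* the **symmetric** band (`extend = FALSE`): $|i-j| \le w$.

The difference matters for semi-global alignment of reads whose lengths
differ by a random indel surplus.  The corridor band widens itself by
$l_1 - l_2$, thereby absorbing most of the drift the random walk
predicts; in our simulations at $w = \lceil\sigma_d\rceil$ it leaves
under 1% of paths constrained.  The symmetric band is the shape under
which restart rates follow the walk model directly
($\approx 32\%$ at $w = \sigma_d$, $\approx 0.3\%$ at $3\sigma_d$), and
it is the geometry `run_table2()` uses so that its two-way
classification reflects the model's design point.  The adaptive aligner
`align_adaptive()` keeps the corridor band: absorbing the length
difference is a feature there (fewer restarts for free), not a bug.

## Certification

A banded score equals the full-matrix optimum whenever the unconstrained
optimal path stays in the band; the package decides this without filling
the full matrix.

**Global mode.**  Any global path leaving the band must cross it, which
costs at least $w+1$ gaps on each side plus the structural
$-(l_1-l_2)$; assuming every other column matches gives the bound
$best_{out} = [2(w+1)-(l_1-l_2)]\,g + [l_2-(w+1)]\,m$.  If the banded
score reaches $best_{out}$, nothing outside the band can beat it
(`certify_global()`).  The bound is generous — it ignores mismatches —
so certification is conservative, never wrong.

**Semi-global mode.**  The ends of an overlap path are free, so no such
bound exists.  Two empirical criteria are applied in order
(`certify_semiglobal()`): (i) reject if the traceback path touches a
band boundary offset — touching is cheap to detect during traceback and
strongly correlated with constraint; (ii) reject if the number of
matches falls below $N p_u - 3\sqrt{N p_u (1-p_u)}$, the lower half of
the binomial 99% confidence interval.  $N p_u$ slightly overestimates
the expected match count (a substituted base can still match by chance,
but a deleted one cannot), which again errs on the side of rejection.
Criterion (ii) uses the *match count*, not the weighted score: the
binomial model is a statement about the number of identical aligned
pairs, and the match count is invariant to the scoring scheme.

Neither criterion is foolproof: a path can ride the band edge and still
be optimal (a wasted restart), or stay inside the band yet be suboptimal
(a silent error).  `run_table2()` measures both failure modes; at
$w = \sigma_d$ on error-rate set 3 the silent-error cell is a few tenths
of a percent before criterion (ii) and drops further after it, while
wasted restarts stay in the low percent range.

## The staged schedule

`band_schedule()` yields $\lceil\sigma\rceil, \lceil 2\sigma\rceil,
\lceil 3\sigma\rceil$, then doubles until the band covers the matrix
(every value capped at $l_2$).  Ceilings keep the exit probability at or
below the nominal level.  With the normal-model stage fractions
(68% of paths fit in $\sigma$, a further 28% in $2\sigma$, 4% in
$3\sigma$) the expected cost coefficient is

```{r}
expected_cost_coefficient(c(0.68, 0.28, 0.04))
```

times $\sigma_d N$, versus 6 for a single $3\sigma_d$ pass — the
rationale for starting narrow.  The final schedule stage always covers
the whole matrix, so `align_adaptive()` degrades gracefully to the exact
full-matrix result on adversarial input (certification may still
report rejection there; the score is nonetheless exact by construction).

## The simulator

`make_pair()` draws a uniform random ancestor of length $N$ and mutates
it per base: substitutions draw a uniformly different base, insertions
append one uniform base after the kept base, deletions emit nothing.
Both reads are mutated independently by default (`both_mutated`) — that
is the situation the factor 2 in $p$ accounts for — with `one_mutated`
available for protocols where one sequence is a reference.  Every event
is logged with its ancestor position, and replaying a log reproduces the
read exactly, which the tests use as a determinism oracle.

What the simulator does *not* emulate: homopolymer-biased indels,
quality values, read-length distributions, chimeras, or any base
composition structure.  Passing simulations therefore validate the band
model's arithmetic and the certification logic under the model's own
assumptions — per-base independent errors — not aligner performance on
real instrument data, whose clustered indels can widen the deviation
distribution beyond $\sqrt{2Np}$.

## Numerical and design choices

* Scores are integers; the default scheme is match $+3$, mismatch $-1$,
  gap $-2$, linear (no affine opening).  Only A/C/G/T can match — any
  other letter mismatches even against itself.
* Traceback ties prefer match/mismatch, then a gap in the vertical
  sequence, then the horizontal one; when a pair is internally
  transposed (the aligner keeps $l_1 \ge l_2$), preferences and the
  semi-global end-cell scan are mirrored so results are identical in the
  caller's coordinates.  Output is fully deterministic.
* Out-of-band cells use a sentinel far below any reachable score, and
  boundary cells only consult in-band predecessors; banded storage is
  $(w_{hi} + w_{lo} + 1)(l_2 + 1)$ cells.
* $N$ in $\sigma_d$ and in the match-count bound is the longer read
  length; reads of a pair are near-equal by construction and the model
  does not distinguish them.
* In `run_table2()` the half-width is floored at 1: a zero-width band is
  the diagonal itself, where every path cell trivially sits on the
  boundary and criterion (i) would reject everything.
* Per-pair RNG streams are derived from the master seed (one sub-seed
  per pair), so experiment cells are reproducible independently of each
  other.

## Study sizes

The validation harnesses default to the benchmark dimensions (read
lengths 2000–6000, 1000 pairs per cell, pooled lengths in the two-way
table), but every dimension is an argument.  The shipped test-suite runs
use 30–200 pairs at lengths 100–2000, and the acceptance script uses 500
pairs of length 2000 — sizes chosen so the whole suite completes in a
few minutes while keeping binomial standard errors on reported
percentages near one point.  Reports carry those standard errors
(`se_mean`, `se_sigma`) so scaled-down runs state their uncertainty.

## Known limitations

* Linear gap penalties only; no affine gaps, no local (Smith–Waterman)
  mode, no linear-space traceback.
* The error profile is an input, not estimated from data.
* The semi-global certification is statistical: at $w = \sigma_d$ a
  fraction of a percent of accepted alignments remain silently
  suboptimal (measured by `run_table2()`), shrinking but not vanishing
  under criterion (ii).  Users needing certainty should widen to
  $3\sigma_d$ or verify with a full-matrix pass.
* Band placement is centred on the main diagonal (or corridor); there is
  no support for an a-priori known diagonal offset.
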