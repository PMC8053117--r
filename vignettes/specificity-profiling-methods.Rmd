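---
title: "Methods: in vitro Cas9 specificity profiling from doped libraries"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: in vitro Cas9 specificity profiling from doped libraries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cas9profiler)
```

This vignette documents the models, conventions and numerical choices
behind `cas9profiler` at the level of detail a user needs to interpret its
outputs or audit its assumptions.

## The assay and its observables

A doped plasmid library carries a 20-nt target region in which every
position holds the reference base with probability $1-f$ and each of the
three alternatives with probability $f/3$. Incubation with a Cas9 RNP
converts supercoiled plasmid (SC) to nicked (one strand cut) and then
linear (double-strand break) forms, which separate on an agarose gel. Two
measurement channels result:

* **Gel densitometry** — band intensities $I_{SC}, I_N, I_L$ per time
  point, giving pool mass fractions and, via one-phase association fits,
  apparent cleavage rates.
* **Amplicon sequencing** of the SC and nicked pools. The linear pool
  cannot be amplified across the break, so sequences absent from both
  sequenced pools are interpreted as linearized. No per-sequence imputation
  is performed for them; their mass is accounted for through the
  gel-derived pool fractions.

Position numbering is PAM-proximal throughout: position 1 is the base next
to the PAM, position 20 is PAM-distal. The seed is positions
1..`seed_len` (default 10, the PAM-proximal block where mismatches are most
disruptive). Mismatches are labelled `rX:dY`, the crRNA base (T written as
U) against the DNA target-strand base it faces — the complement of the base
read from the non-target strand — so a reference G read as A is the
well-tolerated rG:dT wobble pair.

## Library design model

The number of mismatches per molecule under independent per-position doping
is binomial, $P(n) = \binom{L}{n} f^n (1-f)^{L-n}$, and the number of
distinct $n$-mismatch sequences is $3^n\binom{L}{n}$ regardless of $f$.
At the default $f = 0.15$ and $L = 20$ the mode lies at 2–4 mismatches:

```{r}
expected_mismatch_distribution(L = 20, f = 0.15, n_max = 5)
```

Both closed forms are verified in the test suite against exhaustive
enumeration of all $4^L$ sequences for $L \le 8$. The distribution helper
defaults to `n_max = 10` because higher strata are negligibly represented
at practical doping levels; the suppressed tail mass is attached as an
attribute so the tabulation still accounts for 1. Downstream abundance
courses always extend the tabulation to the highest stratum actually
observed, so the fraction identity $\sum_n F_n = 1$ holds exactly on data.

## Kinetic model of the simulator

Each library member evolves by irreversible sequential first-order steps
$SC \xrightarrow{k_1} N \xrightarrow{k_2} L$ — the minimal scheme able to
generate the observed decline of supercoiled DNA with transient nicked
accumulation. Closed forms are used:
$SC(t) = SC_0 e^{-k_1 t}$ and
$N(t) = N_0 e^{-k_2 t} + SC_0\,k_1 t\,e^{-k_1 t}\,\varphi((k_2-k_1)t)$
with $\varphi(x) = (1-e^{-x})/x$ evaluated by `expm1` and by its quadratic
Taylor expansion for $|x| < 10^{-8}$, so the $k_1 = k_2$ limit is exact and
the formula is stable near it (the suite checks agreement with numerical
ODE integration to $10^{-8}$ absolute, including $k_1 \approx k_2$).

A **variant profile** maps a member's mismatches to its rates:
$k_1 = k_{nick}\prod_{p \in \text{mm}} \pi_p$ with per-position penalty
multipliers $\pi_p \in (0,1]$, and
$k_2 = k_{lin}\,\delta^{\,n_{distal}}$ where $\delta$ is the second-strand
penalty per PAM-distal mismatch. Two presets encode the qualitative
contrast the assay is designed to resolve, with parameters chosen once,
analytically, before any simulation was scored:

| parameter (units) | WT-like | HF-like | rationale |
|---|---|---|---|
| $k_{nick}$ (min⁻¹) | 2 | 1.5 | perfect-target cleavage on the sub-minute scale; HF marginally slower |
| $k_{lin}$ (min⁻¹) | 1.8 | 1.5 | second strand follows quickly on-target |
| seed penalty $\pi_{1..10}$ | 0.25 | 0.15 | seed mismatches strongly reduce nicking; more so for HF |
| distal penalty $\pi_{11..20}$ | 0.6 | 0.35 | distal mismatches mildly reduce nicking |
| $\delta$ per distal mismatch | 0.7 | 0.2 | the HF hallmark: distal mismatches stall second-strand cleavage |

With multiplicative compounding these values put two-seed-mismatch targets
near $k_1 \approx 0.1$ min⁻¹ (WT), i.e. mostly cleaved by 180 min but
barely touched at 1 min — which is what makes the specificity score of the
HF-like enzyme exceed the WT-like one early and converge toward parity by
180 min, and what concentrates nicked-pool accumulation at PAM-distal
cells for the HF-like profile. The profiles are a caricature that encodes
direction and ordering of effects, not fitted constants; any figure-level
number derived from them is a property of the simulation, not a
measurement.

Simulated study conditions (the generator defaults): library time points
$\{0, 1, 5, 30, 60, 180\}$ min with $t=0$ the untreated control; perfect
target courses are typically run on a seconds grid and converted to
minutes on input; 100,000 reads per sampled pool; a 5% uniform
prep-derived nicked background at $t=0$ sharing the library's composition
(configurable, since aberrant nicking could in principle be biased);
multinomial read sampling from weight × pool-fraction; single-end 75-nt
reads (25-nt upstream flank + 20-nt target + 30-nt downstream flank) with
constant Phred 40 qualities — paired ends add no information for a fixed
flank layout. The simulator does **not** model indels, PCR amplification
bias, quality-dependent errors, or context-dependent doping bias; passing
tests therefore demonstrate correctness of the analysis arithmetic and
sensitivity to kinetic structure, not robustness to those artefacts of
real libraries.

## Extraction

The 20-nt region is located between exact flank matches (the default;
`max_flank_mm` enables mismatch-tolerant anchoring through a slower
matching path). Regions whose length differs from 20 indicate indels and
are discarded (`bad_length`), as are reads without anchors (`no_anchor`),
reads matching in both orientations (`ambiguous`), and — only if a
minimum quality is configured — reads with low-quality bases. Discard
tallies are attached to every count table and satisfy
extracted + discarded = parsed. Extraction is deterministic and
order-independent; identical regions are collapsed with summed counts and
annotated once.

## Rate fitting

`fit_one_phase()` fits $FR(t) = FR_0 + (FR_{final}-FR_0)(1-e^{-kt})$ with
$FR_0$ pinned to the $t=0$ control and $FR_{final}$ pinned to the last
observed time point, leaving $k \ge 0$ free (`free_plateau = TRUE` frees
the plateau for sensitivity analysis). Numerical choices:

* The single-parameter residual sum of squares is numerically flat for $k$
  far above the identifiable range, which stalls derivative-free
  minimizers started on the plateau. The implementation brackets the
  minimum on a 100-point logarithmic grid over $[10^{-5}, k_{hi}]$
  (with $k_{hi} \ge 200$ min⁻¹) and then polishes with Brent's method at
  tolerance $10^{-12}$.
* `se_k` combines the classical linearized standard error with a
  delta-method term for the pinned plateau: the plateau is itself a noisy
  observation, and ignoring its variance understates the uncertainty in
  $k$. $\partial k/\partial FR_{final}$ is obtained by refitting at
  $FR_{final} \pm h$. A Monte-Carlo check in the suite shows
  $k \pm 3\,se_k$ covers the generating rate in at least 95 of 100 noisy
  series at $\sigma = 0.01$.
* A flat series ($FR_{final} = FR_0$, zero variance) is reported as
  $k = 0$ with a `degenerate` flag rather than an error.
* The estimator is exactly self-inverse only when the course has saturated
  by the last time point; on an unsaturated noiseless course the pinned
  plateau sits $e^{-k t_{last}}$ below the asymptote and $k$ inherits a
  small systematic offset. This is a property of the pinned-plateau
  convention, not of the optimizer.

Replicate rates are compared by a two-sample $t$-test, equal-variance by
default with a Welch option (the equal-variance assumption is conventional
for triplicate gel assays but not sacrosanct). Two degenerate cases the
test statistic cannot express are settled by convention: identical constant
groups give $t=0, p=1$; distinct constant groups give $t=\infty, p=0$.

## Abundance framework

Per pool and time point: $F_n$ = stratum read fraction;
$EA_n = F_n \cdot FR$ with $FR$ the gel-derived mass fraction of that pool
($\sum_n EA_n = FR$); $RA = EA_t / EA_{control}$ against the matched-pool
$t=0$ control (the nicked pool is normalized against its own $t=0$
background rather than the supercoiled composition — switchable in
principle, matched-pool is the default because prep nicking need not be
uniform); and $\log_2 RA$. Conventions for edge cases:

* Strata with zero control abundance give missing RA, never infinity; no
  pseudocounts are added by default because stratum-level zeros are rare
  at the default depth.
* $\log_2$ of an exact zero is floored at half the smallest positive RA in
  the vector (or $10^{-6}$ if none) and flagged, so heatmaps stay finite
  without inventing precision.
* The off-target aggregate over strata 1–5 is a **ratio of sums**,
  $\sum_{n=1}^{5} EA_n(t) \,/\, \sum_{n=1}^{5} EA_n(0)$. The alternative
  sum-of-ratios reading is rejected because it can exceed 1 for an
  uncleaved library and would push the off-target cleaved fraction
  negative in the null case. Strata above 5 are tabulated but excluded
  from specificity scoring, mirroring how thin the library is beyond five
  mismatches.
* Specificity scores with a zero off-target denominator are missing;
  negative cleaved fractions (enrichment beyond control) are kept and
  flagged rather than clipped. Variant-to-reference ratios propagate SEM
  to first order (relative errors in quadrature).

## Positional, bubble and spacing statistics

$RA_{S\text{-}NP}$ is computed for every (nucleotide, position, stratum,
time) cell against the $t=0$ library, including the canonical cells where
the nucleotide equals the reference base — these are flagged
`canonical = TRUE` so plots can grey them out, and they are excluded from
extent normalization. The two pools use deliberately different summaries:

* **Supercoiled** (cleavage): rate = maximum per-interval *depletion*
  slope over the full grid including $t=0$ (positive = depleted), extent =
  minimum RA across the course (`abundance_min`, small = fully cleaved).
* **Nicked** (second-strand defect): rate = mean per-interval slope over
  post-cleavage times only ($t>0$; positive = accumulating), extent =
  maximum RA (`abundance_max`, large = strongly nicked).

The opposite sign conventions (depletion-positive vs accumulation-positive)
are intentional and match the colour semantics of the two heatmap families.
Missing cells are dropped from a series before slopes are taken; a cell
with fewer than two defined values yields a missing metric. Extents are
normalized by the single global maximum across the whole comparison set
(all enzymes, libraries and strata 1–5 supplied together), so normalized
extents live in $[0,1]$, exactly one cell (up to ties) maps to 1, and
within-set ordering is preserved.

Two-mismatch spacing uses the intervening-nucleotide convention: adjacent
mismatches are distance 0 and the extreme pair (positions 1 and 20) is 18.
Raw distance-class counts are divided by the number of ways the class can
occur, $9\,(s-1-d)$ for a span of length $s$ — summed over $d$ this
reproduces the total two-mismatch count, e.g. 1710 for the whole target.
Scoped analyses (seed, PAM-distal) require both mismatches inside the span,
cap $d$ at 8, and exclude cross-region pairs; the whole-target analysis
includes them.

## Pipeline, reproducibility and problem sizes

`run_pipeline()` composes the stages from a single declarative config and
writes tidy TSVs plus optional plots; every stochastic step derives from
the config seed, and reruns are byte-identical. `validate_run()` re-asserts
the framework identities on finished outputs and reports failures instead
of raising.

The test suite exercises the full pipeline at reduced depth (simulated
runs of 30,000 members/reads for property checks; the exact
truth-recovery check runs at the full 100,000-read depth across all ten
pool × time samples), sizes chosen to give comfortable statistical margins
for every assertion while keeping the suite quick to run routinely.
Fixtures are generated in code; the two bundled example targets are
synthetic constructions matching the 55% and 80% GC composition of the
target classes this assay is typically applied to, and are labelled as
such.

## Known limitations

* The simulator's kinetic caricature compounds penalties multiplicatively
  and ignores mismatch-identity effects on rates (identity enters only
  through which sequences exist in the library), so identity-resolved
  cells differ only by sampling noise in simulated data.
* Absent-implies-linearized is an interpretive assumption; sequences lost
  for other reasons (extraction dropouts, extreme depletion below
  sampling depth) are indistinguishable from linearized ones.
* No count-model inference is performed; all metrics are ratio-based, and
  their sampling error is controlled only through depth and replicate
  averaging.
* Gel quantification consumes band intensities as numbers; densitometry
  itself (background subtraction, lane warping) is out of scope.
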