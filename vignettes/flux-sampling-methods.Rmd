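---
title: "Sampling the steady-state flux space: methods and design notes"
author: "fluxsampler"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sampling the steady-state flux space: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fluxsampler)
```

## The model

A constraint-based metabolic model consists of the stoichiometric matrix
$S \in \mathbb{R}^{m \times n}$ (m metabolites, n reactions) and per-reaction
flux bounds. At steady state every metabolite's production balances its
consumption, and each flux is limited by capacity and directionality:

$$S v = 0, \qquad lb \le v \le ub .$$

These constraints define a bounded convex polytope, the *solution space*.
Genome-scale models are underdetermined ($n > m$), so no unique flux vector
exists; sampling the polytope uniformly yields an estimated marginal flux
distribution per reaction. Reversibility is encoded purely through the
bounds ($lb < 0$ allows backward flux); reactions are never split into
forward/backward halves, so the samplers operate on the signed flux polytope
directly.

Before sampling, reactions that cannot carry any flux are removed:
`removeBlockedReactions()` runs flux variability analysis (an LP minimum and
maximum per reaction) and discards reactions whose whole attainable range
lies within `fluxTol = 1e-9` of zero, together with metabolites whose
stoichiometric rows become empty. The operation is idempotent and does not
alter the attainable ranges of surviving reactions.

## Hit-and-run and artificial centering

Plain hit-and-run (`sampleHitAndRun()`) picks an isotropic random direction
in the nullspace of $S$, finds the feasible segment along it, and jumps to a
uniform random point on that segment. It converges to the uniform
distribution but struggles in the irregular, elongated spaces of metabolic
networks: near a thin face almost all directions allow only tiny steps.

Artificial centering hit-and-run (ACHR) replaces the isotropic direction
with the direction from a uniformly drawn member of a *direction pool*
toward the running empirical center of the chain, which adapts step
proposals to the elongated axes. One iterate (`achrStep()`) is:

1. draw a pool point $p$ uniformly; set $d = (p - c)/\lVert p - c \rVert$
   where $c$ is the running center (redraw up to 10 times if
   $\lVert p - c\rVert$ or the feasible segment is degenerate);
2. compute the feasible segment $[\alpha_{\min}, \alpha_{\max}]$ through the
   current point along $d$;
3. move to $x \leftarrow x + \alpha d$ with
   $\alpha \sim U(\alpha_{\min}, \alpha_{\max})$;
4. absorb $x$ into the center: $c \leftarrow (k c + x)/(k+1)$.

Because directions depend on previous iterates, the sequence is not a Markov
chain and carries no asymptotic uniformity guarantee; empirical diagnostics
(below) are the only practical check, and their verdicts should be read with
that caveat.

## Warm-up

All modes seed their chains from linear-programming *warm-up points*
(`minmaxWarmup()`): for each reaction, the flux vector minimising and the
one maximising that flux — $2n$ points that span the polytope's extreme
directions. LP optima lie on the boundary, where step sizes collapse, so
the set is pulled toward its centroid before use
(`pullToInterior()`: $x \mapsto c + \tau (x - c)$, feasible by convexity).
The coefficient $\tau$ is not fixed by the original description of the
transformation; we use $\tau = 0.5$ in every mode, record it in provenance,
and expose it as a parameter.

The classic COBRA scheme additionally generates warm-up points by
maximising random weightings $c^T v$, $c \sim U[-1,1]^n$
(`randomWeightWarmup()`). The long-chain mode skips these deliberately:
LPs on large networks cost far more than sampling iterates, and different
random weightings frequently land on the same or nearby optima, which would
bias the start distribution.

## The two chain orchestration modes

**Long thinned chains** (`sampleOptGp()`, the production sampler): each of
`nChains` logical chains starts at a warm-up point chosen uniformly at
random and runs continuously; every `stepCount`-th iterate is kept. Chain
$j$ stores $\lfloor nS/nP \rfloor$ samples (+1 for the first
$nS \bmod nP$ chains), so exactly `nSamples` rows come back in chain-major
order, the $i$-th stored sample of a chain having travelled
$i \cdot stepCount$ iterates from its start. The direction pool is the
warm-up set plus the chain's own *stored* samples, and the center is
updated at every iterate, stored or not. The original formulation iterates
ACHR continuously while only every `stepCount`-th point is kept as a
sample; we read "previous sampled point" as the points actually retained,
which also keeps memory bounded. The choice is recorded in provenance
(`poolPolicy`) so outputs remain comparable across implementations.

**Restart per sample** (`sampleGp()`): one warm-up point per requested
sample ($2n$ min/max points topped up with random-weight optima), and one
short chain per sample — exactly `stepCount` iterates from warm-up point
$i$ with the whole warm-up set as pool — returning its end point. With a
small step count the end points remain near the (clustered) warm-up points,
which is the regime where this scheme shows bias on larger networks.

Chains are logical: each derives its own RNG stream from the master seed
(`seed * 1000003 + chain * 7919 mod (2^31-1)`), so results depend only on
`nChains` and `seed`, never on physical scheduling. Execution is
sequential; a `workers` argument is accepted for interface compatibility
and provably cannot change the output. When `nSamples` is not divisible by
`nChains`, earlier chains take the extra samples.

## Numerical choices

* Tolerances: `feasTol = 1e-6` on $\lVert Sv\rVert_\infty$,
  `boundTol = 1e-6` on the box constraints, `fixedTol = 1e-9` for fixed
  reactions (never given direction components), `dirTol = 1e-9` below which
  a direction component is ignored in segment computations (prevents
  division blow-ups). Fluxes are conventionally $O(1)$–$O(1000)$
  mmol/gDW/h, so absolute tolerances are appropriate.
* Drift control: directions lie in $\mathrm{null}(S)$ by construction, but
  floating-point drift accumulates over long chains. Every 100 iterates,
  and before any sample is stored, the point is orthogonally projected back
  onto $\mathrm{null}(S)$ (cached projector $NN^T$ from an orthonormal SVD
  basis) and sub-`boundTol` bound violations are clamped to the bound.
  Drift beyond $10^{-3}$ (scaled) aborts the chain as corrupted.
* Unbounded segments cannot occur in a well-formed model (finite bounds are
  enforced at validation), but as a guard the segment is capped at
  $10^6 (1 + \lVert x \rVert)$.
* Degenerate moves: if the feasible segment is shorter than $10^{-12}$ the
  direction is redrawn rather than accepting a null move; ten consecutive
  failures raise a degenerate-pool error.
* The LP backend is the two-phase simplex in the recommended `boot`
  package, applied after shifting fluxes to $x = v - lb \ge 0$; vertex
  tie-breaking is the solver's own, so determinism holds per
  solver-and-options, which is what the provenance records.

## The xy-deviation measure

To compare samplers without a ground truth, each run's per-reaction sample
vector is sorted and normalised by the bound width $ub_j - lb_j$; the $r$
runs of the reference sampler $y$ are averaged element-wise into a mean
chain $\bar y$; and each reaction's deviation is the mean absolute
difference between the sorted chains of $x$ and $\bar y$ at aligned order
statistics:

$$D_j = \frac{1}{rN} \sum_{\text{runs}} \sum_{i=1}^N
        \lvert \hat x_{ij} - \bar y_{ij} \rvert, \qquad
  \text{xy-deviation} = \frac{1}{n'}\sum_{j \text{ included}} D_j \in [0,1].$$

Mean absolute deviation is preferred to a standard deviation for robustness
to aberrant values. Reactions with $ub = lb$ cannot be normalised and are
excluded from the average (they are rare once blocked reactions are
removed) and recorded in the report. Whether one averages per run and then
over runs, or pools all $rN$ terms, is identical for equal $N$; we pool,
and unequal $N$ is an error rather than an interpolation, because the
measure is defined on aligned order statistics. The measure is asymmetric
($y$ supplies the reference); a clearly-labelled symmetric convenience
variant reports the maximum of the two directions.

Two i.i.d. uniform samplers give a noise floor of order $1/\sqrt N$;
degenerate opposed groups give exactly 1; identical groups exactly 0.

## Convergence diagnostics

Three standard empirical diagnostics are implemented with the conventional
defaults of the CODA toolbox, which is how they are normally applied to
flux samplers:

* **Geweke** (`gewekeDiagnostic()`): z-score comparing the means of the
  first 10% and last 50% of the chain, variance from the spectral density
  at frequency zero (AR fit, AIC order selection capped at $N/20$).
  $|z| < 1.96$ is the usual criterion.
* **Gelman–Rubin** (`gelmanRubin()`): per-reaction
  $\hat R = \sqrt{((N-1)/N \cdot W + B/N)/W}$ and the multivariate
  largest-eigenvalue generalisation on the within/between covariance
  matrices. Network fluxes are linearly dependent, so the pooled
  within-chain covariance is regularised with $10^{-10} I$ before the
  eigenproblem. $R < 1.2$ is read as convergence.
* **Heidelberger–Welch** (`heidelbergerWelch()`): Cramér–von Mises
  stationarity statistic on the Brownian-bridge transform of the cumulative
  sum, spectral variance from the second half of the chain; tested on the
  full chain, then after discarding 10%, ..., 50%, passing at the first
  accepted stage ($\alpha = 0.05$). The asymptotic CvM CDF uses the
  classical four-term Bessel-$K_{1/4}$ series, clamped to 1 above
  statistic 10 where the truncated series degrades.

Zero-variance reactions are reported as $z = 0$, $R = 1$, HW fail, each
with a degenerate flag, never as NaN. One behaviour worth knowing: a slow
linear trend inflates the AR spectral variance estimate that standardises
the Heidelberger–Welch bridge, so the test has little power against it
(level shifts are its canonical alternative); Geweke and Gelman–Rubin
catch such trends instead, which is one reason to run all three. All three diagnostics are invariant
to affine rescaling of individual reactions. The tests are known to
disagree — the multivariate $\hat R$ is notoriously liberal on flux
chains — so `convergenceDiagnostics()` reports all three side by side and
never aggregates them into a single verdict.

## What the synthetic generator does and does not emulate

The package tests itself entirely on generated fixtures:

* `makeBox(n)` — no mass-balance rows; exact uniform moments.
* `makeTriangle()` — three reactions with one balance row whose feasible
  set maps isometrically onto the unit right triangle; exact centroid
  (1/3, 1/3), variance 1/18, and a rejection-sampling acceptance rate given
  by the triangle-to-bounding-box area ratio (≈ 0.46 for the rotated
  equilateral embedding).
* `makeRandomNetwork(m, n)` — sparse integer stoichiometry of full row
  rank; bounds built around a planted nullspace vector, so feasibility and
  interiority hold by construction. Mixed tight/loose bound widths
  (defaults 0.5 / 20, mixing probability `looseFraction = 0.5`) create the
  anisotropy — elongated along loosely constrained fluxes, narrow along
  tight ones — that distinguishes real solution spaces from boxes.
* `rejectionSample()` — exactly-uniform ground truth via bounding-box
  proposals in an orthonormal nullspace parameterisation (per-direction
  extents from LPs), restricted to effective dimension ≤ 4 where the
  acceptance rate is workable.

These fixtures reproduce the *geometry class* of flux polytopes but not
genome-scale properties: hundreds of effective dimensions, extreme bound
heterogeneity, near-degenerate faces from coupled subsystems, and
warm-up-point clustering driven by thousands of constraints. Passing tests
therefore validate the algorithms and their small-sample behaviour, not
convergence behaviour at genome scale, where larger step counts are known
to be necessary.

A consequence visible in our checks: on 10-reaction fixtures the
restart-per-sample scheme converges within tens of iterates, so the
classic ordering — restart-mode needing far larger step counts than the
long-chain mode — appears only when the fixture has few, strongly
elongated axes and clustered warm-up optima (we use a single dominant axis,
width ratio 4000:1, `looseFraction = 0.15`) and enough samples per run
(N = 2000) for the ordering to clear the $O(1/\sqrt N)$ sorting-noise
floor. Even then the self-deviation ordering holds with a modest margin;
at genome scale the effect is far larger than at this desk
scale.

## Problem sizes used in the checks

The shipped tests run at sizes chosen to make sampling error a small
fraction of the tested effects while keeping the whole suite lightweight:
feasibility audits at $10^4$ samples per mode and fixture; uniformity
via per-dimension Kolmogorov–Smirnov at $N = 10^4$, step count 100
(KS < 0.025, three times the 95% band for i.i.d. points, the slack
covering residual autocorrelation); diagnostics sanity at $N = 10^4$,
50 reactions; the step-count ordering at $N = 2000$, 4 runs per
configuration; and the mixing benchmark at four runs of 5,000 samples,
step count 500, 4 chains on an $m=5$, $n=10$ network, whose multivariate
$\hat R$ sits far below the 1.2 criterion.

## Known limitations

* ACHR iterates are not a Markov chain; no uniformity proof exists, and
  all convergence statements here are empirical.
* The SBML reader covers Level 3 core plus FBC bound references — the
  subset needed to exchange constraint-based models — not kinetic laws,
  gene-product rules, objectives or compartment semantics. Reactions
  without resolvable finite bounds receive the conventional (−1000, 1000)
  defaults with a warning.
* Sample matrices are written as 17-digit TSV plus a JSON provenance
  sidecar; no binary container is produced.
* The simplex backend is adequate for the small and mid-size models this
  package targets; genome-scale FVA would want an interior-point LP and
  warm starts, which are out of scope here.
* Exact polytope volume, vertex enumeration and constraint-redundancy
  removal are out of scope.
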