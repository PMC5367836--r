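---
title: "Cell-cycle kinetics from pulse-chase labelling: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cell-cycle kinetics from pulse-chase labelling: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(edupulse)
```

## The measurement and the model

An intra-peritoneal injection of EdU keeps the label bioavailable for about
an hour; every cell that traverses S phase in that window incorporates it
permanently. A flow-cytometry dot plot of DNA content against EdU intensity
at sacrifice therefore separates three groups: unlabelled cells with 2N DNA
(G0/G1), unlabelled cells with 4N DNA (G2/M), and labelled cells of any DNA
content. DNA content cannot separate G0 from G1 nor G2 from M, so three
phases is the finest resolution the readout supports.

`edupulse` models the experiment with six compartments — G, S, M unlabelled
and G′, S′, M′ labelled — evolving by linear ODEs. Cells leave G0/G1 for S
at rate $a_G$, S for G2/M at rate $a_S$, and divide out of G2/M at rate
$a_M$, each division returning two daughters to G0/G1. Each phase also has
an exit rate $d_X$ that pools death, differentiation and migration; the
population is treated as a closed system otherwise. During a pulse, S-phase
cells become labelled at rate $\beta$; at division a fraction $\alpha$ of
labelled cells shed the label.

Fitting uses the standard constraint set: labelling is kinetically neutral
(primed rates equal unprimed), labelling is instantaneous ($\beta = \infty$),
no shedding ($\alpha = 0$), the population is at steady state, there is no
exit from S or G2/M ($d_S = d_M = 0$), one injection is a square 1-h pulse,
and S phase lasts 6.5 h ($a_S = 1/6.5$). Steady state of the phase totals
forces $d_G = a_G$: the division influx balances the G0/G1 exit. That
leaves exactly two free parameters, $(a_G, a_M)$, matching the two degrees
of freedom in the observed triplet.

The steady-state phase occupancy has the closed form implemented in
`steady_state()`; the proliferation rate (percent of cells dividing per
hour) is $p = a_M (M + M')_{ss}$, which reduces to
$200 a_G a_M / (2 a_M + 13 a_G a_M + 2 a_G)$ — both identities are asserted
to $10^{-10}$ relative accuracy in the test suite. Internally all rates are
per hour and all abundances are percentages on the 0–100 scale; conversion
to %/day (×24) happens only at the reporting boundary, and durations are
rounded only for display.

The inter-mitotic time is reported as $100/p$ days throughout, the
reciprocal-of-rate convention; mean phase durations are $1/a_G$ and
$1/a_M$. These are population means under exponentially distributed phase
residence — a stretched or age-structured cell-cycle model is out of scope.

## Protocols and integration

`build_protocol()` turns an injection schedule into contiguous half-open
`[start, end)` pulse/chase windows: each injection opens a 1-h label-on
window (the bioavailability is a configurable square window, not a decay
curve), overlapping windows merge, and the last window truncates at
sacrifice. The default study protocol (injections at 0, 1, 16 h; sacrifice
16.5 h) yields a 2-h pulse, 14-h chase and 30-min pulse.

Within each window the model is a linear time-invariant system, integrated
with classical fixed-step 4th-order Runge–Kutta at `dt_h = 0.01` h (36 s).
Instant labelling is implemented exactly as prescribed computationally: at
each pulse onset all unlabelled S cells transfer discretely to S′, and
during the pulse the $a_G G$ flux feeds S′ directly, so unlabelled S stays
empty. Finite-$\beta$ labelling is retained as an option for generality.
Because the system is linear, one RK4 step is the fixed matrix polynomial
$I + hA + (hA)^2/2 + (hA)^3/6 + (hA)^4/24$; endpoint-only evaluations
(the fitting hot path) raise that one-step matrix to the window's step
count by binary exponentiation, which is the identical scheme evaluated
without materialising the trajectory — the two paths agree to $10^{-9}$ in
the tests, step halving moves endpoints by less than $10^{-5}$, and an
independent forward-Euler oracle at `dt = 1e-4` agrees to $10^{-4}$.
States within $-10^{-9}$ of zero are clipped to zero as a floating-point
guard; anything more negative raises an error rather than being silently
clipped. `dt_h` must divide every window length (0.01 h divides the 0.5-h
pulse), with event times snapped to the step grid.

## Fitting

`fit_sample()` minimises the Euclidean distance, in percent units, between
the observed triplet and the simulated endpoint triplet started from the
unlabelled steady state. The distance uses all three components exactly as
defined — redundant under the sum constraint, but kept as specified. The
search is a 60×60 log-spaced grid on $[10^{-4}, 1]$ /h per axis (ties break
lexicographically toward slower kinetics), followed by Nelder–Mead
refinement of the squared distance on log rates with a soft box penalty;
the squared form is smooth at a perfect fit, and the optimiser is restarted
once because Nelder–Mead stalls near machine zero. Noiseless round trips
recover both rates to well under 1% across the kinetic range, and fitted
distances for noiseless targets sit around $10^{-11}$, far below the 0.05
acceptance bound on real fits. Targets whose components sum outside
$100 \pm 0.5$ are renormalised with a warning; a target with no labelled
cells pins $a_G$ at the box edge and sets `boundary_flag`, marking the
estimate as an upper bound rather than failing.

### Confidence intervals

The observed triplet is a multinomial proportion vector over the gated
events. For intervals, the package uses a generalized least-squares
objective on the two free components (unlabelled G0/G1 and unlabelled
G2/M; the third is determined by the sum), weighted by the inverse 2×2
multinomial covariance of the observed proportions at the fitted point and
the sample's event count. At the optimum this objective is asymptotically
$-2\log L$ up to a constant, so the parameter covariance is twice the
inverse Hessian, computed by 9-point central differences with relative
steps of $10^{-3}$ (absolute steps would be ill-scaled for rates near
$10^{-3}$/h). Wald 95% intervals follow for $(a_G, a_M)$, and the interval
for $p$ uses the delta method with the analytic gradient
$\partial p/\partial a_G = 400 a_M^2 / D^2$ (and symmetrically for $a_M$).
This construction is validated by simulation: over 200 multinomial
replicates at 10,000 events the empirical coverage of the 95% interval for
$p$ falls within 88–99%. A singular or non-positive Hessian sets a
non-identifiability flag and widens the intervals to the search box.

## The synthetic experiment

`signature_presets()` encodes strain × age × organ × population kinetic
signatures spanning roughly 1–45% of cells dividing per day: fast young-B6
thymus (whole organ ~32 %/day, mature CD8 single-positives ~45 %/day), slow
old-FVB thymus (~9 %/day, DN1 progenitors ~1.2 %/day), quiet young spleens
(~3 %/day) that accelerate with age in B6 (~13 %/day), near-quiescent naive
T cells and active regulatory T cells. For each group `true_a_m` encodes a
plausible G2/M duration (2 h in young B6 thymus up to ~63 h in quiescent
splenocytes) and `true_a_g` is solved in closed form so the pair hits the
group's nominal rate. Defaults of 4 mice per group and 50,000 events per
sample are typical of gated lymphocyte panels on a modern cytometer.

`generate_events()` draws per-cell records: live cells multinomially across
the six compartments at their simulated end-of-protocol proportions; DNA
content centred at 1 (2N) and 2 (4N) with 5% coefficient-of-variation
Gaussian measurement noise (typical DNA-dye CVs) and uniform across (1, 2)
for S phase; EdU intensity as two log-normal modes ≥10× apart with the gate
threshold at the log-space midpoint, so gating is deterministic; apoptotic
events below 2N and engulfed (>4N) events appended at the design fractions.
`gate_events()` inverts this: sub-G0/G1 events count as apoptotic, >4N as
engulfed, DNA in (2.2, 4] is discarded as aggregates (the stand-in for
doublet exclusion by pulse geometry), labelled live events are EdU-above
threshold regardless of DNA content, and unlabelled live events must fall
in a phase window to enter the triplet — as with manual gates. Dead cells
never enter the fitted triplet, mirroring the model's exclusion of death;
the EdU⁺/dead ratio is reported as an expansion-performance index, `NA`
when no dead event exists.

What the generator does *not* emulate: antibody-marker fluorescence
(populations are labels, not gated from CD markers), compensation and
spillover, instrument drift, aggregates with structured DNA content, or
inter-mouse biological variance beyond counting noise. Passing end-to-end
tests therefore demonstrates correctness of the inference machinery under
the model's own assumptions plus realistic counting and measurement noise —
not robustness to gating subjectivity or model misspecification on real
cytometry.

Reproducibility: every stochastic function takes an explicit seed and
leaves the global RNG untouched; the pipeline derives per-sample sub-seeds
as `seed + 7919·design_row + 104729·mouse` (two primes keep distinct
design/mouse combinations from colliding within any realistic design size).

## The rate-versus-%EdU calibration

Because the 16.5-h protocol is shorter than one full cycle for most
populations, the labelled fraction at sacrifice is nearly proportional to
the S-entry flux and hence to the proliferation rate. Regressing fitted
rate (fraction/day) on %EdU⁺ over a simulated sweep of thymus-like
signatures reproduces a near-functional line (r² > 0.99) with slope close
to 0.0119 fraction/day per percentage point; `edu_to_rate()` exposes that
calibration for quick estimates under this exact protocol duration only.
The slope's y-units are fraction/day: 38% EdU⁺ maps to ≈ 0.45/day, i.e.
45 %/day.

## Validation against a single-pulse chase

`baron_validation()` reruns the historical whole-thymocyte design — one
1-h pulse, nineteen-hour chase — tracking the phase composition within the
labelled cohort, initialised as 100% labelled S cells. Whether unlabelled
steady-state cells coexist with the cohort does not affect within-cohort
composition, so only the cohort is tracked. With young-B6-like parameters
the cohort drains S phase within hours and accumulates in G0/G1, the
expected qualitative signature; the historical curves exist only as a
figure, so the comparison is qualitative.

## Problem sizes and runtime choices

The packaged checks use: a 10×10 log grid of noiseless round trips for
identifiability, 200 multinomial replicates at 10,000 events for interval
coverage, 48 simulated samples for the calibration sweep, and 2–4 mice at
20,000–50,000 events for pipeline smoke tests — sizes at which every Monte
Carlo bound in the tests is stable while the whole suite stays fast on a
single core. The acceptance script regenerates the grid distances and the
calibration slope from scratch at the same sizes.

## Known limitations

- Rates are population averages; heterogeneous subpopulations need finer
  phenotypic decomposition before fitting, not a mixture fit.
- Death, differentiation and migration are pooled into exit rates and the
  fitted triplet carries no information to separate them.
- G0 vs G1 (and G2 vs M) durations are not separable from DNA content.
- The calibration line is protocol-specific; any other schedule requires
  refitting, which the simulator supports directly.
- Inter-mitotic time $100/p$ is indicative: with exponential phase exits
  the mean cycle time of actively cycling cells differs from the
  population-turnover reciprocal.
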