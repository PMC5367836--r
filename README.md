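# edupulse

Estimating lymphocyte proliferation rates and cell-cycle phase durations from
EdU (or BrdU) pulse-chase flow cytometry.

In vivo pulse-chase labelling with thymidine analogues marks every cell that
passed through S phase while the label was bioavailable. At sacrifice, a
DNA-content × EdU dot plot yields three gated percentages per sample:
unlabelled G0/G1 cells, unlabelled G2/M cells, and all EdU⁺ cells. `edupulse`
turns those three numbers into kinetic parameters by fitting a six-compartment
ODE model of cells cycling through G0/G1, S and G2/M in unlabelled
(G, S, M) and labelled (G′, S′, M′) states:

```
dG/dt  = 2 a_M M + 2 α a_M′ M′ − (a_G + d_G) G
dS/dt  = a_G G − (a_S + d_S) S − [0,β] S
dM/dt  = a_S S − (a_M + d_M) M
dG′/dt = 2 (1−α) a_M′ M′ − (a_G′ + d_G′) G′
dS′/dt = a_G′ G′ − (a_S′ + d_S′) S′ + [0,β] S
dM′/dt = a_S′ S′ − (a_M′ + d_M′) M′
```

`a_X` are phase-exit rates, `d_X` population-exit rates (death,
differentiation, migration), `β` the labelling rate during a pulse (infinite
for instant labelling) and `α` the fraction of label shed at division. Under
the standard biological constraints (steady state, neutral labelling, fixed
6.5-h S phase, no exit from S or G2/M, `α = 0`, `β = ∞`) only `a_G` and `a_M`
remain free, and the proliferation rate — percent of cells dividing per hour —
has the closed form

```
p = 200 a_G a_M / (2 a_M + 13 a_G a_M + 2 a_G)
```

from which the package reports rates in %/day, mean G0/G1 and G2/M durations
(`1/a_G`, `1/a_M`) and the inter-mitotic time `100/p` in days. Per-sample 95%
confidence intervals come from the Hessian of a multinomially weighted
least-squares objective at the optimum.

A synthetic flow-cytometry module generates event-level (DNA content × EdU
intensity) data — including sub-G0/G1 apoptotic and >4N engulfed dead cells —
from strain × age × organ × population kinetic signatures, and gates it back
into triplets, so the whole generate → gate → fit → summarise pipeline is
testable without instrument data.

## Worked example

Fit one sample gated at 79.4% unlabelled G0/G1, 2.3% unlabelled G2/M and
18.3% EdU⁺ after the default protocol (EdU injections at 0, 1 and 16 h,
sacrifice at 16.5 h):

```r
library(edupulse)

target <- tibble::tibble(pct_g_unlabelled = 79.4, pct_m_unlabelled = 2.3,
                         pct_labelled = 18.3)
fit <- fit_sample(target, n_events = 50000)
fit
#> <edu_fit>
#>   a_G = 0.0099772 /h, a_M = 0.24548 /h (distance 3.16e-12)
#>   proliferation 21.7 %/day, inter-mitotic 4.62 days
tidy(fit)
#> # A tibble: 3 × 5
#>   term          estimate std.error conf.low conf.high
#>   <chr>            <dbl>     <dbl>    <dbl>     <dbl>
#> 1 a_g_per_h      0.00998  0.000105  0.00977    0.0102
#> 2 a_m_per_h      0.245    0.00713   0.232      0.259
#> 3 p_pct_per_day 21.7      0.209    21.3       22.1
```

So this population turns over at ~21.7% of cells per day (95% CI 21.3–22.1),
spending on average 100 h in G0/G1 and 4 h in G2/M, with one division about
every 4.6 days. The quick calibration shortcut for this protocol,
`edu_to_rate(18.3)`, gives 0.217 /day — the same answer straight from the
labelled percentage.

Batch fitting, simulation and the synthetic pipeline:

```r
# simulate and plot a trajectory
traj <- simulate_protocol(apply_hypotheses(0.01, 0.25), default_study_protocol())
autoplot(traj)

# full synthetic experiment: events -> gates -> fits -> group summaries
res <- run_pipeline(signature_presets(), seed = 1)
res$groups

# calibration line: fitted rate (fraction/day) vs %EdU+
rate_vs_edu_regression(res$fits)
```

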