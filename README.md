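# burstfit

Transcription in single cells happens in bursts: a promoter stochastically
switches between an inactive and an active state, and transcripts are
initiated only while it is active. `burstfit` infers the kinetic parameters
of this process — the switching rates σ<sub>on</sub>, σ<sub>off</sub>, the
initiation rate ρ, and derived quantities such as the burst size ρ/σ<sub>off</sub>
and the fraction of ON time f<sub>ON</sub> = σ<sub>on</sub>/(σ<sub>on</sub>+σ<sub>off</sub>)
— from the kind of data an smFISH experiment produces: per-cell **mature
mRNA spot counts**, and per-cell **transcription-site fluorescence**
normalized to single-mRNA units. It is written for quantitative biologists
who want to go beyond fitting a merged mature-count histogram: it supports
cell-cycle-aware fitting (one gene copy in G1, two in G2), curation of
transcription-site misidentification noise, and validation of fitted
kinetics against live-cell autocorrelation functions.

## Models

* **Telegraph model** (mature mRNA): promoter OFF ⇌ ON at rates
  σ<sub>on</sub>, σ<sub>off</sub>; initiation at ρ while ON; first-order
  degradation at d. The steady-state count distribution is computed by
  finite state projection — a banded linear solve over
  (promoter state) × (count), with adaptive truncation. Only ratios to d
  are identifiable, so d is fixed (default 1/min).
* **Delay telegraph model** (nascent mRNA): each initiated RNA polymerase II
  resides on the gene for a fixed elongation time τ, so the bound-polymerase
  number is the count of initiations in the last τ minutes; solved as a
  transient counting process by uniformization. Only ratios to 1/τ are
  identifiable, so τ is supplied (e.g. `elongation_time(3062, 65)` ≈ 0.785
  min for a 3062-bp transcript at 65 bp/s).
* **Trapezoidal signal**: with probes on the first L1 bp of the transcript,
  a polymerase's fluorescence rises linearly over L1 and plateaus over the
  remaining L2. The site intensity distribution over integer bins is an
  exact binomial/uniform-sum (Eulerian-number) mixture over the polymerase
  number distribution.

Maximum-likelihood fits use self-adaptive differential evolution plus a
multistart quasi-Newton polish; confidence intervals use the profile
likelihood. The package also contains the full synthetic-data machinery
(exact stationary simulators for both models, per-cell log-normal rate
noise, two-copy cells, intensity traces, DNA-content mixtures) and a
parameter-recovery benchmark comparing inference from mature vs nascent
data across a parameter grid.

## Worked example

```r
library(burstfit)

truth <- rate_params(sigma_on = 7.5, sigma_off = 7.5, rho = 50)

# simulate an smFISH-like experiment: 10,000 cells, nascent signal bins
cells <- simulate_nascent_cells(nascent_model(truth, tau = 0.5),
                                sim_config(n_cells = 1e4, seed = 42))
fit <- fit_kinetics(observed_dataset(cells$bin, "nascent-bins"),
                    control = fit_control(pop = 20, max_gen = 50, seed = 1))
fit
```

```
<fit_result> nascent-bins (one-copy)
  sigma_on = 7.24, sigma_off = 8.395, rho = 53.79 (1/min)
  fON = 0.463, burst size = 6.41, effective rate = 24.9
  NLL = 32263.0128 after 1258 evaluations
```

The fitted rates recover the simulation truth to within a few percent:
ρ = 53.8 vs 50 (8% high), f<sub>ON</sub> = 0.46 vs 0.50, with the burst
size ρ/σ<sub>off</sub> = 6.4 against a true 6.7. With real data the same
call is preceded by `classify_cell_cycle()` on the integrated DNA-stain
intensities (bimodal Gaussian fit, ±1 SD windows) and, for G2 cells,
`copy_mode = "two-copy-independent"`; low-bin measurement noise is absorbed
with `curation = "fusion"` (merge the lowest k bins) rather than
`"rejection"` (drop them), because rejection discards the zero-bin evidence
for promoter OFF periods.

A thin command-line wrapper with `simulate`, `fit`, `classify` and `acf`
subcommands is installed under `inst/cli/burstfit`.

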