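---
title: "Methods: telegraph-model inference from mature and nascent mRNA distributions"
author: "burstfit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: telegraph-model inference from mature and nascent mRNA distributions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(burstfit)
```

## The models

Transcription in single cells occurs in bursts. The minimal model capturing
this is the **telegraph model**: a promoter switches OFF→ON at rate
$\sigma_{on}$ and ON→OFF at rate $\sigma_{off}$ (both 1/min), initiates
transcripts at rate $\rho$ only while ON, and mature mRNA decays with
first-order rate $d$. Its steady-state mRNA count distribution is what an
smFISH experiment measures when counting spots per cell. `telegraph_pmf()`
computes it by finite state projection (FSP): the chemical master equation on
(promoter state) × (count $0..K$) is truncated and its stationary
distribution obtained from one banded linear solve (LAPACK band LU with
partial pivoting, anchored at a high-probability state so steeply decaying
tails stay well-scaled). The truncation
starts at mean $+\,8$ standard deviations (closed-form telegraph moments)
and doubles until the probability pressed against the boundary is below the
tail tolerance `eps` (default $10^{-8}$); exceeding a hard cap raises an
error rather than returning an under-truncated distribution.

Only the ratios $\sigma_{on}/d$, $\sigma_{off}/d$, $\rho/d$ are identifiable
from a stationary count distribution, so $d$ is fixed (default 1/min) and
never inferred; all mature-data estimates are rates *relative to* $d$.

**Nascent mRNA** — transcripts still tethered to an elongating RNA
polymerase II at the locus — avoids post-transcriptional noise entirely. In
the **delay telegraph model** every initiation puts one polymerase on the
gene for a deterministic residence (elongation) time $\tau$. Because every
polymerase initiated within the last $\tau$ minutes is still on the gene and
every earlier one has left, the steady-state number of bound polymerases is
exactly the count of initiation events of the telegraph-gated Poisson
process over a window of length $\tau$, started from the stationary promoter
occupancy. `delay_polii_pmf()` integrates this transient counting process by
uniformization (randomization), which keeps every iterate non-negative and is
exact up to a Poisson tail cutoff; the implementation is validated against
the analytic mean identity $E[k] = \rho\,\tau\,f_{ON}$ (relative error
$<10^{-6}$) and against delayed stochastic simulation. Analogously to the
mature case, only $\sigma_{on}\tau$, $\sigma_{off}\tau$, $\rho\tau$ are
identifiable, so $\tau$ is supplied, not inferred — from gene length and
polymerase speed via `elongation_time()` when measured values exist.

## The trapezoidal signal and its binning

smFISH probes that bind the first $L_1$ base pairs of the transcript (e.g.
stem-loop repeats at the 5′ end) make a single polymerase's fluorescence
rise linearly while it transcribes the probe region and plateau at one
mRNA-equivalent across the remaining $L_2$ base pairs. With polymerases
independently and uniformly positioned along the gene — which holds
marginally in steady state because elongation speed is constant — each
per-polymerase signal is $\mathrm{Uniform}(0,1)$ with probability $L_1/L$
and exactly $1$ with probability $L_2/L$ ($L = L_1 + L_2$). The total signal
given $k$ polymerases is then a Binomial$(k, L_1/L)$ mixture of shifted
uniform-sum (Irwin–Hall) variables.

Measured site intensities are normalized by the median single-mRNA intensity
and discretized to integer bins; the model must be binned the same way. We
use right-closed unit bins: signal in $(i-1, i]$ is bin $i$, zero signal is
bin 0, and integer atoms (all polymerases on the plateau) belong to their
own-numbered bin. The bin mass of a sum of $j$ uniforms is the Eulerian
number $A(j, i-1)/j!$, which we evaluate with the normalized recurrence
$e(n,k) = \left[(k+1)\,e(n-1,k) + (n-k)\,e(n-1,k-1)\right]/n$. Unlike the
alternating-sign closed form of the Irwin–Hall CDF (catastrophic
cancellation for $j \gtrsim 25$) or gridded numerical convolution
(discretization error, cost growing with $k$), the recurrence is exact,
stable for arbitrary $k$, and produced by one cached triangular pass.
`signal_bin_pmf()` mixes these conditional bin masses over the polymerase
number distribution; before binning, the continuous-signal mean is checked
against the identity $E[k]\,(L_1/2 + L_2)/L$.

One approximation is inherited from the model itself and worth stating
plainly: conditional on the polymerase *count*, positions are treated as iid
uniform. That is exact for an always-ON promoter (order statistics of a
Poisson process) and excellent for switching much faster than $\tau$, but
when the promoter switches on the $\tau$ timescale, a cell's polymerases are
clustered by the recent promoter history. Against the faithful delayed
simulation, the binned model deviates by total variation ≈0.02 at
$(\sigma_{on}, \sigma_{off}, \rho, \tau) = (2, 3, 20, 0.5)$ and by sampling
noise only (≈0.005 at $10^5$ cells) in the always-ON and fast-switching
regimes. The polymerase *count* distribution is exact in all regimes. Tests
assert the exact regimes at TV < 0.02 and the slow-switching regime at
TV < 0.05.

## Likelihood, gene copies, and curation

`negative_log_likelihood()` evaluates
$-\sum_j \log P(\text{value}_j;\theta)$ on the count histogram
(multiplicity-weighted, identical to the per-cell sum). Cells in G2 carry
two gene copies: under **independent copies** the model distribution is the
single-copy distribution convolved with itself; under **synchronized
copies** (perfect allelic correlation) it is a single trajectory at doubled
initiation rate — the simplest mechanism consistent with perfect state
correlation, and the one the simulator implements for that mode. Merged
(cell-cycle-ignorant) populations are deliberately fitted with the one-copy
model to quantify that misspecification. Model probabilities are floored at
$10^{-15}$; an observation at the floor signals data–model incompatibility
and raises a warning rather than an infinite objective.

When exonic probes label both nascent and mature mRNA, the brightest nuclear
spot in a transcriptionally silent cell is a mature transcript misread as a
transcription site, inflating the low signal bins at the expense of bin 0.
Two curation strategies are provided. The **fusion method**
(`curate_fusion()`) merges the lowest $k$ bins of data *and* model into one
bin ($k{=}1$ is the identity), conserving total probability. The
**rejection method** (`curate_rejection()`) drops all cells below bin $k$
and renormalizes the model over the surviving bins — the conditional
likelihood, the only probabilistically valid form of rejection. On clean
synthetic data both remain consistent estimators; on data with corrupted low
bins, fusion absorbs the corruption while rejection discards the zero-bin
evidence for OFF periods, and its estimates move far from the uncorrupted
fit (in our experiments the fitted fraction ON can collapse toward zero).
This asymmetry, not any property of clean data, is why fusion is the
recommended correction.

## Optimization

The maximum-likelihood search runs over the box
$(\sigma_{on}, \sigma_{off}, \rho) \in [0,250]^2 \times [0,300]$ (1/min)
with a self-adaptive differential evolution (jDE, rand/1/bin, per-individual
$F$ and $CR$), followed by a bounded quasi-Newton (L-BFGS-B) polish of the
best population members plus moment-matched starts at assumed
$f_{ON} \in \{0.2, 0.5, 0.8\}$. The polish matters: the telegraph likelihood
has a secondary low-$f_{ON}$/high-$\rho$ mode that can capture a small DE
population, and the multistart refinement resolves it reliably. Defaults
(population 40, ≤250 generations with early stopping after 60 stalled
generations, 2 restarts) complete a $10^4$-cell fit in seconds to tens of
seconds; the benchmark uses a reduced budget (population 15–25, ≤40–80
generations) that with the polish step loses no measurable accuracy at
$10^4$ cells. All randomness is seeded through `fit_control(seed=)`;
identical inputs give identical fits.

Degenerate inputs are flagged rather than hidden: an all-zero dataset drives
$\rho$ to the boundary with likelihood approaching a point mass, and the
result carries `degenerate = TRUE`.

Confidence intervals use the **profile likelihood**: one parameter is fixed
on a log-spaced scan from the estimate toward each bound, the other two are
re-optimized (L-BFGS-B from the global fit), and the interval is the level
set where the profile exceeds the minimum by $\chi^2_{0.95,1}/2 = 1.9207$,
with endpoints refined by geometric bisection. On a quadratic surface this
reproduces $\pm 1.96\,\mathrm{SE}$; an endpoint that reaches the scan bound
is flagged one-sided.

## What the simulator emulates

`simulate_mature_cells()` and `simulate_nascent_cells()` draw exact
stationary samples: the promoter starts in its stationary Bernoulli state,
initiations within ON intervals are laid down as a conditional Poisson
process, and (mature) each initiation survives to the sampling time with its
exponential-lifetime probability over a 40-lifetime window, or (nascent) the
window is exactly $\tau$ so survivors are precisely the bound polymerases.
This removes burn-in bias entirely; positions are elapsed-time fractions and
the trapezoidal signal and ceiling discretization mirror the inference
convention bit-for-bit (`ceiling_bin`, with a $10^{-9}$ guard so gain
rescaling cannot push an exact-integer signal across a bin boundary).

Cell-to-cell (extrinsic) noise on the initiation rate is modeled by
`perturb_initiation_rates()`: each cell keeps one log-normal $\rho'$ with
arithmetic mean $\rho$ and standard deviation $cv\cdot\rho$ for its whole
history — representing post-transcriptional variability that affects mature
but not nascent measurements, which is why the benchmark applies it to the
mature arm only. `simulate_dna_content()` generates the bimodal DNA-stain
mixture for the cell-cycle classifier. What the simulator does **not**
emulate: replication and binomial partitioning during division, S-phase
populations, volume effects, spot-detection noise, or segmentation errors —
so passing tests validate the inference machinery under the stated model,
not robustness to every experimental artifact.

The study conditions baked into defaults are: $d = 1$/min, $\tau = 0.5$ min
for the synthetic benchmark, gene geometry $L_1 = 862$, $L_2 = 2200$ bp
(5′ stem-loop cassette plus gene body; $\tau = 0.785$ min from
$3062\,\mathrm{bp} / 65\,\mathrm{bp\,s^{-1}}$ when the measured elongation
speed is used), $10^4$ cells per synthetic dataset, and external-noise
levels $cv \in \{0, 0.05, 0.10\}$.

## The benchmark

`generate_parameter_grid()` lays an equidistant mesh over
$(\sigma_{off}, \sigma_{on}, \rho) \in (0,150]^2 \times (0,250]$ — points at
$\mathrm{range}\cdot j/m$, $j = 1..m$, zero excluded, endpoint included —
and keeps sets with effective transcription rate
$\rho\,f_{ON} < 100$/min (strict). At $m = 10$ this yields 741 sets; the
exact surviving count depends on the endpoint/zero convention of the mesh,
which is why the convention is configurable and the count is not treated as
a benchmark target. `run_benchmark()` simulates paired mature (optionally
noise-perturbed) and nascent datasets per set, fits both, and records
per-parameter relative errors and their mean (MRE); `binned_median_relative_error()`
summarizes medians in $f_{ON}$ windows $[x\pm0.05]$. Desk-scale runs use
50 grid-sampled sets at $10^4$ cells (the scale at which the nascent-vs-mature
accuracy comparison is directional and stable); the full grid at the same
cell count is a multi-hour computation with identical code paths.

## ACF validation

`normalized_acf()` computes per-trace mean-subtracted autocovariance
normalized by trace variance — the biased (divide-by-$N$) estimator, chosen
for stability at large lags and switchable only by subsetting lags — then
averages curves across traces. Per-trace normalization makes the curve
invariant to gain and offset, exactly the property needed to compare
simulated kinetics against live-cell traces whose absolute intensities vary
cell-to-cell. `acf_ssr()` interpolates a reference curve onto the model lags
and sums squared deviations. Trace defaults (duration 120 min, step
0.1 min) are configurable because published live-cell references rarely
state them.

## Numerical choices and limitations

* Tail tolerance `eps` defaults to $10^{-8}$ everywhere; fits may relax to
  $10^{-6}$ for speed with no visible effect on estimates at $10^4$ cells.
* FSP truncation is adaptive with a hard cap (default 50\,000) that raises
  a named error; likelihood evaluation extends the support to cover every
  observation before lookup.
* Ties between the fused bin and bin conventions are resolved by the
  right-closed rule stated above; `corrupt_low_bins()` reproduces the
  transcription-site misidentification artifact for curation studies.
* The two-state promoter is an idealization: multi-state promoters,
  polymerase volume exclusion, and stochastic elongation are out of scope,
  and parameters for genes with $f_{ON} \to 1$ (notably $\sigma_{off}$ and
  burst size) are intrinsically poorly identified from stationary
  distributions — the benchmark quantifies, rather than hides, this.
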