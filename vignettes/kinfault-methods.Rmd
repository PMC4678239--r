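---
title: "Kinetic-model-based fault localization: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Kinetic-model-based fault localization: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Many diseases trace back to a single malfunctioning component of a signal
transduction pathway: one reaction whose catalysing enzyme is inhibited or
overexpressed, or one preexisting molecule (a species present before
stimulation, such as a receptor or a kinase pool) whose abundance is
abnormal. Given a sampled, noisy time course of one or a few measurable
pathway outputs — a "clinical" profile — and a validated kinetic model of
the pathway, kinfault asks: which single rate constant or initial
concentration, scaled by what fold change, best explains the observed
profile?

The approach is model-based fault diagnosis by exhaustive simulation. Every
candidate single-target perturbation is applied to the model

$$\frac{dx}{dt} = f(x, p, u),$$

with $x$ the species concentrations (nM), $p$ the rate constants and $u$ a
constant stimulus switched on at $t = 0$. Each perturbed model is
integrated, sampled on the clinical grid, and scored against the data; the
candidates are ranked by the score.

## The similarity score S

Let $Y_\mathrm{clinical}$ and $Y_\mathrm{model}$ be the sampled output
profiles stacked into single column vectors (multiple outputs are
concatenated in a fixed order, raw, with no per-output standardisation).
Then

$$S \;=\; \frac{Y_\mathrm{clinical}^{T} Y_\mathrm{model}}
      {\lVert Y_\mathrm{clinical}\rVert\,\lVert Y_\mathrm{model}\rVert}
  \cdot \frac{1}{\tfrac12\left(\bar Y_\mathrm{c}/\bar Y_\mathrm{m} +
        \bar Y_\mathrm{m}/\bar Y_\mathrm{c}\right)},$$

the product of a *shape* term (the cosine of the angle between the two
profiles; 1 for identical shapes) and a *magnitude* term (the reciprocal
symmetrised ratio of the two profile means; 1 for equal means). For
nonnegative profiles $S \in [0, 1]$, $S$ is symmetric, and
$S(y, c\,y) = 2c/(1+c^2)$ — so doubling a profile costs exactly 0.2.
Degenerate inputs (all-zero profile, nonpositive mean) raise an error;
the scanner maps such candidates to $S = 0$ with a warning rather than
silently, so modelling bugs stay visible. Because outputs are stacked raw,
a large-magnitude output dominates the combined score; per-output S values
are therefore also reported in every rank table.

## Oscillation features H, P, N and the R/A factors

For oscillatory outputs a pointwise score can miss shape features, so peaks
are extracted and summarised:

1. all interior local extrema in the analysis window are detected
   (plateaus contribute one extremum at their midpoint; endpoints never
   count);
2. window artifacts are trimmed: a leading minimum and a trailing maximum,
   which cannot belong to complete peak-pairs;
3. $H = \bar H_\mathrm{max} - \bar H_\mathrm{min}$, the mean amplitude;
4. $P = (\bar P_\mathrm{max} + \bar P_\mathrm{min})/2$, the mean period,
   averaging the mean gap between adjacent maxima and between adjacent
   minima, converted to seconds;
5. $R = 2H/P$ (nM/s, the overall steepness of the oscillation) and
   $A = H \cdot P \cdot N$ with $N$ the number of complete (max, min)
   peak-pairs; $A$ is reported in nM·s·10⁶.

When fewer than two maxima or two minima survive trimming, the period is
not estimable and a zeroed record with `defined = FALSE` is returned.
Ranking uses S first in all situations; R and A are confirmatory criteria
that re-order only near-ties (|ΔS| below `tie_epsilon`, default 0.01) by
closeness of (R, A) to the clinical profile's features. A candidate whose
S clearly exceeds another's is never demoted.

### Numerical choices in peak detection

The prominence filter removes ripples by iteratively deleting the adjacent
max/min pair with the smallest value gap until all gaps reach
`prominence_fraction` (default 0.05) of the series' global range; this
preserves type alternation by construction and leaves an analytic
sinusoid's extrema untouched at any sensible setting. Noisy clinical
series are smoothed with a centered moving average before detection.
The default window is 3 samples: at the clinical density of 6 samples per
hour the oscillator's spikes span only a few samples, and a 5-sample
window was found to flatten their amplitude by more than half, corrupting
H and A. Clean model profiles — and noise-free clinical data — are not
smoothed at all, so a noise-free dataset yields features identical to its
generating profile. Both knobs are exposed on `scan_faults()` and
`detect_peaks()`.

## The fault scan

For each candidate (every rate constant for `rate_up`/`rate_down`; every
preexisting molecule for `molecule_up`/`molecule_down`) and every fold in
the grid, the perturbed model is simulated on the clinical grid and
scored; the fold maximising S is kept per candidate. The default up-grid
is 5–100 in steps of 5 plus 200–1000 in steps of 100; the down-grid is the
reciprocals plus the decades 0.1–0.0001. The generating fold need not lie
on the grid: the max-over-grid rule still localises the target, though the
reported best fold is then only the nearest grid surrogate — the method
identifies *which* component malfunctions, not its exact regulation level.

Ties in the rank table are resolved by ascending R/A distance
(`|R_m − R_c|/max(R_c, ε) + |A_m − A_c|/max(A_c, ε)`, ε = 1e−12) and then
by candidate id. Without R/A information (non-oscillatory models) there is
nothing to re-order ties by, and plain descending-S with id tie-break
applies.

### Identifiability limits

Some faults are exactly degenerate: upregulating an inhibitor's
transcription rate or its translation rate produces mathematically
identical output trajectories whenever the mRNA feeds nothing but
translation, because only the product of the two gains is observable from
the protein level. No score can separate such pairs; the rank table shows
them with equal S and the tie-break picks a deterministic representative.
More outputs, or direct mRNA measurements, would be needed to split them.
Near-degeneracies (e.g. the forward and reverse reactions of one binding
step, or two upstream activation steps in series) are separated by S in
the clean limit but can tie under noise — this is where the R/A
confirmation earns its keep.

## The demo models

The package ships two reduced mass-action models written in nM and
seconds, with a constant stimulus held for the whole horizon.

**Steady-state responder** (`build_demo_steady()`, 10 states, 12
reactions, 10 h horizon): a cytokine-receptor/JAK-STAT-like cascade. The
stimulus activates a preexisting free receptor; active receptor
phosphorylates a preexisting precursor transcription factor; the
phospho-form dimerises and translocates (nuclear dimer = output 1); a
preexisting phosphatase recycles the nuclear dimer back to the precursor;
the dimer drives synthesis of an inhibitor (output 2) that reversibly
sequesters the active receptor. Parameters were tuned once so that under
nominal stimulus the nuclear dimer shows a single interior peak
(≈ 42 nM at ≈ 0.6 h) relaxing to a nonzero plateau (≈ 36 nM) and the
inhibitor rises monotonically to its plateau (≈ 48 nM) well inside the
horizon, and then committed; they are the package's fixtures, not fitted
quantities.

**Two-feedback oscillator** (`build_demo_oscillator()`, 13 states, 20
reactions, 15 h horizon): an NF-κB-style architecture with an IκB-type
inhibitor loop (re-sequestration of the factor in cytoplasm and nucleus)
and an A20-type loop (inactivation of the active kinase), plus kinase
recycling. The committed parameters give spike-like relaxation
oscillations of the nuclear factor with period ≈ 2.7–3 h, minima near
zero, and ≥ 3 complete peak-pairs — at clinical sampling — within 15 h.

Both models hold their initial state exactly when the stimulus is zero
(every reaction flux contains either the stimulus or a species that starts
at zero), so all post-stimulation dynamics are attributable to the
stimulus and the perturbation. The total transcription-factor moiety is
conserved by construction and is checked in the tests as an integration
invariant.

Integration uses `deSolve::lsoda` through a compiled mass-action kernel,
with rtol = 1e−8 and atol = 1e−10 nM — tight enough that metric
differences dominate solver error (halving the tolerances moves sampled
outputs by < 1e−5 relative). Negative solver overshoots are clipped to
zero only in reported trajectories, never in the solver state.

## Artificial clinical data

The generator emulates sparse noisy patient measurements from a known
fault: apply the ground-truth perturbation, simulate, sample (default 6
points per hour), then replace every sampled value by a draw from a
Gaussian whose mean is the clean value and whose standard deviation is
`noise_fraction` (default 20%) of it. Noise is independent across time
points and outputs; zero-valued points stay exactly zero. Draws are
clamped at zero by default since concentrations are nonnegative; the
unclamped variant is available and tested, as the clamping convention is a
modelling choice. The representative perturbation for each abnormal
condition is the candidate × fold whose noise-free profile is *least*
similar (lowest S) to the normal profile — one rule covering both the
steady-state case (largest steady-state change) and the oscillatory case
(largest amplitude/period change). Representative fold magnitudes follow
the experiment presets: ×1000 / ×0.001 rates and ×100 / ×0.01 molecules
for the steady demo; ×100 / ×0.0001 rates and ×10 / ×0.01 molecules for
the oscillator.

What this generator does *not* emulate: cell-to-cell parameter
variability, autocorrelated measurement error, missing samples, or
stochastic gene switching. Passing the recovery experiments therefore
shows robustness to independent proportional measurement noise and to
sparse sampling — not to structural model mismatch between patient and
model, which is the harder clinical reality.

## Experiment suite and problem sizes

The noise sweep regenerates clinical data at σ ∈ {20, 40, 60, 80}% of the
per-point mean (10 seeds each by default) and scans each realisation:
median S of the truth decreases with noise while its rank-1 identity is
preserved. The density sweep generates once at 6 points per hour and
thins to divisor densities (no interpolation; non-divisors are an error),
showing that one point per hour still identifies the fault. The bundled
experiments use the full default fold grids (29 up-folds, 30 down-folds)
over all candidates — roughly 350 integrations per steady-model scan and
600 per oscillator scan, a few seconds each on one core; the test suite
and acceptance script run the complete set in a few minutes.

## Interfaces

Models import from and export to SBML Level 3 Version 1 (mass-action
kinetic laws; events, rules, constraints and delays are rejected by name,
and non-mass-action laws are refused rather than misread). Trajectories
and clinical datasets are CSV (`time_h,<output>,...`) with a JSON metadata
sidecar; rank tables are TSV. A thin command-line front end
(`inst/cli/kinfault`) exposes simulate / generate / scan / sweep-noise /
sweep-density / export-sbml over these files.
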