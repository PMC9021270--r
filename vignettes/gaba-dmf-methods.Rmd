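---
title: "Whole-brain dynamic mean field modelling with receptor-driven inhibitory gain"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Whole-brain dynamic mean field modelling with receptor-driven inhibitory gain}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The model

`gabadmf` simulates whole-brain resting-state activity with a dynamic
mean field (DMF) model: each cortical region is a pair of reciprocally
coupled neural masses, one excitatory (NMDA-dominated) and one
inhibitory (GABA-A-dominated), and regions interact through the
excitatory-to-excitatory connections of a structural connectome
$C_{np}$ scaled by a single global coupling parameter $G$.  Per region
$n$, the input currents are

$$I_n^{(E)} = W_E I_0 + w_+ J_{NMDA} S_n^{(E)}
  + G\, J_{NMDA} \sum_p C_{np} S_p^{(E)} - J_n^{FIC} S_n^{(I)},$$
$$I_n^{(I)} = W_I I_0 + J_{NMDA} S_n^{(E)} - S_n^{(I)},$$

rates follow the sigmoidal F--I curve
$F(x) = x / (1 - e^{-d x})$ with $x = m\,g\,(I - I_{thr})$ (the
removable singularity at $x = 0$ is evaluated as its analytic limit
$1/d$), and the synaptic gating variables evolve as

$$\dot S^{(E)} = -S^{(E)}/\tau_{NMDA} + (1 - S^{(E)})\,\gamma\, r^{(E)}
  + \sigma \nu(t), \qquad
  \dot S^{(I)} = -S^{(I)}/\tau_{GABA} + r^{(I)} + \sigma \nu(t).$$

A note on signs: some renderings of these equations print the gating
drift with $+S/\tau$ and $(1+S)$.  Those signs produce divergent
dynamics; the package implements the standard decaying/saturating form
above, which is the form used throughout the mean-field literature this
model descends from, and exposes no option for the divergent variant.
Rates are in Hz and enter the gating drift divided by 1000 (time is
integrated in ms, with $\tau$ in ms), the convention of the reference
implementations; $\gamma = 0.641$ is dimensionless.

Regional inhibitory gain is modulated by a receptor-density map through

$$g_n^{NM} = 1 + s_I\, d_n,$$

where $d_n \in [0,1]$ is the normalised regional density (in the
intended application, benzodiazepine-site binding from flumazenil PET,
z-scored and min--max rescaled) and $s_I \ge 0$ is the inhibitory gain
scaling.  The modulator multiplies the inhibitory gain factor $g_I$
inside the inhibitory F--I curve only; $s_I = 0$ recovers the
unmodulated model.

## Direction of the gain effect

A property worth stating explicitly because it is counter-intuitive:
at the feedback-inhibition-balanced working point, the inhibitory
population's input current sits *below* its threshold
($I^{(I)} \approx 0.25$ nA vs. $I_{thr}^{(I)} = 0.288$ nA).  For
subthreshold currents ($x < 0$) the F--I value $x/(1-e^{-d m x})$
*decreases* as the multiplicative gain $m$ grows, so raising $s_I$
suppresses inhibitory firing, *disinhibits* the excitatory population,
and raises its stationary rate; re-tuning feedback inhibition after
gain modulation therefore increases $J^{FIC}$.  The package's tests
assert this — the direction the printed equations and constants
actually produce — rather than the naive expectation that more
inhibitory gain always means less excitation.

## Feedback inhibition control (FIC)

$J_n^{FIC}$ is tuned so that every region's long-run mean excitatory
rate sits at approximately 3 Hz.  The tuner is a greedy proportional
controller: simulate a round (default 10 s of model time, continuing
from the previous round's state), measure per-region mean rates, update
$J \leftarrow \max(0,\, J + \eta\,(\langle r_E\rangle - 3)/3)$ with
$\eta = 0.01$ nA, and stop when every region is within $\pm 0.5$ Hz of
target (at most 200 rounds; non-convergence is an error that reports
the worst region).  Tuning is done once per calibrated model and held
fixed across $s_I$ sweeps and connectome replacement; re-tuning is
available by calling `tune_fic()` again on the modified model.

## Integration

The coupled stochastic equations are integrated with Euler--Maruyama at
`dt = 0.1` ms by default (configurable), with gating clipped to
$[0,1]$ after every step and a default burn-in of 10 s discarded.  The
integrator is compiled code; the noise stream is an internal
xoshiro256++ generator seeded by the user-supplied integer, so
trajectories are bitwise reproducible and independent of R's RNG state.
A pure-R single-step reference (`dmf_step()`) exists and the test suite
checks that the compiled trajectory matches it in the deterministic
limit.  With $\sigma = 0$, halving `dt` moves the 10 s endpoint by less
than $10^{-3}$ on the test fixture.

# Haemodynamics and filtering

Excitatory rate traces (bin-averaged to 1 ms) drive a
Balloon--Windkessel model per region: vasodilatory signal $s$, inflow
$f$, venous volume $v$ and deoxyhaemoglobin $q$, with the canonical
constants $\kappa = 0.65\,s^{-1}$, $\gamma_h = 0.41\,s^{-1}$,
$\tau_h = 0.98$ s, $\alpha = 0.32$, $\rho = 0.34$, $V_0 = 0.02$,
$k_1 = 7\rho$, $k_2 = 2$, $k_3 = 2\rho - 0.2$ (all configurable via
`bw_parameters()`).  The neural drive is the rate normalised to its own
baseline, $z = r/\langle r\rangle - 1$, so the resting model sits
exactly at the haemodynamic fixed point $(0, 1, 1, 1)$ and produces
zero BOLD; which neural variable drives the haemodynamics (rate vs.
synaptic activity) is a convention, and this one is chosen so that the
spec of the resting state is exact.  Integration is Euler at the trace
resolution (1 ms).  One numerical guard: sustained near-silent epochs
(`z` close to its lower bound $-1$) give the inflow ODE a negative
fixed point, and an unguarded integrator blows up once $f$ crosses zero
inside $(1-\rho)^{1/f}$; since inflow is physically positive, $f$ is
floored at $10^{-4}$.  Volume and deoxyhaemoglobin going non-positive
still raise an error with the offending region and step.

BOLD is sampled once per TR (2 s in all built-in experiment defaults)
and band-pass filtered to 0.008--0.09 Hz with a zero-phase
(forward--backward) order-2 Butterworth filter after demeaning; any
residual DC is removed so filtered signals have negligible mean.

# FCD and model fitting

Functional connectivity dynamics are computed exactly as in the
sliding-window convention: Pearson correlation matrices of the regional
BOLD inside windows of 30 TRs advanced in steps of 3 TRs, then Pearson
correlation between the vectorised upper triangles of every window
pair, giving a window-by-window FCD matrix.  The *FCD sample* is the
upper triangle of that matrix together with each entry's window lag
$|i-j|$; by default all pairs enter the sample (including overlapping
windows — no exclusion is applied unless `exclude_overlap = TRUE`), and
the raw correlations are used without Fisher transformation.

Model fit is the two-sample Kolmogorov--Smirnov distance between
simulated and empirical FCD samples (sup-norm ECDF difference on raw
values, no binning).  A Peacock-style two-dimensional variant over
(value, lag) pairs is provided for sensitivity to the temporal
arrangement of FC similarity; it scans all four quadrant orientations
at every data point of both samples.

Calibration sweeps follow the study design: `sweep_g()` evaluates $G$
over 0.1--2.5 in steps of 0.1 by default, re-tuning FIC at every grid
value (physically required, since the balanced $J$ depends on $G$) and
scoring `n_sims` seeded simulations against the empirical sample;
`sweep_si()` holds the calibrated model fixed and evaluates $s_I$ over
0--1 in steps of 0.02 with $n = 10$ simulations per value by default.
The optimum is the grid value minimising the mean KS distance, with
ties broken to the smaller parameter and a grid value required to keep
at least 80% of its simulations (numerical blow-ups are excluded and
counted).  `evaluate_model()` generates $n = 100$ simulations by
default and compares their KS distances to two empirical conditions
with a permutation-based pooled-variance t-test (10,000 permutations,
add-one p estimator) plus Cohen's d and Hedges' g.

# Connectome handling

- **Consensus**: an edge survives only when a *strict* majority of
  subjects (> half; ties at exactly half drop the edge) have it
  non-zero, in which case its weight is the mean over the subjects with
  non-zero weight.
- **Random null**: Maslov--Sneppen double-edge swaps (default 10
  attempted swaps per edge) preserve the degree sequence; the original
  weight multiset is then randomly reassigned to the rewired edges.
  Edge count, total weight, weight multiset, degree sequence — all
  preserved exactly.
- **Lattice null**: the same swap machinery, accepting a swap only when
  it strictly reduces the summed ring distance of the two edges, with
  regions ordered on a ring by label order.  Weights travel with their
  edges.
- **Scaling**: before simulation the connectome is rescaled so its
  maximum entry is 0.2 (configurable `sc_max`).  Tract-strength units
  are arbitrary and $G$ absorbs the scale; fixing the maximum makes $G$
  values comparable across connectomes.

Receptor-map surrogates preserve spatial autocorrelation by variogram
matching: candidate maps are Gaussian-kernel-smoothed white-noise
fields over the region coordinates (kernel widths drawn from a grid of
inter-region distance quantiles), rank-remapped onto the original value
multiset, and scored by the mean absolute deviation between their
distance-binned semivariogram (25 bins) and the original's; the best of
`n_candidates = 100` wins.  The uniform control sets every region to
the mean of the normalised distribution.  The shuffled control
permutes the already-normalised values (no re-normalisation after
permutation).

# Synthetic fixtures

Nothing in the package requires external data; the `fixture_spec()`
generators emulate the statistical structure of the intended inputs:

- *Connectome*: regions placed at random on a sphere of radius 70 mm,
  the closest 30% of pairs connected with weights $e^{-0.05\,d}$ (an
  exponential distance rule), so weights fall with distance and lattice
  vs. random nulls are topologically distinguishable.  Regions are
  labelled in azimuthal order, so the lattice null's ring order tracks
  spatial adjacency; with arbitrary label order a ring lattice would
  just be another spatial randomisation and the lattice/random
  contrast would collapse.
- *Cohort*: per-subject multiplicative log-normal weight noise
  (SD 0.2) and independent edge dropout (probability 0.2), exercising
  the strict-majority consensus rule.
- *Receptor map*: Gaussian-kernel-smoothed noise (30 mm kernel) over
  the region coordinates, normalised like the PET map.
- *Pseudo-empirical BOLD*: the model itself run at known parameters
  through the full rate → Balloon--Windkessel → band-pass chain, one
  seed per subject, at the scan lengths of the emulated conditions
  (250 TRs for anaesthesia-style scans, 155 for clinical-style scans).

The pseudo-empirical route is circular *by design*: recovery tests
validate the inference machinery (can the sweep find the parameters
that generated the data?), not the biology.  What passing tests do
not show: that the model fits real fMRI, that the fixture connectome
is brain-like beyond its distance rule, or that receptor maps measured
by PET behave like smoothed noise.

# Problem sizes used by the test suite

The package's own experiments are exercised at deliberately reduced
scale so the whole suite runs on a laptop: 20-region fixtures for the
structural machinery and the $G$ and $s_I$ recovery sweeps (coarse
grids, 120-TR scans), a 34-region fixture for the
connectome-replacement experiment (150-TR scans, 10-subject
pseudo-empirical targets, 50 simulations per evaluation), 68 regions
(the parcellation size of the intended application) for the
firing-rate acceptance run, 5 simulations per sweep grid value, and
`dt = 0.2` ms for the sweep-based experiments (`dt` convergence is
itself tested).  The defaults of every function remain at the full
study settings (G grid 0.1--2.5 by 0.1, s_I grid 0--1 by 0.02, 10
sweep simulations, 100 evaluation simulations, 250 TRs, `dt = 0.1`
ms).

Properties established during development shape what these
experiments can and cannot resolve, and are worth knowing when
designing studies with this package:

- Per-simulation FCD distributions are highly variable at small
  network sizes.  $G$ — a strong lever on the dynamics — is
  recoverable at 20 regions, and the replacement contrast resolves at
  34 regions with well-pooled targets, but the inhibitory-gain
  landscape is shallower than the per-simulation KS noise at these
  sizes.
- The $s_I$ fitting landscape of the self-consistency experiment is
  nearly flat near 0 (gains $1 + s_I d$ barely move the dynamics for
  small $s_I$) and saturates above roughly $0.3$, where the
  (subthreshold) inhibitory population is largely silenced and the
  FCD distribution stops changing.  Tight recovery of a generating
  $s_I$ by the mean-KS argmin is therefore beyond desk scale: the
  corresponding recovery test in the package's suite states the
  intended $\pm 0.06$ band and is expected to fail at this problem
  size, documenting the resolution limit rather than hiding it.

# Known limitations

- No conduction delays, no excitatory-gain modulation variant, no
  spiking-level simulation.
- The Balloon--Windkessel drive convention (normalised rate) is one of
  several in use; absolute BOLD amplitudes are not comparable across
  conventions, though band-passed FCD statistics are robust to it.
- The lattice null optimises ring distance in label order; for
  parcellations whose labels are not spatially ordered, the resulting
  lattice is relative to that arbitrary ring.
- Permutation p-values are lower-bounded by 1/(n_perm + 1).
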