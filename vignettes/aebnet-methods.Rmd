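---
title: "Methods: directed theta-band network analysis for action-effect binding EEG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: directed theta-band network analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aebnet)
```

# Scope and model of the data

`aebnet` implements an analysis chain for studying how cortical regions
communicate in the theta band while people form and retrieve action-effect
bindings: the association between a motor act and the sensory effect it
produces. The experimental paradigm it targets is a forced-choice task in
which a colored cue instructs a keypress and correct responses immediately
trigger a flickering visual "action effect" (4.5 or 8 Hz), so that
stimulus-locked steady-state visual evoked potentials (SSVEPs) tag the
processing of the effect. Three successive 1000 ms analysis phases carry the
cognitive interpretation: *action planning* (0--1000 ms after cue onset),
*standby* (1000--2000 ms after cue onset) and *perception* (0--1000 ms after
action-effect onset).

The chain is: sensor EEG → preprocessing (resample to 256 Hz, 0.5--40 Hz
band-pass, epoching) → Morlet time-frequency contrasts of the two measured
frequencies under FDR control → DICS source localization of 4.5 Hz activity
with DBSCAN-based region-of-interest (ROI) extraction → LCMV virtual-sensor
time series for the three ROIs (anterior temporal lobe, ATL; insular cortex,
IC; inferior frontal cortex, IFC) → a neural-network nonlinear multivariate
autoregressive estimator of directed linear and nonlinear connectivity →
circular time-shift surrogate significance and a paired t / FDR / Cohen's
*d* / Bayes-factor report of bidirectional asymmetries.

Because no public recording accompanies this design, the package ships a
synthetic-data generator with known ground truth; every stage is validated
against that truth or against closed-form oracles.

# The synthetic-data generator

`simulate_trial_events()` draws the trial timeline (fixation 2000 ms, cue
2000 ms, response window 1000 ms, effect 2000 ms; 300 trials with 150 per
flicker frequency by default; accuracy 0.97). `simulate_source_dynamics()`
integrates a K-node nonlinear vector autoregression

$$x_i(t) = \sum_j \sum_{k=1}^{p} a_{ijk}\, x_j(t-k) + \sum_{\text{nl terms} \to i} g\, \phi\!\big(x_{j'}(t-\ell)\big) + d_i(t) + \varepsilon_i(t),$$

with nonlinear forms $\phi \in \{x^2,\; x \cdot y,\; \tanh x\}$ chosen to
span even, cross-term and saturating interactions. Stationarity of the
linear part is enforced by requiring the companion-matrix spectral radius to
be below 1; the emitted adjacency matrices are exactly the support of the
nonzero couplings. The default model order is $p = 3$ at 256 Hz, which
covers directed delays up to ~12 ms without inflating the design matrix.

Design choices a user should know about, with reasons:

* **Theta drive.** The optional 4.5 Hz oscillatory drive $d_i(t)$ uses a
  per-node phase random walk (diffusion 2 rad²/s, ~0.3 Hz linewidth) rather
  than a fixed sinusoid. An endogenous rhythm is not phase-locked to the
  stimulus, and a fixed-phase drive would interfere coherently with the
  SSVEP tag for a whole session, biasing per-subject tag amplitudes; it
  would also make all sources mutually coherent, which defeats beamformer
  separation for reasons unrelated to the head model. Inter-node coherence
  should come from the coupling terms.
* **Sensor noise** is 1/f-shaped Gaussian (spectral exponent 1) plus a
  stationary alpha-band (8--13 Hz) component of equal amplitude. The alpha
  bump matters: without it the baseline power near 8 Hz is so small that the
  *relative* power change at the 8 Hz control frequency is dominated by the
  4.5 Hz tag's first harmonic (9 Hz) leaking through the wavelet bandwidth,
  inverting the tagging contrast. Real resting EEG always carries an alpha
  floor.
* **SSVEP** is a pure sinusoid at the trial's flicker frequency plus a first
  harmonic 6 dB down, injected at the sensors with the largest gain to the
  occipital voxel patch, only during the action-effect interval of correct
  trials. `snr` is defined as tag amplitude over noise SD, so `snr = 3`
  realizes a tag at three times the noise SD.
* **Toy head model.** Sensors sit on a Fibonacci lattice over the upper
  hemisphere of a 10 cm sphere; voxels fill a regular grid; gains fall off
  with inverse-square distance and each column is normalized to unit L2
  norm, so beamformer maps carry no depth bias by construction. Labels
  partition the grid into ATL / IC / IFC / OCC stand-ins by nearest region
  seed. This is deliberately not a BEM/FEM model; it gives smooth,
  full-rank, non-collinear leadfields that make localization errors
  attributable to the algorithms, not to tissue modeling.
* **Condition effect.** `study_coupling_network()` makes the cross-coupling
  of one pair (ATL--IFC by default) asymmetric in one phase (perception by
  default), with the asymmetric direction reversed between the "placebo" and
  "mph" conditions — a minimal, fully known analogue of a pharmacological
  reversal of directed-communication asymmetry. Everything else is
  symmetric, so any flagged asymmetry outside the manipulated phase is a
  false positive by construction.

What the generator does **not** emulate: ocular/muscle artifacts, volume
conduction through realistic tissue, bad channels, non-stationary coupling
within a phase, or between-subject anatomical variability. Passing tests
therefore demonstrate correctness of the algorithms under clean,
well-specified conditions, not robustness to real-world artifact structure.

# Preprocessing

Resampling is FFT-domain: the spectrum is truncated at the new Nyquist
(an ideal anti-aliasing low-pass) on a rational p/q grid, which preserves
in-band amplitude to well under 1%. Event samples rescale by the rate ratio
and round half-to-even. The band-pass is a 5th-order Butterworth applied
forward-backward (zero phase); at this order the 0.5--40 Hz band leaves a
60 Hz tone below 0.5% RMS while 10 Hz passes within 0.02%. Epochs are
half-open sample windows `[start, end)`; trials whose window leaves the
record are dropped and counted. BrainVision I/O supports the multiplexed
and vectorized binary orientations in IEEE float-32 and int-16, always
returning microvolt.

# Time-frequency analysis

Morlet wavelets use $\sigma_t = n_\text{cycles}/(2\pi f)$ with 5 cycles by
default and the kernel truncated at $\pm 3\sigma_t$. The truncation is the
wavelet "length" parameter; it implies an amplitude ripple floor of order
$10^{-3}$ on perfectly stationary input, which is why exactness assertions
in the tests use that floor rather than machine precision. Power is
normalized so a unit-amplitude sinusoid at a wavelet's centre frequency has
power 1. Relative power change divides by the mean baseline power
(cue-locked −350 to −150 ms in the standard analysis; endpoints inclusive
at sample resolution).

The pointwise contrast runs a two-sided paired *t*-test at every
(electrode, time) point between the measured 4.5 Hz and 8 Hz relative power
within the 4.5 Hz-flicker condition, with Benjamini--Hochberg correction
applied jointly across all points of the map. Points with zero within-pair
variance are reported as undefined and excluded from the FDR family rather
than assigned p = 0. One consequence of map-wide FDR worth stating plainly:
when a large part of the map carries true effects, the truly-null part is
*expected* to contribute up to the nominal q (5%) of the discoveries. The
package's end-to-end checks therefore require the baseline interval's share
of discoveries to stay at that noise floor, not to be literally zero.

# Beamforming

The cross-spectral density at the analysis frequency is the trial average
of outer products of Hann-tapered Fourier coefficients (Hermitian and PSD
by construction; the window must span at least two cycles). DICS uses the
real part of the CSD with diagonal loading
$C_\text{reg} = \mathrm{Re}(C) + \lambda\,\overline{\mathrm{diag}}\,I$
($\lambda$ = 5% by default — the main free parameter of the source step)
and the unit-gain minimum-variance filter
$w = C_\text{reg}^{-1} l / (l^\top C_\text{reg}^{-1} l)$; LCMV applies the
same filter form to the time-domain covariance and averages sign-aligned
voxel series within an ROI. Thresholding keeps the top
$\lceil 0.03\,V \rceil$ voxels (ties at the cut all included), DBSCAN
(classic core/border/noise semantics; eps = 1.5 grid spacings,
min_samples = 3) clusters them, and clusters are consolidated into ROIs by
the majority of their voxel labels, ties broken lexicographically and
logged, subcortical-labeled voxels dropped. The label-majority rule is a
deterministic replacement for manual anatomical grouping; it is the one
step of the chain where a human judgement was replaced by a rule, and it is
surfaced in the ROI provenance table.

Two limitations are inherent and visible in the demo workflow: beamformers
merge or displace *coherent* sources, and a top-3% threshold on a small
grid can cover only the dominant source's neighborhood, leaving some ROIs
empty; the workflow then falls back to label-centre voxels and says so.

# Directed connectivity

The estimator fits a single-hidden-layer tanh network to predict
$x(t) \in \mathbb{R}^K$ from the channel-major lag embedding
$z_t = (x_1(t-1..p), \dots, x_K(t-1..p))$, z-scored with train-split
statistics. Training is full-batch BFGS with analytic gradients, a fixed
iteration budget (default 200), deterministic seeded initialization, and a
contiguous (not shuffled) train/test split (80/20) that respects temporal
dependence. Per-channel MSE and $R^2$ on both splits are stored with the
model; a mean test $R^2$ below 0.1 flags the model rather than silently
passing it downstream. Trials within a subject/condition/phase are demeaned
and concatenated, with embedding rows that straddle trial boundaries
dropped.

Writing $u_h(z) = W^{in}_h z + b_h$ for the hidden pre-activations, the
first-order Taylor expansion around the z-scored mean $z = 0$ gives the
global linear map

$$A_{i,(j,k)} = \sum_h W^{out}_{ih}\,\mathrm{sech}^2(b_h)\,W^{in}_{h,(j,k)},$$

and the nonlinear component is defined exactly as the residual
$f(z) - Az - f(0)$, so the decomposition identity holds at every point to
machine precision (a unit test asserts $10^{-10}$). The directed edge
statistics are:

* linear: $L_{j \to i} = \mathrm{mean}_t\,\lvert \sum_k A_{i,(j,k)}
  x_j(t-k) \rvert$ — the time-averaged magnitude of channel *j*'s
  first-order contribution to predicting channel *i*;
* nonlinear: $NL_{j \to i} = \mathrm{mean}_{t,k}\,\lvert
  J_{i,(j,k)}(z_t) - A_{i,(j,k)} \rvert$ with
  $J_{i,(j,k)}(z) = \sum_h W^{out}_{ih}\,\mathrm{sech}^2(u_h(z))\,
  W^{in}_{h,(j,k)}$ — the time-averaged deviation of the instantaneous
  sensitivity from the global linear term.

These aggregation formulas are this package's operationalization of the
linear/nonlinear split; absolute magnitudes are therefore comparable within
an analysis but are not expected to match any particular published scale —
the comparative structure (which direction is stronger, which edges exist)
is the contract, and that is what the acceptance checks test.

Numerical choices: 10 hidden units by default (3 ROIs × 3 lags = 9 inputs);
weight decay $10^{-3}$. The decay value is the estimator's bias-variance
dial and was chosen so that on *purely linear* VAR data the hallucinated
nonlinear share stays below 15% of the linear estimate on true edges
(at $10^{-4}$ it reaches 20% on single seeds) while edge-ranking AUC on
mixed linear/quadratic networks remains 1.0 and the AR(1) benchmark attains
its theoretical $R^2 = a^2$. Z-scoring makes both edge statistics invariant
to per-channel rescaling of the raw input (verified to 2%).

# Surrogate significance and group inference

The circular time-shift surrogate divides each series into consecutive
windows of half a cycle of the lowest frequency (round(fs/9) samples at
4.5 Hz), and circularly shifts each channel within each window by an
independent uniform amount; each window's sample multiset — hence its mean,
variance and marginal distribution — is preserved exactly, while
cross-channel and cross-window dependence is destroyed. With identical
network configuration, the observed edge value is compared with the 95th
percentile (type-7, linear interpolation) of 100 surrogate values; a
divergent surrogate fit is resampled once, and a second failure is an
error. Calibration on independent-channel null data lands within sampling
error of the nominal 5% per-edge false-positive rate.

Group-level asymmetry inference compares the two directions of each ROI
pair across subjects with a paired two-sided *t*-test; zero-variance
differences are undefined and excluded from the FDR family. The FDR family
is the nine bidirectional comparisons within one linearity × condition
analysis. Effect sizes use the paired identity $d = |t|/\sqrt{n}$, and the
Bayes factor is the default-prior (JZS) BF10 with effect-size prior
Cauchy$(0, \sqrt{2}/2)$, evaluated by adaptive quadrature of the
inverse-gamma scale-mixture form in log space (relative error well under
$10^{-6}$; strictly monotone in $|t|$). The prior scale was validated
against multiple published (t, BF10) pairs before being frozen: recomputed
values agree within ~1% — the level explained by rounding of the printed
*t* — across three orders of magnitude of BF10. Evidence labels follow
Jeffreys bands on $\max(\text{BF10}, 1/\text{BF10})$ (1--3 anecdotal, 3--10
moderate, 10--30 strong, 30--100 very strong, >100 extreme), with BF10 = 1
labeled "anecdotal H0".

# Problem sizes used in validation

The validation suite runs the estimator at $n = 5000$ samples (20 seeds)
for edge-ranking recovery; the surrogate calibration at 20 surrogates × 20
seeds on 1200-sample series with a 6-hidden-unit, order-2 configuration;
the tagging contrast at 6 synthetic subjects × 8 trials × 20 seeds; and the
group report at 12 subjects × 2 conditions × 3 phases × 1500 samples × 20
seeds. These sizes were chosen so each property is tested with clear
statistical margin while a full run of the suite stays in the minutes
range; all of them are ordinary function arguments, so larger replications
are one-line changes.

# Known limitations

* The linear/nonlinear edge statistics quantify *predictive contribution
  magnitude*, not information flow in bits; like all MVAR-family measures
  they can be distorted by unobserved common drivers.
* The surrogate preserves within-window autocorrelation only up to the
  rotation seam, so surrogate fits are very slightly less predictable than
  the original; at the tested window lengths this bias is far below the
  null spread, but extremely short windows would amplify it.
* Beamformer steps assume the toy head's unit-norm, fixed-orientation
  leadfields; no depth-bias normalization variants or vector orientations
  are implemented.
* The generator's accuracy model is Bernoulli per trial; there is no
  learning curve across trials, and incorrect trials simply lack the
  action effect.
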