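---
title: "Simulating analog-to-feature conversion with non-uniform wavelet sampling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating analog-to-feature conversion with non-uniform wavelet sampling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Wireless biomedical sensors (ECG patches, inertial units for activity
recognition) spend most of their energy budget transmitting raw samples to
an aggregator. When the downstream task is classification — is this
heartbeat arrhythmic? is the wearer walking or sitting? — most of that
Nyquist-rate sample stream is irrelevant. An analog-to-feature (A2F)
converter inverts the architecture: a handful of task-relevant scalar
features is extracted *in the analog domain*, and only those features (or
only the classification result) are digitized and transmitted.

`nuws` is a software simulator of such a converter. It models the feature
extraction, the hardware-aware feature selection that decides *which*
features the circuit must implement, the small neural-network classifier
consuming them, and the energy economics of the whole communication chain.

## Non-uniform wavelet sampling

The extraction primitive is a wavelet inner product. For a windowed signal
$x(t)$ and a wavelet $\psi_{f_o,t_s,\Delta t}$ parameterized by oscillation
frequency $f_o$, support duration $t_s$ and time shift $\Delta t$, the
feature is

$$F(f_o, t_s, \Delta t) = \int_{\Delta t}^{\Delta t + t_s}
  x(t)\,\psi_{f_o,t_s,\Delta t}(t)\,dt .$$

Unlike the classical wavelet transform, the three parameters are
independent: support and frequency are decoupled, which is what makes the
dictionary rich enough for classification while each atom stays trivially
realizable as a mixer plus integrator. In hardware this is a multiplication
of the analog signal by a generated ±1 square wave followed by a Gm-C
integrator; in the simulator it is a Riemann sum scaled by $1/f_s$
(`extractFeature()`). The $1/f_s$ convention gives features in
signal-units·seconds; the scale is irrelevant to any classifier that
standardizes its inputs, but fixing it keeps every number in the package
reproducible.

## Dictionary enumeration

`haarDictionary(windowLen, fs)` enumerates the admissible Haar atoms for a
power-of-two window:

* periods double from one oscillation per window down to 2 samples (half a
  period can never be shorter than one sampling interval, so $f_o$ stops at
  $f_s/2$);
* for each period, supports double from one period up to the full window;
* shifts are restricted to multiples of the support, so atoms sharing
  $(f_o, t_s)$ never overlap.

For an $N$-sample window the count is $\sum_{P} (2N/P - 1)$ over periods
$P = 2, 4, \dots, N$: 502 atoms for $N = 256$ and 247 for $N = 128$. The
ordering (descending period, ascending support, ascending shift, constant
atom last) is deterministic, and serialization round-trips bit-exactly so a
dictionary index is a stable feature identifier.

Two further families are provided:

* the **constant wavelet** — all ones across the window. A genuine wavelet
  is zero-mean, so every Haar feature annihilates a constant signal; static
  activities (sitting, standing, laying) are exactly such signals and are
  inseparable without the window mean. The constant atom is modeled as its
  own family rather than a degenerate Haar because downstream accounting
  differs: it needs no wavelet generator (direct integration) and its
  extractor serves nothing else within the window.
* **Gabor atoms** — real part of a Gaussian-windowed sinusoid, de-meaned
  over the support. The published account does not state the enumeration
  that produced its Gabor dictionary sizes, so `gaborDictionary()` is
  config-driven (default phase grid $\{0, \pi/2\}$, envelope
  $\sigma = t_s/6$) and no Gabor count is treated as ground truth.

Haar polarity starts at +1; a `polarity` flag exists because the convention
is arbitrary — a sign flip propagates linearly into the features and is
absorbed by the classifier.

## Feature selection under hardware constraints

With ~500–1500 candidate features, a wrapper search over all of them is
quadratic and wasteful. The pipeline therefore:

1. **Filters by information gain** (`preselectTopK()`, default top 100).
   Each feature is discretized into 12 equal-width bins over its observed
   range and scored by the entropy drop of the class label, in bits.
   Twelve bins and the equal-width rule follow the reference protocol;
   equal-width binning also makes the score invariant under positive affine
   rescaling of a feature.
2. **Runs a sequential forward search** (SFS) around the classifier. At
   each step, a fresh network is trained for every remaining candidate
   joined to the current set, and the best accuracy wins. Ties go to the
   better filter rank — deterministic, and it favors stronger marginal
   evidence. Three variants:
   * `sfsBasic()` — unconstrained;
   * `sfsAdapted()` — a candidate is admissible only if the augmented set
     still fits on at most `nExtMax` parallel extractors;
   * `sfsOptimized()` — scores candidates by
     $\mathrm{acc} - \lambda\, E(S \cup \{F\}) / E_{\mathrm{ref}}$.
     No published formula exists for the energy-aware criterion, so the
     package uses this linear penalty with configurable $\lambda$ and
     normalizer ($E_{\mathrm{ref}}$ defaults to the cost of a full-window
     feature). With $\lambda = 0$ the scores equal the accuracies and the
     search reproduces `sfsAdapted()` bit-exactly — a tested contract.

**Extractor scheduling.** One hardware extractor can serve several features
whose supports do not overlap inside the window. `scheduleExtractors()`
sorts supports by start time and assigns each to the first extractor free
at that instant. For interval graphs this greedy coloring is optimal, so
the returned count is the true minimum (the maximum overlap depth); the
test suite cross-checks it against an exhaustive assignment search on small
instances. Admissibility in the adapted search is evaluated on this
minimum, not on any fixed earlier assignment. Extractors are
channel-agnostic by default (the hardware places a multiplexer at each
extractor input); scheduling is per-window, so the count is also the
converter's required parallelism.

**Seed discipline.** Network weights are initialized randomly, and which
feature wins a step depends on it. Every candidate evaluation therefore
derives its seed deterministically from (base seed, step, candidate rank),
making whole selections bit-reproducible — the property the λ = 0 contract
and the regression tests rely on.

**Evaluation split.** The original protocol scores candidate subsets on the
test set. That leaks the test set into model selection, so the default here
(`evalPolicy = "validation"`) carves a stratified hold-out (default 25%)
from the training rows and scores on it; `evalPolicy = "test"` restores the
historical behavior for comparison. Final metrics are always computed on
the untouched test split.

## The classifier

A single-hidden-layer feedforward network (10 units for the binary ECG
task, 20 for six-class activity recognition) with softmax outputs,
uniform random initial weights in ±0.05, fitted by `nnet` (BFGS on the
cross-entropy). The reference implementation used ReLU hidden units and
Adam; neither choice is load-bearing — the search only needs a consistent,
deterministic inner evaluator — and `nnet`'s logistic hidden layer with a
full-batch quasi-Newton fit is the canonical small-network choice in R.
Parameter counts (`countParameters()`) are backend-independent
(weights + biases over consecutive layers: 466 for 16–20–6, 486 for
17–20–6) and are verified against the fitted object's weight vector.

Inside the SFS loop the network trains with a reduced iteration budget
(60–100) and the final refit uses a larger one (300 in the tests, 1500 by
default in `classifierSpec()`); the inner loop only needs a stable ranking
of candidate subsets, not a fully converged model.

Metrics come from the confusion matrix: accuracy, and for binary problems
sensitivity, specificity and the Matthews correlation coefficient (MCC),
with the second factor level as the positive class. An MCC with a zero
denominator factor is reported as 0 and flagged degenerate — the common
convention. The zero-rule baseline returns the majority-class share of the
evaluated set.

## Quantization

The analog features must be digitized; `quantizeFeatures()` models a
fixed-range ADC. Per feature, the range $[\min, \max]$ is learned on the
training split (the range policy is unstated in the reference; a
train-calibrated per-feature range mirrors a realistic programmable-gain
front end), levels are uniform with spacing $(\max-\min)/(2^b - 1)$
(mid-tread: the extremes are representable), out-of-range test values are
clipped, and the map is idempotent. Standardization for the classifier is
applied after quantization, as the digitized features are what the network
would consume.

## Energy model

Per-feature extraction energy is

$$E_{\mathrm{feat}} = (P_{\mathrm{amp}} + P_{\mathrm{int}} +
  P_{\mathrm{wavelet}})\cdot \frac{t_s}{f_s} + \frac{P_{\mathrm{ADC}}}{F_s},$$

with the support duration $t_s/f_s$ as the active time and one ADC
conversion per feature. (The published formula reuses the symbol
$\Delta t$ for this duration while the extraction formula uses it for the
shift; the energy model binds it to the support, as its prose states.)
Constant-family features drop the $P_{\mathrm{wavelet}}$ term — direct
integration needs no generator. $P_{\mathrm{wavelet}}$ itself has no
published value (it is cited to prior silicon); `powerBudget()` therefore
refuses to default it, and every report echoes the value used.

Chain comparisons over a signal duration $T$:

* **Nyquist** — continuous amplifier + anti-aliasing filter + ADC
  (5.04 + 0.7 + 0.3 µW = 6.04 µW per channel) and every sample transmitted
  (3.7 nJ/bit ⇒ 37 nJ per 10-bit sample);
* **A2I** (compressive sampling) — 0.9 µW acquisition, transmission divided
  by the compression ratio (4), reconstruction cost excluded;
* **A2F** — per-window feature energies times the number of whole windows
  in $T$ (cadence: contiguous 0.711 s ECG windows; one inertial window per
  1.28 s given the 50% overlap), features transmitted at ADC precision, or,
  with in-sensor classification, only the result bits plus
  $P_{\mathrm{class}} t_{\mathrm{class}}$ per window.

An optional shared-amplifier mode charges $P_{\mathrm{amp}}$ over the union
of supports per signal instead of per feature (one amplification stage per
signal is never active twice at once); it can only lower the total, which
is tested. The published headline chain ratios are not reproduced as fixed
targets because they depend on the unpublished $P_{\mathrm{wavelet}}$ and a
stochastic selection; the package computes them for any configured budget.
Whether the reference prorated fractional windows over 10 s is unstated;
`chainA2f()` counts whole windows.

## Synthetic data: what it does and does not emulate

The generators make the full pipeline testable offline.

* `simulateEcg()` — 256-sample, 360 Hz windows, one beat per window with
  the R peak at sample 100, 85/15 normal/abnormal prior, stratified 70/30
  split. Normal beats are a P–QRS–T bump train; abnormal beats widen and
  attenuate the QRS and add a shifted secondary peak — an ectopic-like
  morphology detectable by short-support atoms near the QRS. Defaults:
  600 windows, additive noise sd 0.05 and amplitude jitter sd 0.05 against
  a unit QRS.
* `simulateInertial()` — 128-sample, 50 Hz, 6-channel windows, six
  balanced classes. Static classes are distinct gravity-projection
  constants (plus noise); dynamic classes oscillate at distinct
  fundamentals placed *on the Haar period lattice* (periods 32, 64, 16
  samples) with distinct amplitudes, a 20% second harmonic and a small
  phase jitter (sd 0.4 rad).

The class structures are chosen so that separability is provable by
construction — static classes are separable only through the constant
wavelet (every zero-mean feature collapses to noise on them), dynamic
classes through matching-period Haar features — rather than tuned until a
search happens to succeed. Consequences worth keeping in mind:

* passing end-to-end tests show the *machinery* (dictionary → extraction →
  filter → constrained search → classifier) recovers structure it is
  designed to see; they say nothing about accuracy on real recordings,
  where morphology varies across subjects, windows are imperfectly
  aligned, and noise is not white;
* real inertial windows are not phase-aligned to the gait cycle; the small
  phase jitter is a simplification that keeps single-atom features
  informative;
* no baseline wander, electrode artifacts, sensor placement or subject
  heterogeneity is modeled.

Problem sizes in the test suite (600 ECG windows, 360 inertial windows,
pool of 100 candidates, reduced training iterations inside the search) are
chosen as the smallest instances on which the generators' structure is
comfortably recoverable; they keep a full run of the suite around a minute
on a laptop core.

## Numerical and degenerate-input choices

* Integer periods/supports/shifts make enumeration and scheduling exact;
  frequencies in Hz are derived, never stored.
* A constant feature (max = min) has zero information gain by convention;
  bins at the range maximum close on the right.
* Quantizing a constant feature returns the constant.
* Empty candidate pools, empty selections, one-class training labels,
  mismatched lengths and non-power-of-two windows are rejected with
  messages naming the offending values.
* `nfMax = 0` returns an empty selection; an unsatisfiable extractor bound
  simply stops the search when no admissible candidate remains.

## Limitations

* The analog chain is ideal: no mixer offset, integrator leakage, finite
  cut-off or noise figure — these are explicitly downstream circuit
  concerns.
* One hidden layer only (the configurations studied); deeper topologies
  are counted by `countParameters()` but not trained.
* The optimized-search criterion is one reasonable linear penalty, not a
  validated power-aware objective.
* Real-dataset readers are not bundled; the containers accept any windowed
  data arranged as `[windows × channels × samples]`.
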