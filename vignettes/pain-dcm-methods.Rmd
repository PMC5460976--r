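---
title: "Modelling pain-evoked MEG responses with canonical microcircuits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling pain-evoked MEG responses with canonical microcircuits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(painDCM)
```

## The scientific problem

Painful stimuli evoke larger cortical responses when they are unexpected
and when they are attended. Under predictive coding both effects can be
read as changes in the *precision* afforded to ascending prediction
errors, implemented neuronally as postsynaptic gain control on superficial
pyramidal cells. painDCM implements, end to end and on synthetic data, the
modelling pipeline used to test this account with
magnetoencephalography (MEG): a roving-oddball design delivering painful
stimuli to alternating hands under attended and unattended blocks, an
eight-source cortical network model (bilateral S1, S2, inferior frontal
gyrus IFG, inferior parietal cortex IPC) whose condition-specific
modulation explains the eight condition-average evoked fields, Bayesian
model comparison over network architectures and modulation models, and a
group stage that relates subject-level connectivity estimates to
behavioural pain-modulation ratings.

## The stimulus design

Within a block, trains of 3–7 identical painful stimuli (inter-stimulus
interval 1 s) are delivered to one hand; the hand then switches. The
train-initial stimulus (the location change) is the *deviant*; to keep
deviant and standard counts balanced only the last repetition before a
change is labelled a *standard*. Train lengths are drawn i.i.d. with
probabilities 5/15/60/15/5% for 3–7 repetitions; a session is 8 blocks of
25 trains under one of two counterbalanced attention orders (ABBABAAB /
BAABABBA), which gives exactly 200 deviants and 1000 expected stimuli:

```{r design}
s <- generateSession(seed = 1)
s
conditionTable(s)
```

Two readings of the block structure are possible — a fixed number of 25
trains per block (which reproduces the printed totals of 1000 stimuli and
200 deviants and is the default), or a fixed per-block stimulus budget
with a variable train count (`mode = "fixed-budget"`), which matches the
reported between-block variability in deviant counts. Fixation-cross
colour changes (2–5 s jitter) are generated as metadata only; they never
enter the modelled design. Seeding uses one master seed with per-block
seeds derived by a documented counter scheme (`blockSeed()`), so any block
is reproducible in isolation.

## The neural-mass model

Each source is a canonical microcircuit of four populations — spiny
stellate (SS, layer 4), superficial pyramidal (SP, layers 2/3), inhibitory
interneurons (II) and deep pyramidal (DP, layers 5/6). Each population
follows damped second-order synaptic kinetics

$$\dot V = I, \qquad \dot I = \kappa\,d - 2\kappa I - \kappa^2 V,$$

where $d$ is the presynaptic drive and $\kappa$ the synaptic rate
constant; the impulse response of a single population is
$\kappa t e^{-\kappa t}$, peaking at $1/\kappa$. Drives combine
intrinsic coupling gains $\gamma_{m\to n}$ (ten pairs; all
self-connections inhibitory), excitatory forward extrinsic connections
$A^F$ (SP of the lower source onto SS and DP of the higher source),
inhibitory backward connections $A^B$ (DP of the higher source onto SP
and II of the lower source), and the thalamic input $Cu(t)$ onto spiny
stellate cells of the input-receiving sources. Voltages pass through a
firing-rate sigmoid before coupling.

Choices the equations leave open, and how this package resolves them:

* **Sigmoid.** A centred logistic $\sigma(V) = 1/(1+e^{-rV}) - 1/2$ with
  default slope $r = 2$, so $\sigma(0)=0$ and the zero state is an exact
  fixed point of the undriven network.
* **Damping terms.** The standard damped-oscillator form
  $-2\kappa I - \kappa^2 V$ is used for the current equation.
* **Input sign.** The thalamic drive enters excitatorily, $+Cu$.
* **Rate constants.** Defaults $\kappa = 1/4, 1/8, 1/16, 1/28$ per ms for
  SS, SP, II, DP. These give a strongly damped network whose driven SP
  response peaks about 40 ms after stimulus onset (just after the 36 ms
  input latency, consistent with early somatosensory components) and has
  fully decayed within the 400 ms window. Slower kernels were rejected
  because, at the default coupling gains, they make the SS–SP–II loop
  ring visibly within the analysis window.
* **Intrinsic gains.** Defaults of order 0.5–2 (dimensionless), with the
  SP and II self-inhibition at 2; stability of the zero state was checked
  numerically.
* **No SP→DP intrinsic input.** The DP equation receives only forward
  extrinsic input and intrinsic inhibition, exactly as printed in the
  model this reimplements; common CMC variants with an SP→DP term are not
  used.
* **Integration.** Fixed-step RK4 (compiled) at `dt = 1` ms from −100 ms,
  sampled by linear interpolation onto a 300 samples-per-second grid over
  20–400 ms. Halving the step changes trajectories by well under $10^{-3}$
  relative. Divergence (|V| beyond a bound, reachable only at absurd
  parameter values since the sigmoid bounds all firing rates) raises a
  typed error carrying the offending time.

Units: time in ms, $\kappa$ in 1/ms, voltages dimensionless "mV-like".

## Condition-specific modulation

Three contextual factors modulate the network: attention (block level,
bilateral), left expectation violation and right expectation violation
(deviant vs. standard per hand). A factor with input $x_k$ scales
extrinsic connections as $A \odot \exp(\sum_k B_k x_k)$ and the SP
self-inhibition gain as $\gamma_{SP\to SP} e^{\sum_k B^G_k x_k}$ — so a
*negative* gain entry is disinhibition, i.e. increased superficial
pyramidal gain, the model's proxy for increased precision of ascending
prediction errors. The eight conditions (uLS … aRD) each carry a factor
vector and an input routing: left-hand stimuli drive right S1 and S2,
right-hand stimuli the left, matching contralateral spinothalamic
projections.

Expectation-violation effects are tied across hemispheres (one parameter
per region and factor, applied to homologous sites), with the
contralateral scope routing the left-violation factor onto
right-hemisphere sites and vice versa.

## Observation model

MEG sensors see a weighted sum of superficial-pyramidal voltages only
(the dominant contribution to the measured field). In place of an
anatomical head model the package ships a synthetic lead field: 32
helmet-like sensors in mirrored left/right pairs, with gains given by a
smooth Gaussian kernel of the sensor–source distance over the eight
source coordinates (MNI, mm) used for the somatosensory hierarchy. This
preserves realistic spatial mixing and left/right symmetry without any
anatomy dependency; it does not emulate gradiometer physics, volume
conduction or correlated sensor noise (i.i.d. Gaussian noise is the
default; that is what passing tests certify, and real recordings are
messier in exactly these respects). The exogenous input is a Gaussian
bump with prior latency 36 ms and dispersion 16 ms.

## Inversion by variational Laplace

All positive parameters (rate constants, gains, extrinsic strengths,
input amplitude) are fitted as Gaussian log-scaling factors around their
baseline; modulatory B parameters are additive on the log scale; the
input latency is parameterized in units of its 16 ms prior SD. Model
identity — which connections exist, which modulations a model allows — is
encoded purely through prior variances: absent parameters have variance
exactly 0 and are excluded from the free vector, so adding a switched-off
parameter provably cannot change the free energy. Default prior
variances: extrinsic 1/8, intrinsic gain 1/16, modulatory 1/4, input 1/8.

Sensor data are projected onto the top principal spatial modes of the
pooled conditions (default 8; full rank is lossless). The fitter performs
Gauss–Newton ascent on the Laplace free energy with Levenberg–Marquardt
damping, forward finite-difference Jacobians (step $10^{-3}$ on the log
scale), and a single observation log-precision hyperparameter optimized
by 1-D search each iteration under a weak gamma-form hyperprior. Rejected
steps shrink the trust region; the best-F iterate is returned.
Convergence is declared after 3 consecutive free-energy increments below
0.05 nats (maximum 64 iterations). The free energy decomposes as
accuracy minus complexity, the complexity being the KL divergence from
prior to posterior — the quantity that lets fixed-effects Bayesian model
selection trade fit against parameterization. None of these numerical
constants are prescribed by the modelled analysis; they are package
defaults, recorded here.

Grand-average inversion (one dataset under the assumption of a common
functional architecture) and per-subject inversion use the same routine.

## Model spaces

`enumerateArchitectures()` builds the 24 Step-1 networks: 3 IFG-only and
3 IPC-only models (S1, S2, or both connected to the node) and 18
both-node models crossing S1-connectivity {IFG, IPC, both} ×
S2-connectivity {IFG, IPC, both} × hierarchy (IPC above IFG for ids 4–12,
IFG above IPC for 16–24). All connections are reciprocal, homotopic
interhemispheric connections accompany every included high-level node,
and every architecture keeps the bilateral S1–S2 backbone. Homotopic
S1–S1/S2–S2 connections are not included by default (only high-level
homotopic links are declared). Model 10 — all eight sources, IPC on top,
S1 connected to both fronto-parietal nodes, S2 to IFG — is the reference
winning structure.

The Step-2 factorial space crosses 13 attention models (null + 12
bilateral gain-site combinations; attention never modulates extrinsic
connections) with 29 expectation-violation models (null + the same 12
bilateral combinations + 16 contralateral-family models: {contralateral
S1; contralateral S2; contralateral S1+S2; contralateral S1 with
bilateral S2} × {no fronto-parietal gain, IFG, IPC, both}; every non-null
model also allows recurrent extrinsic modulation). "All combinations" of
four regions would give 15, not 12; the shipped list
(`inst/extdata/bilateral_models.json`, fully overridable) excludes the
three combinations that include both IFG and IPC without both
somatosensory regions, an ordering that places {S1, S2, IFG} at id 10 —
consistent with the reference winning attention model. The full crossing
has 13 × 29 = 377 models; the source publication prints "337", which is
inconsistent with its own factor counts, and the product is implemented
as stated rather than silently corrected.

## Evidence, averaging, and the group stage

Fixed-effects Bayesian model selection softmaxes free energies (group
level: sums over subjects). Bayesian model averaging draws seeded
Monte-Carlo samples (default $10^4$) from the evidence-weighted mixture
of per-model Gaussian posteriors — chosen over moment matching because
sign-probability queries ("is this connection disinhibited with
probability > 99%?") then fall out directly; parameters switched off in a
model contribute their prior mean under that model's weight.

The parametric-empirical-Bayes stage treats each subject's posterior
(mean and covariance) as data with known first-level uncertainty under a
between-subject GLM with two regressors: a group mean and the Z-scored
pain-modulation rating (attended minus unattended). A single
random-effect log-precision hyperparameter is optimized against the model
evidence under a weak gamma-form hyperprior; group-effect priors default
to variance 1 (mean) and 1/4 (covariate). Bayesian model reduction scores
on/off patterns of covariate effects analytically from the full posterior
(greedy bidirectional search by default, exhaustive available for ≤ 16
effects; the search strategy is a package choice). Retention uses the
default threshold of 0.95 posterior probability. Leave-one-out
cross-validation refits the group model without each subject and predicts
their covariate by least-squares inversion of the retained group mapping
applied to their first-level posterior means — the predictive mapping is
a documented package contract, not prescribed by the modelled analysis.
All modulatory parameters enter the group model by default; a subset can
be selected.

## The synthetic-data generator

`makeGroundTruth("paper_like")` plants the qualitative effect pattern the
pipeline is designed to recover: attention disinhibits bilateral S1/S2
(−0.3 log-units) and inhibits right IFG (+0.3); expectation violation
disinhibits contralateral S1 (−0.3) with lateralized S2 effects, plus
right-lateralized forward increases and contralateral backward decreases
(±0.2) on extrinsic connections. The magnitudes are package defaults —
the modelled study constrains signs and sites, not sizes. Cohorts
(default n = 22, the reference sample size) add Gaussian between-subject
deviations (default SD 0.15 log-units) to the planted entries, couple the
pain-modulation rating to selected deviations, and simulate per-subject
evoked fields plus their grand average; ratings map affinely onto the
0–10 visual-analogue scale around a baseline of 5 with clipping counted.

## Scales used by the shipped tests

The test-suite exercises the full method at reduced problem sizes, chosen
so the whole suite runs in about a minute on one core: parameter-recovery
and model-recovery simulations use 2–4 source networks, 8–16 sensors,
4–8 spatial modes and a handful of free parameters at signal-to-noise 5;
the end-to-end pipeline test uses 8 subjects; group-stage calibration
uses 50 synthetic cohorts of 22 subjects whose first-level posteriors are
generated directly (truth plus estimation noise with known covariance) —
the group stage consumes posteriors, so this isolates the stage under
test, while the end-to-end test runs real per-subject inversions. Passing
at these scales certifies the machinery and its calibration, not
field-strength claims about real MEG, which depend on preprocessing,
head modelling and noise structure outside this package's scope.

## Known limitations

* The lead field is a smooth synthetic stand-in; no claim of anatomical
  fidelity.
* Extrinsic connections carry no conduction delays (none are present in
  the printed equations this follows).
* Observation noise is modelled i.i.d. with a single precision
  hyperparameter (per-channel precision is a config option).
* Fixed-effects model comparison only; random-effects BMS is out of
  scope.
* The Jacobian is finite-difference; no gradient propagation through the
  integrator.
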