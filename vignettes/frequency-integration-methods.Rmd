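---
title: "Modelling frequency integration in the owl's auditory space map"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling frequency integration in the owl's auditory space map}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(icxfreq)
```

## The scientific problem

Space-specific neurons in the external nucleus of the inferior colliculus
(ICx) of the barn owl derive unambiguous tuning to interaural time
difference (ITD) by combining inputs across frequency channels.  Their
inputs come from the lateral shell of the central nucleus (ICcl), whose
neurons are narrowly tuned to frequency and therefore have nearly
sinusoidal, phase-ambiguous ITD tuning.  Across-frequency convergence
suppresses the side peaks of that ambiguity, and the question this
package addresses is *how*: is the convergence a linear sum followed by a
spiking nonlinearity (a point neuron), or do dendritic subunits apply
their own nonlinearities before somatic summation (a two-layer neuron)?

`icxfreq` implements the full modelling tool chain for this question:

1. a deterministic rate model of the ICcl input population,
2. the two-layer ICx neuron with configurable subunit and spiking
   nonlinearities and its parameter-space exploration,
3. tuning-shape metrics (half-width, side-peak suppression) with
   z-scoring against the published in vivo population statistics,
4. candidate-nonlinearity fitting and model selection exactly in the
   form used for the in vivo analyses (joint MSE minimization, adjusted
   R², leave-one-out cross-validation, dominance on both metrics),
5. a generator of synthetic intracellular recordings so that every
   analysis stage can be validated against known ground truth, and
6. a passive compartmental (cable) model with AMPA/NMDA synapses that
   links the functional subunits to biophysical mechanisms.

## ICcl input model

Each ICcl neuron has an exponential-of-cosine ITD tuning curve

$$r(\mathrm{ITD}) = \frac{e^{b\cos(2\pi\,\mathrm{bf}\,(\mathrm{ITD}-\mathrm{ITD}_0))}-e^{-b}}
{e^{b}-e^{-b}},$$

normalized to [0, 1], with best frequency $\mathrm{bf}$ in kHz and ITD in
ms internally (so $\mathrm{bf}\cdot\mathrm{ITD}$ is in cycles; all public
interfaces take microseconds).  The concentration parameter $b$ controls
how much narrower than a sinusoid the curve is and is tied to best
frequency through the smaller root of a quadratic,

$$b = \frac{17-\sqrt{17^2-4\cdot 2.8\,(24.12-2.44\,\mathrm{bf})}}{2\cdot 2.8},$$

reproducing the published relation between best frequency and ITD
half-width in ICcl.  The printed source for this quadratic is
typographically garbled; the parse above is the only reading of its
glyphs that yields positive widths over essentially the whole 0.5–10 kHz
range, and the four coefficients are exposed as arguments should a
different reading be preferred.  Above ≈9.9 kHz the root crosses zero and
is clamped at ε = 0.01, letting tuning degrade gracefully toward a pure
raised cosine.  The default population is a bf-major grid, best
frequencies 0.5–10 kHz in 0.1-kHz steps with a single best-ITD column at
0 µs, because the two-layer analyses model neurons whose inputs share a
preferred ITD near zero.

Tone responses multiply the ITD factor by a Gaussian frequency-tuning
factor (width 0.5 kHz by default) and a level scale; ICcl ITD tuning is
known to be similar for tones and noise, which is what makes this
factorization reasonable.

## Two-layer neuron and the parameter studies

Subunit $j$ pools the population with unnormalized Gaussian weights
$w_{ij}=\exp(-\tfrac12((\mathrm{bf}_i-\mathrm{cf}_j)/\sigma)^2)$ and
applies a static nonlinearity $g$ to the sum; the soma adds the 10
subunit outputs to form the model PSP, and a spiking nonlinearity
(rectified-linear or thresholded logistic) maps PSP to spike count.
Keeping the weights unnormalized is deliberate: broader frequency tuning
recruits more inputs and therefore delivers a larger drive, which is the
mechanism by which a *fixed* saturating nonlinearity can treat broadly
and narrowly tuned subunits differently.

Two parameter studies are built in:

* `map_subunit_space()` sweeps the power-law subunit nonlinearity
  $g(x)=x^p$ over $\sigma \in [0.1, 4]$ kHz (step 0.1), 25 log-spaced
  exponents $p \in [0.1, 10]$ and CF spreads of 0, 1.25 and 2.5 kHz
  centered at 5 kHz (subunit center frequencies equally spaced across the
  spread — the original description states the ranges but not the
  spacing).  Every cell is scored by the z-scores of side-peak
  suppression (SPS) and half-width (HW) against the experimental
  population moments (SPS 23.18 ± 12.27 %, HW 75.17 ± 17.12 µs).
* `sigmoid_subunit_feasibility()` asks whether one *fixed* offset-logistic
  subunit nonlinearity can stay within two standard deviations of the
  experimental population across all bandwidths 0.5–4 kHz.  Because both
  SPS and HW are invariant to positive affine transformations of the
  response, only the logistic slope and midpoint matter, and the search
  is a deterministic coarse-to-fine grid over those two parameters
  (21×21 coarse pass, two 11×11 refinements).  A stochastic optimizer
  was deliberately avoided so the result is bit-for-bit reproducible.

Numerical choices: ITD curves are evaluated on −250..250 µs in 5-µs steps
(finer than the 30-µs experimental step, keeping the interpolation error
of HW below ~2 µs); the main peak is the global maximum with ties broken
toward 0 µs; local maxima are strict on the sampled grid; SPS is
normalized by the full response range,
$100\,(R_{main}-R_{side})/(R_{main}-R_{min})$, so equal peaks score 0 and
a side peak at baseline scores 100 (the alternative main-peak
normalization is available as an option, since the original metric's
exact definition lives in earlier literature).  Curves whose window
contains no secondary local maximum get a missing SPS rather than an
imputed extreme — this keeps degenerate, ultra-narrow curves from
polluting feasibility maps.

One symmetry worth noting: with linear subunits, partitioning a fixed
weight vector among any number of subunits leaves the PSP unchanged
(tested to 1e-10).  A nonzero CF spread, however, *changes* the summed
weight profile, so even linear subunits respond differently across
spreads; the map should be read per spread column.

## Fitting and model selection

`fit_model()` implements the five candidate forms: rectified-linear and
thresholded-sigmoid spiking nonlinearities, and linear, quadratic and
"stack sigmoid" (linear term plus standard logistic) candidates for the
relation between $V_{add}$ and $V_{stack}$.  The printed sigmoid
denominators of the source material read $1-e^{-c_1(V-c_2)}$, which
diverges at $V=c_2$; both are implemented as the logistic
$1+e^{-c_1(V-c_2)}$, the standard form matching the plotted shapes.

Linear and quadratic fits are closed-form least squares.  The ReLU is
fitted by exact enumeration: with positive slope the rectified set is an
upper tail of the sorted inputs, so solving one quadratic subproblem per
tail finds the global optimum deterministically.  The sigmoid families
use Levenberg–Marquardt with a deterministic multi-start protocol
(moment-based start plus a fixed 3×3 perturbation grid; ties broken by
lexicographic parameter order), positivity of slopes enforced by
log-parameterization, and the hard threshold of the spiking sigmoid
profiled over a fixed quantile grid.  Two identifiability bounds are
imposed on the logistic transition: its midpoint must lie within the
data, and its width ($\approx 4/b_3$) may not be sharper than a fixed
fraction of the data spread — steeper fits are step functions chasing
individual noisy points rather than a saturating response.

Model comparison uses adjusted $R^2 = 1-\frac{RSS/(n-p-1)}{TSS/(n-1)}$
and the leave-one-out cross-validation MSE, with a winner declared only
when one candidate is strictly best on *both* metrics.  This dominance
rule is intentionally conservative, and it has a measurable cost: on
data generated from a truly linear model, the 3- and 5-parameter
competitors dominate by chance in roughly 15–20 % of replicates (for one
added parameter, $P(F>1)\approx 0.32$ alone), so conclusive selections
recover a linear ground truth only about two-thirds of the time, while
quadratic and sigmoidal ground truths are recovered in ≈85 % and ≈100 %
of conclusive replicates.  The package reports `"inconclusive"`
honestly rather than forcing a class.

## Synthetic recordings

`build_experiment()` emulates the in vivo protocol: 100-ms stimuli with
5-ms linear rise/fall, ITD varied in 30-µs steps, two or three tones
presented individually and as a simultaneous stack at matched overall
level (each of $m$ stack components at level $1/m$), 3–5 trials per
stimulus, and responses summarized by the median membrane potential over
the 50 ms starting 10 ms after onset, averaged over trials.  Membrane
noise is Ornstein–Uhlenbeck (τ = 5 ms, SD 1 mV by default) — realistic
autocorrelation without biophysical machinery.  Spikes are drawn as an
inhomogeneous Poisson process whose instantaneous rate is the spiking
nonlinearity of the instantaneous depolarization normalized by the
envelope-integrated window (so the expected count at steady
depolarization $V$ equals $f(V)$), with a 1-ms refractory period, and
each spike adds a stereotyped 2-ms biphasic waveform — enough to verify
that the median-based PSP measure really does resist spike
contamination.  A longer dead time was rejected because it censors
counts by more than 10 % at realistic ICx rates, which would corrupt the
very mapping the generator exists to test.  $V_{add}$ references all
responses to the experiment-wide minimum trial-averaged PSP (the
stated "minimum recorded during stimulation" leaves the scope open;
experiment-wide is the stable choice and a per-stimulus option exists).

What the generator does *not* emulate: interaural level difference
pathways, sound-level nonlinearities in ICcl, electrode artifacts, and
trial-to-trial rate adaptation.  Passing tests on synthetic data
therefore demonstrate correctness of the analysis chain, not fidelity of
every biological detail.

## Compartmental model

The cable model builds a soma (10–30 µm), unbranched dendrites
(50–300 µm long, 4–20 µm thick) and cylindrical spines (0.1–0.4 µm
diameter, 2–80 µm length, ±10 % per-spine jitter; corner combinations of
extreme diameter with opposite-extreme length are rejected) and
integrates the passive cable equations by backward Euler with a Hines
tree solve (compiled via Rcpp), dt = 0.025 ms.  Membrane is passive
only — no spiking conductances.  Leak is specified per named section in
µS (0.0001–0.01) and divided over a section's compartments by membrane
area; axial resistivity 100 Ω·cm and specific capacitance 1 µF/cm² are
package defaults, as are the synaptic reversal (0 mV), resting potential
(−65 mV), Mg²⁺ 1 mM and the NMDA kinetics (α = 0.35 ms⁻¹, β = 0.015 ms⁻¹,
transmitter pulse 1 ms) — all configurable and reported in metadata.
AMPA synapses decay exponentially (τ = 4.5 ms); NMDA conductance is the
bound fraction gated by the voltage-dependent magnesium block
$1/(1+e^{-0.062V}[\mathrm{Mg}]/3.57)$, evaluated at the previous time
step's voltage.

Inputs are homogeneous Poisson trains whose rates combine, per synapse,
an ITD factor (the ICcl tuning form at the tone frequency), a Gaussian
frequency-tuning factor around the synapse's preferred frequency
(width σ_f = 0.5 kHz — the printed rate equation reuses one symbol for
both the second weight and this width, so they are separated here), and
a floor of 1/100 ms⁻¹ capping the maximum inter-spike interval.  Input
weights default to 0.25 events/ms so that peak inter-event intervals sit
in the ~3–20 ms band.

`combination_experiment()` presents the two tones independently and
simultaneously across the ITD grid, extracts median-PSP soma responses,
and classifies the $V_{add}$–$V_{stack}$ relation with the same
selection machinery as the recordings analysis.  Three reference regimes
are packaged (`compartmental_preset()`): AMPA on 5-µm dendritic shafts
with high leak combines linearly; AMPA on thin spines saturates locally
(driving-force nonlinearity behind a large neck resistance) and combines
quadratically; NMDA on spines adds the expansive Mg-block limb at weak
drive and combines sigmoidally.  Because the Poisson inputs make any
single experiment a random realization — and a strictly dominant winner
is genuinely a coin toss when the truth sits near the linear boundary —
the packaged demonstrations and their tests use the *modal conclusive
classification* over a handful of replicate experiments (seeds 1–6,
five trials each), which is stable across the regimes.  The same
variability is why the matched/mismatched analysis (responses to the two
tones within 3 mV of each other, strictly) is reported per ITD point:
matched points cluster at the main peak, mismatched ones on side peaks,
and nonlinear combination concentrates on the latter.

Problem sizes throughout (101-point ITD grids for the parameter studies,
17-point 30-µs grids for simulated experiments, 150-ms simulations,
6 replicate experiments per compartmental regime, 200 replicates per
class in the recovery study) were chosen so the full analysis suite runs in
minutes on a single core while keeping every Monte-Carlo margin
comfortably away from its threshold.

## Known limitations

* The drive entering subunit nonlinearities depends on the input-grid
  density (weights are unnormalized), so absolute sigmoid midpoints are
  implementation-relative; z-score maps are verified to be stable under
  halved grid density, but absolute parameter values should not be
  compared across grids.
* The exact published definition of side-peak suppression lives in
  earlier literature; the range-normalized form used here matches the
  qualitative orderings and is swappable.
* The strict both-metrics dominance rule undercalls linear ground
  truths (see above); treat "inconclusive" as a first-class outcome.
* The compartmental model is subthreshold only and its spines are single
  cylinders; spine neck/head subdivision and active conductances are out
  of scope.
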