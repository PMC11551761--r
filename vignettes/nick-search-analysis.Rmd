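---
title: "Models and methods behind nicksearch"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind nicksearch}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`nicksearch` quantifies how a DNA ligase locates single-strand nicks on DNA
in two single-molecule geometries: confocal kymographs of a long nicked DNA
held in a dual optical trap, and two-colour TIRF traces of short
surface-tethered single-nick DNAs. This vignette is the package's own
account of the models it fits, the tunable parameters and why their defaults
are what they are, what the synthetic-data generator does and does not
emulate, and the numerical choices a maintainer would want written down.

## The observables and their models

### Kymographs

A kymograph is a stack of 1D confocal line scans (40 ms per line by
default, 0.1 um pixels) along the stretched DNA. Bound, labelled ligase
renders as a Gaussian point-spread function (sigma 0.15 um) sampled once
per line with Poisson photon statistics over a Poisson background; two red
marker dyes at known basepair coordinates (33,786 and 44,826 bp on the
48.5 kbp substrate) anchor an exact two-point linear map between image
microns and basepairs, so binding positions can be expressed in bp without
assuming anything about the stretch factor.

Binding events are tracked per line (robust threshold: background median
plus four median absolute deviations; sub-pixel refinement by a local
Gaussian fit) and linked greedily by nearest neighbour within 3 px,
bridging up to 2 missed lines; tracks shorter than 3 lines are discarded.
These defaults are matched to the frame time: the fastest lifetime in the
data (~0.08 s) spans about two lines, so the minimum length sits just above
the single-line noise floor while the gap tolerance bridges isolated missed
detections. Two detections closer than one PSF footprint (4 px) are treated
as duplicates of one emitter — Poisson ties routinely produce twin local
maxima, and without deduplication the duplicates seed rival tracks that
steal detections and fragment long events.

### Static versus diffusive segments

A track's frame-to-frame displacement variance over a 10-line window is
compared with four times the localization variance (pure localization noise
contributes twice the localization variance, so the factor-four threshold
sits a factor two above the noise floor). Windows vote on the positions
they cover; runs shorter than one window are absorbed into their longer
neighbour, and a run touching a track end must span at least two windows —
ends are covered by fewer windows, so a chance cluster of mislabelled
windows would otherwise fabricate short boundary segments. Diffusion is
then estimated per diffusive segment only, mirroring the splitting rule
used in the experiment.

### The covariance-based diffusion estimator

For uniformly sampled positions with displacements $\Delta x_n$,

$$\hat D = \frac{\langle \Delta x_n^2\rangle}{2\Delta t}
         + \frac{\langle \Delta x_n \Delta x_{n+1}\rangle}{\Delta t},
\qquad
\hat\sigma^2 = R\,\langle \Delta x_n^2\rangle
             + (2R-1)\,\langle \Delta x_n \Delta x_{n+1}\rangle,$$

where $R$ is the motion-blur coefficient. $R = 1/6$ (continuous
illumination over the full line time) is the package default for real
scans; simulations that draw positions instantaneously use $R = 0$.
Negative per-track estimates are legitimate for short noisy tracks and are
retained in population means — clipping them would destroy the estimator's
unbiasedness, which the test suite verifies against both the generating
values and an MSD-slope oracle. Segments with fewer than 5 displacements
are skipped and counted.

### Dwell-time mixtures with left truncation

Dwells are modelled as exponential mixtures with up to four components. A
detection dead time $t_{min}$ (one frame: 0.04 s C-Trap, 0.1 s TIRF)
left-truncates the observable dwells; conditioned on $t \ge t_{min}$ the
shifted dwells $t - t_{min}$ again follow an exponential mixture with the
same lifetimes and re-tilted weights
$\tilde a_k \propto a_k e^{-t_{min}/\tau_k}$, so the EM runs on shifted
data and the weights are un-tilted afterwards — an exact correction, not an
approximation. With lifetimes of 0.08 s against a 0.04 s frame the
truncation is far from negligible; a zero-threshold dwell set reproduces
the naive fit.

EM initialization uses log-spaced lifetimes with equal weights, spaced
between the 10th and 90th percentile of the (shifted) dwells rather than
between the minimum and maximum: anchoring a start at the sample minimum
reliably trapped one component on the single smallest observation (the
well-known degenerate likelihood spike of exponential mixtures at
$\tau \to s_{(1)}$, $a \to 1/n$), and every jittered restart converged to
that trap. Ten restarts with log-normal jitter (sd 0.6) guard against the
remaining local maxima; convergence is a log-likelihood gain below 1e-8.

### Model order: BIC gated on bootstrap unimodality

For each order $K \in \{1..4\}$ the fit is scored by
$\mathrm{BIC} = (2K-1)\ln n - 2\log L$ and its uncertainty by a
nonparametric bootstrap (500 resamples by default; each refit from the
point estimate, components matched by sorting lifetimes). The selected
order is the lowest-BIC model whose every parameter passes a unimodality
gate; orders within 2 BIC units resolve to the smaller $K$. The gate
operationalizes a visual criterion: a bimodal bootstrap distribution, or a
weight whose lower 5% quantile falls below 0.01, means the extra component
is sometimes collapsing to nothing in the resamples and the order is not
supported.

Unimodality is tested with Hartigan's dip statistic — the sup-norm distance
between the empirical distribution function and the nearest unimodal
distribution function — implemented in the package via the classical
greatest-convex-minorant / least-concave-majorant modal-interval narrowing
scheme. The implementation is validated in the test suite against
closed-form anchors (evenly spaced data give $1/(2n)$; two balanced point
masses give $1/4$) and against an exact linear-programming formulation of
the minimax unimodal fit on small samples; its null quantiles reproduce the
published critical-value tables. P-values come from a Monte-Carlo null
(uniform samples, the least-favourable unimodal case) simulated once per
sample size under a fixed internal seed and cached, which makes the test
deterministic and cheap under repeated use.

### TIRF traces and their idealization

The protein (Cy5) channel alternates between unbound and bound intensity
levels (alternating renewal: mixture-distributed bound dwells, exponential
unbound dwells); the DNA-reporter (AF488) channel is constant until it
photobleaches in one step. Trace QC follows the experimental criteria: a
single-step reporter bleach — best change point by least-squares step
fitting, accepted when the two-segment fit removes at least 30% of the
flat-fit residual, a third segment does not do the same to the two-segment
fit, and the post-step level sits at the background (final 10% of the
trace) — plus at least two protein-channel spikes exceeding twice the
background. Only the pre-bleach portion of the protein channel is analysed
(after the reporter is gone, binding can no longer be attributed to the
DNA), and a trace must retain at least 120 s of pre-bleach observation:
windows much shorter than a few unbound lifetimes (~40 s) cannot constrain
dwell statistics and would contribute mostly noise.

Idealization is a two-state hidden Markov model with Gaussian emissions,
trained by scaled forward–backward EM (initial means at the 20th/80th
intensity percentiles, tolerance 1e-6, at most 500 iterations — the
log-likelihood trace is checked to be non-decreasing) and decoded by
Viterbi; state 1 is the higher mean. If the two fitted means end up closer
than three pooled emission standard deviations the trace carries no
resolvable two-level signal (typically: no binding event in the window) and
the EM has merely split the noise; such fits are returned flagged
degenerate, as an all-unbound path, rather than as a spurious
fast-flickering idealization that would flood the dwell pool with one-frame
artifacts.

Dwells are run lengths times the frame time; the first and last run of
every idealization touch the window edges, are censored, and are excluded
by default (a flag re-includes them). Bound and unbound lifetimes are
fitted on cumulative frequency curves,
$F(t) = 1 - \sum_k a_k e^{-t/\tau_k}$ with weights summing to one, after
shifting by the one-frame dead time. The empirical curve is evaluated on a
uniform time grid (200 points spanning the dwells) rather than at the
sorted dwells themselves: both are unbiased, but with ~500 dwells dominated
by the fast component the sorted-dwell evaluation concentrates nearly all
points in the first seconds and leaves the slow lifetime poorly
constrained (observed spread roughly 16% versus 6% on the grid). The
sorted-dwell variant remains available (`eval_grid = "sorted"`). A
double exponential is preferred over a single one only when a partial
F-test on the residual sum of squares is decisive.

### Tether verification

Force–distance curves are compared with the extensible worm-like chain in
the Odijk regime,
$x(F) = L_c\,(1 - \tfrac12\sqrt{kT/(F L_p)} + F/K)$, with standard
lambda-DNA constants ($L_c = 16.5$ um, $L_p = 50$ nm, $K = 1200$ pN,
$kT = 4.114$ pN nm at 25 °C). The contour length is the only free
parameter; a tether passes when the RMS force residual over 1–30 pN stays
below threshold and the fitted contour is within 10% of nominal. A doubled
tether shares force between two molecules and fails both checks.

## What the generator emulates — and what it does not

The simulator reproduces the features the analysis actually exercises:
Poisson arrivals with static/diffusive/transient modes, reflected Brownian
sliding between the bead positions, per-line PSF rendering with Poisson
photon noise, intermittent marker excitation, camera noise at a set
signal-to-noise ratio, single-step reporter bleaching, and optional
two-state blinking inside bound periods (off by default — the
oxygen-scavenger/Trolox buffer suppresses blinking in the experiment).
Defaults follow the published experimental conditions where those are
stated: 48.5 kbp DNA, markers at 33,786/44,826 bp, 40 ms lines, 100 ms
TIRF frames, lifetime mixtures and diffusion coefficients at the published
values. Where no value is published the default is chosen once on
experimental-practice grounds: ten nicks evenly spaced over 4–44 kbp (the
real site list lives in supplementary material), Cy5 levels 600/300 with
sd 75 (SNR 4 on the binding step, and a background against which the
"twice background" spike criterion is meaningful, as in the assay), and a
mean AF488 bleach time of 1200 s (protected-dye imaging is tuned to keep
the reporter alive over the movie).

It does **not** emulate: 2D scanning or axial drift, bead motion and force
fluctuations, protein–protein interactions (two molecules can co-occupy a
position; the collision flag only handles resolvable neighbours),
sequence-dependent sliding, Cy5 photobleaching within bound events, or
non-Gaussian camera artifacts. Passing tests therefore demonstrate the
estimators' correctness under the stated noise models, not robustness to
every instrumental pathology of real data.

## Known limitations

* **Window censoring of long dwells.** Interior-complete dwells observed in
  a finite pre-bleach window under-represent long dwells; for unbound times
  of ~40 s in windows capped at 600 s this biases the naive
  cumulative-frequency estimate downward by roughly 5–15% depending on the
  bleach-time distribution, and the effect saturates rather than vanishes
  as bleaching slows (conditioning on an observed bleach step caps the
  window). The pipeline reports the conventional estimate; a
  survival-analysis treatment of the censored runs is the natural extension.
* **Model selection at close lifetimes.** Lifetimes separated by less than
  roughly a factor three are difficult to resolve at n ~ 1000; the
  unimodality gate then correctly prefers the smaller order, which is a
  feature of the rule, not an estimator defect.
* **Greedy linking.** The tracker is a greedy nearest-neighbour linker;
  crossing trajectories can swap identities. Crossings are rare on this
  substrate (collision-flagged tracks are excluded from diffusion and
  lifetime pools), but a motion-model tracker would be needed for denser
  fields.

## Problem sizes in the shipped tests

The suite exercises the pipeline at the sizes a single desk run supports:
400–2,000 simulated tracks for diffusion recovery, 2,000-dwell mixture
fits, model selection at n = 1,000 with 200 bootstrap resamples over ten
replicates, 300 TIRF traces of 600 s at 10 Hz through QC–HMM–fitting, and
kymograph scenes of one to four minutes. These sizes give sampling errors
comfortably inside the recovery tolerances asserted by the tests while
keeping the default suite in the minutes range.
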