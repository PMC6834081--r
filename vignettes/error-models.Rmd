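---
title: "Error models for merging still-image serial crystallography data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Error models for merging still-image serial crystallography data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

In serial crystallography every crystal contributes a single still
diffraction snapshot, so every reflection is only partially recorded: the
reciprocal-lattice point clips the Ewald sphere rather than sweeping
through it. Before merging, each partial intensity $I^P_{hj}$ (measurement
$j$ of Miller index $h$, in photon units) and its photon-counting error
$\sigma^P_{hj}$ must be scaled to the full-intensity equivalent. With a
per-image scale factor $G_c$, Wilson factor $B_c$ and partiality fraction
$P_{hj} \in (0, 1]$, all provided by upstream post-refinement, the package
applies

$$ I_{hj} = K_{hj}\, I^P_{hj}, \qquad
   \sigma_{hj} = K_{hj}\, \sigma^P_{hj}, \qquad
   K_{hj} = \left[ G_c\, e^{-2 B_c \sin^2\theta_h / \lambda_c^2}\,
   P_{hj} \right]^{-1}. $$

Dividing by scale, Wilson falloff and partiality means $K \ge 1$ whenever
$P < 1$ at $G = 1$, $B = 0$, as it must be for a partially recorded
observation. $K$ is treated as an exact constant: the same factor
multiplies intensity and sigma, so per-measurement $I/\sigma$ is
preserved. Propagating the uncertainty of the post-refined parameters
inside $K$ is deliberately out of scope here.

After correction, counting statistics alone badly underestimate the
observed spread of replicate measurements — partiality estimation error
usually dominates. The package therefore implements three merging error
models:

1. **Unweighted** — $I_h$ is the plain mean; the error is the observed
   spread, $\sigma_{\rm res} = [\sum_j (I_{hj} - I_h)^2/(n-1)]^{1/2}$, and
   $\sigma_h = \sigma_{\rm res}/\sqrt{n}$. Uses no counting information;
   reliable only at multiplicity of roughly 5 and above. For $n = 1$ the
   spread is undefined; the measurement's own sigma is reported and the
   reflection flagged.
2. **Counting-weighted** — inverse-variance weights $w = 1/\sigma_{hj}^2$;
   $I_h = \sum w I_{hj} / \sum w$ and $\sigma_h = (\sum w)^{-1/2}$.
   Because the weights ignore partiality scatter, the merged sigmas come
   out far too small when partiality dominates.
3. **Ev11** — as protocol 2, but with weights $1/\sigma_{\rm Ev11}^2$
   from the inflated per-measurement sigma
   $$ \sigma_{\rm Ev11} = s_{\rm fac} \left[ \sigma_{hj}^2 +
      s_B \langle I_h \rangle + (s_{\rm add} \langle I_h \rangle)^2
      \right]^{1/2}, $$
   where $\langle I_h \rangle$ is the plain mean of the corrected
   measurements of $h$. $s_{\rm fac}$ absorbs multiplicative
   miscalibration (an erroneous detector gain scales all counting sigmas
   by $\sqrt{\rm gain}$); $s_{\rm add}$ captures intensity-proportional
   error such as instrument instability; $s_B$ carries no assigned
   physical meaning but improves the fit.

With identity parameters $(1, 0, 0)$ protocol 3 collapses exactly —
bit for bit on the merged intensities — to protocol 2; the weights are
computed from $\sigma^2$ directly so no rounding enters.

# Normalized deviations and the refinement target

Whether sigmas explain the spread is judged through leave-one-out
normalized deviations

$$ \delta_{hj} = \left( \frac{n-1}{n} \right)^{1/2}
   \frac{I_{hj} - \langle I'_{hj} \rangle}{\sigma_{hj}}, $$

with $\langle I'_{hj}\rangle$ the mean of the other $n-1$ measurements.
The $(n-1)/n$ prefactor is exactly the equal-variance correction for a
leave-one-out difference, which is why the denominator holds the single
measurement's sigma only — folding the uncertainty of the leave-one-out
mean into the denominator as well would double-count it. For $n = 1$ the
deviation is defined as 0 and the measurement takes no part in the
analysis. Correct sigmas make $\delta$ standard normal.

**Initialization.** The sorted deviations are plotted against rankits
$z_i = \Phi^{-1}[(i - a)/(m + 1 - 2a)]$, $a = 3/8$ for $m \le 10$ and
$1/2$ otherwise (the familiar `qqnorm` plotting positions). A straight
line is fitted by ordinary least squares to the central region (rankits in
$[-0.5, 0.5]$), avoiding the outlier-dominated tails. The slope estimates
the overall sigma under-scaling and seeds $s_{\rm fac}$; the offset seeds
$s_{\rm add}$ (clamped at 0, it is a non-negative scale) and $s_B$ is
seeded with $\sqrt{s_{\rm add}}$.

**Target.** Reflection means $\langle I_h \rangle$ are split into 100
equal-width intensity bins spanning their range (top edge inclusive);
every measurement of $h$ lands in the bin of $\langle I_h \rangle$, and
$n = 1$ groups are excluded. With per-bin root-mean-square deviation
${\rm rmsd}_b = [(1/m_b) \sum_k \delta_{bk}^2]^{1/2}$ (about zero, since
calibrated deviations have zero mean by construction), the refinement
minimizes

$$ f_\sigma = \sum_b \sqrt{m_b}\, ({\rm rmsd}_b - 1)^2 $$

over $(s_{\rm fac}, s_B, s_{\rm add})$ using L-BFGS-B with the analytic
chain-rule gradient. Empty bins contribute nothing. $\langle I_h \rangle$
and the bin assignment are computed once from the corrected intensities
and held fixed during refinement, keeping the target smooth in the
parameters.

## Numerical choices

* **Bounds.** All three parameters are bounded below at zero
  ($s_{\rm fac}$ at a small positive floor, since it divides the
  deviations). Leaving $s_B$ free lets it drift negative on
  instability-dominated data, where the $s_B \langle I \rangle$ and
  $(s_{\rm add}\langle I\rangle)^2$ terms partially trade off and the
  negative $s_B$ eats into the recovered $s_{\rm add}$; the bounded fit
  reaches an indistinguishable target value with a cleaner decomposition,
  and refined values of exactly 0 are reported at the bound.
* **Two deterministic starts.** The slope-based initialization encodes a
  gain-dominated hypothesis: all inflation goes into $s_{\rm fac}$. When
  the dominant error is intensity-proportional, that start sits in the
  wrong basin of $f_\sigma$ and a single quasi-Newton run can stall
  there. `refineErrorModel` therefore also runs from the complementary
  counting-calibrated start $(1, 0, \max({\rm offset}, 0.02))$ and keeps
  the lower final target. Both runs are deterministic — no randomness is
  introduced into the minimization.
* **The $s_{\rm add} = 0$ trap.** $s_{\rm add}$ enters only through its
  square, so $\partial f/\partial s_{\rm add} \propto s_{\rm add}$
  vanishes identically at 0: a start clamped to exactly 0 can never move
  off that axis. Automatic starts are floored at 0.02, the classic
  default for the additive term; user-supplied starting points are used
  verbatim.
* **Negative radicand.** A large $\langle I_h \rangle$ with $s_B < 0$ can
  drive the radicand of $\sigma_{\rm Ev11}$ negative (possible only for
  user-supplied parameters, given the bound); such measurements fall back
  to $s_{\rm fac}\sigma_{hj}$, are counted, and contribute no
  $s_B$/$s_{\rm add}$ gradient.
* **Convergence.** Projected-gradient tolerance $10^{-8}$, relative
  function decrease $10^{-10}$, at most 200 iterations. The reported
  trace holds the target at the start and after each accepted improving
  evaluation, so it is non-increasing; restarting at a stationary point
  terminates immediately with unchanged parameters.
* **Ties.** Sorting of deviations for the plot is stable; ties cannot
  affect the central-region fit.
* **Degenerate input.** If all reflection means coincide the bin range
  collapses; a single bin is used and a warning raised.

# Other design decisions

* **Per-image resolution filter.** Each image is binned into 10
  equal-volume resolution bins ($1/d^3$); the cutoff is the
  low-resolution edge of the first bin whose mean $I/\sigma$ falls below
  the threshold (default 0.1, appropriate for photon units — a threshold
  chosen for detector units must be divided by $\sqrt{\rm gain}$). The
  filter runs on the partial (pre-correction) values by default, since it
  models a per-image signal cutoff at integration time; a switch selects
  corrected values instead.
* **Asymmetric-unit mapping.** Indices map to the lexicographically
  largest equivalent under the rotational point group of the space group;
  with `anomalous = TRUE` the Friedel inversion is excluded from the
  orbit, keeping Bijvoet pairs separate (centric reflections merge either
  way, as they must). Translational parts of the symmetry operators are
  irrelevant for equivalence and are not represented.
* **Merged-sigma form.** The weighted protocols propagate
  $\sigma_h = (\sum w)^{-1/2}$; this is the only form consistent with
  counting-weighted merged errors collapsing far below the spread-based
  ones when partiality scatter dominates. A spread-based weighted
  standard error is available behind `weightedSem = "spread"` for
  sensitivity analysis.
* **No outlier rejection, no truncation.** Negative merged intensities
  are retained; the only data removal is the optional partiality floor
  and the per-image resolution filter.
* **CC1/2.** Community-standard random half-splits per reflection (odd
  measurement to a random half), seeded and reproducible.

# The synthetic generator

`simulateDataset` emulates exactly the error structure the model is meant
to explain, with known ground truth:

* true intensities $J_h \sim {\rm Exp}({\rm mean} = 2000\ {\rm photons})$
  (Wilson statistics for acentric reflections; the simulated space group
  is P1, so centric statistics are not needed);
* per-image $G_c \sim U(0.5, 2)$ and $B_c \sim U(0, 10)\ \mathring{A}^2$,
  a single wavelength of 1.3 Å, and reflections placed uniformly in
  reciprocal volume between 30 and 1.8 Å;
* partialities from a Beta(2, 1.5) law rescaled to $(0.05, 1]$ —
  left-skewed towards zero, as estimated partialities of still images
  are;
* photon counts ${\rm Poisson}(\mu)$ with
  $\mu = G_c e^{-2 B_c s} P J_h$, optionally plus Gaussian instrumental
  error of SD $s_{\rm add}^{\rm true}\mu$; detector units are
  ${\rm gain}_{\rm true} \times$ photons, the analyst divides by
  ${\rm gain}_{\rm assumed}$ and takes $\sigma = \sqrt{\max(I, 1)}$ (a
  one-photon floor for empty cells). A gain misestimation ratio $g$
  therefore miscales sigmas by exactly $\sqrt{g}$, which is what the
  $s_{\rm fac}$ term models.

Presets pin down the study conditions used throughout the tests:
`clean-poisson` (2000 images × 60 reflections = 120000 calibrated
measurements), `gain25` and `instability` (5000 images × 50 reflections
each, gain ratio 25 and $s_{\rm add}^{\rm true} = 0.5$ respectively) and
`partiality-heavy` (1000 images, Beta(1, 3) partialities on
$(0.02, 1]$). These sizes give stable parameter recovery while keeping a
full test run in well under a minute per preset.

What the generator does **not** emulate: spot shape and mosaicity
physics, per-pixel gain non-uniformity, wavelength spectra, correlated
per-image systematics, radiation damage, or real partiality-estimation
error (partialities are generated exactly and supplied exactly, so the
simulated corrections are perfect). Passing tests therefore demonstrate
that the estimators and the refinement behave correctly under the stated
noise model — not that the model captures everything in real XFEL data.
On real data the inflation terms additionally absorb partiality-model
error, and refined values should be read as effective, not physical,
constants.

# Known limitations

* The error model inflates sigmas as a function of the reflection mean
  only; measurement-specific systematics (e.g. per-panel detector
  effects) are outside its reach.
* $\langle I_h \rangle$ is the unweighted mean even under protocol 3;
  recomputing it with the refined weights would couple the weights into
  the target and is deliberately avoided.
* The initialization line fit assumes enough deviations fall in the
  central rankit window; pathological datasets (fewer than two points
  there) need a wider `fitRange`.
* Reflection files are read and written as tab-separated text; binary
  reflection formats are not produced.
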