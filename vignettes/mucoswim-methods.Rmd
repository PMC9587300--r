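---
title: "Models and methods behind mucoswim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind mucoswim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mucoswim)
```

# The system being modelled

Magnetic microparticles (10 µm diameter) suspended in a mucin solution can
swim. Mucus is a rod-climbing-like viscoelastic fluid: when a particle is
spun by a rotating magnetic field, first and second normal stress
differences squeeze it along its rotation axis, and it translates along
that axis. The symmetry of the rotating body gives two equal and opposite
propulsion states, $U_+$ and $U_-$; with no bias the state is selected at
random (spontaneous symmetry breaking), while a static field superimposed
along the propulsion axis tilts the particle's dipole and selects one state
deterministically. The propulsion direction is set by the in-plane heading
angle $\theta$, and the particle's speed depends on its surface chemistry
(avidin, biotin, Biotin-PEG3-amine, biotin chitosan), the field settings,
and the local mucus it happens to sit in.

`mucoswim` implements the complete computational chain around such an
experiment — field synthesis, a propulsion simulator, closed-loop waypoint
control, microscopy-style tracking, and velocity analysis — so that every
stage can be exercised and tested without hardware.

# Field model

The coil waveform is
$$
\vec B(t) = \begin{pmatrix}
 -B_s\cos\theta + B_r\sin\theta\,\cos\omega t\\
 \ \ B_s\sin\theta + B_r\cos\theta\,\cos\omega t\\
 \ \ B_r\sin\omega t
\end{pmatrix},
\qquad B_r = \beta f,\qquad \omega = 2\pi f,
$$
a circle of constant radius $B_r$ traced in the plane normal to the heading
vector $\vec n = (-\cos\theta, \sin\theta, 0)$, plus a constant component
$B_s$ along $\vec n$. Two consequences are used as exact invariants in the
tests: $\lVert\vec B\rVert^2 = B_s^2 + B_r^2$ for all $t$, and
$\vec B\cdot\vec n = B_s$. The amplitude–frequency coupling $B_r=\beta f$
keeps the drive torque growing with frequency, which is what pushes the
step-out transition out of the working range; a configurable cap on $B_r$
stands in for the power budget of a physical coil driver.

Note the heading convention: $\theta = 0$ points along $-x$, and
$\theta = \pi$ along $+x$. All modules share this convention; the sweep
drivers propel along $+x$ by commanding $\theta = \pi$.

```{r field}
cfg <- field_config(B_s = 1, beta = 0.5, f = 15, theta = 0)
field_at(cfg, t = c(0, 1/60))
```

# Propulsion model

No constitutive law is available for spontaneous-symmetry-breaking
propulsion in mucus, so the simulator uses a deliberately small
phenomenological law per coating:
$$
U = c\,\bar f\!\left(f, f_c(\beta)\right)\, g(B_s)\, m(x,y)\,(1+\varepsilon),
$$

* $c$ — the speed slope (µm/s per Hz): the linear velocity–frequency
  response observed below step-out.
* $\bar f(f, f_c)$ — the attained rotation rate of an overdamped driven
  rotor: $\bar f = f$ for $f \le f_c$ and
  $\bar f = f - \sqrt{f^2 - f_c^2}$ above, the classical long-time average
  of $\dot\varphi = \omega_c \sin(\omega t - \varphi)$. The tests verify
  this closed form against a `deSolve` integration of the rotor equation to
  better than 1% on a 10×10 grid. Above $f_c$ the average decays
  monotonically toward $f_c^2/2f$.
* $f_c(\beta) = f_{c0}\,(\beta/\beta_{\mathrm{ref}})^p$ with
  $\beta_{\mathrm{ref}} = 0.5$ — the step-out scale. Because $B_r = \beta f$,
  a naive torque balance would make synchrony frequency-independent; the
  exponent $p$ is the simplest family that reproduces the empirical fact
  that nonlinearity appears only in the low-$\beta$ regime (shear-thinning
  fluids do not owe us a constant effective viscosity).
* $g(B_s) = 1 + g_{\mathrm{shape}} B_s^2$ — an even, positive shaping of
  speed by the static field with $g(0)=1$; mucoadhesive coatings are given
  small positive $g_{\mathrm{shape}}$ so their speed grows toward the
  extremes of the static sweep.
* $m(x, y)$ — the local mucus mobility multiplier (below).
* $\varepsilon \sim \mathcal N(0, \sigma_U)$ truncated at $-0.9$ — trial
  multiplicative noise, drawn once per run so trials, not time steps, vary.

The dipole-tilt physics of state selection is abstracted into a threshold
rule: the propulsion sign is $\operatorname{sign}(B_s)$ when
$|B_s| > B_{\mathrm{th}}$ (default 0.1 mT) and a fair coin otherwise.
Direction reversal is carried entirely by the sign $s$; displacement per
control interval is $s\,U\,\Delta t\,(-\cos\theta, \sin\theta)$, integrated
by forward Euler at the control sample interval $\Delta t = 1/30$ s. Euler
is adequate here: the plant is kinematic (no fast internal dynamics) and
the per-step displacement is a small fraction of every relevant length
scale.

An optional Gaussian bump in $1/\beta$ (amplitude, centre, width) may be
attached to a coating. It is a descriptive device for the non-monotone
velocity response seen when $\beta$ is swept at fixed frequency — possibly
a resonance of the rotating particle with the mucin network, but no
mechanism is modelled or asserted; only the beta-sweep presets use it.

# Heterogeneous mucus

Mucus is spatially heterogeneous: mucin glycoproteins concentrate at
random, so nominally identical particles in different regions swim at
visibly different speeds. `make_mucus_field()` models this as a smooth,
strictly positive, mean-one multiplicative mobility field: Gaussian white
noise on a grid, smoothed with a Gaussian kernel of the requested
correlation length (default 10 µm — a few particle diameters), then
exponentiated to a lognormal field and rescaled to mean 1 and the requested
coefficient of variation. Defaults use cv = 0.3; the demonstrations of
region-to-region velocity differences use cv = 0.4, which comfortably
produces the >20% particle-to-particle differences seen in trajectory
experiments. Sampling is bilinear; queries outside the extent are bounds
errors rather than silent extrapolation.

What this generator does *not* emulate: temporal evolution of the fluid,
anisotropy, particle-induced remodelling of the network, and any coupling
between heterogeneity and the step-out scale. Passing tests therefore say
nothing about those aspects of real mucus.

# Closed-loop control

The heading angle is steered by a proportional law
$\dot\theta = k\,\alpha_d$, $\alpha_d = \psi - \theta$, with $\psi$ the
bearing of the active target under the same heading convention
($\psi = \operatorname{atan2}(\Delta y, -\Delta x)$). Discretised at the
30 Hz sample rate, the linearised loop contracts the heading error by
exactly $1 - k\Delta t$ per step — $5/6$ at the default gain $k = 5$ —
which the tests measure to $10^{-6}$. Gains with $k\Delta t > 1$ overshoot
(a warning) and $k\Delta t \ge 2$ diverge (asserted as a negative test).
Heading errors are always wrapped to the shortest arc $(-\pi, \pi]$.

A human operator advanced targets "when the particle got close"; the
package replaces this with an automatic capture radius (default 3 µm,
comfortably above one step of travel) and a run timeout, reported
distinctly from completion. The controller uses the commanded field heading
rather than an image-estimated one: the plant is phase-locked to the field
by construction below step-out, so the two coincide in the model. When the
particle lands exactly on the target mid-step the previous $\psi$ is held
to avoid an undefined bearing.

```{r nav}
nav <- navigate(make_waypoint_plan("A"), start = c(-10, 0),
                speed_fn = constant_speed(10),
                controller = controller_config(timeout = 120))
nav$status
tail(error_series(nav), 3)
```

# Tracking and velocity analysis

The synthetic renderer draws an anti-aliased dark disk (radius 5 µm) on a
bright background at 0.5 µm/px on a 256×256 frame at 30 fps — matching the
control sample rate — with seeded Gaussian intensity noise. The tracker
mirrors a real-time bounding-box pipeline: Otsu threshold, connected
components, keep the component nearest the previous bounding box (largest
when there is no prior), intensity-weighted centroid. On noiseless fixtures
the centroid is recovered to better than 0.1 px, and to ≤0.5 px RMS at
noise sd 0.05.

Velocities are instantaneous frame differences times the frame rate; the
sweep protocols report only the x-component (the commanded propulsion
axis), while trajectory runs report total speed. Trajectory speed series
are conditioned exactly as the experimental videos were: speeds beyond 3×
the series mean are set to that (pre-replacement) mean, then a 60-point
centered moving average is applied with truncated windows at the edges.
Two conventions had to be fixed where the procedure is underspecified:
replacement runs *before* smoothing (recorded in the output flags so the
alternative order can be compared), and the outlier rule is one-sided,
since speeds are non-negative. Note that the full operation is not
idempotent — a moving average applied twice is not the same as once — only
the replacement stage is.

Velocity–frequency profiles aggregate trials as mean ± standard error
(sd/√n), and the linear fits are constrained through the origin:
$\hat c = \sum fU / \sum f^2$, with
$R^2 = 1 - SS_{\mathrm{res}}/SS_{\mathrm{tot}}$, $SS_{\mathrm{res}}$ about
the constrained line and $SS_{\mathrm{tot}}$ about the mean of $U$. The
zero-intercept $R^2$ has no universal convention, so the definition is
spelled out; for a constant profile $SS_{\mathrm{tot}} = 0$ and $R^2$ is
reported as `NA`.

# Coating presets and what they encode

Experimental velocity curves for these systems are published as plots, not
tables, so preset numeric values are invented, shipped as versioned data
(`inst/extdata/coating_presets.json`), and constrained only by the
qualitative structure of each regime:

* **1–19 Hz, β = 0.5** — all coatings linear ($f_c \approx 150$ Hz at this
  β); PEG fastest, biotin slowest, chitosan ≈ avidin.
* **5–50 Hz, β = 0.175** — still linear ($f_c \approx 72$ Hz); biotin ≈
  avidin, PEG slower, chitosan ≈ 2× at 50 Hz.
* **10–100 Hz, β = 0.1** — step-out active ($f_c \approx 50$ Hz), so the
  10–50 Hz sub-range fits a line markedly better than the full range;
  chitosan fastest, then biotin, avidin, PEG.
* **14 Hz β-sweep** — a steeper step-out exponent ($p = 2$) plus the bump
  term gives chitosan its rise-then-fall curve in $1/\beta$ and biotin a
  weak spike near $1/\beta = 3$.
* **15 Hz static sweep** — symmetric speed response; PEG and chitosan carry
  small positive $g_{\mathrm{shape}}$ (faster near ±2 mT).

Simulated cohort sizes default to the experimental ones (9/9/10/7, 5 each,
4/5/4/5 particles across the three sweeps; ≥3 trials each). During sweeps a
small selection field $B_s = 0.5$ mT pins the $U_+$ state so the signed
x-velocity is well defined; the sweep presets have $g_{\mathrm{shape}}=0$,
so this does not perturb the speed law.

```{r sweep}
prot <- sweep_protocol("sweep_1_19", n_trials = 2,
                       n_particles = c(avidin = 3, biotin = 3,
                                       biotin_peg3_amine = 3,
                                       biotin_chitosan = 3),
                       duration = 2)
rb <- run_frequency_sweep(prot, seed = 1)
rb$fits$biotin_peg3_amine
```

# Numerical choices and problem sizes

* Trial velocity is the net x-displacement over the run divided by elapsed
  time (default 10 s simulated; tests and examples use 1–2 s, which is
  exact anyway in the noise-free linear regime).
* All randomness flows from one explicit integer seed per run;
  `withr::with_seed()` scopes it so library calls never disturb the
  caller's RNG. Result bundles are reproducible bit-for-bit from
  (configuration, seed).
* The test-suite ODE oracle integrates the slip-frame rotor equation over
  400 drive periods at `rtol = 1e-9`, on a grid that avoids the
  near-critical band $f/f_c \in (1, 1.3)$ where the beat period diverges
  and any finite-time average converges slowly.
* The mobility-field positivity guard (floor at 0.05) exists for extreme
  cv values; at the default cv ≤ 0.4 it essentially never binds.
* Letter waypoint plans are schematic polylines of ~50 µm extent; at
  10 µm/s ideal-plant speed each letter completes in well under the 150 s
  timeout used in the tests.

# Known limitations

The simulator is kinematic and phenomenological: no normal-stress fluid
mechanics, no 3D dipole dynamics, no wall effects, sedimentation or
particle–particle interactions. The preset constants are synthetic — they
reproduce orderings and regime structure, not absolute experimental
velocities — and the renderer is far from photorealistic (no PSF, no
illumination gradients). Conclusions supported by this package are
therefore about the *procedures* (field synthesis, control, tracking,
analysis) and the qualitative regime structure, not about the physics of
any particular mucus sample.
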