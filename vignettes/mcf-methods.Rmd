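---
title: "Matrix-continued-fraction methods for the theta neuron with colored noise"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Matrix-continued-fraction methods for the theta neuron with colored noise}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thetamcf)
```

## Model and assumptions

The package treats the theta neuron, the phase representation
$x = \tan(\theta/2)$ of the quadratic integrate-and-fire model, driven by a
constant input $\mu$, an Ornstein–Uhlenbeck (OU) noise $\eta(t)$ and up to
two cosine stimuli:

$$\frac{d\theta}{dt} = (1-\cos\theta) + (1+\cos\theta)\,(\mu + \eta + s(t)),
\qquad
\tau\,\frac{d\eta}{dt} = -\eta + \sqrt{2\tau\sigma^2}\,\xi(t).$$

A spike is registered when $\theta$ crosses the threshold $\pi$; the phase
then continues from $-\pi$, so no reset rule is needed. At the threshold the
velocity is exactly 2 for *any* input, which is what makes the firing rate
proportional to the probability density at $\theta=\pi$:
$r(t) = 2\int d\eta\,P(\pi,\eta,t)$.

All times (including $\tau$ and $1/\omega$) are measured in units of the
membrane time constant and all rates in units of its inverse; dividing a
rate by the membrane time in seconds gives Hz. Two standard normalizations
of the noise are provided as parameter maps:

* **constant variance** ($\sigma = 1$): $\hat\mu = \mu/\sigma$,
  $\hat\tau = \sqrt{\sigma}\tau$, rates scale by $\sqrt\sigma$; the noise
  effect vanishes as $\tau \to 0$;
* **constant intensity** ($D = \sigma^2\tau = 1$): $\tilde\mu = \mu/D^{2/3}$,
  $\tilde\tau = D^{1/3}\tau$, rates scale by $D^{1/3}$; this admits a
  nontrivial white-noise limit as $\tau \to 0$.

Both maps are exact symmetries of the model; the test suite verifies that
the numerically computed rate respects them to $10^{-6}$ relative at random
parameter points.

## The stationary solver

The joint Markov process $(\theta, \eta)$ obeys a two-dimensional
Fokker–Planck equation. Its stationary density is expanded in the product
basis of phase Fourier modes and Hermite functions,

$$P_0(\theta,\eta) = \frac{\phi_0(\eta)}{2\pi}
\sum_{p=0}^{\infty}\sum_{n=-\infty}^{\infty} c_{n,p}\,e^{in\theta}\phi_p(\eta),$$

where the $\phi_p$ are the $L^2$-orthonormal eigenfunctions of the
symmetrized OU generator: $\phi_0^2$ is the Gaussian of variance $\sigma^2$
and the ladder relation
$\eta\,\phi_p = \sigma(\sqrt{p+1}\,\phi_{p+1} + \sqrt{p}\,\phi_{p-1})$
holds (this is the standard construction for OU spectral methods; the
package unit-tests orthonormality and the ladder directly). The prefactor
convention is fixed by requiring $c_{0,0} = 1$ to be exactly the
normalization condition of the density; reality of $P_0$ gives
$c_{-n,p} = c_{n,p}^*$.

Substituting the expansion yields a three-term matrix recurrence over the
Fourier index,

$$\hat K_n\,\mathbf c_n = \mathbf c_{n-1} + \mathbf c_{n+1},
\qquad
\hat K_n = 2(\hat B^{-1} - \mathbb 1) - \frac{\hat B^{-1}\hat A}{n},$$

with $\hat A = \mathrm{diag}(iq/\tau)$ and the symmetric tridiagonal
$\hat B$ holding $(1-\mu)/2$ on the diagonal and $-(\sigma/2)\sqrt{p+1}$ on
the off-diagonals. The recurrence is solved by the matrix continued fraction
$\hat S_{n-1} = (\hat K_n - \hat S_n)^{-1}$, truncated with
$\hat S_{n_{\max}} = 0$, after which $\mathbf c_{n+1} = \hat S_n \mathbf
c_n$ propagates the coefficients up from $\mathbf c_0 = (1, 0, \dots)^T$.
Matrix inversions use pivoted LU (LAPACK) with an `rcond` guard.

Two independent rate formulas are evaluated on every solve — the
two-coefficient expression
$r_0 = [(1+\mu) - (1-\mu)\mathrm{Re}\,c_{1,0} + \sigma\,\mathrm{Re}\,c_{1,1}]/(2\pi)$
and the threshold-current sum $(1/\pi)\sum_n (-1)^n c_{n,0}$ — and their
disagreement beyond `check_tol` (default $10^{-6}$ relative, with an
absolute floor of $10^{-12}$ so that two essentially-zero rates count as
agreeing) raises an error: it is the package's primary truncation
diagnostic.

### Truncation choices

The defaults are $n_{\max} = p_{\max} = 150$, matching what is adequate for
the bulk of the $(\mu, \tau)$ plane at $\sigma^2 = 1$. Two regimes need
more:

* **long correlation times** spread the conditional density over many
  Hermite modes; at $\mu = 1, \tau = 10$ the two rate formulas only agree
  to $10^{-6}$ once $p_{\max} \approx 300$;
* **weak noise in the excitable regime** concentrates the phase density
  near the stable fixed point $\theta^* = 2\arctan(-\sqrt{|\mu|})$, so the
  Fourier side decays slowly; at $\mu = -1, \tau = 10^{-3}$ the
  (exponentially small) rate needs $n_{\max} \approx 400$.

Both are the known hard limits of the continued-fraction approach for this
model, and both are caught by the dual-rate diagnostic rather than
returning silently wrong numbers.

One exact-arithmetic quirk deserves emphasis: at $\mu = 1$ the matrix
$\hat B$ loses its diagonal and becomes a zero-diagonal symmetric
tridiagonal matrix, which is *exactly singular whenever its dimension
$p_{\max}+1$ is odd*. The solver refuses with advice to change `p_max`;
all computations at $\mu = 1$ in this package use an odd `p_max`.

## Response to periodic signals

Under $s(t) = \varepsilon\cos\omega t$ the density approaches a
cyclo-stationary state expanded in powers of $\varepsilon$ and stimulus
harmonics, $P = \sum_{\ell,k}\varepsilon^\ell e^{-ik\omega t}
P_{\ell,k}(\theta,\eta)$. Each member solves

$$(\hat L_0 + ik\omega)\,P_{\ell,k} =
\tfrac12 \hat L_\mathrm{per}\,(P_{\ell-1,k-1} + P_{\ell-1,k+1}),$$

seeded by the stationary density, with
$\hat L_\mathrm{per} = \partial_\theta(1+\cos\theta)$ acting spectrally
($(1+\cos\theta)$ couples neighbouring Fourier modes, the derivative
contributes $in$). Members with $k > \ell$ or $k+\ell$ odd vanish
identically; only $k \ge 0$ is solved, negatives follow from
$P_{\ell,-k} = P_{\ell,k}^*$.

**Design choice.** Rather than generalizing the continued fraction to these
inhomogeneous problems, each member is solved as one linear system over all
$(n, p)$ coefficients. In this basis the operator is block tridiagonal over
the Fourier index with dense $(p_{\max}+1)$-sized complex blocks, so a
block-Thomas elimination with LAPACK solves is exact, fast, and — unlike a
nested-fraction scheme — directly *residual-verifiable*: the package applies
the discretized operator to every solution and checks the residual against
$10^{-9}$. The row belonging to the $(n=0, p=0)$ coefficient is replaced by
the normalization constraint (the double integral of every correction
vanishes; that of the stationary member is 1).

The rate components follow from the coefficients at the threshold phase,
$r_{\ell,k} = (2-\delta_{k,0})\,\pi^{-1}\sum_n(-1)^n a_{n,0}$, giving the
susceptibility $\chi(\omega) = r_{1,1}(\omega)$, the time-averaged rate
shift $r_{2,0}$, higher harmonics, and the reconstruction
$r(t) = \sum \varepsilon^\ell |r_{\ell,k}|\cos(k\omega t - \varphi_{\ell,k})$.
The amplitude $\varepsilon$ enters only here, not in the hierarchy. Checks
built into the tests: $\varphi_{1,1}\to 0$ and $|\chi|\to\partial r_0/
\partial\mu$ as $\omega\to 0$ (the derivative computed by central
differences with $d\mu = 10^{-3}$, chosen well above solver noise and small
enough for the smooth $r_0(\mu)$; halving it moves the result by
$<10^{-4}$), $|\chi| \to 2r_0/\omega^2$ with phase $\pi$ as
$\omega\to\infty$, and agreement with simulated PSTH harmonics. The
$\omega\to 0$ and $\omega\to\infty$ checks are evaluated at
$\omega = 10^{-3}$ and $\omega = 50$: beyond the resonant region yet inside
comfortable numerical conditioning.

### Two signals

For $s(t) = \varepsilon_1\cos\omega_1 t + \varepsilon_2\cos\omega_2 t$ the
same machinery runs on a doubly-indexed expansion. The package solves the
hierarchy **up to second order** ($\ell_1+\ell_2 \le 2$): the two linear
members, second harmonics and mean-rate corrections of each channel, and
the two mixed members at $\omega_1+\omega_2$ and $\omega_1-\omega_2$.
Arbitrary-order two-signal expansions are deliberately out of scope. Two
conventions were settled during implementation:

* the normalization integrals run over the full noise line
  $\eta \in (-\infty,\infty)$, consistent with the natural boundary
  conditions and the one-signal hierarchy (a half-line lower limit would
  break the $\delta$-orthogonality that makes the constraint a single
  coefficient);
* a member whose operator frequency $k_1\omega_1 + k_2\omega_2$ falls below
  $10^{-6}$ in magnitude (commensurable degeneracy, e.g.
  $\omega_1 = \omega_2$ for the difference member) makes the operator
  singular; the solver errors with advice to perturb a frequency, and the
  scan driver records such points and continues.

The mixed terms resonate when $\omega_1+\omega_2$ (or
$|\omega_1-\omega_2|$) matches the deterministic angular firing frequency
$2\pi r_\mathrm{det}$; at $\mu=1, \sigma^2=1, \tau=0.05$ the package
computes a converged ratio of about 4.5 between the mixed-response RMS at
the resonant pair $(0.5, 1.5)$ and the detuned pair $(1.0, 1.5)$, the
magnitude of which is validated against simulation in the test suite.

## The Langevin simulator

The simulator is the package's ground truth: Euler–Maruyama for the phase
with step `dt` (default $5\times10^{-3}$), and for the noise either the
**exact OU transition** $\eta \mapsto e^{-dt/\tau}\eta +
\sigma\sqrt{1-e^{-2dt/\tau}}\,\mathcal N(0,1)$ (default; it removes all
time-discretization bias from the noise channel) or the plain
Euler–Maruyama update. Spikes are detected as upward crossings of $\pi$
(the velocity there is always $+2$, so every crossing is upward), with the
crossing time linearly interpolated inside the step before wrapping the
phase by $-2\pi$.

Initial conditions default to stationarity ($\eta \sim \mathcal
N(0,\sigma^2)$, the phase relaxed by a signal-free burn-in); a `reset` mode
($\eta = 0$, $\theta = -\pi$, no burn-in) exists for transient-response
studies. All trials advance in lockstep as vectors drawn from a single
seeded RNG stream: identical settings and seed give bit-identical
ensembles, which the tests assert. (Per-trial counter-based streams would
allow trial-level reproducibility under a changing trial count; the
lockstep design was chosen because it keeps the R implementation vectorized
and exactly reproducible, which is what the oracle role requires.)

Estimators: a count-based stationary rate with across-trial standard
errors; a PSTH (trial-averaged binned rate) with per-bin standard errors;
and Fourier projections of the PSTH onto stimulus harmonics over an integer
number of periods, with a sinc correction for bin averaging — dividing the
first-harmonic amplitude by $\varepsilon$ estimates $|\chi(\omega)|$.

**What the simulations do and do not show.** The Monte-Carlo comparisons
validate that the MCF solver and the Langevin model agree *with each other*
under the stated model: a one-dimensional phase neuron, Gaussian
exponentially-correlated input, stationary or strictly periodic signals.
Passing them says nothing about features of real neurons the model omits —
refractoriness beyond the phase dynamics, spike-triggered adaptation,
network feedback, non-Gaussian or nonstationary input statistics. The
transient after signal onset is likewise outside the cyclo-stationary
theory; estimators therefore discard a transient (the tests use 10–20
membrane time constants) before comparing.

## Problem sizes used by the tests

Module tests run at truncations 40–100 where the dual-rate diagnostic shows
full convergence; the validation tests use 2000–6000 trials of length
30–60 (time step $5\times10^{-3}$), i.e. about $10^5$ observed membrane
time constants per comparison, which puts Monte-Carlo standard errors near
0.5% of the rate. The frequency scan for the second-harmonic resonance uses
40 points at truncation $(80, 79)$; the long-$\tau$ limit checks use
truncations up to $(300, 301)$. These sizes were chosen as the smallest at
which the quantities under test are converged (in the sense of the
truncation-refinement checks), so that the assertions test physics, not
luck.

## Known limitations

* Very long correlation times and very weak noise in the excitable regime
  require truncations that grow quickly (see above); the solver detects,
  rather than survives, these regimes.
* The response hierarchy assumes the perturbative expansion in
  $\varepsilon$ converges at the evaluated order; reconstructions warn when
  they go negative, the usual symptom of leaving the perturbative regime.
* Commensurable two-signal frequencies that zero an operator frequency are
  refused rather than regularized.
* The spike-train power spectrum, harmonic (band-pass) noise, and
  arbitrary-order two-signal responses are out of scope.
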