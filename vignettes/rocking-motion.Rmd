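---
title: "Quantifying rigid-body rocking of proteins in crystal lattices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying rigid-body rocking of proteins in crystal lattices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(latticerock)
```

## The problem

Protein molecules in a crystal are not frozen: beyond their internal
dynamics, each molecule can undergo small-amplitude rigid-body
reorientational fluctuations within its lattice site — "rocking" motion.
Rocking degrades X-ray diffraction resolution and leaves a clear signature
in solid-state NMR: it adds a nearly site-independent offset to the 15N
rotating-frame relaxation rate R1rho measured under magic-angle spinning
(MAS) with a spin-lock, and it scales down all dipolar order parameters by a
common factor. latticerock provides the complete computational chain needed
to quantify this motion: ground-truth simulation of crystal trajectories
with known rocking, extraction of the rocking signal from any multi-copy
crystal trajectory, relaxation theory to translate amplitudes and
timescales into measurable rates, fitting of the corresponding experimental
observables, and crystal packing metrics.

## The rocking observables

For each molecule in the lattice, a per-frame rotation matrix
$\Xi(t)$ is obtained by least-squares superposition (Kabsch fit) of the
Calpha atoms of the molecule (mapped into a common template frame by the
crystal symmetry operations) onto reference coordinates. Translations are
removed by centroid subtraction, so $\Xi$ carries the pure reorientational
signal. The sequence $\Xi(t)$ is turned into an isotropic rocking
correlation function by applying it to a quasi-uniform set of unit vectors
$u_k$ (100 by default, placed by a deterministic generalized spiral so the
result is seed-free):

$$ g_\mathrm{rock}(\tau) \;=\; \big\langle P_2\!\left[ (\Xi(t)u_k)\cdot(\Xi(t{+}\tau)u_k) \right] \big\rangle_{t,k}, \qquad P_2(x) = \tfrac{3x^2-1}{2}. $$

Averaging runs over all time origins (stride configurable for very long
inputs) and all vectors; per-molecule curves are screened for outliers
(root-mean-square deviation from the median curve larger than `k_mad = 3`
times the median of those deviations — the outlier rule is this package's
own definition) and averaged. The mean curve is fitted with a
bi-exponential plus a flat base,

$$ g_\mathrm{rock}(\tau) \approx (1 - c_f - c_s) + c_f e^{-\tau/\tau_f} + c_s e^{-\tau/\tau_s}, $$

whose base $1 - c_f - c_s$ is reported as the rocking order parameter
$S^2_\mathrm{rock}$. Amplitudes are bounded below by zero and both time
constants are confined between the sampling interval and the curve length;
a multi-start strategy over a log-spaced $(\tau_f,\tau_s)$ grid guards
against local minima. Two labelling rules keep $c_s$ attached to the
physically dominant slow component, which downstream relaxation mapping
consumes: components whose time constants collapse (ratio above 0.5) are
merged, so a mono-exponential curve yields its full amplitude in $c_s$;
and a component slower than — but much weaker than (amplitude below a
quarter of) — the dominant decay is folded into it by amplitude-weighted
geometric averaging of the time constants. The latter matters on finite
trajectories: when the slow decay is sampled only a few hundred memory
times over, the correlation tail drifts and the fit would otherwise spend
$c_s$ on a faint artefactual ultra-slow term, demoting the real rocking
component to the fast slot.

## From motion to relaxation rates

Site dynamics are described in model-free form: a P2-normalized correlation
function $C(\tau) = S^2 + \sum_i c_i e^{-\tau/\tau_i}$ with spectral density

$$ J(\omega) = \frac{2}{5} \sum_i \frac{c_i \tau_i}{1 + (\omega\tau_i)^2}. $$

The 2/5 factor is carried inside $J$ — a convention choice that must be
stated, since rate formulas move it around in the literature. Only the
decaying part of $C$ relaxes; the plateau does not.

Longitudinal relaxation uses the standard NH-dipolar + 15N-CSA expression
$R_1 = \frac{d^2}{4}[J(\omega_H-\omega_N) + 3J(\omega_N) +
6J(\omega_H+\omega_N)] + c^2 J(\omega_N)$ with
$c = \Delta\sigma\,\omega_N/\sqrt{3}$.

For the spin-locked rate under MAS, the static secular spectral density
$J(0)$ of the solution-state expressions is redistributed by sample
rotation over the sidebands of the spin-lock frequency with the rank-2
Wigner weights (2/3 at $\omega_1 \pm \omega_r$, 1/3 at
$\omega_1 \pm 2\omega_r$, split evenly over the two signs):

$$ \tilde J = \tfrac{1}{3}\left[J(\omega_1-\omega_r) + J(\omega_1+\omega_r)\right] + \tfrac{1}{6}\left[J(\omega_1-2\omega_r) + J(\omega_1+2\omega_r)\right], $$

$$ R_{1\rho} = \frac{d^2}{4}\left[2\tilde J + \tfrac12 J(\omega_H-\omega_N) + \tfrac32 J(\omega_N) + 3J(\omega_H) + 3J(\omega_H+\omega_N)\right] + c^2\left[\tfrac23 \tilde J + \tfrac12 J(\omega_N)\right]. $$

An on-resonance spin-lock is assumed throughout (no off-resonance tilt).
Because transcribing such coefficient sets is error-prone, the test suite
pins the expression against an independent numerical model: explicit
propagation of spin-locked magnetization under the MAS-modulated secular
dipolar and CSA offsets with two-site orientational exchange
(`r1rho_numeric_jump()`), implemented as exact per-step Bloch rotations
with a Strang-split exchange superoperator, powder-averaged over a
deterministic quasi-uniform orientation grid (144 orientations by default,
100 steps per rotor period, refined automatically for fast exchange). Each
crystallite's decay is fitted log-linearly and the rates powder-averaged —
the quantity the powder-averaged Redfield expression describes. The two
routes agree to within a few percent wherever the exchange correlation time
is short compared to the inverse of the smallest sampled frequency gap
$|\omega_1 - n\omega_r|$, and the numerical model remains valid beyond,
where Redfield theory overestimates the rate; `r1rho_redfield()` attaches
an advisory attribute in that territory. The rate surface over
$(S^2, \tau)$ is unimodal in $\tau$ for every amplitude, so a measured base
rate is consistent with exactly two timescales; `solve_tau_branches()`
returns both, and `iso_rate_contour()` traces whole contours by root
finding (points re-evaluate to the target rate, rather than being
interpolated off a grid).

When mapping a fitted rocking correlation function into a rate, only the
slow component is used ($1 - S^2 = c_s$, $\tau = \tau_s$): a nanosecond
fast component of amplitude a few thousandths changes the result by less
than two percent (asserted in the tests), so excluding it is safe.

## Ground truth: the synthetic crystal generator

No public trajectory data are needed anywhere in the package: all
trajectory-level functionality is exercised against synthetic lattices with
exactly known motion.

* **Lattice** — a template chain (a synthetic, clearly labelled
  mini-protein with N, H and Calpha atoms) expanded by proper rigid
  symmetry operators in fractional coordinates and integer unit-cell
  replication; every copy stores the transform that generated it, so
  analyses can map copies back to the common frame. Operators whose
  Cartesian rotation part is not orthonormal with determinant +1 are
  rejected.
* **Rocking** — two stand-in processes (the motivating observations come
  from crystal MD, which supplies no generative model, so these are
  explicit models with exact statistics, not re-creations of any particular
  crystal): a symmetric two-site jump by angle $\Phi$ about a fixed axis
  with exponential dwell times, and restrained diffusion implemented as
  independent Ornstein–Uhlenbeck processes on the three components of a
  rotation vector, composed through the exponential map (an approximation
  valid for $\sigma \lesssim 0.3$ rad). For the OU process the stationary
  isotropic plateau has the closed form $S^2 = g^2$,
  $g = [1 + 2(1-\sigma^2)e^{-\sigma^2/2} + 2(1-4\sigma^2)e^{-2\sigma^2}]/5$,
  inverted by `sigma_for_plateau()`; tests verify it against brute-force
  Monte-Carlo sampling of the stationary distribution.
* **Two-site geometry, carefully** — for a *vector* jumping by $\Phi$
  (the geometry of the numerical relaxation model), the plateau is the
  classic $(1+3\cos^2\Phi)/4$. For a whole molecule jumping by a rotation
  of angle $\Phi$, probe vectors at different angles to the axis reorient
  by different amounts, and the isotropic-vector plateau is
  $(1 + \chi_2(\Phi)/5)/2$ with $\chi_2$ the rank-2 rotation character —
  never below 0.375. Both closed forms are exported
  (`two_site_s2()`, `jump_plateau_isotropic()`) and both are tested; probe
  vectors perpendicular to the jump axis recover the classic formula
  exactly. Conflating the two geometries is a real pitfall in this
  analysis.
* **Internal motion** — amide H wobble as a jump-refresh uniform-in-a-cone
  process: at rate $1/\tau_\mathrm{int}$ the NH direction is redrawn
  uniformly within the cone. The stationary distribution is exactly uniform
  in the cone, so the order parameter equals the diffusion-in-a-cone closed
  form $[\cos\theta_0(1+\cos\theta_0)/2]^2$ and the memory is exactly
  exponential — chosen over a tangent-plane diffusion precisely so the
  trajectory-level oracle is closed-form. Only H moves; N and Calpha stay
  fixed, keeping the rigid-body fit independent of internal motion.

What the generator does *not* emulate: lattice disorder and progressive
structural drift, anisotropic rocking, translational diffusion, correlated
motions between neighbouring molecules, solvent. Passing tests therefore
demonstrate the correctness of the analysis chain on clean rigid-body
signals, not the fidelity of any force field or the convergence of real MD.

## Internal dynamics

Per-residue order parameters use the Bruschweiler–Wright formula on the
time-averaged Cartesian second moments of the NH unit vectors, after
superposing all symmetry copies into the template frame and pooling their
samples into one long array (the Cartesian and spherical-harmonic forms of
the formula are algebraically identical, so the choice is cosmetic).
Correlation functions are computed per residue on a logarithmic lag grid
(about 25 points per decade from the time step to a fifth of the
trajectory, the same grid used for `g_rock`), averaged over molecules but
never across molecule boundaries, and fitted by non-negative least squares
over a fixed dictionary of 40 log-spaced correlation times plus a free
constant, pruned to at most six components. Fitted times are capped at the
trajectory length: slower motion is indistinguishable from the constant.
Individual (amplitude, tau) pairs of such fits are not identifiable — only
the reconstructed curve is, and tests assert reconstruction error rather
than component equality. A closed-form scaling factor
(`global_s2_scaling()`) compares order-parameter profiles between datasets.

## Experimental curve fitting

Relaxation decays are fitted as $A e^{-Rt}$ with errors from Monte-Carlo
noise resampling at the curve's noise level. REDOR dephasing for an
isolated 15N–1H pair with ideal pi pulses is computed from the exact
analytic phase integral of the MAS-modulated dipolar frequency with the
REDOR sign alternation, powder-averaged by 64-point Gauss–Legendre
quadrature in $\cos\beta$ times a 64-point $\gamma$ grid (the $\gamma$
average is kept numerical so arbitrary, not just rotor-synchronous, times
are supported); the ideal-pulse result matches the quarter-order
Bessel-function universal curve to better than $10^{-3}$. Radio-frequency
field inhomogeneity enters as a weighted mixture of scale factors on the
effective coupling (default: 7-point Gaussian, mean 1, 5% sd — a stand-in
for the unpublished probe profile; finite-pulse effects are out of scope).
Couplings are fitted by a chi-square grid search with parabolic refinement,
and errors come from Monte-Carlo resampling with the noise inflated
threefold by default, mirroring the conservative practice of using three
times the spectral noise level. `coupling_to_s2()` converts a fitted
coupling into an order parameter via the rigid-limit coupling at
$r_\mathrm{NH}$.

## Parameters, defaults, and why

| parameter | default | rationale |
|---|---|---|
| $r_\mathrm{NH}$ | 1.02 Å | standard effective NH bond length for dipolar couplings; configurable |
| $\Delta\sigma$(15N) | −170 ppm | typical backbone amide 15N CSA (axially symmetric, unique axis along NH); configurable |
| field / MAS / lock | 600 MHz / 39.5 kHz / 15 kHz | the measurement conditions of the motivating experiments |
| vector set size | 100 | sufficient for isotropy to ~0.01 in the second moments; deterministic spiral, so results carry no seed |
| lag grid | 25 pts/decade to T/5 | resolves multi-decade decays while bounding cost; origins at stride 1 by default |
| `k_mad` | 3 | conventional robust-outlier multiplier; the underlying outlier rule is this package's own definition |
| dictionary | 40 taus, max 6 terms | enough resolution for smooth correlation functions without overfitting |
| powder grids | 144 orientations (relaxation), 64×64 (REDOR) | convergence checked against larger grids in development |
| gyromagnetic constants | CODATA 2018 | pinned in `nmr_constants()` |

Physical constants and gyromagnetic ratios are pinned so every rate is
reproducible to the digit. All generator randomness flows from a single
integer seed recorded in outputs; the packaged demo pipeline reproduces its
report byte-for-byte under a fixed seed.

## Numerical choices and degenerate inputs

Kabsch fits reject selections with fewer than three atoms or collinear
reference geometry, and force determinant +1 when the unconstrained optimum
is a reflection. Correlation values at lag zero equal one by construction.
The branch solver brackets the rate maximum on a log-tau grid before
bisecting each side, returns an explicit no-solution marker when the target
exceeds the maximum, and reports coincident roots at tangency. The
rotary-resonance conditions $\nu_1 = \nu_r$ and $\nu_1 = 2\nu_r$ raise
warnings. Trajectory sizes used in the shipped tests (a hundred thousand
frames for parameter-recovery checks, a few thousand for smoke tests) were
chosen as the smallest sizes at which the statistical tolerances quoted in
the tests are comfortably met.

## Worked example

```{r example, eval = FALSE}
report <- run_pipeline(demo_config(), seed = 1)
report
tidy_fit <- report$rocking_fit        # plateau, c_f, c_s, tau_f, tau_s
report$rocking_r1rho_s                # rocking contribution to R1rho

cond <- spectrometer_conditions()
solve_tau_branches(12, s2 = 0.985, cond)   # the two timescales behind a rate
```

## Known limitations

* Rocking anisotropy is not decomposed (the isotropic correlation function
  is the only rocking observable); translational disorder is not modelled.
* The Redfield expressions assume an on-resonance spin-lock and neglect
  CSA/dipolar cross-correlation; the numerical model covers only the
  secular relaxation pathway (negligible high-frequency terms for the slow
  motions it targets).
* The OU rotation-vector process is an approximation to restrained
  rotational diffusion, accurate for per-axis spreads below about 0.3 rad.
* REDOR is simulated for an isolated spin pair with ideal pulses;
  multi-spin effects and finite pulse widths are out of scope.
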