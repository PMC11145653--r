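---
title: "Excitonic analysis of light-harvesting complexes: models and methods"
author: "excitonkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Excitonic analysis of light-harvesting complexes: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(excitonkit)
```

# Scope

`excitonkit` implements the reduced excitonic description commonly used
for plant light-harvesting complexes: a Frenkel Hamiltonian for the
coupled Qy two-level systems of the chlorophylls, bath spectral densities
estimated from site-energy fluctuations, secular-Redfield and
second-order-cumulant optical spectra, and ensemble-averaged wave-packet
(NISE) population dynamics. The package consumes the *outputs* of
atomistic simulation — energy-gap trajectories, geometries, transition
charges — or synthetic stand-ins for them; it does not run MD or
excited-state electronic structure. The shipped example system is the
minor antenna complex CP24 of Photosystem II (11 chlorophylls: six Chl-a,
five Chl-b), whose time-averaged Hamiltonian is packaged as a plain-text
fixture.

# The exciton Hamiltonian

Site energies $E_i$ and couplings $V_{ij}$ (both cm$^{-1}$) form
$H = \sum_i E_i |i\rangle\langle i| + \sum_{i\neq j} V_{ij}
|i\rangle\langle j|$. Printed tables are often rounded, so
`parse_hamiltonian()` accepts an asymmetry up to 0.05 cm$^{-1}$ and
removes it by averaging $V$ with $V^\top$, recording the largest
asymmetry found. Internally everything is cm$^{-1}$; eV is accepted on
input only (1 eV = 8065.544 cm$^{-1}$).

Diagonalization uses the dense symmetric eigensolver. Two conventions
make the output platform-independent: each eigenvector's
largest-magnitude coefficient is made positive (ties to the lowest site
index), and degenerate states are ordered by their dominant site.
Exciton transition dipoles are $\vec d_\mu = \sum_i c_i^\mu \vec d_i$,
which preserves the total dipole strength exactly because the coefficient
matrix is orthonormal.

Coupling clusters are the connected components of the graph with edges
where $|V_{ij}|$ exceeds a threshold (30 cm$^{-1}$ reproduces the three
CP24 clusters plus the isolated b607):

```{r clusters}
h <- table2_fixture()
coupling_clusters(h, threshold = 30)
```

# TrEsp couplings

The vacuum coupling is the Coulomb sum over atomic transition charges,
$V = C\sum_{IJ} q_I q_J / r_{IJ}$ with
$C = e^2/4\pi\varepsilon_0 = 1.16146\times 10^5$ cm$^{-1}$ Å (charges in
e, distances in Å; the constant is fixed for bit-reproducibility).
Charges are first rescaled by a single scalar so the set's transition
dipole matches the experimental magnitudes, 5.7 D for Chl-a and 4.6 D
for Chl-b. Environmental screening multiplies the sum by
$f(R_{mn}) = A e^{-B R_{mn}} + f_0$ with defaults $A = 2.68$,
$B = 0.27$ Å$^{-1}$, $f_0 = 0.54$; it is never applied to site energies.

The intermolecular distance $R_{mn}$ is not uniquely defined in the
literature; the package defaults to the geometric center of the
charge-bearing atoms, which is always available, and accepts explicit
centers (e.g. Mg positions) through the `centers` argument. Real
chlorophyll transition charges are user-supplied — the package ships only
synthetic toy sets (`toy_pigment()`), deliberately, to avoid restating
published charge tables it cannot verify.

# Spectral densities

The bath is characterized by the cosine transform of the site-energy
autocorrelation $C(\tau)$ (unbiased estimator, FFT-based):

$$J(\omega) = \frac{\beta\omega}{\pi\hbar}
  \int_0^{t_\max} C(\tau)\cos(\omega\tau/\hbar)\,\mathrm d\tau,
  \qquad
  \lambda = \frac{1}{\pi}\int_0^\infty \frac{J(\omega)}{\omega}
  \,\mathrm d\omega .$$

Transform conventions differ across the literature; this one was chosen
because it closes on itself: an Ornstein–Uhlenbeck bath with variance
$\sigma^2$ and correlation time $\tau_c$ maps *exactly* onto the
Drude–Lorentz form $J = 2\lambda\gamma\omega/(\omega^2+\gamma^2)$ with
$\lambda = \beta\sigma^2/2\pi$ and $\gamma = \hbar/\tau_c$, so parameter
recovery is testable end to end (the test suite requires the round trip
to recover $\lambda$ within 20%).

Defaults: 2 ps transform window with a Hann taper (stable at the 10⁵–10⁶
frame trajectory lengths the generator produces; the window's ~17
cm$^{-1}$ symmetric broadening does not move peak positions), frequency
grid 0–2500 cm$^{-1}$ in 10 cm$^{-1}$ steps, $T = 300$ K,
$k_B = 0.695035$ cm$^{-1}$/K, $\hbar = 5308.84$ cm$^{-1}$ fs. Negative
lobes from windowing are clamped to zero and the clamped fraction is
recorded in an attribute. The $\omega = 0$ integrand of the $\lambda$
integral is replaced by its linear-slope limit.

`parametric_sd()` provides the standard overdamped Drude–Lorentz and
underdamped Brownian-oscillator forms, each parameterized directly by its
reorganization-energy contribution, for analytic baths and ground truths.

# Lineshapes and spectra

Redfield rates between exciton states use the secular expression
$k_{\nu\leftarrow\mu} = (2\pi/\hbar)\sum_m |c_m^\mu|^2 |c_m^\nu|^2
J_m(\omega_{\mu\nu})\,(n(\omega_{\mu\nu})+1)$ for downhill transitions
and detailed balance $k_{up} = k_{down}e^{-\beta\hbar|\omega|}$ uphill,
so detailed balance holds to machine precision by construction. Lifetimes
are inverse total depopulation rates.

The lineshape function is the standard second-order cumulant
$$g(t) = \frac{1}{\pi}\int_0^\infty \mathrm d\omega\,
 \frac{J(\omega)}{\omega^2}\Big[\coth(\beta\omega/2)(1-\cos\omega t)
 + i(\sin\omega t - \omega t)\Big],$$
transformed to the exciton basis with $|c|^4$ participation weights
(likewise $\lambda_\mu = \sum_m |c_m^\mu|^4\lambda_m$). Absorption per
state is the half-Fourier transform of
$\exp[-i(E_\mu-\lambda_\mu)t/\hbar - g_\mu(t) - t/2\tau_\mu]$, summed as
$\alpha(\omega)\propto\omega\sum_\mu|d_\mu|^2 D_\mu(\omega)$; the
cumulant variant simply omits the lifetime term and therefore coincides
with the Redfield spectrum as $\tau\to\infty$ (a tested identity).
Emission mirrors each state's profile about $E_\mu - 2\lambda_\mu$
(conjugate-$g$ response centered at $E_\mu-3\lambda_\mu$), weighted by
Boltzmann populations and $\omega^3$; for a slow bath this reproduces the
classical $2\lambda$ Stokes shift. The full complex $g$ is used
throughout. Spectra are computed by direct trapezoid quadrature of the
time integral on a grid dense enough for the phase (2 fs default in the
analysis scripts), floored at zero, optionally peak-normalized. Rigid
red-shifts — presentation devices when comparing with experiment — are an
explicit argument and never applied silently. No static disorder is
added by default; site-energy means can simply be redrawn by the caller
to emulate it.

# NISE dynamics

The time-dependent Hamiltonian holds couplings at their time-averaged
values while site energies fluctuate frame by frame. Within each stored
frame the Hamiltonian is constant and the wave function advances by the
exact eigen-exponential of the 11×11 frame Hamiltonian (implemented in
C++ via Armadillo), which conserves the norm unconditionally; per-frame
propagators are precomputed once and shared across all overlapping
windows. One long trajectory (default 40 ps, 1 fs frames) is split into
1000 windows of 6 ps whose offsets are evenly spaced — deterministically,
not randomly — over the available range and floored to frame boundaries.
Realizations are therefore not fully independent, which is the accepted
price of the windowing scheme.

Ensemble-averaged wave-packet dynamics does not thermalize: at long times
it tends to equal populations of the coupled sites, not a Boltzmann
distribution. The relaxation-time extraction reflects this: the plateau
inside an $N$-site coupling cluster is taken as $1/N$ and the reported
time is the first crossing of $P_\infty + (1-P_\infty)/e$ by the
initial-site population (no published extraction rule exists; this 1/e
rule is the package's documented choice, and it is degenerate for
singleton clusters).

# The synthetic-data generator

`gen_site_trajectory()` emulates energy-gap trajectories as stationary
Gaussian processes: exact-discretization Ornstein–Uhlenbeck components
plus AR(2) damped stochastic oscillators, mixed by variance weights and
scaled to a marginal standard deviation `sigma`. The defaults — one OU
mode, $\sigma = 710$ cm$^{-1}$ ($\approx 0.088$ eV, the reported
magnitude of chlorophyll site-energy fluctuations in a protein at 300 K)
and $\tau_c = 50$ fs — define the study conditions used by the tests and
the acceptance script. Cross-site correlations are zero (sites are
treated independently); seeds make every trajectory bit-reproducible and
the global RNG state is restored on exit.

What the generator does *not* emulate matters for interpretation: real
chlorophyll baths carry much of their variance in underdamped
intramolecular modes above 1000 cm$^{-1}$, while a pure OU process puts
all of it below a few hundred cm$^{-1}$. Tests passing under OU noise
therefore validate the machinery (propagation, windowing, estimation),
not quantitative transfer rates of real systems — with the whole 710
cm$^{-1}$ at low frequency, inter-site transfer is systematically faster
than with a structured bath, and in particular the near-absence of
transfer between the two stromal-side CP24 clusters seen with
QM/MM-derived baths is *not* reproduced (the generator's spectral weight
at the inter-cluster gaps is several times too large). The underdamped
mode support exists precisely so users can build structured baths when
that distinction matters.

# Structural descriptors

Mg coordination uses the standard 2.5 Å cutoff, with water distances
measured Mg–O. The four porphyrin nitrogens are counted implicitly
(coordination number = 4 + axial ligands), matching the usual
five-/six-coordinated language. The cis/trans water classification (Wc /
Wt) is geometric — no published rule defines it — as the sign of the
water's distance from the least-squares porphyrin plane relative to the
first phytyl-chain atom; waters within 0.1 Å of the plane are flagged
ambiguous. RMSF superposes each frame on the mean structure (Kabsch, one
self-consistency pass); note the rigid-body fit removes 6 of the $3N$
fluctuation degrees of freedom, visible for small atom sets.
Representative-frame selection runs PCA on flattened Mg coordinates,
keeps components explaining ≥ 90% of the variance, and clusters with
K-means using 50 seeded random restarts — `stats::kmeans` has no
k-means++ initializer, and at these problem sizes multi-start is equally
robust; returned frames are those nearest each centroid.

# Problem sizes and numerics

The test suite and acceptance script run at desk scale by design:
spectral-density estimation uses 10⁶-frame trajectories (the package's
FFT autocorrelation makes this a second or two), NISE uses the full
1000 × 6 ps windowing on the 11-site fixture (≈ 1 min via the compiled
propagator), and spectra use 1–2 fs time grids over 1.5–3 ps. Tolerances
quoted in the tests (e.g. λ recovery within 20%, Stokes shift within
10%, detailed balance 10⁻¹⁰) are properties of the estimators and
identities involved, not tuned margins.

# Known limitations

* Site energies and transition charges for real pigments must be
  supplied by the user; the package validates machinery on synthetic
  stand-ins and the packaged Hamiltonian.
* Redfield spectra share the known weaknesses of secular Markovian
  theories for weakly coupled clusters; the cumulant absorption is the
  more faithful lineshape but omits lifetime broadening.
* No two-exciton manifold, charge-transfer states, carotenoids, vibronic
  models, static-disorder averaging or inter-complex transfer.
* The NISE scheme has no back-reaction (infinite-temperature limit) and
  its long-time populations are equal, not thermal.
* Wc/Wt classification is per frame; water identity is not tracked across
  frames (swapped-water bookkeeping has no published rule and is out of
  scope).
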