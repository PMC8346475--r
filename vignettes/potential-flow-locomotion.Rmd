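---
title: "A unified potential-flow view of swimming, flying and diving"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A unified potential-flow view of swimming, flying and diving}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(potflow)
```

## The model

Animal appendages — wings, fins, flukes — are thin and wide, and a diving
body pushing through the free surface behaves, in cross-section, like a
widening plate. `potflow` builds everything on the single canonical
solution for a rigid thin plate of half-width $c$ moving normal to itself
at speed $V$ in an inviscid, incompressible fluid. Its complex potential is

$$\Phi = \phi + i\psi = -iVz + iV\,(z^2-c^2)^{1/2}, \qquad z = x + iy,$$

with complex velocity $d\Phi/dz = u - iv = -iV + iVz/(z^2-c^2)^{1/2}$.
Everything else in the package — circulation, pressure, added mass, impact
force, thrust — is an integral or a limit of this one solution. The model
is inviscid and instantaneous: there is no wake history, no vortex
shedding dynamics, no viscous correction. The $y$ axis points up and
$V < 0$ means downward motion; public summaries report force and pressure
magnitudes, with `signed = TRUE` accessors restoring the convention in
which reaction forces oppose the motion.

### The branch cut is the plate

The square root $(z^2-c^2)^{1/2}$ is deliberately *not* the principal root
of $z^2 - c^2$: that choice would put branch cuts along the horizon
$|x| > c$ and destroy the boundary conditions there. Instead the package
computes the product of principal roots
$\sqrt{z-c}\,\sqrt{z+c}$, which in elliptical coordinates
($z - c = r_1 e^{i\theta_1}$, $z + c = r_2 e^{i\theta_2}$,
$\theta \in (-\pi,\pi]$) equals
$\sqrt{r_1 r_2}\, e^{i(\theta_1+\theta_2)/2}$ and places the only cut on
the plate segment itself. The test suite verifies the two constructions
agree to $10^{-12}$ relative on $10^4$ random points, and that the
solution then satisfies all four boundary conditions:

* on both plate faces, $v = V$ (kinematic condition) and a tangential slip
  $u_\pm = \pm Vx/(c^2-x^2)^{1/2}$;
* on the horizon $y = 0$, $|x| > c$: $u = 0$ and $\phi = 0$.

The equipotential horizon is what lets the same solution serve the
free-surface (diving) problem: $\phi = 0$ on $y=0$ is precisely the
linearised free-surface condition.

Points exactly on the open plate segment are ambiguous in floating point
(`y = +0` and `y = -0` are indistinguishable), so the on-plate functions
`face_potential()` and `face_velocity()` take an explicit `side`
argument, and the off-plate functions refuse on-cut input rather than
silently picking a face.

### Circulation

The slip-velocity jump integrates to the circulation bound in each shed
edge vortex: $\Gamma^{(\mathrm{right})} = -2Vc$ and
$\Gamma^{(\mathrm{left})} = +2Vc$, summing to zero (Kelvin's theorem).
`edge_circulation()` exposes both the closed form and an independent
quadrature that substitutes $x = c\sin\theta$, turning the integrable
edge singularity $x/(c^2-x^2)^{1/2}$ into the bounded $c\sin\theta$. The
substitution is a correctness requirement, not a convenience: adaptive
quadrature on the raw integrand stalls at the endpoint.

### Pressure

The unsteady Bernoulli equation gives the pressure jump across a
submerged plate as a pure time derivative,

$$\frac{p_- - p_+}{\rho} = -2\,\frac{\partial}{\partial t}
  \left[V(c^2-x^2)^{1/2}\right],$$

the quadratic $|\nabla\phi|^2$ term being equal on the two faces. For a
plate at the free surface only the water side is loaded, and the
steady-inertia term $-\tfrac12 V^2 c^2/(c^2-x^2)$ reappears — singular at
the plate tips. The package omits it by default
(`include_singular_term = FALSE`), keeping the slamming term whose
integral is finite; with the flag on, tip values overflow to `-Inf`
rather than raising. No regularisation of the edge singularity is
offered: omission is the only treatment implemented, and the flag exists
so users can see what is being dropped.

## Added mass

Integrating the face-potential jump gives the 2D plate added mass per
span, $\rho\pi c^2$; a test verifies the quadrature route against the
closed form to $10^{-8}$. Three 3D shapes have closed forms:

* **Prolate spheroid** (semi-axes $a \ge b$, eccentricity
  $e = \sqrt{1-b^2/a^2}$): $M = K_i\,\tfrac43\pi\rho a b^2$ with
  $K_\mathrm{Axial} = \alpha_0/(2-\alpha_0)$ and
  $K_\mathrm{Lateral} = \beta_0/(2-\beta_0)$, Lamb's coefficients.
* **Sphere**: the $e = 0$ limit, $K = 1/2$ in every direction.
* **Elliptical disc**, broadside: $K = 1/E(e)$ with $E$ the complete
  elliptic integral of the second kind (via `pracma::ellipke`), applied
  to the same $\tfrac43\pi\rho a b^2$ base. Only $K$ has a printed closed
  form; the base is fixed by requiring the circular-disc limit to equal
  the classical $\tfrac83\rho a^3$, which it does exactly at $e = 0$
  since $E(0) = \pi/2$.

The closed forms for $\alpha_0(e)$ and $\beta_0(e)$ are $0/0$ at $e = 0$
and lose digits to cancellation well before that. Below $e = 0.05$ the
package switches to their Maclaurin series,
$\alpha_0 = \tfrac23 - \tfrac{4}{15}e^2 - \tfrac{4}{35}e^4 - \cdots$ and
$\beta_0 = \tfrac23 + \tfrac{2}{15}e^2 + \tfrac{2}{35}e^4 + \cdots$
(through $e^8$). The switch point was chosen so that both the sphere
limit is exact and the two branches agree to better than $10^{-10}$ at
the seam: at $e = 10^{-3}$ the closed forms in double precision are only
$\sim 10^{-9}$-accurate, so a smaller threshold would not meet that
continuity requirement. The series coefficients were derived
independently and checked against a 40-digit evaluation of the closed
forms; frozen high-precision values at $b/a = 1/2$
($K_\mathrm{Axial} = 0.21002$, $K_\mathrm{Lateral} = 0.70421$) anchor
the tests.

## Diving impact

A body of mass $M$ jumping to height $H$ re-enters the water at
$V = \sqrt{2gH}$. During entry the wetted added mass grows, and the
slamming force is $F = -V\,d(M_\mathrm{added}/2)/dt -
(M_\mathrm{added}/2)\,dV/dt$ — the half because only the water side of
the growing section is loaded. Approximating the body as a prolate
spheroid and evaluating at the moment of maximum cross-section (where
the peak occurs, with $dV/dt = 0$ there):

$$F_\mathrm{Head\text{-}first} \simeq K_\mathrm{Axial}\,\tfrac23\pi\rho
  b^2 V^2, \qquad
  F_\mathrm{Belly\text{-}first} \simeq K_\mathrm{Lateral}\,\tfrac43\pi
  \rho a b V^2.$$

Head-first entry grows the axial wetted extent (only $a$ is
time-dependent, $V \approx da/dt$); belly-first grows the lateral one.
The shape coefficient is held frozen at the full-body value throughout
entry. This is a genuine modelling choice, not an innocuous one: if the
coefficient instead follows the instantaneous immersed aspect ratio, the
product $K_\mathrm{Axial}(e(t))\,a(t)$ is *decreasing* near the maximum
section for a 2:1 body, and the instantaneous-coefficient "peak" differs
from the frozen-coefficient formula by a factor of about three with the
opposite trend. The frozen form is the one whose predictions the
comparative survey uses, and the time-resolved test verifies it exactly
in its own terms.

The impact pressure is the peak force over the wetted area, taken as
half the spheroid surface $\pi b^2(1 + \tfrac{a}{be}\arcsin e)$ (sphere
limit $2\pi r^2$, again via a small-$e$ series). `impact_pressure()` is
computed as the literal quotient, so the force/area/pressure identity is
exact by construction and tested to $10^{-10}$ on random bodies.

Composing the empirical jump-height allometry $H \propto L^{2/3}$ with
isometry ($M \propto L^3$, area $\propto L^2$) gives
$F \propto M^{8/9}$ and $P \propto M^{2/9} \approx M^{0.22}$: impact
force grows almost linearly with mass while impact pressure is nearly
size-independent — the scaling reason animals of any size can dive.
`allometric_exponents()` does this composition for arbitrary input
exponents.

```{r}
allometric_exponents()
```

## Flapping thrust, flight and swimming

For a plate flapping as $V(t) = A(2\pi f)e^{i2\pi ft}$ the pressure-jump
integral gives a sinusoidal force per unit span of amplitude
$\rho\pi c^2 A(2\pi f)^2$. Its period average vanishes for a symmetric
stroke; real animals break the symmetry (angle-of-attack changes, wing
folding), which the model absorbs into a fitted group prefactor rather
than predicting from first principles. `thrust_amplitude_per_span()`
therefore reports the amplitude, the dimensional scaling form
$\rho c^2 A f^2$, and the constant $4\pi^3$ between them — never a mean
thrust.

* **Fliers** cruise with flapping force balancing weight:
  $Mg = \beta\,\rho c^2 A f^2 L$. The prefactor $\beta$ is fitted per
  group with `fit_prefactor()` (bats and birds evolved flight
  independently and get separate values). An optional `mass_cutoff`
  excludes the smallest fliers, which systematically deviate from the
  balance.
* **Swimmers** balance thrust against drag. Form drag gives
  $U = \beta f\sqrt{Ac}$; Blasius skin drag (relevant to larvae) gives
  $U \propto (Ac)^{2/3} f^{4/3} L^{1/3}\nu^{-1/3}$. The automatic regime
  switch uses the Reynolds number of the form-drag estimate against a
  threshold of $Re = 5000$, reflecting that most adult swimmers sit at a
  few thousand and above; the threshold is a configurable argument, the
  switch is deterministic, and no continuity between the two laws is
  claimed — they are different asymptotic balances, not a matched
  expansion.

The inverse of the swimmer prefactor is the cruise Strouhal number in
this package's geometric-mean convention,
$St = f\sqrt{Ac}/U_\mathrm{swim}$ — degree-zero homogeneous in
$(A, c, U)$, which the property tests assert. Kinematic viscosities
default to $1.00\times10^{-6}\,\mathrm{m^2/s}$ (freshwater) and
$1.05\times10^{-6}\,\mathrm{m^2/s}$ (seawater) at 20 °C, with densities
1000 and 1025 kg/m³.

## The synthetic populations

`generate_population()` emulates the *structure* of a compiled
comparative dataset — per-animal morphometrics plus stroke kinematics —
so that every fitting pipeline can be exercised end-to-end with a known
ground truth. It is explicit about what it does and does not emulate.

Body lengths are log-uniform over the group's range: divers 0.1–10 m
(goldfish to small whale), flier spans 0.25–1.5 m, swimmers 0.02–2 m
(larva to large fish). All derived traits follow the group's scaling law
times multiplicative lognormal noise $e^{\mathcal N(0,\sigma^2)}$:

* **divers** — $a = L/2$, $b = a/\mathrm{aspect}$, mass from spheroid
  volume at tissue density 1000 kg/m³, $H = L^{2/3}$ m (coefficient 1
  at $L = 1$ m, giving a 2.5 m animal a 1.8 m jump — the realistic
  order). The aspect ratio defaults to uniform in $[1, 6]$, an
  illustrative spread matching the observation that large divers are
  more streamlined. A *sampled* aspect deliberately breaks isometry
  (mass is no longer an exact $L^3$ law), so analyses whose point is
  exponent recovery pass a single fixed `aspect`; the package's own
  recovery tests use `aspect = 2`.
* **fliers** — chord half-length $L/12$, amplitude $0.35L$, frequency
  $4/\sqrt{L}$ Hz, and mass set by the lift balance at the requested
  prefactor.
* **swimmers** — fin geometry proportional to $L$ and speed
  $U = f\sqrt{Ac}/St^{*}$, a population holding the target Strouhal
  number (default 0.3).

Generation is purely functional: the seed is part of the specification,
identical seeds give identical tibbles, and the global RNG stream is
saved and restored. What the generator does **not** emulate: measurement
error structure of real kinematic data, phylogenetic correlation between
species, group-specific allometric curvature, or the streamlining trend
of large divers beyond the aspect-ratio spread. Passing recovery tests
therefore demonstrate that the estimators are consistent under the
model's own assumptions — not that real animal data satisfy them.

Recovery problem sizes were chosen as the smallest that make the checks
statistically sharp: $n = 200$ divers at $\sigma = 0.2$ for the
force–mass exponent ($\pm 0.05$), $n = 50$ fliers at $\sigma = 0.1$ for
the prefactor ($\pm 5\%$), $n = 200$ swimmers for the Strouhal mean
(within the CI of the mean). Under heavy multiplicative noise the
arithmetic mean of a lognormal quantity is biased upward, so the
wide-scatter school surrogate is checked through the geometric mean, the
consistent estimator in that setting.

```{r}
pop <- generate_population(
  population_spec("diver", n = 200, seed = 2024, noise_sigma = 0.2,
                  aspect = 2))
glance(dive_survey(pop))
```

## Fitting

All comparative fits are ordinary least squares on $\log_{10}$
quantities (`loglog_fit()`), with the prefactor read off the intercept.
No weighting, no reduced major axis, no errors-in-variables: OLS on logs
is the plainest defensible choice and its slope standard errors give the
confidence intervals quoted by `glance()`. The fit rejects non-positive
values by row index rather than silently dropping them, and is
scale-equivariant (rescaling $x$ moves only the intercept, by the known
amount — asserted numerically in the tests).

## Numerical choices, degenerate inputs, limitations

* Quadratures use `stats::integrate` at tight tolerances; every
  singular integrand is transformed to a bounded one first.
* `e = 1` (a needle) and $a < b$ (an oblate body) are rejected:
  oblate spheroids, general 3D plates and arbitrary geometries are out
  of scope, as are wake dynamics, Wagner-type wetting corrections,
  splash and cavity formation, and unsteady airfoil theory.
* The plate tips are genuine singularities of the inviscid solution;
  functions either refuse them (`face_velocity`), return the
  documented infinity (`pressure_water_entry` with the singular term),
  or integrate through them with a substitution.
* Real comparative data enter through the frozen CSV schema
  (`animal_record_schema()`); nothing in the package downloads data.
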