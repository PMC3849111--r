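---
title: "Response functions of gap-junction coupled dendritic trees"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Response functions of gap-junction coupled dendritic trees}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dendrotrips)
```

## The model

`dendrotrips` computes the Green's function (response function)
$G_{ij}(x, y, t)$ of a network of dendritic trees coupled by
dendro-dendritic gap junctions: the voltage at location $x$ on branch $i$ in
response to an idealised impulse of current injected at location $y$ on
branch $j$ at $t = 0$.  Because the model is linear, every stimulus response
follows from $G$ by convolution.

Each branch is a cable with quasi-active ("LRC") membrane: besides the usual
leak resistance $R$ and capacitance $C$ per unit area, the membrane carries
an inductive pathway (resistance $r$ in series with an inductance $L$), the
standard linearisation of slow voltage-dependent currents such as I~h~ that
endow dendrites with subthreshold resonance.  In the Laplace domain the
voltage on a branch decays in space at the rate

$$\gamma_k^2(\omega) \;=\; \frac{1}{D_k}\left[\frac{1}{\tau_k} + \omega +
\frac{1}{C_k\,(r_k + \omega L_k)}\right],$$

with the diffusion coefficient $D = a/(4 R_a C)$ and time constant
$\tau = C R$ derived from the diameter $a$, the axial resistivity $R_a$ and
the specific membrane constants.  Passive ("RC") membrane is the
$r \to \infty$ limit and simply drops the inductive term.  Cells may carry a
lumped soma — an iso-potential node with admittance
$\gamma_s(\omega) = C_s \omega + 1/R_s + 1/(r_s + L_s \omega)$ — and pairs of
cells are joined by gap junctions: purely resistive contacts ($R_{GJ}$)
between the cytoplasm of two dendrites, each modelled as a node that splits
its host cable into two segments.

## The sum-over-trips expansion

On a branched structure the Laplace-domain Green's function can be written as
a sum over *trips*: paths from $x$ to $y$ along the network that change
direction only at nodes.  Each trip contributes an infinite-cable kernel of
its $\gamma$-scaled length, weighted by a product of node factors:

* branch points contribute $2 p_k$ (passing onto branch $k$) or $2 p_k - 1$
  (reflecting), with $p_k = z_k / \sum_n z_n$ and the characteristic
  admittance $z_k = \gamma_k / r_{a,k}$;
* a lumped soma behaves the same with $\gamma_s$ added to the denominator;
* closed and open terminals reflect with $+1$ and $-1$;
* a gap junction transmits to the other cell with $p_{GJ}$, passes straight
  along the host dendrite with $1 - p_{GJ}$, and reflects with $-p_{GJ}$
  (for heterogeneous cells the two dendrites carry their own coefficients
  $p_{GJ,m}, p_{GJ,n}$).

The series converges geometrically because every factor has modulus at most
one and every extra reverberation adds length.  `enumerate_trips()` performs
an exhaustive depth-first enumeration of all trips up to a length cutoff
(a trip can never re-emerge from a semi-infinite branch, so those are entered
only when they host the target point), and `greens_laplace()` assembles the
response with an adaptive cutoff.

```{r}
mp  <- membrane_params(a_um = 2, tau_ms = 2, r_Ohm_cm2 = 100, L_H_cm2 = 5)
net <- two_cell_network(mp, R_GJ = 100)
ex  <- enumerate_trips(net, point_location("m_minus", 10),
                       point_location("m_minus", 100), cutoff = 1000)
ex
```

On the two-infinite-cable network the expansion is exact with finitely many
trips, and `two_cell_ghat()` provides the same solution in closed form — the
package's first internal cross-check.  For two soma-and-dendrites cells the
reverberations between the somata and the gap junction resum into a compact
geometric-like series (`word_series_ghat()`), the second cross-check; the
third is a numerical residual check of the node boundary conditions
themselves (`gj_boundary_residual()`, `soma_branch_residuals()`).

### Truncation

Trips are enumerated once, by a length that does not depend on $\omega$, so
one enumeration serves every frequency on a grid or inversion contour.  Two
numerical choices matter here.

* **Electrotonic truncation.**  The cutoff is measured in decay units: each
  branch's physical length is weighted by its slowest spatial decay rate,
  $\min_j \mathrm{Re}\,\gamma_k(\omega_j)$ over the requested frequencies.
  This makes the traversal cost a true per-trip bound on the amplitude decay
  — so ordering trips by cost ranks their amplitude bounds consistently even
  when the coupled cells have very different space constants or when the
  classes decay at very different rates at complex $\omega$.  A purely
  physical cutoff would let an electrically compact cell contribute
  exponentially many already-negligible reverberations.  The exported
  `enumerate_trips()` keeps the physical-length contract; `greens_laplace()`
  supplies the weights.
* **Tail control.**  Trips cluster into shells: each reverberation family
  (a soma–junction loop in either cell, a branch-point–terminal loop, …)
  recurs with its own period and decay rate, and the families interleave.
  The remainder is therefore estimated from the two outermost *windows*,
  each as wide as the longest elementary cycle of the network's continuation
  graph (Floyd–Warshall over the live states), so that every family is
  sampled in both: the window *modulus* sums — immune to cancellation inside
  a window — are extrapolated geometrically, and the cutoff grows until the
  estimate falls below the requested tolerance times the response magnitude
  (or a caller-supplied scale when the response itself nearly vanishes, as
  next to an open terminal where image trips cancel).  When the continuation
  graph is acyclic the trip set is finite and the expansion is exact.
  Enumerations are capped at $10^6$ trips; the driver retries shallower and
  reports an honest convergence error if the tolerance is unreachable.

## Inverse Laplace transforms and stimuli

All kernels are analytic to the right of the negative real axis (the
inductive poles $-r/L$, $-r_s/L_s$ and the square-root branch cut all lie on
$\mathrm{Re}\,\omega < 0$), so standard right-half-plane inversion applies.
`inverse_laplace()` implements two independent schemes: an Euler-accelerated
Bromwich--Fourier series (the default) and a fixed-Talbot contour.  Their
default orders (16 and 20 nodes) sit at the double-precision optimum — the
Euler weights grow like $10^{M/3}$ and the Talbot factor like $e^{2M/5}$, so
larger $M$ amplifies roundoff faster than it reduces truncation error.  At
these defaults both schemes reproduce the passive-membrane closed forms
(infinite-cable kernel, shifted-pole kernel, pulse responses) to better than
$10^{-10}$ relative to the curve maximum, and they are cross-checked against
each other in the test suite.

Rectangular pulses are inverted as a difference of two *step* responses
$\mathcal{L}^{-1}[\hat G/\omega]$, which keeps the integrand smooth across
the pulse edge.  Chirp currents $A \sin(\omega_c t^2)$ have no convenient
transform and are handled by FFT convolution of the time-domain Green's
function with the stimulus, on a grid refined to at least 20 samples per
period of the highest instantaneous frequency reached.

## The preferred frequency

The resonance analysis works with the power function
$P(\Omega) = |\hat G(\Omega)|^2$ evaluated at *real* Laplace argument, and
`find_omega0()` locates its maximiser $\Omega_0$ by coarse grid search
(step 0.005 rad/ms on [0.001, 5] by default) plus golden-section refinement.

The real-axis convention deserves a remark, since the Fourier magnitude
$|\hat G(i\Omega)|$ may look like the more natural object.  For these
kernels every segment formula is a monotone decreasing function of
$\gamma$ alone, so the real-axis maximiser is *exactly*
$\arg\min_\omega \gamma(\omega)$ — for the reference resonant membrane
$\Omega_0 = 1/\sqrt{\tilde C \tilde L} - \tilde r/\tilde L = 0.42721$
rad/ms — and is therefore rigorously identical on every segment of a
homogeneous network and rigorously independent of the gap-junction
resistance.  Those two exact invariances are properties of the model worth
preserving (and are asserted in the tests); the Fourier-magnitude maximiser
sits a few percent higher (≈ 0.46 rad/ms here), varies slightly across
segments, and is the frequency at which a slowly swept chirp transient
actually peaks.  The chirp consistency test therefore compares the chirp
peak against the Fourier maximiser, while all $\Omega_0$ analysis uses the
real-axis definition.  Both conventions agree on every qualitative statement
the package makes (trend directions, segment comparisons, coupling
dependence).

```{r}
cfg <- two_cell_config(mp, R_GJ = 100)
find_omega0(function(w) two_cell_ghat(cfg, "m-", x = 10, y = 100, w))
```

For two soma-and-dendrites cells, `sweep_gj_location()` tracks the somatic
$\Omega_0$ of both cells as the gap junction is moved away from the somata
(stimulus at `y0 = L_GJ + 10` um).  With a passive soma and resonant
dendrites the preferred frequency *increases* with distance; with a resonant
soma (passive or resonant dendrites) it *decreases* — moving the electrical
contact away dilutes the soma's own resonant load more slowly than the
dendritic one.

```{r, eval = FALSE}
sw <- sweep_gj_location(network_fixture("sweep_passive_soma"),
                        L_GJ = seq(50, 500, by = 50), R_GJ = c(100, 1000))
sweep_trend(sw)
```

## Units

Internally everything is expressed in micrometres, milliseconds, millivolts,
nanoamperes and megaohms (so capacitance is in nanofarads and mV/nA = MΩ
keeps Ohmic relations coefficient-free); the conventional cm-based specific
constants are converted at ingest by `membrane_params()` and
`soma_params()`.  Two derived choices matter:

* the somatic admittance is made absolute by multiplying the specific
  admittance by the somatic membrane area $\pi a_s^2$, which puts
  $\gamma_s$ in the same 1/MΩ units as the cable admittances $z_k$ — for a
  25 um soma with $R_s = 2000$ Ω cm² this gives
  $\gamma_s(0) = 9.82\times10^{-3}$ MΩ⁻¹, comparable to the input
  admittance of a reference dendrite, which is what makes the somatic load
  (and the location sweeps above) non-trivial;
* point responses carry a $1/c$ prefactor with $c = C \pi a$ the capacitance
  per unit length (nF/um), so that a current in nA yields a response in mV.
  $\Omega_0$ and all normalised spectra are invariant to this choice.

## Validation surface and the random-network generator

`random_network()` generates seeded two-cell networks for property testing:
per cell, a lumped soma (resonant with probability one half), 2–4
semi-infinite dendrites with electrical constants drawn log-uniformly within
one decade of the reference set (a = 2 um, C = 1 uF/cm², Ra = 100 Ω cm,
τ = 2 ms, r = 100 Ω cm², L = 5 H cm²), optionally one branch point carrying
a terminated child, and one gap junction with $R_{GJ}$ log-uniform in
1–1000 MΩ.  Finite lengths are drawn as 0.8–2 electrotonic lengths of the
host cell, which pins the reverberation decay per shell and hence the
enumeration depth to a predictable range.  The residual suite then verifies,
at random complex frequencies in the right half-plane, that the assembled
trip expansion satisfies value continuity and current balance at the gap
junction (with conductance $1/R_{GJ}$), Kirchhoff balance at branch points,
the somatic admittance condition, and the terminal conditions, using
Richardson-extrapolated one-sided finite differences.

What these networks do *not* emulate: realistic reconstructed morphologies
(tapering, many branch orders), spatially distributed or active conductances,
more than two coupled cells, and multiple gap junctions per pair.  Passing
the residual suite demonstrates the correctness of the trip calculus on the
model class, not biological realism of any particular parameter draw.

## Degenerate inputs and limitations

* Gap junctions must sit strictly inside a branch.  A contact at a branch
  tip would create a zero-length segment, on which infinitely many trips of
  equal length accumulate and length-ordered truncation breaks down; such
  configurations are rejected at build time.
* Kernel evaluation exactly at the inductive poles $-r/L$, $-r_s/L_s$
  raises an error; inversion contours and frequency grids never touch them.
* The closed-form rectangular-pulse solution has a removable degeneracy when
  $r_a/R_{GJ}$ coincides with $1/\sqrt{D\tau}$ (its partial-fraction
  coefficients blow up); the function asks for a perturbed $R_{GJ}$ in that
  measure-zero case.  The reference parameter set sits 0.7% away from the
  degeneracy, which costs about three digits of cancellation — still far
  inside the validated tolerance.
* Trip enumeration is exponential in the (electrotonic) cutoff depth; the
  practical limit is roughly $10^6$ trips per source/target pair.  Deeply
  reverberant structures (many short, strongly reflecting branches) may hit
  the cap and report a convergence error rather than silently truncate.
* Quantitative statements in the tests are computed at specific problem
  sizes (50 random networks × 10 frequencies for the residual suite; series
  truncation order 20 against the trip engine at 20 frequencies); these
  sizes are the package's validation choices, not statistical claims.
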