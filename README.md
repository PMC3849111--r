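# dendrotrips

Response functions of gap-junction coupled dendritic trees by the
sum-over-trips path expansion.

Many neurons carry dendrites whose membrane is not merely leaky but
*resonant*: slow restorative currents (such as I<sub>h</sub>) linearise to an
inductive pathway, so the membrane behaves as an 'LRC' circuit and amplifies
subthreshold inputs near a preferred frequency.  When two such cells touch
through a dendro-dendritic **gap junction** — a purely resistive contact
R<sub>GJ</sub> between the cytoplasm of two dendrites — the pair forms a
single extended cable structure whose response to current injection can be
written down exactly in the Laplace domain.

`dendrotrips` is for computational neuroscientists who want those responses
without compartmental simulation.  It computes the Green's function
G<sub>ij</sub>(x, y, t) — the voltage at location x on branch i due to an
impulse of current at location y on branch j — as a **sum over trips**:

```
Ĝ_ij(x, y, ω) = 1/(c_j D_j γ_j(ω)) · Σ_trips A_trip(ω) · e^(−L_trip(ω)) / 2
```

where every trip is a path from x to y that changes direction only at nodes,
L_trip is its length with each branch scaled by that branch's decay rate
γ_k(ω) = √[(1/τ + ω + 1/(C(r + ωL)))/D], and the coefficient A_trip collects
a factor at every node the trip visits: 2p_k or 2p_k − 1 at branch points,
the same with the somatic admittance γ_s added for a lumped soma, ±1 at
closed/open terminals, and p_GJ / (1 − p_GJ) / −p_GJ for crossing, passing
or reflecting at a gap junction.  The package provides

* a validated network data model (branches + typed nodes, YAML/JSON configs,
  optional SWC import),
* the exact frequency-domain kernels and node coefficients,
* exhaustive, adaptively truncated trip enumeration on arbitrary networks
  (`greens_laplace()`), with closed forms for the two-cable network
  (`two_cell_ghat()`) and a resummed word series for two soma-and-dendrites
  cells (`word_series_ghat()`) as independent cross-checks,
* numerical inverse Laplace transforms and time-domain responses to impulse,
  rectangular-pulse and chirp stimuli (`voltage_response()`),
* preferred-frequency analysis and gap-junction location sweeps
  (`find_omega0()`, `sweep_gj_location()`),
* a boundary-condition residual suite on seeded random networks
  (`gj_boundary_residual()`, `soma_branch_residuals()`, `random_network()`).

## Worked example

Two identical resonant cables (diameter 2 um, C = 1 uF/cm², Ra = 100 Ω cm,
τ = 2 ms, r = 100 Ω cm², L = 5 H cm²) coupled by a 100 MΩ gap junction;
observe at x = 10 um, stimulate at y = 100 um on the same cable:

```r
library(dendrotrips)

mp  <- membrane_params(a_um = 2, tau_ms = 2, r_Ohm_cm2 = 100, L_H_cm2 = 5)
net <- two_cell_network(mp, R_GJ = 100)

enumerate_trips(net, point_location("m_minus", 10),
                point_location("m_minus", 100), cutoff = 1000)
#> <trip_expansion> 2 trips, lengths 90 .. 110 um (cutoff 1000)
#>   from x = 10 um on 'm_minus' to y = 100 um on 'm_minus'; 4 node-factor types
```

Only two trips exist on the stimulated segment — the direct path (90 um) and
the image reflected off the gap junction (110 um, factor −p_GJ) — so the trip
engine reproduces the closed form to machine precision:

```r
om <- 1 + 2i
g_trips  <- greens_laplace(net, point_location("m_minus", 10),
                           point_location("m_minus", 100), om)
g_closed <- two_cell_ghat(two_cell_config(mp, R_GJ = 100), "m-", 10, 100, om)
Mod(g_trips - g_closed) / Mod(g_closed)
#> [1] 2.248604e-16
```

The preferred frequency of the power function P(Ω) = |Ĝ(Ω)|² is the same on
every segment and does not move with R_GJ:

```r
cfg <- two_cell_config(mp, R_GJ = 100)
find_omega0(function(w) two_cell_ghat(cfg, "m-", 10, 100, w))
#> [1] 0.4272136
```

0.427 rad/ms ≈ 68 Hz, the subthreshold resonance this parameter set encodes;
it equals the analytic minimiser of γ(ω), which is why it is exactly
segment- and coupling-independent here.  A time-domain response to a 2 nA,
5 ms rectangular pulse on the coupled (unstimulated) cell:

```r
s <- stimulus("rectangular", eta0 = 2, tau_R = 5)
V <- voltage_response(function(w) two_cell_ghat(cfg, "n-", 10, 100, w),
                      s, t = c(5, 10, 20, 50))
round(V, 4)
#> [1]  6.6846 -7.1943  0.3967  0.0222
```

— a few millivolts cross the junction and *ring*: the resonant membrane
swings the coupled cell below baseline right after the pulse ends.  For two
soma-and-dendrites cells, the somatic preferred
frequency shifts with the gap-junction location; the direction of the shift
depends on which membrane is resonant:

```r
sw <- sweep_gj_location(network_fixture("sweep_passive_soma"),
                        L_GJ = seq(50, 500, by = 50), R_GJ = c(100, 1000))
sweep_trend(sw)
#>   cell R_GJ_MOhm      trend
#> 1    1       100 increasing
#> 2    2       100 increasing
#> 3    1      1000 increasing
#> 4    2      1000 increasing
```

(passive somata + resonant dendrites: Ω0 increases with distance; a resonant
soma reverses the trend — see the vignette for why.)

A thin command line sits over the same functions:

```sh
exec/dendrotrips greens --network net.yaml --x m_minus:10 --y m_minus:100 --out out/
exec/dendrotrips sweep --fixture sweep_passive_soma --out out/
exec/dendrotrips validate --seeds 10
```

## Documentation

The methods vignette (`vignettes/sum-over-trips.Rmd`) describes the model
and its assumptions, the truncation and inversion machinery, the
power-function evaluation convention, the random-network generator behind
the validation suite, and known limitations.
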