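---
title: "Methods: two-dimensional stem heating and fire injury"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-dimensional stem heating and fire injury}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stemheat)
```

## The model

`stemheat` simulates the heating of a horizontal slice of a tree stem
exposed to fire, and converts the resulting temperature histories into
tissue injury. The stem cross-section is a disk discretized in polar
coordinates into $n_\theta$ uniform angular wedges and, within each wedge,
radial nodes at fixed spacing $\Delta r$. Heat conduction obeys

$$\rho c_p \frac{\partial T}{\partial t}
  = \frac{1}{r}\frac{\partial}{\partial r}\!\left(k\,r\,
    \frac{\partial T}{\partial r}\right)
  + \frac{1}{r^2}\frac{\partial}{\partial \theta}\!\left(k\,
    \frac{\partial T}{\partial \theta}\right) - S,$$

where the moist density $\rho$, conductivity $k$ and heat capacity $c_p$
are all functions of local moisture content and temperature, and $S$
collects the desiccation and charring energy sinks. The outer boundary is a
prescribed per-wedge fire heat flux plus net black-body exchange with
ambient air, $\varepsilon\sigma(T_o^4 - T_s^4)$; the circumferential
direction is periodic; the stem center carries a no-flux condition, so heat
crosses the center only by diffusing around the innermost ring of cells.
Tissue viability $N$ decays at an Eyring-type, temperature-dependent rate;
a node whose viability falls below a threshold (default $10^{-3}$, a 3-log
reduction) is dead, and the necrotic depth of a wedge is the depth of its
deepest dead node after cool-down.

Key assumptions inherited from the model family: no vertical (axial) heat
or water transport, no xylem sap flow or cavitation, no heat release from
bark combustion, and fire forcing prescribed (not simulated) per wedge.

## Reconstructed empirical forms

The source text from which this package was specified transmits the
empirical property and kinetics equations only through their symbol lists,
so each closed form was reconstructed from those lists plus the literature
the equations come from. The exact forms implemented are stated here and
frozen by unit tests; they are the package's definitions.

**Wood.** Moist density $\rho = \rho_w(1 + M(r))$ with a piecewise-linear
radial moisture profile: fractions $P_1$, $P_2$, $P_3$ of the maximum
moisture $M$ at the cambium, mid-radius and center (breakpoints
configurable). Conductivity
$k = G_M(0.1941 + 0.4064\,M) + 0.01864\ \mathrm{W\,m^{-1}\,K^{-1}}$, where
$G_M$ is specific gravity. The symbol definition "$G_M = \rho/\rho_w$" is
resolved as density over the density of water (1000 kg m$^{-3}$), the
definition under which the coefficients were fitted; the solver passes the
node dry density. Heat capacity (kJ kg$^{-1}$ K$^{-1}$):
$c_p = (c_{p0} + M c_{pw})/(1+M) + A_c$ with
$c_{p0} = 0.1031 + 0.00386\,T$, $c_{pw} = 3.8 + 130/(645-T)$ below 630 K
and 15 above (at exactly 630 K the lower branch applies, chosen for
continuity), and the wood–water bond correction
$A_c = M_\%(-0.06191 + 2.36\times10^{-4} T - 1.33\times10^{-4} M_\%)$ with
$M_\%$ in percent — the final factor of $M_\%$ restores a term the source
prints truncated.

**Bark.** Moist density $\rho_b(1+M_b)$. Conductivity is the additive
three-term form
$k = 2.104\times10^{-4}\rho_b + 5.544\times10^{-4}\rho_b M_b
 + 3.266\times10^{-4} T - 1.66216\times10^{-2}$ (SI; the calorie-based
original converted once with 1 cal = 4.184 J), increasing in density,
moisture and temperature. Heat capacity is a reconstruction: a dry
calorie-based linear curve $0.264 + 0.00116\,(T - 273.15)$ cal g$^{-1}$
K$^{-1}$, water mixing as for wood, and a moisture correction $\Delta_c$ of
the same functional family as $A_c$, all converted to SI. A property test
verifies positivity over $T \in [280, 700]$ K, $M_b \in [0, 1.2]$.

**Desiccation.** Water mass in a control volume is lost at
$\dot m = W_m\,k_w\,T^{-1/2} e^{-E_w/(RT)}\,M\rho V$ with
$k_w = 6.05\times10^5\ \mathrm{K^{1/2}s^{-1}}$ and $E_w/R = 5956$ K; the
energy sink is $L_v \dot m$ with $L_v = 2.26\times10^6$ J kg$^{-1}$
(configurable). The rate is capped at (remaining water)/$\Delta t$ so water
mass can never go negative. One consequence of the printed constants is a
small ambient tail: at 295–310 K the relative loss rate is of order
$10^{-4}$ s$^{-1}$, negligible over a fire passage (minutes) but not over
hours. Tests therefore assert ambient negligibility on fire timescales,
not over an hour.

**Charring.** Pyrolysis of essentially desiccated tissue ($M < 0.01$)
converts charrable mass (the fraction above the char floor
$c_f \rho_{dry}$, $c_f = 0.3$) at
$\dot m = P_m A_p e^{-E_p/(RT)}(\rho - c_f\rho_{dry})V$, with
$A_p = 7\times10^7$ s$^{-1}$, $E_p/R = 15610$ K. Only the node just below
the current char front can char in a given step, so the front advances at
most one node per wedge per step and never retreats. Charred nodes take
density $c_f\rho_{dry}$ and configurable char properties (defaults
$k = 0.1$ W m$^{-1}$ K$^{-1}$, $c_p = 1000$ J kg$^{-1}$ K$^{-1}$; the
source gives none). The pyrolysis heat (default $2.5\times10^5$ J
kg$^{-1}$, endothermic) is likewise a package choice; with $P_m = 0$ —
the value used in all bench-scale work — none of this is active.

**Viability.** $f(T) = (k_B/h)\,T\,
\exp\!\left(\Delta S/R - \Delta H/(RT)\right)$ with the compensation law
$\Delta S = \Delta H/T_{crit} + b_{comp}$, $k_B/h = 2.08\times10^{10}$
(s K)$^{-1}$, $R = 8.31$ J mol$^{-1}$ K$^{-1}$. The published thermal
tolerance estimates are not redistributable here, so the shipped defaults
($\Delta H = 310$ kJ mol$^{-1}$, $T_{crit} = 333$ K, $b_{comp} = -282.8$
J mol$^{-1}$ K$^{-1}$) are synthetic stand-ins pinned to two behavioral
anchors: a 3-log kill in ten minutes at 333 K, and $N > 0.999$ after 24 h
at 295 K. Any species-specific estimates can be supplied through
`viability_params()`. Viability is integrated in log space
($\log N \leftarrow \log N - f(T)\Delta t$), which is exact at constant
temperature and avoids underflow.

## Numerics

Finite volumes on the polar grid, with faces midway between nodes, the
outermost node at the bark surface (so the flux boundary applies at a
node), and the innermost cell closed at the center, making the discrete
cell areas sum exactly to $\pi R^2$. Radial conductances combine a
harmonic-mean face conductivity (flux continuity across bark/wood/char
interfaces) with the exact cylindrical geometry factor
$\Delta\theta / \ln(r_i/r_{i+1})$, which reproduces the steady logarithmic
annulus profile to solver precision. Circumferential conductances use arc
length at the node radius.

Time integration is $\theta$-weighted ($\theta = 0.5$, Crank–Nicolson, by
default; up to implicit Euler). The radiant exchange term is linearized
about the old surface temperature and folded implicitly into the matrix
diagonal (source-term linearization), which keeps 1 s steps stable on thin
surface cells. Property coefficients are evaluated at the old time level;
an optional Picard flag re-evaluates them at the new level (the difference
is below a few percent of the temperature rise at the default steps, and a
test pins that). The sparse symmetric system is solved by direct
factorization (`Matrix`), with a $10^{-8}$ relative-residual contract
checked every step.

Operator splitting per step: (1) implicit conduction; (2) water loss and
its latent sink; (3) charring; (4) property refresh (at the next step's
assembly); (5) viability update. The discrete energy budget — stored
change equals boundary input minus sinks — closes to machine precision by
construction of the conservative stencil, and the residual is recorded on
every run (`$energy$residual_frac`) so conservation regressions surface in
routine use.

Default steps: 1 s for mm-resolution grids, 0.1 s recommended for 0.1 mm
grids. Crank–Nicolson is unconditionally stable; the caps bound the
splitting and linearization errors, not stability.

## Forcing and the virtual experiments

Fire forcing is a `forcing_series`: per-wedge heat flux over time plus
ambient temperature, interpolated linearly. Flux can come from
measurements (CSV), from fire air temperature via
$\varepsilon\sigma(T_f^4 - T_o^4)$ (clamped at zero when $T_f < T_o$), or
from the built-in generators. The five circumferential redistribution
cases assign quadrant shares of the total dose (uniform; front+lee only;
3/8–1/8; 2.67/8–5.33/8; 2/8–4/8–1/8–1/8), normalized so the mean wedge
multiplier is exactly 1 — total delivered energy is case-invariant. "Front"
is the upper-right quadrant (bearings clockwise from north), "lee" the
lower-left.

The height experiment scales the peak flux as $e^{cz}$ with
$c = -0.0155\ \mathrm{m^{-1}}$ by default. The shape parameter is taken as
given rather than re-derived: the algebra that produced it from the
anchor temperatures (823 K at ground, ambient 285 K, decayed by 20 m) is
not reproducible from the prose, so it is exposed as a plain parameter.

## What the synthetic generators do and do not establish

`synthetic_lab_pulse()` (linear ramp, hold, exponential decay) stands in
for bench-scale heat-flux records, and `surface_fire_shape()` (4 min
build-up, 2 min peak, 6 min decay, 30 min cool-down tail, 1-min cadence)
stands in for a fire-line passage observed by a ~1-minute temperature
logger. Both are deterministic and chosen once on physical plausibility.
They emulate the magnitude ($10^4$–$10^5$ W m$^{-2}$ peaks) and the
ramp/decay structure of real records, but not their high-frequency
variability, wind-driven asymmetry, or the measured vertical profile of a
specific fire. A green test against these generators therefore establishes
the correctness of the numerics and the internal consistency of the
injury chain — not agreement with any particular measured fire. In
particular, the absolute necrotic depths of the height experiment depend
strongly on the integrated dose of the stand-in pulse and are reported as
computed, without claiming correspondence to published depths that were
driven by unpublished measured series.

The calibration tests use the model itself as the data generator
(synthetic twins): recovery of $W_m$ to the search resolution on noiseless
twins, and within 0.1 under 1 K probe noise, establishes that the
objective (mean squared probe temperature error on a 200 s resampled grid
plus squared necrotic depth error in mm, summed over sections) identifies
the parameter — not that any particular published $W_m$ value is correct.

## Degenerate inputs, tie-breaks, tolerances

Zero bark thickness is allowed (all-wood stem); any positive bark
thickness occupies at least one node. A single tabulated bark thickness is
split half outer / half inner bark by default; inner bark moisture
defaults to the section mean, outer (dead) bark to half of it; dry bark
density defaults to the wood value — all overridable, since the section
table carries only means. Bearings wrap modulo $2\pi$; the wedge containing
bearing 0 is wedge 1. The linear-solve contract is $10^{-8}$ relative;
grid area conservation is asserted at $10^{-10}$ relative; forcing CSV
round-trips at $10^{-12}$.

## Known limitations

Two-dimensional only: no axial transport, so peak sub-bark temperatures
are expected to run hot relative to stems with active sap flow. The
bark heat-capacity moist term and the viability defaults are
reconstructions/stand-ins as described above. The ambient Arrhenius tail
of the desiccation law makes "pre-fire" simulation segments slowly lose
water; keep lead-in segments short or start runs at ignition. Charring
thermal properties are nominal defaults, untested against data. The
measured surface- and crown-fire forcing series that drive the published
height-experiment numbers are not shipped; `import_fire_series_csv()`
accepts them as CSV exports when available.
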