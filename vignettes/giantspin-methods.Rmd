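---
title: "Powder EPR of high-spin and giant-spin systems: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Powder EPR of high-spin and giant-spin systems: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

The package simulates field-swept continuous-wave EPR of an isolated spin
multiplet `S` governed by the effective spin Hamiltonian

$$
H \;=\; \sum_{k,q} B_k^q\, O_k^q \;+\; \beta\, \mathbf{B}\cdot
\mathbf{g}\cdot\mathbf{S},
$$

with extended Stevens operators $O_k^q$ of even order $k \in \{2,4,6\}$ and
even component $0 \le q \le k$ (orthorhombic or higher symmetry), Stevens
coefficients $B_k^q$ in cm$^{-1}$, and the electronic Zeeman interaction
with $\beta = 0.4668645$ cm$^{-1}$ T$^{-1}$.  The familiar conventional
parameters map onto the second-order coefficients as $B_2^0 = D/3$,
$B_2^2 = E$; rhombicity is $\eta = E/D$, canonically $0 \le \eta \le 1/3$.
Signed $D$ and $E$ inputs are preserved as given — for isotropic g only
$|\eta|$ affects a powder pattern — and `validate_terms()` warns (without
rejecting) when $|B_2^2| > |B_2^0|$.

Operators of order $k$ act within a multiplet only when $k \le 2S$.  The
package enforces $k \le 2S$, the standard operator-equivalent rule, which
is also the condition under which quartic terms first appear at $S = 2$ and
sextic terms at $S = 3$.  All matrices are built in the descending basis
$m = +S \dots -S$; because only even $q$ is supported they are real
symmetric, and every assembled zero-field Hamiltonian is traceless.

### Assumptions and scope

* One isolated spin multiplet: no hyperfine or nuclear Zeeman structure, no
  explicit exchange coupling between centres.  Exchange-coupled clusters
  enter only through their net (giant) spin, via `net_spin()` and the
  scaling relations below.
* Perpendicular-mode detection: the microwave field is taken perpendicular
  to the static field, with transition moments
  $(|\langle i|S_{x'}|j\rangle|^2 + |\langle i|S_{y'}|j\rangle|^2)/2$
  evaluated in the frame with $z'$ along the static field.
* Thermal equilibrium populations (Boltzmann difference of the two
  connected levels at the configured temperature) or, alternatively, exact
  equal populations; no saturation or relaxation model.

## Resonance search and powder averaging

For each orientation $(\theta,\varphi)$ of the static field the sorted
eigenvalues of $H(B)$ are computed on a dense field pre-scan (`n_scan`
points, default 256).  Sorted eigenvalues are continuous in $B$, so the
gaps between sorted indices enumerate every level pair even through
crossings, and every sign change of $E_j(B)-E_i(B)-h\nu$ across a scan
interval brackets a resonance; looping transitions simply produce several
brackets for the same pair.  The single-orientation API
(`resonance_fields()`) polishes each bracket with a safeguarded
regula-falsi iteration to a relative field tolerance of $10^{-6}$.  The
powder accumulator places each stick at the secant zero of its bracket
instead: with the default scan the bracket is $\sim$25 G wide and the
secant error is far below the smallest linewidths in use, which the
scan-doubling self-convergence test confirms directly ($<10^{-3}$ RMS of
peak for the shipped presets).

Each stick's amplitude is the product of the transition moment, the
population factor, and the frequency-to-field Jacobian
$1/|d\Delta E/dB|$ that converts a fixed-frequency resonance into a
field-swept amplitude.  Near level anticrossings the gap can become flat
and the Jacobian divergent; the slope is floored at a configurable
fraction of the isotropic Zeeman slope $g\beta$ (`jac_floor_frac`,
default $10^{-2}$), and floored sticks are counted in the spectrum
metadata.  A much smaller floor would let a single orientation contribute
a stick thousands of times heavier than all others, which a finite
orientation grid cannot average; the default caps that enhancement at
100$\times$, below the amplitude resolution of the shipped grids.
Transition moments are evaluated from eigenvectors computed on a coarser
stride of the pre-scan (every 4th point) and interpolated to the stick
position; pairs whose moments at both bracket ends are below
`mom_cutoff_frac` $\times S(S+1)$ (default $10^{-6}$) are dropped as
forbidden.

The powder average runs over a deterministic igloo-type equal-solid-angle
grid on one octant, sufficient for orthorhombic symmetry: rings at
midpoints of equal-$\theta$ intervals carry azimuthal points in proportion
to $\sin\theta$, each weighted by its ring's solid angle divided by its
point count.  Two symmetry reductions are applied automatically: systems
whose transverse anisotropy vanishes ($q = 0$ terms only, $g_x = g_y$) use
a $\theta$-only grid, and a pure $q = 4$ ($q = 6$) transverse term — whose
in-plane pattern repeats with period $\pi/2$ ($\pi/3$) and is even in
$\varphi$ — uses the fundamental domain $[0, \pi/4]$ ($[0, \pi/6]$).
There is no randomness anywhere: rebuilding a spectrum from the same
configuration is bit-identical.

Sticks are accumulated into field-axis bins (linearly split between the
two neighbouring bins) and convolved once with the analytic lineshape and
its analytic field derivative, so the derivative trace is exactly the
derivative of the absorption trace up to discretization.  Gaussian and
Lorentzian shapes are provided; spectra are presented as first derivative
(the CW-EPR convention) with the absorption trace alongside.

### Problem sizes

The shipped presets use grids chosen by self-convergence: 5000
orientations for the $S = 5/2$ spectra and 2000 for the $S = 10$
giant-spin spectra, with a 256-point pre-scan.  Doubling either the
orientation grid or the pre-scan changes the shipped presets' derivative
traces by well under 1% RMS of peak (typically 0.2–0.4%), which is the
package's accuracy target for powder patterns with the configured
linewidths (100–300 G).  The orientation floor below which a grid is
flagged as under-resolved in the metadata is $50(2S+1)$.

## Effective g values and rhombograms

A resonance at field $B$ under frequency $\nu$ has effective g value
$g_{\rm eff} = h\nu/(\beta B)$.  For half-integer (Kramers) spins in the
strong zero-field limit $|D| \gg h\nu$, each zero-field doublet behaves as
an effective two-level system with its own principal effective g values.
`rhombogram()` charts those values against rhombicity by searching for the
intra-doublet resonance with the field along each principal axis, at a
documented large $|D| = 10$ cm$^{-1}$ (X-band, 9.5 GHz), where the
doublets are separated by several cm$^{-1}$ and the strong-field limit is
accurate to the percent level.  The classic landmarks emerge numerically:
the axial $\pm 1/2$ doublet of $S = 5/2$ gives $(g_x, g_y, g_z) =
(6, 6, 2)$, and at maximal rhombicity the middle doublet gives the
isotropic $g \approx 4.29$ of the ubiquitous "$g = 4.3$" signal.

Frozen-solution heterogeneity is modelled as a normal distribution of
rhombicity: `distributed_spectrum()` superposes powder spectra over
Gauss–Hermite quadrature nodes (default 11) in $\eta$, truncated to the
canonical interval $[0, 1/3]$ with the surviving weights renormalized.
The truncation is exact — no node outside the interval is ever evaluated —
and $\sigma_\eta = 0$ reduces identically to the plain powder spectrum.

## Giant-spin scaling for nanoparticle cores

Superparamagnetic cores such as the ferritin iron core have system spins
of order $10^3$–$10^4$, far beyond direct diagonalization.  The scaled
giant-spin bookkeeping implemented in `scaling_scheme()` is

$$
S = \mu/(g\beta), \qquad S_{\rm eq} = S/n, \qquad
D_{\rm eff} = nD, \qquad T_{\rm eff} = T/n,
$$

with $n$ a positive integer, plus the link
$D = \gamma B_a/(2S)$ between the axial parameter and the classical
anisotropy field $B_a$, interpreting $\gamma$ as $g\beta$ in energy units
and taking the easy-axis (negative) sign.  With $g = 2.00$,
$B_a = 1400$ G and $S = 5000$ this formula gives $|D| = 1.31\times
10^{-5}$ cm$^{-1}$; the value commonly reported for this system is
$-1.2\times 10^{-5}$ cm$^{-1}$ (an unstated g value or rounding accounts
for the $\sim$8% gap), and the package's audit and scaling defaults start
from the reported number rather than re-deriving it.

### Why higher-order terms do not scale

The matrix elements of $O_k^0$ grow roughly as $S^k$, so a fixed ratio
between successive coefficients ($B_4^0 = 10^{-4} B_2^0$,
$B_6^0 = 10^{-8} B_2^0$, the conservative pattern seen in single-molecule
magnets) cannot keep higher-order terms small as the spin grows.
`divergence_audit()` quantifies this with the magnitude of the largest
diagonal element of each $B_k^0 O_k^0$: starting from the reported
$D = -1.2\times10^{-5}$ cm$^{-1}$ at $S = 5000$, the three terms are
strictly decreasing in $k$ at $S_{\rm eq} = 10$, within one order of
magnitude of each other at $S_{\rm eq} = 100$ ("comparable" is
operationalized as max/min $\le 10$), and strictly increasing at
$S_{\rm eq} = 1000$.  The audit evaluates the closed-form diagonal
polynomials, and the tests verify them against a brute-force scan of the
assembled operator matrices up to $S = 100$.

## The switch-on inventory and feature detection

`inventory_run()` catalogues what each orthorhombic coefficient does to
the powder line shape of a giant spin ($S = 10$, $g_{\rm iso} = 2.00$,
equal populations, Gaussian FWHM 300 G): starting from the zero-field-free
base spectrum, each $B_k^q$ is switched on alone — except $B_2^2$, which
requires an axial partner and is tied to $B_2^0$ at maximal rhombicity —
at a base value that is then doubled and tripled.  The $(2,0)$ base value
corresponds to $D = 100$ MHz ($= 0.0033$ cm$^{-1}$) via $B_2^0 = D/3$.
"Just resolved" is not a quantity with a published definition.
`resolve_threshold()` operationalizes it as the smallest coefficient whose
maximum absolute derivative-trace change exceeds a declared fraction of
the base peak-to-peak amplitude, found by doubling and bisection to 2%
relative width.  The standalone default fraction is 5%; the inventory
itself calibrates the fraction on its own $(2,0)$ anchor — the $D = 100$
MHz axial base value produces a relative deviation of about 0.28, and
that measured value becomes the resolution criterion for every other
coefficient, so "just resolved" means the same thing for the searched
coefficients as for the one published base value.  (At a 5% criterion the
switched-on coefficients are five to six times weaker than the anchor
implies and none of the catalogue's qualitative structure — splittings,
shoulders, low-field features — develops at all, which is why the
anchor-consistent calibration is the default.)  The search runs on a
reduced grid (a quarter of the orientations, half the scan) since the
threshold only needs percent-level accuracy; the final 28 spectra (base +
9 coefficients × 3 multipliers) use the full preset grid.

`detect_features()` classifies a spectrum against the base with declared
rules kept in one internal table.  Main-line splitting is two or more
zero crossings of the derivative within $\pm 20\%$ of the base centre
field $B_0$, each qualified by derivative swings of at least 10% of the
trace's own peak-to-peak on both sides (so weak shoulder spill-over does
not mimic a split).  Half-field and near-zero-field features are local
maxima of the absorption trace — judged against the trace's own
absorption maximum (floor 1%), because a sharp central line would
otherwise mask broad low-field intensity on any derivative-amplitude
scale — inside the windows $|B - B_0/2| \le 0.15 B_0$ and
$B < 0.10 B_0$.  Shoulders are derivative extrema (floor 1% of the base
peak-to-peak) flanking the main window, up to $1.6 B_0$.  The main-line
width ratio compares derivative peak-to-peak widths inside the main
window; the overall broadening ratio compares RMS widths of the
absorption distributions, which registers growth of outlying intensity
even when the central line is untouched.

Three caveats follow from the physics rather than the implementation.
First, low-field intensity is carried by nominally forbidden transitions
that borrow allowedness from state mixing; a purely axial second-order
term mixes nothing at zero field, so its near-zero-field intensity stays
orders of magnitude below the detection floor even at three times the
base value (about $10^{-3}$ of the trace maximum for $D = 300$ MHz),
while transverse and higher-order terms develop it readily.  Second, at
triple strength the zero-field interaction becomes comparable to the
microwave quantum and the low-field structure migrates: several
coefficients' half-field and near-zero bumps sit at 0.12–0.30 of $B_0$
rather than inside the fixed windows, so the window-based flags are
conservative at the highest multiplier (at double strength all nine
coefficients show a half-field feature).  Third, the inventory's base
values for $k > 2$ coefficients are outputs of the resolution criterion,
not published numbers, so the catalogue's quantitative columns
(thresholds, splittings, width ratios) are implementation-declared; the
sharpest reproducible qualitative content is that the axial quartic and
sextic terms — and only they — split the main line, that every term
broadens the spectrum monotonically with its multiplier, and that the
$q = 2$ terms broaden the centre far more strongly (width ratios
$\gtrsim 2.4$) than the $q = k$ terms (width ratios $\lesssim 1.4$).

## What the simulations do and do not show

The shipped presets are model calculations, not fits: they reproduce
published parameter sets for a maximally rhombic high-spin Fe$^{3+}$
model ($D = -0.9$, $E = -0.3$ cm$^{-1}$ versus $D = -0.9$, $E = -0.14$,
$B_4^4 = 0.24$ cm$^{-1}$, both at $g_{\rm iso} = 2.00$, 15 K, FWHM 100 G)
and demonstrate their near-degeneracy (derivative-trace Pearson
correlation $\ge 0.9$ on the shipped field range 0–3000 G at 9.5 GHz; the
microwave frequency is not part of the published parameter sets and 9.50
GHz X-band is the package default).  Real frozen-solution spectra add
strain broadening, distributed parameters, and baseline artefacts that
none of these presets emulate; passing tests demonstrate the fidelity of
the spin-Hamiltonian model calculations, not agreement with any
particular experimental spectrum.  Fitting experimental data, parallel-
mode detection, frequency-swept spectra, hyperfine structure and explicit
many-spin exchange Hamiltonians are out of scope.

## Numerical choices, in one place

* Constants: $\beta = 0.4668645$ cm$^{-1}$ T$^{-1}$,
  $k_B = 0.6950348$ cm$^{-1}$ K$^{-1}$, 1 cm$^{-1}$ = 29979.2458 MHz.
* Basis: descending $m = +S \dots -S$; eigenvalues reported ascending;
  degenerate eigenvectors in LAPACK's deterministic order.
* Root bracketing: 256-point pre-scan per orientation; polished
  (single-orientation API) to $10^{-6}$ relative field tolerance, or
  placed by secant interpolation (powder accumulation).
* Jacobian floor: $10^{-2}$ of $g\beta$; moment cutoff: $10^{-6}$ of
  $S(S+1)$; both configurable per experiment.
* Lineshape kernels truncated at $5\times$FWHM (Gaussian) or
  $40\times$FWHM (Lorentzian), renormalized to unit integral; sticks are
  accumulated on the field axis extended by the kernel half-width, so
  lines just outside the window contribute their tails.
* Gauss–Hermite quadrature: 11 nodes, truncated to $\eta \in [0, 1/3]$,
  weights renormalized.
* Degenerate doublets: intra-doublet transitions of Kramers systems at
  zero transverse anisotropy have vanishing gap slope along some axes; the
  rhombogram search reports NA when no resonance exists below the field
  search limit (30 kG).
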