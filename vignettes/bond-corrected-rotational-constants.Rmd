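---
title: "Bond-corrected geometries and rotational constants: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bond-corrected geometries and rotational constants: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rotofit)
```

## The problem and the model

Rotational constants are inversely proportional to the principal moments
of inertia, so a 0.1% constant demands bond lengths good to roughly
0.5–1 mÅ and angles to ~0.1°. Double-hybrid DFT optimizations with
quadruple-ζ-quality valence basis sets get the angles right but leave two
systematic bond-length defects: the missing core–valence (CV) correlation
(frozen-core-quality treatment of the core leaves bonds a few mÅ too
long) and a slight overestimation of conjugation that makes multiple CC
bonds a touch too short a correction in the opposite direction. Both
defects are local, transferable properties of the bonded atom pair, which
is what makes a cheap post-correction possible.

`rotofit` implements that post-correction as a four-stage pipeline, each
stage a plain function over tibbles so the steps can also be used (and
tested) in isolation.

### Bond perception

Two atoms are bonded when their Pauling bond order

$$P_{ij} = \exp\!\left[\frac{r_i^{cov} + r_j^{cov} - r_{ij}}{b}\right]$$

exceeds 0.3. The decay constant defaults to $b = 0.3$ Å, which places the
0.3-order threshold 0.36 Å beyond the covalent-radius sum — consistent,
within 0.02 order units, with the defining statement that order 0.3
corresponds to a distance 0.35 Å past the radius sum. (`.onLoad` asserts
this relation as a transcription guard.) The perception is purely
geometric: exactly invariant under rigid motion, and invariant up to
relabeling under atom reordering. Nonbonded intramolecular H···H
contacts (~1.8 Å) fall below threshold on their own; no anti-bonding
rules are needed. A force/forbid override exists for pathological inputs.

### Bond-length corrections

The CV contraction is estimated from element data alone:

$$\Delta r_{CVB} = -k\,\sqrt{n_{ij} - 1}\,(r_i^{cov} + r_j^{cov}),
\qquad k = 0.0011,$$

with $n_{ij}$ the product of the principal quantum numbers. Using
covalent radii rather than the actual bond length makes the estimate
method-independent, and the $\sqrt{n_{ij}-1}$ factor sends it to zero
identically for bonds between first-period atoms, which have no core
shell to correlate. Typical values: −1.2 mÅ (C–H), −2.7 mÅ (C–O),
−2.8 mÅ (C–N), −2.9 mÅ (C–C).

The conjugation correction applies only to carbon–carbon bonds (a
Kronecker δ on the element pair) and grows with multiplicity through the
geometric bond order:

$$\Delta r_{VB} = c\,\delta_{CC}\,(P_{ij} - 1), \qquad c = 0.0018.$$

It vanishes for single bonds, contributes ~+1 mÅ for aromatic bonds and
~+2–3 mÅ for genuine double/triple CC bonds; because the corrections are
on the mÅ scale, the result is insensitive to whether an aromatic order
comes out 1.4 or 1.6. The order is always computed from the actual input
geometry — the pipeline never needs an assigned formal bond order.
Angles receive no correction at all: CV effects on valence and dihedral
angles are negligible at this level.

Both coefficients (and the radii table) are arguments with pinned
defaults, and every correction report echoes them.

### The refit problem

Corrected bond lengths are finite displacements, so in a ring it is
generally impossible to move every bond onto its target while keeping
every angle fixed. Nonredundant Z-matrix coordinates handle this badly;
the package instead works with the full redundant set — every bond, and
every angle formed by two bonds sharing a central atom (dihedrals are
deliberately excluded; torsions stay free to relax) — and minimizes the
penalty

$$S = \sum_{i}^{n_B} (r_i - r_i^{target})^2
    + f \sum_{\alpha}^{n_A} (\theta_\alpha - \theta_\alpha^{ref})^2$$

over Cartesian coordinates by plain gradient descent
$x_{i+1} = x_i - \eta \nabla_x S$, with the gradient assembled by the
chain rule through the standard Wilson derivatives of bonds and bends.
Reference angles are the input geometry's own values. Connectivity is
frozen at the input geometry; it is never re-perceived mid-refit.

**Angular unit and the weight f.** The penalty mixes Å² bond terms with
squared angle deviations; $f$ sets the exchange rate. The package uses
degrees with $f = 0.00115$ (the default is dimensionless and stated
without units in the literature this follows): a 0.03° angle drift then
costs about as much as a 1 mÅ bond error, which matches the accuracy
targets of the two coordinate types (0.5–1 mÅ vs ~0.1°). A
`angle_unit = "radians"` switch exists; with radians the same $f$ would
make angles ~3300× stiffer, effectively freezing them, so the degrees
default is also the scientifically sensible one.

**Convergence.** The method's criterion is an RMS Cartesian displacement
per iteration below $10^{-6}$ Å. That criterion alone can fire while $S$
is still decaying geometrically toward an exactly attainable minimum
(trees), leaving $S \sim 10^{-10}$ on the table; the package therefore
declares convergence only when the step criterion holds *and* the
penalty decrement of the iteration has stagnated
($\Delta S \le \max(10^{-16}, 10^{-12} S)$). For tree connectivity this
drives $S$ to numerical zero; for rings it adds a handful of iterations
past the plateau. With $\eta = 0.1$ the default cap of 200 000
iterations is never approached — the bundled fixtures converge in a few
hundred.

**Step safeguard.** An iteration that increases $S$ is rejected and
$\eta$ halved (counted in the result; set `adaptive_step = FALSE` to
recover the plain unguarded update). If $\eta$ underflows ($<10^{-12}$)
the refit stops and reports `converged = FALSE`; a non-converged result
is always flagged, never returned silently.

**Degenerate inputs.** Exactly collinear angle triples make the bend
derivative singular and raise an error; near-linear angles (>179.9°) are
flagged but retained — e.g. a nitrile bend at 178.65° is handled
normally. Coincident atoms (<0.1 Å) are rejected at geometry
construction unless explicitly flagged degenerate.

What the refit achieves, by connectivity class:

- *Acyclic:* all targets simultaneously attainable; final $S < 10^{-10}$,
  bonds within $10^{-5}$ Å of target, angles within 0.01° of reference.
- *Symmetric rings* (benzene with a uniform contraction): exact to
  $10^{-4}$ Å with the symmetry preserved to $10^{-6}$ Å.
- *Mixed rings:* neighboring bond classes get different targets (N–C
  −2.8 mÅ vs aromatic C–C net −1.9 mÅ), which a closed ring cannot
  satisfy simultaneously while angles stay put; the refit distributes
  the incompatibility into per-bond residuals of a few $10^{-4}$ Å —
  below the correction scale and the sub-mÅ accuracy target, and the
  reason the residual report exists.

Because $S$ depends on internal coordinates only, its gradient carries
zero net force and zero net torque, so the refit preserves the centroid
(verified to $10^{-9}$ Å) and never rotates the structure.

### Rotational constants

Equilibrium constants come from diagonalizing the inertia tensor at the
center of mass, $B_i = \kappa / I_i$ with
$\kappa = h/(8\pi^2) = 505379.0091$ MHz·amu·Å², computed once from CODATA
$h$ and the atomic mass constant and frozen at 10 significant digits.
Constants are labeled $a \ge b \ge c$; for degenerate pairs (symmetric
tops) the labels are fixed deterministically by the $|z|$ component of
the principal axes. Linear molecules report an infinite $a$ constant;
monoatomics are an error. Masses default to the most abundant isotope
(¹H, ¹²C, ¹⁴N, ¹⁶O, ³²S) so constants refer to the parent species, with
a per-atom override for isotopologues. For planar structures the
reported planarity defect $1/C - 1/A - 1/B$ vanishes to machine
precision and is a useful sanity probe.

Ground-state constants are assembled, never computed ab initio here:

$$B_0 = B_{eq} + \Delta B_{CVB} + \Delta B_{VB} + \Delta B_{vib},$$

with $\Delta B_{vib} = -\tfrac12 \sum_r \alpha_r$ from user-supplied
vibration–rotation interaction constants (an anharmonic force-field
product, out of scope by design) and the electronic term
$\Delta B_{el} = (m/M_p)\,g_{ii} B_i$ kept for reporting but excluded
from $B_0$, matching the convention of the bundled benchmark tables
where it is below the method's accuracy target. The sign convention
follows the standard effective-rotational-constant form
$B(1 + \tfrac{m}{M_p} g)$; the source tables show both signs across
molecules and cannot disambiguate it, so the convention is stated here
and isolated in one function.

### Benchmark statistics

`percent_error` is the unsigned relative deviation in percent;
`summary_stats` reports its mean (MUE%) and maximum (MAX%) plus a
Gaussian profile $N_c \exp[-(x-\Delta_{av})^2/(2\Delta_{std}^2)]$ with
$N_c = (\Delta_{std}\sqrt{2\pi})^{-1}$. By default $\Delta_{av}$ and
$\Delta_{std}$ summarize the *unsigned* errors (that is how the bundled
footer values are defined); `signed = TRUE` profiles signed errors
instead, since either view is defensible for the density plot and the
choice is surfaced rather than buried.

## Bundled data and what the tests do (and do not) show

Four plain-text tables ship with the package: three
rotational-constant component tables (validation panel; polycyclic
aromatics, with the phenanthrene rows flagged excluded as a suspected
experimental outlier; polycyclic heteroaromatics) and the
internal-parameter table of 2-furonitrile at four levels of theory.
Two transcription quirks are worth knowing:

- One published angle label ("C3C4O5") names two non-bonded atoms around
  the wrong center; it is stored as the ring angle C4–C3–O5 at C3, the
  only chemically possible reading (in-plane angles at C3 then sum to
  360°).
- Summing the printed 0.1-MHz-rounded components reproduces the printed
  totals within 0.1 MHz for 91 of 93 rows; the naphthalene $b$ and
  benzothiophene $a$ components are inconsistent with their printed
  totals by 0.6 and 0.4 MHz (the footer statistics match the totals, so
  the component cells carry the misprint). Rows are stored exactly as
  printed and `check_component_sums()` quantifies the drift per row.

Test geometries are built in code, not stored: an idealized benzene
hexagon, water/methane, random jittered-chain clusters under fixed
seeds, and a planar 2-furonitrile reconstructed from the bundled
internal parameters. The reconstruction realizes the nine printed bonds
and seven of the nine printed angles exactly; the ring-closure bond
(C4–C9, absent from the printed table) emerges from the construction,
and the two redundant hydrogen angles at C9 absorb the small closure
defect of rounded parameters symmetrically (±0.1°). Equilibrium
constants of the reconstruction agree with the tabulated ones to well
under 0.5% (the tests assert this bound), limited by the
4-decimal/2-decimal rounding of the printed parameters and by the
arbitrary bending side chosen for the near-linear nitrile.

These fixtures exercise planar, semirigid aromatic systems — precisely
the regime the correction scheme targets. They do not probe flexible
molecules with large-amplitude motions, multiple conformers, elements
beyond H/C/N/O/S, charged or open-shell species, or the quality of
externally supplied $\alpha$ constants; passing tests say nothing about
those. Problem sizes were chosen to keep the full suite under ~10 s:
clusters of 4–6 atoms for derivative oracles (100 seeds), 10–12-atom
rings for the refit, and the 93 tabulated constants for the statistics —
the method itself is $O(n^2)$ in atoms for perception and linear per
refit iteration, so dozens-of-atoms inputs are routine.

## Parameters at a glance

| parameter | default | units | role |
|---|---|---|---|
| `decay` ($b$) | 0.3 | Å | bond-order exponential decay |
| `threshold` | 0.3 | — | minimum order counted as bonded |
| `k` | 0.0011 | — | core–valence correction strength |
| `vb_coef` ($c$) | 0.0018 | Å/order | CC conjugation correction strength |
| `angle_weight` ($f$) | 0.00115 | — | angle-vs-bond penalty weight (degrees²) |
| `learning_rate` ($\eta$) | 0.1 | — | gradient-descent step |
| `convergence_rms` | 1e-6 | Å | RMS Cartesian step threshold |
| `max_iterations` | 200000 | — | iteration cap |
| `radii` | Cordero set | Å | covalent radii (C generic 0.76) |

The covalent radii deserve one note: tabulated sets offer
hybridization-specific carbon radii (0.76 generic/sp³, 0.73 sp², 0.69
sp). The generic 0.76 Å radius is the default everywhere because it
reproduces the published heteroatom corrections (C–N −2.8, C–O −2.7 mÅ)
exactly, while the sp² value would shift them by ~0.2 mÅ; the `radii`
argument lets a user switch per call, and the same set feeds both the
bond order and the CV correction so the two stay consistent.

## Known limitations

- The refit is first-order gradient descent: robust and dependency-free,
  but hundreds of iterations where a Newton/generalized-inverse
  back-transformation would take a handful. At these molecule sizes that
  is milliseconds and irrelevant; it would not scale to thousands of
  atoms.
- $\Delta B_{vib}$ is an input. Without externally computed $\alpha$
  constants the package can only deliver equilibrium constants, which
  sit ~0.3–0.7% above experimental ground-state values.
- Corrections are parameterized for H/C/N/O/S; other elements error out
  loudly rather than extrapolate.
- The conjugation correction assumes the input comes from a
  double-hybrid-quality optimization; applied to a geometry from a much
  cruder method, the mÅ-scale corrections would be swamped by the
  method's own errors.

```{r example}
g <- furonitrile_geometry("rdsd")
cg <- correct_geometry(g)
glance(cg$refit)
cg$constants
```
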