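---
title: "Mapping the ion atmosphere around charged macromolecules"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping the ion atmosphere around charged macromolecules}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

A charged macromolecule in electrolyte solution is surrounded by a diffuse
cloud of counter- and co-ions — its ion atmosphere.  Large enough regions
of that cloud neutralise the macromolecular charge, and its spatial
structure controls measurable quantities such as the effective
(electrophoretic) charge and preferential-interaction coefficients.
`ionatmos` characterises this atmosphere on a regular 3-D grid by two
independent routes and provides the statistics needed to compare them:

1. **Trajectory route**: ion positions from an equilibrated particle
   trajectory are turned into concentration maps by kernel density
   estimation.
2. **Mean-field route**: the electrostatic potential from a grid solution
   of the Poisson–Boltzmann (PB) equation is Boltzmann-inverted into
   per-species concentration maps.

Everything downstream — ion counts, excesses, total-charge and
ionic-strength profiles, molality-based radial distribution functions,
dispersion summaries, iso-concentration masks — operates on the same
`grid_map` container regardless of the route.

## Models and conventions

### Units

Lengths are Å, charges protonic units e, concentrations mol/L, potentials
kT/e (so `exp(-z * phi)` is dimensionless).  Grid *nodes* carry values;
node `(i,j,k)` sits at `origin + (index - 1) * spacing` and represents one
voxel of volume `prod(spacing)` in integrals.

### Poisson–Boltzmann solver

The solver discretises

$$\nabla\!\cdot(\epsilon \nabla \phi) \;-\;
  \epsilon_s \kappa^2 a(\mathbf r)\, \sinh\phi \;=\;
  -4\pi \ell_B^{vac} \rho_f$$

with a 7-point stencil on a uniform cubic grid, where
$\ell_B^{vac} = e^2/(4\pi\varepsilon_0 k T)$ (557.0 Å at 300 K) and
$\kappa^2 = 8\pi (\ell_B^{vac}/\epsilon_s) N_A I \cdot 10^{-27}$ for a 1:1
salt.  Conventions:

* **Molecular surface** — a two-pass approximation: nodes within
  `atom radius + probe` (probe default 1.4 Å) of any atom are tentatively
  interior; tentative nodes within one probe radius of a definitely
  exterior node are reclassified exterior.  This captures probe inflation
  and first-order re-entrant behaviour; its error is bounded by one probe
  radius and it is grid-local, which keeps coefficient assignment fast and
  testable.  Face dielectrics are harmonic means of the node values
  (interior default 4, solvent 80).
* **Stern layer** — ion accessibility $a(\mathbf r)$ is 0 within
  `atom radius + stern` (default 2.0 Å) of any atom, 1 elsewhere.
* **Charges** — spread to the 8 surrounding nodes with trilinear weights
  (exactly charge-conserving).
* **Boundary condition** — superposition of per-charge Debye–Hückel
  monopoles on the six faces; exact for an isolated charge, and its
  influence shrinks under two-level focusing (`focus()`), which
  interpolates a coarse solution onto the fine-grid boundary.
* **Linear solve** — successive over-relaxation (ω default 1.6) to a
  relative residual of 1e-6 (residual over the L2 norm of the source).
* **Nonlinear solve** — damped local-Newton Gauss–Seidel (damping 0.6) on
  the sinh form, *initialised from the converged linear solution*.  This
  continuation matters: with an interior dielectric of 4 the bare nodal
  potentials at charge sites reach thousands of kT/e, and a zero-start
  nonlinear sweep overflows `sinh`.  The sinh/cosh argument is also
  clamped at |φ| = 50 during sweeps; the clamp can only affect transients
  because the mobile term acts only on Stern-accessible nodes, where the
  converged potential is modest.
* Against the closed-form screened sphere (q = +12 e, a = 10 Å, I = 0.1 M,
  uniform ε = 80) the linear solver is accurate to ~0.4% at 1 Å spacing
  over 12 Å ≤ r ≤ 32 Å, improving with roughly second-order behaviour
  under refinement once the solver tolerance is tightened below the
  discretisation error.

### Boltzmann inversion

$c_i(\mathbf r) = c_i^{bulk} e^{-z_i \phi(\mathbf r)}$, with the
concentration *assigned* zero (not multiplied) wherever the accessibility
mask is zero — interior potentials can overflow the exponential and those
nodes are ion-free by definition.  For a 1:1 salt this enforces the exact
reciprocal symmetry $c_+/I = I/c_-$ and the product identity
$c_+ c_- = I^2$ at every accessible node.  The same formula applied to a
*linearised* potential is thermodynamically inconsistent (the linear form
drops the higher Taylor terms that the exponential restores); the package
deliberately lets you feed an LPB potential to `boltzmann_concentration()`
to reproduce that known artefact.

### Trajectory maps

The kernel estimator deposits an isotropic radial triangular (cone)
kernel, $K(d) \propto \max(0,\, 1 - d/h)$, for every sample.  The
bandwidth h (default 2 Å) is interpreted as the kernel *support radius*:
the compact-support reading keeps locality testable (no node farther than
h from every sample is nonzero).  Each sample's kernel is renormalised
*on-grid* to total weight exactly 1, so integrating the map (Avogadro ×
concentration × voxel volume) recovers the mean number of retained
particles per frame to machine precision; the alternative free-space
normalisation would differ only at edge nodes.  Frames are superposed
onto a user-supplied reference with a proper-rotation Kabsch fit before
estimation when the structure moves.

### Distances, regions, profiles

All distances are node-to-closest-atom-*center* (no surface convention —
center-based distance is unambiguous).  A region is the set of nodes
within a cutoff of the closest atom; analyses are restricted to nodes
within `max_distance` (default 15 Å) of the structure, mirroring the
boundary-exclusion needed when a periodic trajectory is analysed on a
non-periodic grid.  Profiles report, per cutoff d:

* ion counts $N_\pm(\le d) = N_A \sum c_\pm \cdot v_{voxel} \cdot 10^{-27}$,
* excesses $\Delta N_\pm = N_\pm - N_A c^{bulk} V(\le d)$,
* total charge $Z + N_+ - N_-$,
* ionic strength $(N_+ + N_-) / (2 N_A V(\le d))$ — the formula adopted
  for the local ionic strength of a 1:1 salt; nodes are unweighted by
  accessible volume in all scatter/dispersion summaries.

### Ion addition

For solute charge Z, ionic strength I and solvent volume V the
neutrality-plus-ionic-strength conditions
$N_+ + N_- = 2 I N_A V$, $Z + N_+ - N_- = 0$ give
$\Delta N_\pm = \mp Z/2$ and $N_\pm = I N_A V \mp Z/2$.
`ion_addition()` computes the excesses *first* — they are exact in
floating point — and derives the ion numbers from them; computing
$\Delta N$ as a difference of $\sim 10^{20}$-scale numbers would destroy
the identities.  Integer counts round half away from zero (the rounding
direction is otherwise unspecified; this one is fixed and documented).
The solvent volume of a box defaults to box volume minus
$\sum \frac{4}{3}\pi r^3$ over atoms, ignoring overlaps — an approximation
documented here; an exact overlap-corrected volume can be supplied
instead.

### Molality RDF

Around an irregular shape, radial shell volumes are ill-defined.  The
molality-based RDF avoids them: with $h_i(r)$ the ensemble-averaged
histogram of species-to-closest-atom distances and $h_w(r)$ the water
histogram, $m_i(r) = h_i / (h_w M_{water})$ and
$g_i(r) = m_i / m_i^{bulk}$, the bulk molality coming from whole-box
counts.  Bins with no water are flagged `NA` (the ratio is undefined),
never zero.  Default bin width 0.2 Å.  The synthetic water model is
single-site, so the three-atom histogram averaging that an atomistic
water model would need reduces to the single histogram.

### Dispersion summaries

Box-plot statistics over nodes within `max_distance`: median and
quartiles by linear interpolation between order statistics (R's type-7
quantile — no rule is canonical, so one is fixed for reproducibility),
whiskers at the 0.0005/0.9995 empirical quantiles (enclosing a 0.999
fraction of the values), values outside the whiskers reported as
outliers, plus the fraction of exactly-zero nodes.

## The synthetic-data generator

`sample_ion_configurations()` equilibrates monovalent hard-sphere ions
(radius 1.5 Å) in a rectangular box by Metropolis Monte Carlo:

* **ion–bead**: Debye–Hückel sphere potential
  $z q_b \ell_B e^{-\kappa(d-b)} / ((1+\kappa b) d)$ with contact radius
  $b$ = bead radius + ion radius — the ion-free shell between the bead
  surface and the closest-approach distance carries no screening, which
  is also exactly how the PB Stern layer treats it;
* **ion–ion**: Yukawa $z_i z_j \ell_B e^{-\kappa d}/d$ plus hard cores;
* single-particle moves (default 3 Å), rejection outside the box, the
  standard Metropolis criterion; 30% of sweeps discarded as
  equilibration by convention; all randomness from R's RNG, so a seed
  reproduces a trajectory bit for bit.  Incrementally updated and
  freshly recomputed total energies agree to 1e-8 relative.
* water is an *ideal uniform background* (fresh uniform positions outside
  the beads each recorded frame); it exists solely so the molality
  denominator is exercised, and carries no structure of real water.

Ion numbers default to the ion-addition protocol for the box's solvent
volume, so whole-box excesses obey the half-charge relation by
construction.

**What the generator emulates and what it does not.**  It reproduces the
statistical structure of an equilibrated ionic atmosphere around a fixed,
irregularly charged solute at prescribed ionic strength — enough to
exercise every downstream stage with known ground truth.  It does not
emulate conformational flexibility, titrating (pH-dependent) charges,
explicit solvent structure, or genuinely self-consistent many-body
screening; passing tests therefore validate the *pipeline*, not the
fidelity of any particular force field.  Fluctuating protonation states
can only be approximated by supplying different fixed charge sets per
run.

**Cross-route consistency.**  The package's strongest internal check
compares the 10 Å ion excess of a weakly charged bead solute (8 beads of
+0.5 e, radius 3 Å, 60 Å box, I = 0.1 M) between the trajectory route and
the NLPB route, over six seeds.  For this check the sampler runs in its
external-field-only mode (`interactions = "no-ion-ion"`): the bead–ion
potential is a potential of mean force that *already contains* small-ion
screening, so adding explicit ion–ion Yukawa interactions screens twice
and measurably depresses the counterion excess below the mean-field
value.  With the double counting removed, both species' excesses agree
within sampling error (observed within ~1.6 standard errors at total
charges +2 and +4).  At higher charge densities the two routes are
*expected* to separate — the mean-field route overestimates counterion
accumulation — which is precisely the kind of comparison the pipeline is
built to expose.

## Problem sizes

The shipped tests and the acceptance script use desk-scale systems chosen
to make statistical checks decisive: the homogeneous-system RDF check
uses 1050 recorded frames (36000 sweeps, stride 24) of 50 + 50 ions and
2000 water sites in a 60 Å box, which puts the seed-to-seed spread of the
bulk-asymptote estimate near 1.4%; the sphere-oracle solver check runs on
65³ (1 Å) and 129³ (0.5 Å) grids; the cross-route check uses a 61³ grid
and six seeds of 5000 sweeps.

## Known limitations

* Rectangular boxes only; periodic (and rhombic-dodecahedral) geometries
  are out of scope — analyses rely on the `max_distance` restriction
  instead.
* The nonlinear mobile term is hard-wired to a symmetric 1:1 salt
  (`sinh`); general valence mixtures are supported only by the linear
  solver.
* The two-pass molecular surface is an approximation to the rolling-probe
  re-entrant surface (error ≤ one probe radius).
* No size-modified or correlation-corrected PB variants; no multigrid
  acceleration (two-level focusing only).
* Pointwise agreement with any particular external PB package is not a
  goal; the solver is validated against closed forms and symmetry
  properties instead.
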