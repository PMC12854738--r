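---
title: "Energy-landscape ensemble analysis with ktnr: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Energy-landscape ensemble analysis with ktnr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ktnr)
```

# The model

A kinetic transition network (KTN) coarse-grains a potential energy surface
into its local minima and the index-1 saddle points (transition states)
connecting them. Because the description is geometric, it is independent of
barrier heights and captures arbitrarily rare transitions — the regime where
direct time propagation fails, and precisely the regime of slow RNA
conformational exchange between a ground state and a sparsely populated
excited state.

`ktnr` implements the analysis layer of this framework. Its stationary-point
tables carry, per minimum, the potential energy $V$ (kcal/mol), the log
product of the $\kappa$ harmonic vibrational frequencies, and the point-group
order $\sigma$; transition states carry the same with $\kappa - 1$ real
frequencies plus the two minima they connect.

## Thermodynamics: harmonic superposition

The total partition function is approximated as a sum of per-minimum
classical harmonic wells. After dropping the $\kappa \ln(\beta h)$ factor
common to all minima, the log-weight of minimum $i$ at temperature $T$ is

$$\ln w_i = -\beta V_i - \ln \prod_j \nu_{ij} - \ln \sigma_i,
\qquad \beta = 1/k_B T .$$

Occupations are the normalised weights, free energies are
$F_i = -k_B T \ln w_i$ up to a common additive constant (only *differences*
are meaningful outputs, and they depend only on stored columns), and the
heat capacity is

$$C_v(T)/k_B = \kappa + \frac{\langle V^2\rangle - \langle V\rangle^2}{(k_B T)^2},$$

the closed form of the temperature derivative of
$\langle V\rangle + \kappa k_B T$. The suite checks this against a central
finite difference of the internal energy (step $10^{-3}$ K, agreement to
$10^{-6}\,k_B$). Assumptions: vibrations are classical and harmonic; no
anharmonic, quantum, or rotational corrections. These cancel in the
free-energy differences that the analysis reports, to the extent that they
are similar between states.

## Kinetics

Harmonic transition-state theory gives the elementary rate

$$k(a \to b) = \frac{\sigma_a}{\sigma_{ts}}
\exp\!\big(\ln\Pi\nu_a - \ln\Pi\nu_{ts}\big)\, e^{-\beta (V_{ts}-V_a)},$$

whose units (s$^{-1}$) come from the one leftover frequency factor. Detailed
balance with the harmonic weights holds algebraically, and the test-suite
verifies residuals below $10^{-10}$ on every generated network.

Effective rates between two sets $A$, $B$ use mean first passage times: with
the generator $K$ (here stored column-from, `K[b, a]` = rate $a \to b$), the
MFPTs to an absorbing $B$ solve a linear system on the non-$B$ states, and
$k_{A\to B} = 1/\langle \tau \rangle$ with the average taken over $A$ with
equilibrium weights conditioned on $A$. Dense LU solves are used; at the
desk scales this package targets (up to a few thousand states) this is
simpler and more transparent than graph-transformation approaches, and it is
cross-checked against dense matrix-exponential propagation of the master
equation (log-linear fit of the $A$-population relaxation at 20 log-spaced
times). One caveat is worth stating: the identity
$k_f/k_r = p_B^{eq}/p_A^{eq}$ is exact for MFPT-based rates only when $A$
and $B$ exhaust the network; with intermediate minima the deviation is of
the order of the intermediate population, which is also the regime boundary
(intermediate occupancy $< 10^{-3}$) inside which the rates agree with the
master-equation oracle to 1%.

The Eyring relation $\Delta G^\ddagger = k_B T \ln\!\big(k_B T/(h k)\big)$
(transmission coefficient fixed at 1, since no recrossing model is
available) converts rates to barriers; two-state exchange data enter as
$k_f = p_{minor} k_{ex}$, $k_r = (1-p_{minor}) k_{ex}$. Both reported
exchange-rate measurements for the TAR stemloop (737 s$^{-1}$ from CEST and
474 s$^{-1}$ from relaxation dispersion, minor population 0.4%) are
supported; the default reproduction uses 474 s$^{-1}$, which matches the
printed barriers most closely, and switching to 737 s$^{-1}$ moves each
barrier by less than 0.3 kcal/mol at 310.15 K. The default analysis
temperature throughout is 310.15 K (37 °C).

**Fastest paths** minimise $\sum -\ln P$ over directed steps with branching
probabilities $P(a\to b) = k(a\to b)/\sum_c k(a\to c)$ (rates summed over
parallel transition states). Waiting times are deliberately ignored — this
is the "best path" notion of discrete path sampling, a product of branching
probabilities; an alternative weight including $-\ln k$ would rank by
expected time instead and is intentionally not implemented. Ties are broken
deterministically: among equally good next minima the smallest id wins, and
among parallel transition states the fastest, then the smallest id.

## Regrouping

Free-energy regrouping lumps minima into kinetic groups at a temperature:
group free energies are $-k_B T \cdot \mathrm{logsumexp}$ over member
weights, the inter-group transition-state ensemble pools every connecting
saddle the same way (so parallel-path entropy is included), and two groups
merge when the pooled barrier is below the threshold $\Delta G_{thresh}$ in
*both* directions. Merging repeats to a fixed point.

Two numerical conventions matter here:

* Minimum weights carry $\kappa$ modes and transition-state weights
  $\kappa - 1$, so their dropped constants differ by one factor of
  $\ln(\beta h)$. The pooled transition-state free energies are therefore
  shifted by $+k_B T \ln(k_B T / h)$ onto the *Eyring scale*, making
  `effective_barriers()` directly comparable with barriers derived from
  experimental rates, and making the merge criterion dimensionally
  meaningful. On a network constructed from barriers (17.8, 14.3) kcal/mol
  the regrouped barriers recover the construction to $10^{-6}$.
* The merge order is deterministic (smallest worse-direction barrier
  first), and the fixed point is empirically merge-order independent: the
  suite replays randomised merge orders on seeded networks and finds the
  same partition.

No specific threshold is privileged: the published landscape barriers
(21.1/15.1 kcal/mol for the wild-type TAR stemloop, 41.1/11.6 for the ES2
variant) depend on the unstated threshold used with the deposited database,
so `regroup_scan()` emits barriers as a function of threshold instead of
baking in a constant. The suite demonstrates on synthetic landscapes with
known construction barriers that the scan localises a threshold reproducing
them within 0.5 kcal/mol; the same scan applies unchanged to a downloaded
stationary-point database.

## Disconnectivity analysis

Two minima share a superbasin at threshold $E$ iff a path connects them
whose transition states all lie at or below $E$ (union-find over the
filtered edge set). A disconnectivity tree evaluates this partition on a
descending grid of spacing $\Delta E$; leaves attach at their own energies,
and a leaf pair's merge level brackets the exact minimax path energy from
above within one $\Delta E$ (verified against a brute-force enumeration of
simple paths on networks up to 15 minima). Funnels are selected by anchor
minimum and cutting level — the programmatic equivalent of the manual
branch-cutting used in practice. Free-energy trees are built on the
regrouped quotient network at the analysis temperature.

Colouring by an order parameter (for the TAR system, the distance between
the Watson–Crick-edge nitrogens of the G10/C21 equivalents) assigns leaves
their own value and internal nodes the occupation-weighted mean of their
members; the aggregation rule is a package convention, stated because the
field's figures colour branches without specifying one. Layout (recursive
midpoint x-positions) is emitted as structured data; rendering is left to
the host environment.

# RNA structural descriptors

## Base-pair annotation

Pair detection follows the r-vector idea: project the centre of base $j$'s
six-membered ring into the frame of base $i$ (origin at the ring centroid,
$z$ the Newell normal over the ordered ring atoms, $x$ in-plane towards the
Watson–Crick edge nitrogen), and require **both** mutual r-vectors inside
the ellipsoid $(x/a)^2 + (y/a)^2 + (z/b)^2 \le 1$.

The defaults $a = 6.5$ Å (in-plane) and $b = 2.0$ Å (normal) were fixed by
measuring physically constructed Watson–Crick pairs: with standard
hydrogen-bond geometry the six-ring centre separations are 5.5–5.9 Å (GC
5.6, AU 5.5, GU wobble 5.9), and helically stacked neighbours sit at a 2.8 Å
normal offset. An in-plane semi-axis of 5 Å would detect *no* canonical
pair, and a normal semi-axis of 3 Å would annotate stacked neighbours as
pairs, so those values were rejected; 6.5/2.0 leaves a safety margin on both
sides. Both semi-axes are exposed as arguments.

Edges are assigned from the in-plane azimuth of the partner centre with
per-base-type sectors. This is deliberate: traversing the six-ring in the
same atom order (N1…C6) circulates in opposite senses relative to the
Hoogsteen/sugar edges for purines and pyrimidines, so a single global sector
convention cannot be correct for both. The sectors were calibrated once on
the ideal nucleotide templates (purine N7/C8 at negative azimuth, pyrimidine
C5/C6 at positive azimuth) and are documented in the source as the principal
interpretation risk of the module.

Orientation uses the operational rule standard in the field: the glycosidic
torsion C1′(i)–N(i)–N(j)–C1′(j) with $|\tau| \le 90°$ meaning *cis*. A
normal-dot-product proxy was considered and rejected because it
misclassifies the sheared GU wobble. Pairs that satisfy the distance
criterion but whose edge/orientation assignment fails (missing glycosidic
atoms) are reported as category `XXX`, matching the convention of keeping
geometric pairs that resist classification visible rather than dropping
them. Dot-bracket output exists as a utility but is never used for
classification, since secondary-structure strings are ambiguous under
register wobbling.

## Other descriptors

* **WC-edge distance**: N1 (A, G) / N3 (C, U) nitrogen separation; around
  3 Å for paired bases. This is both a descriptor column and the
  disconnectivity colouring order parameter.
* **Sugar pucker**: Altona–Sundaralingam phase from the five endocyclic
  torsions, evaluated as $P = \mathrm{atan2}(\tau_m \sin P, \tau_m\cos P)$
  so that the quadrant correction by the sign of $\nu_2$ is automatic;
  amplitude $\tau_m = \sqrt{\nu_2^2 + ((\nu_4+\nu_1-\nu_3-\nu_0)/2(\sin
  36°+\sin 72°))^2}$. A planar ring has $\tau_m = 0$ and an undefined phase,
  reported as `NA`. A mirror-image ring negates every torsion and maps
  $P \to (P + 180°) \bmod 360°$ at unchanged amplitude — this, not
  $360° - P$, is the correct chirality behaviour of the formula, and it is
  what the suite asserts.
* **Inter-helical angles**: per stem, the helical axis is the first
  principal direction of the C1′–C1′ pair-midpoint cloud (oriented along
  the pair order) and the x-axis comes from the first pair's C1′–C1′
  vector; the rotation between stem frames is decomposed in the z-y-z Euler
  convention, with $\beta$ the bend. The exact convention of the cited
  helix-angle method is not recoverable from the text, so the convention is
  pinned, stated, and tested against constructed rotations (coaxial ⇒
  $\beta \approx 0$, constructed 30°/90° bends recovered within 2°), which
  are convention-independent checks.
* **SASA**: Shrake–Rupley with a 1.4 Å probe and 960 deterministic
  Fibonacci-lattice points per atom; Bondi-type radii (C 1.70, N 1.55,
  O 1.52, P 1.80, S 1.80, H 1.20 Å), configurable. A single isolated atom
  reproduces $4\pi(r+1.4)^2$ exactly because every lattice point is
  accessible.
* **PCA**: z-score standardisation then covariance eigendecomposition
  (via `prcomp`); zero-variance columns are dropped with a warning;
  projection applies the stored means/scales/loadings, which is how
  externally supplied ensembles are placed on the landscape's components.
  The default descriptor block reproduces the TAR analysis: WC-edge
  distances for pairs 8–23, 9–23, 10–21, 10–22, 10–23, 11–22, 12–21,
  pucker phases for residues 6–9, three inter-helical angles, and the SASA
  of nucleotide 23 (1-based numbering in which position 1 is G17 of the
  full RNA).

# Stationary-point search on analytic potentials

The search core exercises the full exploration loop without a force field.
Potentials are pluggable (energy/gradient/Hessian callables with
finite-difference defaults); two are built in — the 1D double well
$x^4 - x^2$ and the standard four-term exponential 2D benchmark surface,
whose three minima and two saddles are established at test time by an
independent in-repo oracle (dense $161^2$ grid of $|\nabla V|^2$, Newton
polish of every grid-local minimum, Hessian classification) rather than
taken from any table.

* **DNEB**: straight-line bands (quasi-continuous interpolation is a
  biomolecular necessity, not needed for low-dimensional analytic surfaces,
  and is explicitly out of scope), doubly nudged force projection, and an
  adaptive-step relaxation. After relaxation, interior energy maxima enter a
  *climbing* phase (parallel force reversed, springs released): without it,
  candidate energies undershoot the true saddle by the image-spacing
  discretisation error ($\tfrac12 |\lambda| \delta^2$, several kcal/mol on
  the stiff benchmark surface), with it they converge onto the saddle.
* **HEF**: uphill Newton step along the lowest Hessian eigenvector,
  Newton minimisation with shifted positive curvatures in the orthogonal
  complement, trust radius 0.1, gradient tolerance $10^{-7}$; convergence to
  a Hessian index other than 1 is a rejection with a diagnostic.
* **Connection**: two minimisations from the saddle displaced
  $\pm 10^{-3}$ (scaled by coordinate magnitude) along the unique negative
  eigendirection, a short steepest-descent leg committing to the basin
  followed by BFGS and Newton polish.
* **Exploration**: repeated DNEB→HEF→descend cycles over unconnected (then
  nearest unattempted) minimum pairs; minima and saddles deduplicate at
  $10^{-4}$ coordinate / $10^{-6}$ energy tolerance; log-frequency products
  come from Hessian eigenvalues as $\nu_j = \sqrt{\lambda_j}/2\pi$ (unit
  masses), point-group orders are 1. The loop stops on budget, exhaustion,
  or when the network is connected and the heat-capacity curve on a fixed
  temperature grid changes by less than a relative $10^{-6}$ between rounds
  — the same convergence signal used for real landscape sampling. The
  several literature refinements (trap removal, barrier short-cutting,
  enhanced local sampling) are collapsed into this single loop; they are
  sampling accelerators, not definitions, and the desk-scale surfaces here
  do not need them. Temperature grids for the toy potentials are in reduced
  units matched to their barrier scales (thousands of K for the benchmark
  surface, whose wells are ~40–100 energy units deep).

# Synthetic data: what it emulates, and what it does not

The generators define the package's test conditions:

* `generate_funnel_ktn()` emulates a multi-funnel topography: chains of
  minima (base energy + Uniform(0, 2) kcal/mol spread) with intra-funnel
  saddles 3 kcal/mol above the higher of each pair, funnels joined by a
  single saddle 12 kcal/mol above the global minimum, log-frequency products
  Uniform(ln 10¹², ln 10¹³) — magnitudes typical of molecular vibrational
  products. Defaults (2 funnels × 5 minima) mirror the two-main-funnel
  organisation of the TAR landscape at toy scale. The construction makes
  funnel membership and every pairwise minimax merge energy exact ground
  truth.
* `generate_two_state()` inverts the barrier-extraction pipeline exactly:
  minima at 0 and $\Delta G_f - \Delta G_r$, saddle at $\Delta G_f$, and
  log-products supplying the $k_BT/h$ prefactor, so harmonic TST rates equal
  `barrier_to_rate()` of the construction barriers identically.
* `build_helix_fixture()` places ideal nucleotide templates (PDB Chemical
  Component Dictionary geometries, stored as plain-text TSV under
  `inst/extdata/nt_templates/` with provenance noted there) on an ideal
  helical lattice (rise 2.81 Å, twist 32.7°), constructing each prescribed
  pair by exact two-point alignment of its hydrogen-bond atoms onto
  standard donor–acceptor distances (GC: N1–N3 2.92, O6–N4 2.91, N2–O2
  2.86 Å; AU: N1–N3 2.82, N6–O4 2.95; GU: O6–N3 2.83, N1–O2 2.79). Bends
  apply a rotation between stems at the junction; registry slippage shifts
  every partner index before construction; unpaired residues are flipped
  10 Å out of the helix on staggered steps so every residue's sugar and
  base exist without colliding with anything.

What passing tests on these fixtures shows: the geometry pipeline
(frames, r-vectors, edges, orientations, pucker, angles, SASA) is correct
on structures whose answers are known exactly. What it does not show:
robustness to thermal distortion, modelling error, non-ideal sugar puckers,
or the energetics of real RNA — the fixtures are geometrically ideal and
thermodynamically meaningless, and no sequence-dependent stability is
modelled. Likewise the toy KTNs validate the kinetics/topography machinery,
not any force field.

# Degenerate inputs and numerical conventions

* Energies are kcal/mol everywhere; $k_B = 0.0019872041$ kcal mol⁻¹ K⁻¹;
  rate prefactors use SI $k_B$ and $h$.
* Stationary-point files: whitespace-separated, ids are 1-based line
  numbers, numbers written with 17 significant digits so read∘write is the
  identity on doubles; up to three trailing columns (moments of inertia in
  the common convention) are read and ignored rather than interpreted.
* Validation enforces $V_{ts} \ge \max(V_{min1}, V_{min2})$ with
  discard/clamp/error policies; degenerate rearrangements
  (`min1 == min2`) are retained in the tables but excluded from graph
  edges and rates.
* `logsumexp` is max-shifted; occupations normalise to 1 within $10^{-12}$.
* Disconnectivity levels are a descending grid from `E_max` (default: top
  stationary point + $\Delta E$); minima above a level are excluded from
  its partition.
* Single minima, empty transition-state sets, identical DNEB endpoints,
  planar sugar rings, and zero-variance PCA columns all take defined
  branches rather than erroring obscurely.

# Known limitations

* Harmonic, classical thermodynamics only; no rotational or anharmonic
  partition-function terms (differences are assumed vibrational +
  potential).
* MFPT linear solves are dense; networks far beyond ~2×10³ states would
  want sparse solves or graph transformation.
* The edge-sector azimuth boundaries (±60°) and ellipsoid semi-axes are
  calibrated conventions, not fitted to annotation corpora; borderline
  non-canonical pairs may classify differently than other tools.
* The saddle search is for low-dimensional analytic potentials; no
  biomolecular force field, implicit solvent, or Cartesian RNA search is
  included, and QCI-style interpolation is out of scope.
* Reproducing the published landscape-level numbers (regrouped barriers,
  PCA variance fractions) requires the externally deposited
  stationary-point database; the package ships the machinery (`regroup_scan()`,
  `fit_pca()`) and verifies it on synthetic constructions with known answers.
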