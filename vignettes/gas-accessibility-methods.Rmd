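---
title: "Methods: gas accessibility maps and catalytic-loop dynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gas accessibility maps and catalytic-loop dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ilsmap)
```

This vignette documents the models, conventions and defaults behind
`ilsmap`, in enough detail that every number the package produces can be
reproduced by hand from the equations.

## 1. The free-energy map (implicit ligand sampling)

`computeIlsMap()` estimates, on a regular Cartesian grid, the free-energy
cost of placing a weakly interacting gas probe at position $\mathbf{r}$ in
a frozen simulation ensemble:

$$G(\mathbf{r}) = -k_B T \,\ln \frac{1}{N\,C}\sum_{f=1}^{N}\sum_{c=1}^{C}
  e^{-\Delta E_{fc}(\mathbf{r})/k_B T}$$

where $N$ is the number of frames, $C$ the number of probe orientations and
$\Delta E_{fc}$ the probe-system interaction energy of frame $f$,
orientation $c$. This is Widom test-particle insertion performed on every
voxel of a grid; vacuum gives $G \equiv 0$ by construction, and negative
values mark sites that attract the probe.

Conventions, all settable through `ilsConfig()`:

* `temperature = 300` K; $k_B$ = 0.0019872041 kcal/mol/K, so
  $k_B T \approx 0.60$ kcal/mol (`thermalEnergy(300)`).
* `gridSpacing = 1` Å, `cutoff = 10` Å (truncated, unshifted
  Lennard-Jones), minimum-image convention in orthorhombic boxes. A box
  length of 0 on an axis disables wrapping on that axis, which is how the
  non-periodic wall systems are handled.
* `energyCap = 87 * kB * T`: insertions whose energy exceeds the cap
  contribute zero weight (their Boltzmann factor is below $10^{-37}$).
  Voxels where *every* insertion is capped are **occluded**: they carry the
  `displayCap` value (30 kcal/mol) in the map for rendering, but the
  authoritative record is the logical `occludedMask()`, and path searches
  treat them as impassable rather than as finite barriers.
* Because every retained Boltzmann factor is at least $e^{-87}$, plain
  summation of $e^{-\beta\Delta E}$ is exact to machine precision; no
  log-sum-exp rearrangement is needed and none is used, which keeps the
  optimized engine bit-comparable to a naive reference loop.

### The O2 probe

`o2Probe()` models dioxygen as two identical Lennard-Jones sites 1.21 Å
apart (±0.605 Å along the local z axis) with $\sigma = 1.7$,
$\epsilon = 0.12$ kcal/mol, no charges. The published parameter is read, by
default, as the CHARMM `Rmin/2` radius (`sigmaIs = "rmin2"`), because 1.7 Å
is the conventional oxygen `Rmin/2` in CHARMM tables and the combination
rule used here is CHARMM's: $R_{min,ij} = R_{min,i}/2 + R_{min,j}/2$,
$\epsilon_{ij} = \sqrt{\epsilon_i \epsilon_j}$. The literal
Lennard-Jones-σ reading is available as `sigmaIs = "lj"`; it shrinks the
site radius by the factor $2^{1/6}/2$ and deepens apparent accessibility
slightly.

### Orientations

O2 is a symmetric rotor, so orientations are axes, not full rotations, and
antipodal axes are redundant. `generateOrientations(21)` (the default
count) places axes by a spherical Fibonacci scheme restricted to the upper
hemisphere: $z_i = (i + 0.5)/n$ with the golden angle in azimuth. A count
of 1 degenerates to the +z axis, which makes single-orientation tests
exact.

### Bulk reference

Relative (solvation-referenced) barriers need the probe's free energy in
bulk solvent. `bulkReference()` pools the Boltzmann weights of all voxels
farther than 12 Å (default) from any non-solvent atom:

$$G_{bulk} = -k_B T \ln \overline{e^{-G_v / k_B T}}$$

with the uncertainty estimated by splitting the qualifying voxels into 5
blocks. In a pure synthetic water box at 0.997 g/cm³ (216 molecules,
500 frames) the package obtains $G_{bulk} \approx 2.1$–2.2 kcal/mol for
the O2 probe. Two accuracy caveats are deliberate: the water sampler uses
a molecule-based cutoff with an infinite-dielectric reaction field rather
than Ewald electrostatics, and the probe-water interaction is truncated at
the map cutoff; both bias the absolute solvation number at the 0.1 kcal/mol
scale, which is why barriers are reported relative to the *same* bulk
reference rather than as absolute numbers.

## 2. Pathways and barriers

`minimaxBarrier()` finds, between an active-site voxel and a goal region
(another voxel set or the literal `"boundary"` of the map), the path that
minimizes the *maximum* $G$ along it — the widest-path / minimax objective,
which is the natural notion of a gas migration barrier since the rate is
controlled by the worst point of the best channel. The search is a
best-first expansion over the 26-connected voxel graph; occluded voxels are
impassable. The reported `bottleneck` includes the starting voxel's own
$G$, and the unit tests pin the implementation to an independent
characterization: the bottleneck equals the smallest threshold $t$ at which
start and goal are connected in the subgraph $\{G \le t\}$.

`enumeratePathways()` takes an isovalue (in kcal/mol), floods the
$G \le$ isovalue region reachable from the site (26-connectivity again),
and partitions it into channels by the connected components of its
boundary exits; each channel is the set of voxels closest (by BFS) to its
exit component. `liningResidues()` reports, for a path, the heavy atoms'
residues within a radius (default 4.5 Å) of any path voxel center in at
least half the frames, sorted by minimum distance.

## 3. Loop geometry

All loop metrics operate on ensembles aligned by
`alignPrincipalAxisZ()`: per frame, the selection's centroid moves to the
origin and its gyration-tensor principal axis is rotated onto +z (signs
fixed by continuity with the previous frame, and with +z/+y for the first
frame — a convention meant for continuous trajectories, not for arbitrary
frame permutations).

* **Opening angle θ** (`thetaDefinition()` / `openingAngle()`): the angle
  at the anchor residue's Cα (default residue 342) between the vector to
  the tip residue's Cα (default 348) and the vector to the point
  $(0, 0, z_{ref})$, where $z_{ref}$ is the z coordinate of the loop-Cα
  centroid of a designated closed-reference structure, frozen into the
  definition. θ is invariant under rotations about z, so the arbitrary
  azimuthal orientation of the aligner is harmless.
* **Contact distance** (`minDistance()`): minimum heavy-atom pair distance
  between two selections, per frame, no periodic imaging.
* **Helical content** (`helicalContent()`): Kabsch–Sander hydrogen-bond
  energy $E = 27.888\,(1/r_{ON} + 1/r_{CH} - 1/r_{OH} - 1/r_{CN})$ with
  amide hydrogens rebuilt at 1.01 Å opposite the carbonyl when absent; a
  residue is helical when it sits inside an $i \to i+4$ (or $i+3$) bonded
  run with $E < -0.5$ kcal/mol. On an ideal $(\phi,\psi) = (-57,-47)$ helix
  of 12 residues the interior 10 qualify.
* **Correlation time** (`correlationTime()`): integrated autocorrelation
  time $\tau = \Delta t\,(1/2 + \sum_k \rho_k)$, truncated at the first
  negative autocorrelation. For white noise this converges to
  $\Delta t / 2$; for an exact AR(1)/OU series it recovers the relaxation
  time within sampling error.

## 4. Conformational landscape

`pcaLoop()` superposes all frames on a *fit selection* — by default the
Cα set complementary to the loop, i.e. the stable core, because fitting on
the moving loop itself would absorb the very motion being measured — then
eigendecomposes the covariance of the loop Cα coordinates. `fes2d()` turns
two projection columns into $F = -k_B T \ln(n_{bin}/n_{max})$ with empty
bins carried as `NA` plus an explicit mask (never as fake numbers).
`gromosCluster()` implements the greedy neighbour-counting GROMOS
algorithm on the pairwise RMSD matrix (fit on the core, RMSD over the
loop; default cutoff 6.2 Å), deterministic under ties.

## 5. Synthetic generators

Every generator is a pure function of its arguments including the seed.

* `genWaterBox()`: rigid three-site water (TIP3P geometry and charges),
  Metropolis MC with molecule-based cutoff and infinite-dielectric
  reaction field. Default move sizes give 20–70% acceptance.
* `genLJFluid()`: single-site Lennard-Jones fluid; with $\epsilon = 0$ it
  is an ideal gas (uniform positions), which provides closed-form checks.
* `genCavityChannel()`: a watertight wall lattice with a spherical cavity
  and bored cylindrical channels. The system is deliberately *non-periodic*
  (box 0): a periodic image of the wall would seal the channel exit at the
  box face.
* `genLoopTrajectory()`: a rigid 40-residue Cα core helix along +z plus a
  20-residue loop interpolating between two endpoint conformations driven
  by a latent coordinate. With `wellDepth = 0` the latent process is an
  exact (unbounded) Ornstein–Uhlenbeck AR(1), so its autocorrelation is
  exactly exponential and `tauTrue` is recoverable; with `wellDepth > 0`
  it becomes a double-well Langevin reflected into [0, 1], concentrating
  frames in two basins at the cost of the analytic ACF. An explicit
  `latent` series can be supplied for controlled cluster-recovery tests.
* `genIdealHelix()`: ideal backbone geometry at fixed $(\phi, \psi)$.

## 6. Worked example

```{r example, eval = FALSE}
# accessibility of a synthetic cavity with one bored channel
cav <- genCavityChannel(cavityRadius = 6, channelRadius = 4.7,
                        boxLength = 20, wallSpacing = 1.6)
res <- runO2Accessibility(list(
  input = cav,
  ils = list(gridSpacing = 1.5, cutoff = 6,
             region = list(min = c(0, 0, 0), max = c(20, 20, 20))),
  sites = list(pocket = c(10, 10, 10)),
  isovalue = 1, bulk = list(skip = TRUE)))
res$report

# loop dynamics on a synthetic two-basin trajectory
lt <- genLoopTrajectory(nFrames = 500, tauTrue = 20, seed = 1)
core <- "name CA and resid 100-139"
loop <- runLoopDynamics(list(inputs = list(lt$ensemble),
                             align = core, fitSelection = core))
loop$tau$A
head(loop$metrics)
```

## 7. Limitations

* Absolute solvation numbers inherit the reaction-field and truncation
  approximations of the synthetic sampler; use relative barriers.
* XTC trajectories are not readable (no R-level reader is available);
  DCD and multi-model PDB are supported.
* The ILS estimator assumes the probe does not perturb the ensemble
  (infinite-dilution, frozen-environment approximation) — standard for
  implicit ligand sampling, but it ignores induced fit.
* θ values depend on the alignment convention; compare only angles
  computed under the same `thetaDefinition()` and aligner selection.
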