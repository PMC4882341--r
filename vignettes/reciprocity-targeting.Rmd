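---
title: "Reciprocity-based TES targeting: models, algorithms and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reciprocity-based TES targeting: models, algorithms and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The forward model

At EEG/TES frequencies (< 100 Hz) volume conduction in the head is
quasi-static: the potential $\psi$ obeys $\nabla\cdot(\sigma\nabla\psi) = 0$
in the head $\Omega$ with no current through the free scalp surface. Real
electrodes are not points: each electrode $l$ covers a finite contact patch
$E_l$ and couples to the scalp through a contact impedance per unit area
$z_l$ (units $\Omega\,\mathrm{m}^2$). The *complete electrode model* (CEM)
adds, per electrode, one potential unknown $V_l$ and the boundary conditions

$$\psi + z_l\,\sigma\,\partial_n\psi = V_l
\quad\text{and}\quad
\int_{E_l}\sigma\,\partial_n\psi\,\mathrm{d}S = I_l \quad\text{on } E_l ,$$

where $I_l$ is the injected current. A lumped contact resistance $R$
measured for a disc electrode of diameter $d$ converts to
$z_l = R\,\pi d^2/4$; the package default $z_l = 2.01\ \Omega\,\mathrm{m}^2$
corresponds to a typical dense-array electrode (8 mm, about 40 k$\Omega$).

First-order Galerkin discretisation on a tetrahedral mesh gives the
symmetric system $\mathbf{K}\mathbf{v} = \mathbf{f}$ of order $N + L$
($N$ nodes, $L$ electrodes): the volume stiffness, $1/z_l$-weighted facet
mass matrices on the contact patches (evaluated in closed form on linear
triangles), the node–electrode coupling block and the electrode diagonal
block. Before grounding, $\mathbf{K}$ is positive semi-definite with the
constant vector as its one-dimensional nullspace.

Two right-hand sides matter:

* **TES**: per-electrode currents (zero sum) in the last $L$ entries;
* **EEG**: a current dipole $\mathbf{d}$ at $\mathbf{r}$ by partial
  integration, $f_n = \mathbf{d}\cdot\nabla\varphi_n(\mathbf{r})$ on the
  four vertices of the containing tetrahedron. Shape-function gradients sum
  to zero inside a tet, so charge is conserved exactly. When the position
  sits on a face or vertex the lowest-index containing element is used
  (deterministic tie-break).

With linear elements the electric field $\mathbf{E} = -\nabla\psi$ and the
current density $\mathbf{J} = \sigma\mathbf{E}$ are constant per element.

### Solver

`solve_system()` runs preconditioned conjugate gradients restricted to the
orthogonal complement of the constant nullspace vector (rank-one deflation:
the right-hand side and every iterate are projected). The preconditioner is
a cached sparse Cholesky factorisation of the grounded matrix (last unknown
pinned), so in practice the iteration converges in one or two steps to the
default tolerance of $10^{-11}$ on the relative residual of the full
assembled matrix; the residual and iteration count are always recorded.
The factorisation is computed once per system and reused by every
subsequent solve — this is what makes the $L-1$ transfer-matrix solves and
the repeated topography solves cheap. Potentials are returned re-referenced
to zero-mean electrode potential (the average-reference convention; every
ranking used downstream is reference-invariant). Incompatible right-hand
sides (currents that do not sum to zero) are rejected rather than silently
projected.

### Electrode currents from the solution

The current through a contact patch is evaluated from the Robin boundary
condition, $\sigma\,\partial_n\psi = (V_l - \psi)/z_l$, integrated exactly
over the contact facets (`electrode_current_flux()`). The naive alternative
— dotting the adjacent element's constant gradient with the facet normal —
converges extremely slowly here because the CEM current density is singular
at the contact edge; the Robin form is the standard choice in impedance
tomography and reproduces the prescribed currents to solver precision.

## The synthetic head model

`generate_layered_sphere_mesh()` builds concentric shells
(brain/CSF/skull/scalp by default, outer radii 80/83/88/94 mm — conventional
four-layer values, freely configurable) as a conforming tetrahedral mesh:

* subdivided-icosahedron surfaces are placed at radial levels that include
  every shell interface exactly, so each element lies wholly inside one
  shell and the tissue label is read off the centroid radius;
* the prisms between consecutive levels are split into three tetrahedra
  with the *smallest-global-index diagonal* rule, which guarantees that
  neighbouring prisms make the same choice on shared quadrilateral faces
  (a conforming mesh with interior faces shared by exactly two elements);
* the innermost surface is fanned to the centre node.

The construction is closed-form and involves no randomness, so meshes are
bit-reproducible; a structured decomposition was preferred over a Delaunay
tetrahedralisation precisely for this reproducibility and to avoid any
external mesher. `target_edge` controls the angular resolution (surface
edge length) and `radial_spacing` the radial level distance; because the
icosphere topology is fixed per level, deep-brain elements get radially
elongated when the spacing is much larger than the local tangential edge.
For field metrics and tangential-dipole accuracy a roughly isotropic
aspect near the cortical shell matters, hence the layered defaults
(e.g. 10 mm edges with 8 mm radial spacing) used in the validation runs.

Tissue conductivities default to the standard literature values (S/m):
gray matter 0.33 (used for the whole brain shell), white matter 0.2, CSF
1.79, skull 0.008, scalp 0.35, eyes 1.5.

Electrodes are laid out on a deterministic Fibonacci-spiral lattice —
quasi-uniform at any montage size (64/128/256) without optimisation — and
each electrode claims the boundary facets whose centroids fall within its
contact radius, nearest-centre assignment keeping patches disjoint.

What the sphere model does *not* emulate: cortical folding (on a sphere
every surface normal is radial, so "tangential targets" are specified by
orientation rather than geometry), the CSF channelling effects of real
sulci, skull foramina and internal air, tissue anisotropy, and realistic
electrode positions. Passing tests on the sphere therefore validate the
numerics and the algorithmic contracts, not subject-specific dosimetry.

### Mesh quality

The per-element *stretch factor* is the inscribed-sphere radius over the
longest edge, normalised so a regular tetrahedron scores 1; the natural
constant is $2\sqrt6$ (since $r_\mathrm{in} = a/(2\sqrt6)$ for edge $a$),
which we adopt explicitly as a design choice. Degenerate elements score 0
without raising. The reported summary is the fraction of elements below
0.05, the usual sliver criterion.

## Targeting algorithms

All optimizers consume either the EEG topography of an oriented target
dipole (reciprocity family) or the transfer matrix (LS/LCMV):

* **Transfer matrix.** The $L-1$ elementary patterns ($I_{max}$ at
  electrode $i$, $-I_{max}/(L-1)$ elsewhere) span the zero-sum space; their
  per-element fields form the dense $3T\times(L-1)$ matrix $\mathbf{T}$
  (element-major, x/y/z-minor). Any zero-sum pattern decomposes uniquely on
  the first $L-1$ elementary patterns (normal-equations solve).
* **LS** minimises $\|\mathbf{T}\mathbf{c}-\mathbf{e}\|$ with
  $\mathbf{e} = \mathbf{b}\otimes\mathbf{d}$ (the desired orientation
  replicated on the ROI elements, zero elsewhere *over the whole head* —
  restricting to the brain invites spurious source–sink pairs in the outer
  tissues). The problem is overdetermined ($L-1 \ll 3T$) and solved
  unregularised.
* **LCMV** enforces $\tilde{\mathbf{T}}\mathbf{c} = \mathbf{d}$ exactly at
  the target element and minimises total field power; the closed-form
  equality-constrained solution is used, and the pre-scaling constraint
  residual is recorded.
* Both are mapped to electrode currents and $\ell_1$-rescaled,
  $\mathbf{p} = 2 I_{max}\,\mathbf{q}/\|\mathbf{q}\|_1$, so the positive
  (source) currents sum to exactly $I_{max}$.
* **Reciprocity family.** Sources are the top-ranked topography electrodes
  (ties broken by electrode index): all others as sinks (*one source*; no
  per-electrode cap by design — it is a reference), the bottom-30 as sinks
  (*opposite*), the 10 electrodes nearest the source centroid as sinks
  (*ring* — "closest" is interpreted as nearest to the source-set centroid
  in 3-D, a deliberate reading that reproduces the ring topology), or the
  ROADSS rule: $\mathbf{r}_s = \mathbf{r} - \|\mathbf{r}_m -
  \mathbf{r}\|\,\mathbf{d}$ with $\mathbf{r}_m$ the source centroid, sinks
  the $n_{sources}$ electrodes nearest $\mathbf{r}_s$ (fixed at the source
  count, configurable). Equal splits keep every electrode at
  $I_{max}/n_{sources} = I_{max}/10$ at the defaults. For montages smaller
  than the 10 + 30 assumption the counts scale down proportionally and the
  cap rises to keep the budget feasible.

### Polarity convention

With the partial-integration dipole right-hand side the discrete identity
$\Phi(a)-\Phi(b) = \mathbf{d}\cdot\nabla\psi_{ab}(\mathbf{r})/I_{ab}$ holds
to solver tolerance (the matrix is symmetric, so both sides are the same
bilinear form). Injecting the positive current at the *positive* topography
pole therefore maximises the directional potential gradient
$\mathbf{d}\cdot\nabla\psi$; since $\mathbf{J} = -\sigma\nabla\psi$, the
delivered current density at the target then points along $-\mathbf{d}$,
i.e. *into* the cortex under the sources — the anodal convention. The
selection rules keep the classical "source at the maximum" form; signed
directional metrics simply carry that polarity, reversing every current
reverses it, and qualitative method comparisons use the magnitude of the
directional component.

## Performance metrics

For a delivered per-element density $\mathbf{J}$ and a target (centre
$\mathbf{r}$, unit normal $\mathbf{d}$, ROI elements):

* intensity = volume-weighted ROI mean of $\mathbf{J}$, its projection on
  $\mathbf{d}$, and the normalised dot product (directionality in
  $[-1,1]$);
* global/local targeting error = distance from $\mathbf{r}$ to the centre
  of gravity of the suprathreshold density (75% of the maximum), weights
  $|J|_i V_i$ — the volume factor is a deliberate choice for
  mesh-resolution independence, as the plain "weighted average" leaves the
  weight open; the local variant restricts to brain elements within 3 cm
  (threshold re-applied inside the neighbourhood), so the local error is
  bounded by 3 cm by construction;
* global focality = radius of the smallest target-centred sphere holding
  half of the brain's $|J|_i V_i$ mass (computed by sorting centroid
  distances; membership is decided by centroid);
* $F_{loc}$ = mass within 1 cm of the local centre of gravity over mass
  within 3 cm of the target. When the local CoG drifts more than 2 cm from
  the target the inner sphere can leave the outer one and the ratio may
  exceed 1; the value is reported as-is with a warning.

## Analytic oracles

Two closed-form layered-sphere solutions validate the FEM path
independently:

* a dipole inside the innermost shell of an $M$-layer sphere with
  insulating exterior (Legendre series; per-degree radial transfer systems
  in a two-end-scaled basis so high degrees stay well conditioned; default
  truncation at 80 terms with a tail-magnitude early stop);
* two point current sources on a homogeneous sphere. Interior points use
  the series $\frac{I}{4\pi\sigma R}\sum_n \frac{2n+1}{n} (r/R)^n
  P_n(\cos\gamma)$; on the surface itself that series converges only
  conditionally, so its closed-form sum $\frac{I}{4\pi\sigma R}
  [1/s - 2 - \log(s(1+s))]$, $s=\sin(\gamma/2)$, is evaluated instead.

The two oracles are cross-checked against each other through the
reciprocity identity with no FEM involved. When comparing FEM electrode
potentials with the oracles, the analytic solution is area-averaged over
each electrode's actual contact patch (`patch_average_potentials()`):
a finite contact measures the patch mean, and evaluating the closed form at
the nominal centre instead conflates the patch-assignment discretisation
with solver error. Comparisons use the standard relative-difference (RDM)
and magnitude-ratio measures, excluding a 10° cap around each injection
site where the point-source idealisation diverges from the finite patch.

## Validation problem sizes

The shipped validation suite (tests and `scripts/acceptance.R`) runs at
sizes chosen to exercise the claims while staying desk-scale: the
reciprocity identity on a ~67k-element four-shell head with 64 electrodes;
pole-pair/topography agreement on a ~13k-element head (the identity is
discretely exact, so coarse is enough); FEM-versus-oracle comparisons on
~174k (single shell) and ~189k (four shells, 8 mm radial spacing) element
meshes where the element aspect is near-isotropic at the cortex; method
comparisons on a ~44k-element head with 64- and 128-electrode montages.

## Known limitations

* Sphere geometry only: no cortical folding, anisotropy, or internal air;
  conclusions about method *orderings* transfer, absolute dose numbers do
  not.
* First-order elements: current densities next to contact edges and in
  slivers are locally inaccurate (quality is monitored via the stretch
  factor; the contact-edge singularity is handled via the Robin-form flux).
* The unconstrained LS/LCMV references do not impose the per-electrode cap
  (by design, as in their classical formulations); the $\ell_1$-constrained
  iterative variants are out of scope.
* Single-target patterns only; multi-target stimulation is not implemented.
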