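# restim: reciprocity-based targeting for transcranial electrical stimulation

Transcranial electrical stimulation (TES/tDCS) drives weak currents (1–2 mA)
through scalp electrodes to modulate cortical excitability. With dense EEG-style
electrode arrays the montage design becomes an optimization problem: choose
per-electrode currents that maximise the current density delivered to a cortical
target along its surface normal while sparing the rest of the brain, under a
total budget `I_max` and a per-electrode safety cap (typically `I_max/10`).

`restim` is an R toolkit for studying this problem end to end on synthetic
layered-sphere head models, with no external data:

* **Forward solver.** A first-order tetrahedral Galerkin discretisation of the
  quasi-static volume conduction problem with the *complete electrode model*
  (CEM): finite contact patches with contact impedance `z_l` enter as extra
  boundary unknowns, giving the symmetric `(N + L) x (N + L)` system
  `K v = f`. The same system solves both the TES forward problem (scalp
  injections) and the EEG forward problem (cortical dipoles via
  partial-integration right-hand sides).
* **Reciprocity.** The package is built around the TES–EEG reciprocity
  identity: for a dipole with moment **d** at **r**,
  `Phi(a) − Phi(b) = d · grad(psi_ab)(r) / I_ab`,
  where `psi_ab` is the potential of a current `I_ab` injected between scalp
  points *a* and *b*. The electrode pair maximising the dipole's EEG
  topography therefore maximises the directional potential gradient at the
  target — so a single EEG forward solve replaces a full optimization.
* **Optimizers.** The unconstrained least-squares (`ls_pattern`) and
  linearly-constrained-minimum-variance (`lcmv_pattern`) reference solutions
  on the `3T x (L−1)` transfer matrix, and four reciprocity selection rules:
  `one_source`, `opposite` (10 sources / 30 sinks), `ring` (sinks encircling
  the sources), and `roadss` (Reciprocity Opposite Averaged Distance Sink
  Selection), which interpolates between *opposite* and *ring* behaviour
  according to the target orientation.
* **Metrics.** Target intensity and directionality, global and local (3 cm)
  centre-of-gravity targeting error with a 75% density threshold, the global
  half-total-density focality radius, and the local focality ratio `F_loc`
  (1 cm / 3 cm sphere mass ratio).
* **Oracles.** Closed-form Legendre-series solutions for dipoles in
  concentric multilayer spheres and point-electrode injection on a
  homogeneous sphere, used as independent validation of the FEM path.

Meshes round-trip through TetGen `.node`/`.ele` text files; per-element fields
export to legacy VTK; montages and patterns to TSV/CSV.

## Worked example

```r
library(restim)

head <- generate_layered_sphere_mesh(
  radii = c(0.08, 0.083, 0.088, 0.094),            # brain/CSF/skull/scalp, m
  labels = c("brain", "csf", "skull", "scalp"),
  target_edge = 0.014, radial_spacing = 0.009)
montage <- place_electrodes(head, 64, contact_radius = 0.008)
system <- assemble_cem_system(head, default_conductivities(), montage)

target <- target_from_seed(head, seed = c(0, 0, 0.08), n_elements = 12)
topo <- eeg_topography(system, target$center, target$direction)
pattern <- roadss_pattern(topo, montage, target)
evaluate_pattern(system, pattern, target)
```

which prints (abridged):

```
tet_mesh: 7705 nodes, 43520 tetrahedra, 1280 boundary facets
electrode_montage: 64 electrodes, contact radius 8.0 mm
tes_target: 12 elements, centre (0.0, 0.0, 76.9) mm, normal (0.00, 0.00, 1.00)
injection_pattern [roadss]: 64 electrodes (20 active), sum 0 A, l1 0.002 A, max |I| 0.0001 A

 method intensity directional directionality te_global te_local focality_global  f_loc
 roadss    0.0247     -0.0246         -0.996     0.013   0.0078          0.0672 0.0846
```

The ROADSS montage activates 20 electrodes (10 sources at the topography
maximum, 10 sinks ringing them for this radial target), keeps every electrode
at or below `I_max/10 = 100 uA`, and delivers `~0.025 A/m^2` at the target,
nearly all of it along the target axis (directionality magnitude 0.996; the
sign records the anodal polarity convention — sources sit at the positive
topography pole, so the delivered density points into the cortex). The global
targeting error is 13 mm and half of the brain's current-density mass lies
within 67 mm of the target.

A whole comparison study (all methods, several targets, CSV/VTK reports) is
one call: `run_pipeline(default_run_config(), "out_dir")`.

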