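# ringmech

Mechanics of superelastic Nitinol ring-stent bundles — the radial-support
element of ring-based endovascular stent grafts — as a self-contained R
package. A ring bundle is wound from `n` turns of a single Nitinol wire
(0.16–0.22 mm), crimped into a delivery catheter, released into an
oversized artery and cycled by the cardiac pressure pulse. Because
superelastic Nitinol is load-history dependent, the clinically relevant
quantities — chronic outward force (COF) and the fatigue-relevant strain
extrema over the pulse cycle — can only be computed by simulating the whole
life of the ring: forming from straight stock, crimping, deployment,
pulsation.

The package implements, from the constitutive level up:

* a 1-D superelastic Nitinol model with linear transformation kinetics,
  hysteresis and tension-compression asymmetry (closed-form return
  mapping): elastic with mixture modulus `1/E(xi) = (1-xi)/E_A + xi/E_M`
  below the active surface, forward transformation over
  `[sigma_LS, sigma_LE]`, reverse over `[sigma_US, sigma_UE]`, compression
  surfaces scaled by `sigma_CS/sigma_LS`;
* a geometrically nonlinear corotational Timoshenko beam core with
  fiber-discretized circular sections, exact welds, spring connectors and
  penalty contact against rigid/driven cylinders, solved by
  incremental-iterative Newton with a consistent finite-difference tangent;
* circle-packing bundle geometry (`BW = R_bundle/R_wire`, tabulated for
  n = 1..14 and cross-checked by a numerical packing optimizer);
* the manufacturing step (wire bent to the ring mean radius; peak strain
  validated against `eps = R_wire/R_ring`);
* the four-string saddle pull test (structural stiffness over the
  operational deflection range, with and without manufacturing pre-strain);
* a hyperelastic artery tube (6th-order reduced polynomial wall,
  semi-analytic thick-wall inflation) sized for a target oversize at the
  time-weighted mean pressure `P_m = P_d + (P_s - P_d)/3`;
* the full deployment scenario: guided compaction into the catheter,
  release onto the pressurized wall, pulsation between 80 and 120 mmHg,
  reporting COF, `eps_Diast`, `eps_Syst` and the maximum cycle-mean strain
  `M_eps`.

Units are mm / N / MPa / mmHg throughout. See the methods vignette
(`vignettes/ring-bundle-mechanics.Rmd`) for the models, assumptions,
numerical choices and limitations.

## Worked example

Form the largest fixture ring (0.200 mm wire, 48.09 mm mean diameter, 9
turns), crimp it into a 6.9 mm catheter, deploy at 10% oversize and
pulsate:

```r
library(ringmech)

ring <- ringConfig(d_wire = 0.200, D_ring = 48.09, n_turns = 9)

fr <- formRing(ring, n_elem = 96)
print(fr)
#> formedRing
#> ringConfig: wire 0.200 mm, ring 48.09 mm, 9 turns, prestrain yes
#>   FE peak forming strain  : 0.0041589
#>   analytic R_wire/R_ring  : 0.0041589
#>   relative deviation      : 3.89e-10%

res <- runDeployment(ring, n_elem = 96, nincr_compact = 50)
print(res)
#> Deployment result
#>   COF at P_m : 1.637 N (diast 1.659, syst 1.622)
#>   eps_Diast  : 0.739%  at 86 deg
#>   eps_Syst   : 0.716%  at 180 deg
#>   M_eps      : 0.715%
```

Reading the numbers: the manufacturing strain equals the bending closed
form `R_wire/R_ring = 0.42%` to ten digits (the forming program is exact by
construction, and the released ring is in self-equilibrium). After
crimping and deployment the wire's peak surface strain is 0.74% at
diastole, located at a peak of the saddle (86 degrees), dropping to 0.72%
at systole when the vessel dilates; the ring pushes on the wall with about
1.6 N of chronic outward force at mean pressure. These strain extrema are
the inputs a fatigue assessment would take downstream.

The saddle pull test and the pre-strain effect:

```r
sr  <- runSaddle(formRing(ring, n_elem = 64))          # with pre-strain
sr0 <- runSaddle(formRing(ringConfig(0.200, 48.09, 9,
                          include_prestrain = FALSE), n_elem = 64))
stiffnessDeviation(sr0$curve, sr$curve)   # no-prestrain curve is stiffer
```

A command-line interface wrapping the same functions ships under
`inst/cli/ringmech` (subcommands `form`, `saddle`, `deploy`, `packing`,
`vessel-curve`, `convergence`; configurations are YAML with the presets
`ring1`..`ring4`, `nitinol_37C`, `aorta_labrosse_67_77`).

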