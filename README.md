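# osteofem

Mechanical prediction of osteoporotic hip-fracture probability from clinical
bone-densitometry trajectories.

Osteoporosis management rests on DXA bone mineral density (BMD), but BMD alone
says little about the *mechanics* of the failing bone. `osteofem` closes that
gap for the proximal femur: it turns a patient's per-Gruen-zone BMD — and its
projected evolution under natural ageing or drug therapy — into evolving bone
material properties, pushes them through a linear-elastic finite element (FE)
model of the femur under stance loading, and maps the resulting strain field
to mechanical damage and a normalized fracture probability. The audience is
researchers in bone biomechanics and quantitative osteoporosis modelling.

## The model

The pipeline chains five standard relations:

1. **Device cross-calibration.** Densitometer readings are standardized,
   e.g. Hologic: sBMD = 1.008·BMD + 6 (mg/cm²).
2. **Density law.** Apparent density from standardized BMD:
   ρ = ρ_max (sBMD / BMD_max)^λ with λ = 9/25, ρ_max = 1.909 g/cm³,
   BMD_max = 1610 mg/cm².
3. **Stiffness law (Carter–Hayes).** E = 2875 ρ³ MPa.
4. **Continuum damage.** With equivalent strain
   ε_c = √(ε_I² + ε_II² + ε_III² − ε_I ε_II − ε_I ε_III − ε_II ε_III),
   damage is D = 1 − κ ε_c^γ above a threshold ε₀ (D = 0 below it), where
   γ = ln(1/(1−D_cri)) / ln(ε₀/ε_cri) and κ = ε₀^(−γ) anchor the law at
   D(ε₀) = 0 and D(ε_cri) = D_cri. Cortical defaults: D_cri = 0.38,
   ε_cri = 0.0174, ε₀ = 0.0015.
5. **Fracture probability.** A Paris-law (da/dN = α ΔK^β, β = 5 for cortical
   bone) cycle-count argument normalized between no damage and critical
   damage gives P = (D / D_cri)^(β/2 − 1), with P(0) = 0 and P(D_cri) = 1.

At every time step the engine evaluates each Gruen zone's (patient-adapted)
BMD curve, rebuilds the zone-wise material map, solves the femur under a
3110 N head contact force and a 1360 N abductor pull with the mid-diaphysis
clamped, and converts per-element equivalent strains to D and P. Results are
referenced to baseline as ΔP(t) = P(t) − P(0).

Because no clinical geometry ships with the package, a parametric synthetic
proximal femur (head + neck + trochanter + shaft with medullary canal,
tissue- and Gruen-zone-labelled tetrahedra) is generated on demand; BMD
evolution curves can be fitted to data (polynomial, exponential and
exponential-asymptotic families with model selection) or taken from built-in
templates emulating natural decline, alendronate, intermittent ibandronate
and a PTH-then-bisphosphonate switch.

## Worked example

```r
library(osteofem)

# densitometry -> material properties for the healthy reference femur
add_material_properties(healthy_femur_bmd())
#>    zone device   bmd  sbmd density modulus
#>       1 hologic   782  794.   1.48   9325.
#>       2 hologic  1093 1108.   1.67  13356.
#>       3 hologic  1429 1446.   1.84  17816.
#>       4 hologic  1591 1610.   1.91  19998.
#>       ...

# 15-year natural evolution on a coarse synthetic femur
mesh <- generate_femur_mesh(target_edge = 8)
res  <- run_evolution(healthy_femur_bmd(), "natural", mesh,
                      times = seq(0, 180, by = 36))
subset(tidy(res), region == "neck")
#>   time_months  bmd modulus   eps_c damage probability delta_p
#> 1           0 1001   11992 0.00683  0.156       0.292 0.00000
#> 2          36  993   11886 0.00687  0.157       0.295 0.00294
#> 3          72  983   11758 0.00692  0.159       0.298 0.00656
#> 4         108  970   11600 0.00697  0.160       0.303 0.01109
#> 5         144  955   11400 0.00705  0.163       0.309 0.01695
#> 6         180  935   11139 0.00715  0.166       0.317 0.02479
```

Reading: as femoral-neck BMD declines from 1001 to 935 mg/cm² over 15 years,
the volume-averaged neck modulus drops ~7%, equivalent strain rises, and the
normalized fracture probability climbs from 0.292 to 0.317 — a ΔP of about
2.5 percentage points attributable to the untreated course. Re-running with
`scenario = "alendronate_like"` yields a negative ΔP (risk below baseline),
reproducing the qualitative ordering between treated and untreated cohorts.
`export_maps()` writes per-element ε_c / D / P / ΔP fields as VTK for
inspection; `autoplot(res)` draws the region curves.

A thin CLI over the same functions lives at `inst/cli/osteofem.R`
(`fit-bmd`, `make-femur`, `simulate`, `verify-fe`, `report`).

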