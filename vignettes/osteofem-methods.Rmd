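---
title: "Methods: evolutionary fracture-probability modelling of the proximal femur"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: evolutionary fracture-probability modelling of the proximal femur}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
library(osteofem)
```

`osteofem` predicts how the probability of an osteoporotic hip fracture
evolves as a patient's bone mineral density (BMD) changes — naturally with
age, or under drug therapy. This vignette is the package's own account of
the model: the governing relations, the tunable parameters and their
defaults, what the synthetic generators emulate (and what they do not), the
numerical choices, and the known limitations.

## 1. From densitometry to material properties

Clinical input is areal BMD (mg/cm²) per Gruen zone, the conventional
7-region partition of the proximal femur. Readings from different
densitometer makes are first cross-calibrated to standardized BMD with
linear maps (`device_calibrations()`); for Hologic,
sBMD = 1.008·BMD + 6 mg/cm². Standardized BMD is converted to apparent
density by the power law

$$\rho = \rho_{max}\left(\frac{sBMD}{BMD_{max}}\right)^{\lambda},$$

with defaults $\lambda = 9/25$, $\rho_{max} = 1.909$ g/cm³ and
$BMD_{max} = 1610$ mg/cm² — the reference point being the densest Gruen zone
of a healthy adult femur (`healthy_femur_bmd()`). Both reference values are
per-patient configurable; $\lambda$ is treated as global rather than
per-zone (the calibration data do not resolve zone-wise exponents). Young's
modulus then follows the Carter–Hayes cubic law $E = 2875\,\rho^3$ MPa (low
strain rates).

All BMD values are carried unrounded through the pipeline; rounding happens
only in presentation output. This matters at the third decimal of apparent
density: rounding sBMD to the printed integer first can flip the final digit
(e.g. zone 6 of the reference table, 1.7765 g/cm³).

## 2. BMD evolution curves

Continuous BMD-versus-time models (`bmd_curve`) come in three parametric
families, fitted by least squares (`fit_bmd_curve()`):

* polynomial $a_0 + a_1 t + \dots + a_n t^n$ (linear fit);
* exponential $k(1 - e^{-(a_1 t + \dots + a_n t^n)}) + a_0$. The source
  formulation is typographically ambiguous about whether $a_0$ sits inside
  the exponent; we place it outside so that the curve starts at $a_0$, which
  is the physically meaningful reading (baseline BMD at $t=0$);
* exponential-asymptotic
  $\rho_0 + (\rho_{lim} - \rho_0)(1 - e^{-a t/(t_m - t)})$, defined for
  $t < t_m$ and approaching $\rho_{lim}$ as $t \to t_m$.

Model selection (`select_bmd_curve()`) minimizes mean squared error
(unweighted, in standardized-BMD space), with ties broken by fewer
parameters and then by family order polynomial < exponential < asymptotic.
Candidate polynomial degrees default to 1–4.

**Nonlinear fitting.** The two exponential families are linear in their
amplitude parameters given the rate parameters, so initialization profiles
them out: a coarse grid over $(a, t_m)$ (or the rate vector) solves a linear
least-squares problem per grid point, and the best grid point seeds
Levenberg–Marquardt (`minpack.lm::nlsLM`), followed by five restarts from a
fixed jitter table (no RNG, so fits are reproducible and never perturb the
user's random stream). Non-convergence of every start raises an error
carrying the best initial residual.

**Identifiability of the asymptotic family.** With realistic measurement
noise (σ ≈ 5 mg/cm²) the rate $a$ is only weakly identified unless the data
cover the approach to the asymptote: a Cramér–Rao analysis at the harness
parameters ($\rho_0 = 900$, $\rho_{lim} = 700$, $a = 0.02$, $t_m = 240$,
$n = 40$) shows the standard error of $a$ exceeding 100% when sampling stops
at 120 months and still ≈ 7% for a uniform grid reaching $0.9975\,t_m$. The
synthetic recovery generator (`generate_asymptotic_series()`) therefore uses
the design $t_i = 0.9975\,t_m\,(1 - (1-u_i)^2)$, concentrating samples where
the curve changes fastest; under it all four parameters recover with median
relative error below 5% and fitted R² ≥ 0.98 on every seeded replicate.

**Patient adaptation.** Population curves carry trend, not level. A curve is
personalized by the constant translation
$\mathrm{curve}(t) + (\mathrm{measured} - \mathrm{curve}(t_0))$
(`adapt_to_patient()`), so it passes exactly through the patient's measured
baseline; natural and therapy curves adapted to the same measurement
coincide at $t_0$. The translation is applied in standardized-BMD space by
default — the curves are fitted to BMD, and offsetting before the density
law keeps its nonlinearity single-use — but `offset_space = "density"`
switches to density-space offsets for sensitivity analysis.

**Schedules.** Intermittent or sequential therapies are piecewise curves
(`compose_schedule()`): contiguous segments, each evaluated in local time
since its start, with every segment after the first vertically shifted to
enforce continuity at the junctions.

**Templates.** Four built-in trajectories emulate published evolution
shapes, all sharing one baseline (900 mg/cm² by default): *natural* — an
asymptotic decline losing ≈ 7% over 15 years (≈ 0.5%/year, a typical
elderly femoral-neck rate), with the decline accelerating as $t \to t_m$;
*alendronate-like* — an exponential rise of ≈ 4% in the first year that
plateaus; *ibandronate-like* — rise (0–36 mo), decline at the natural rate
while dosing is interrupted (36–96 mo), renewed rise (96–180 mo);
*PTH-switch-like* — a steep 18-month rise followed by a mild
bisphosphonate-style consolidation. Therapy templates never fall below the
natural course at equal baseline, which is what makes the scenario-dominance
check meaningful. The templates are smooth population means with additive
Gaussian noise on top (`generate_bmd_series()`); they do not emulate visit
irregularity, device switches mid-series, secular cohort effects or
responder/non-responder heterogeneity — tests passing on them validate the
machinery, not clinical generalization.

## 3. Damage and fracture probability

Mechanical damage is an instantaneous function of the equivalent strain
$\varepsilon_c = \sqrt{\varepsilon_I^2 + \varepsilon_{II}^2 +
\varepsilon_{III}^2 - \varepsilon_I\varepsilon_{II} -
\varepsilon_I\varepsilon_{III} - \varepsilon_{II}\varepsilon_{III}}$
(computed internally from tensor invariants, avoiding per-element
eigensolves):

$$D = \begin{cases} 0 & \varepsilon_c \le \varepsilon_0 \\
1 - \kappa\,\varepsilon_c^{\gamma} & \varepsilon_c > \varepsilon_0
\end{cases}
\qquad
\gamma = \frac{\ln\frac{1}{1-D_{cri}}}{\ln\frac{\varepsilon_0}{\varepsilon_{cri}}},
\quad \kappa = \varepsilon_0^{-\gamma}.$$

Defaults (cortical bone): $D_{cri} = 0.38$, $\varepsilon_{cri} = 0.0174$,
$\varepsilon_0 = 0.0015$, giving $\gamma \approx -0.19504$ and
$\kappa \approx 0.28134$. Note $\gamma < 0$: the implementation must not
assume a positive exponent — $\kappa\varepsilon^{\gamma}$ is decreasing, so
$D$ increases with strain as intended. Damage equals stiffness deficit,
$D = 1 - E/E_0$, and the two routes round-trip exactly.

Fatigue life between damage levels follows a Paris crack-growth argument
with crack size $a = \omega D$:

$$N(D_i, D_f) = \frac{(\omega D_i)^{1-\beta/2} - (\omega D_f)^{1-\beta/2}}
{\alpha\,\Delta\sigma^{\beta}\gamma_k^{\beta}\,(\beta/2-1)},$$

which is non-negative, telescoping-additive, and diverges as $D_i \to 0$
(zero initial damage is rejected). Normalizing the life consumed between no
damage and critical damage yields the fracture probability

$$P = \min\!\left(1, \left(\frac{D}{D_{cri}}\right)^{\beta/2-1}\right),$$

independent of $(\alpha, \Delta\sigma, \gamma_k, \omega)$, which cancel —
they default to 1 and `cycles_between()` is exposed for sensitivity studies
only. Two caveats are inherited from the source formulation and resolved
explicitly here: the closed form $(D/D_{cri})^{\beta/2-1}$ is taken as the
definition of $P$ (it is not algebraically identical to $1 - N(D)/N_{max}$
for an arbitrary lower damage bound), and the symbol $\gamma$ is overloaded
between the damage law and the stress-intensity factor — the package keeps
them as distinct fields (`gamma` in `damage_params()`, `gamma_k` in
`paris_params()`). Damage above $D_{cri}$ is left unclamped ($P$ is clamped
at 1) and flagged by `is_supercritical()`.

$\beta = 5$ is a cortical-bone value, so damage and probability are
evaluated on cortical elements only by default; supply your own $\beta$ and
tissue handling to extend to cancellous bone.

## 4. The finite element model

**Geometry and mesh.** The synthetic femur (`femur_geometry()`,
`generate_femur_mesh()`) is a union of primitives — shaft cylinder with
medullary canal, neck cylinder at a 110–140° neck-shaft angle, spherical
head, ellipsoidal greater trochanter — voxelized on a structured grid and
decomposed into tetrahedra by the Freudenthal (Kuhn) 6-tet split, which is
conforming without parity flips and yields positive volumes by
construction. Tissue labels come from signed-distance logic (cortical =
within the cortical thickness of the outer surface, thinner proximally;
marrow = canal; cancellous = the rest), regions
(head/neck/trochanteric/subtrochanteric/diaphysis) and Gruen zones 1–7 from
element centroids: zones 1/7 proximal (lateral/calcar, with head and neck
split by the neck axis into superolateral and inferomedial sides), 2/6
subtrochanteric, 3/5 diaphyseal, 4 the distal band. The mesh is
deterministic; element count scales as (edge)⁻³. At coarse resolution the
voxelized boundary can pinch at isolated edges; the watertightness check
accepts closed-but-non-manifold edges and reports them separately.

**Elements and assembly.** Linear 4-node tetrahedra are the default;
quadratic 10-node tetrahedra (straight edges, 4-point Gauss rule — exact for
the quadratic integrand) are available with `order = 2` and are what the
bending benchmark uses, since linear tets converge slowly in bending. For
fixed Poisson ratios the element stiffness is proportional to E, so
`fe_structure()` precomputes unit-modulus triplets once per mesh; each
material update rescales them and re-assembles a sparse symmetric matrix
solved by CHOLMOD Cholesky (which doubles as an SPD check — a singular
system raises a named error). Strains are recovered at element centroids;
principal strains use the closed-form trigonometric eigensolution for
symmetric 3×3 tensors, vectorized over elements.

**Loads and constraints.** Only magnitudes are clinically reported, so
directions are conventional and configurable: the 3110 N head contact force
(4 × body weight at 79.3 kg, printed to the nearest 10 N) acts downward,
tilted 13° from the shaft axis in the frontal plane; the 1360 N abductor
force pulls the greater trochanter superomedially at 21° from vertical —
the anatomical line of action of the abductors toward the ilium (a
"downward" abductor pull would contradict their insertion geometry; pass
`abductor_direction` to override). Both forces are distributed over nodal
patches (default radius 8 mm) to avoid singular strain spikes. The distal
10% slab of the modelled shaft — the mid-diaphyseal cut, far from the
proximal region of interest — is clamped.

**Verification.** The solver passes a patch test (prescribed linear
displacement field reproduced with constant strain to machine precision),
scales linearly in loads and inversely in stiffness, is frame-indifferent in
$\varepsilon_c$ under rigid rotation, and matches the Euler–Bernoulli tip
deflection of a 100×10×10 mm cantilever within 2% at the refinement level
accepted by the 1% potential-energy rule (`mesh_convergence_study()`); the
remaining ≈ 0.6% gap is real shear deflection that beam theory ignores.

## 5. The evolutionary algorithm

`run_evolution()` steps a 0–180 month grid (default 6-month steps — the
evolution curves are smooth at that resolution) and at each time: evaluates
every zone's adapted curve → density law → stiffness law → FE solve →
$\varepsilon_c$ → $D$ → $P$, then volume-averages element values per region
(element-level first, then average: the maps are nonlinear, so the order
matters and is fixed). $\Delta P(t) = P(t) - P(0)$ references everything to
baseline. Cancellous bone keeps a constant stand-in density (0.5 g/cm³ →
≈ 359 MPa) and marrow 20 MPa: zone-wise cancellous densitometry is rarely
available, and cortical stresses are only weakly sensitive to the much
softer interior tissues.

Damage is **reversible** by default: it is a state function of the current
strain, so therapy that raises BMD lowers damage — matching the published
treated-cohort curves, which do decrease, and which an irreversible
accumulation law could not produce. `irreversible = TRUE` retains the
running maximum for sensitivity analysis.

Time-step cost is one sparse Cholesky solve (~0.3 s at the default ~15k
elements), so a full 31-step scenario runs in ~10 s. The unit tests run on
~2k-element meshes; the acceptance checks use the default ~15k-element
femur and 31 steps per scenario.

## 6. Design decisions in brief

* Calibration slopes/intercepts for Hologic/Lunar/Norland are the standard
  published linear maps; the Hologic map reproduces the reference table's
  standardized integers exactly, which validates the choice.
* Poisson ratios are not clinically reported: ν = 0.3 (cortical,
  cancellous), ν = 0.45 (marrow), configurable.
* The default element order is 1 (desk-scale runtime; the convergence study
  compensates); order 2 exists for verification-grade runs.
* Zone 4's printed density/BMD pair defines the density-law reference point;
  both are per-patient overridable.
* Config I/O is JSON with all-violations-at-once validation naming full key
  paths; the canonical dump is a fixed point of load. The reference-table
  fixture parser accepts European decimal commas; everything else is
  dot-decimal CSV.
* Mesh and field I/O is legacy-ASCII VTK written at full precision
  (`%.17g`), so numeric round trips are exact; ΔP maps are exported in
  percent.

## 7. Limitations

* The femur is idealized; no patient-specific geometry, cortical-thickness
  maps or CT calibration. Hotspot statements are about the synthetic
  geometry's neck/trochanteric stress concentrations, not about any
  individual anatomy.
* Linear elasticity under a single static stance load: no sideways-fall
  impact, contact, or large-deformation mechanics. The model predicts where
  resistance degrades, not the fracture event itself.
* The probability is a normalized mechanical index, not a calibrated
  clinical risk (no FRAX-style epidemiology).
* Damage is isotropic and tension/compression-symmetric; no crack-geometry
  modelling.
* Template curves are population means; real series need `fit_bmd_curve()`
  on actual measurements, and the identifiability caveat of §2 applies to
  any asymptotic-family fit whose data stop far from the asymptote.
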