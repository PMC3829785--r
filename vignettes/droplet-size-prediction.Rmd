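---
title: "Predicting droplet and microparticle size in ultrasonic atomization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting droplet and microparticle size in ultrasonic atomization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sonodrop)
```

## The problem

Microencapsulation of drugs in polymer carriers by spray processes needs
control over droplet size: the droplet set in flight becomes the microparticle
after gelation and drying, and particle size governs loading and release.
Ultrasonic atomization produces droplets by ejecting them from the crests of
capillary waves on a liquid film covering a vibrating surface (a sonotrode).
Compared with pressure or rotary nozzles it delivers a narrow size
distribution at low mechanical stress, which makes it attractive for fragile
biopolymer/drug systems such as alginate shell-core microparticles.

No first-principles equation predicts the droplet diameter; the field works
with empirical correlations built on dimensionless groups. `sonodrop`
implements that machinery end to end: fluid rheology, the ultrasonic source
model, the dimensionless numbers, the operating window for the feed rate,
four published droplet-size correlations with validity checking, and the
droplet-to-dried-particle shrinkage transform.

## Model

### Dimensionless framework

For jet/drop breakup the classical groups are the Reynolds, Weber and
Ohnesorge numbers,

$$Re = \frac{\rho u d_p}{\mu},\qquad
  We = \frac{\rho u^2 d_p}{\sigma},\qquad
  Oh = \frac{\sqrt{We}}{Re} = \frac{\mu}{\sqrt{\rho\sigma d_p}}.$$

On a vibrating surface there is no free-jet velocity, so the groups are
recast in terms of the feed flow rate $Q$, the driving frequency $f$ and the
surface vibration amplitude $Am$:

$$We = \frac{f Q \rho}{\sigma},\qquad
  Oh = \frac{\mu}{f\,Am^2 \rho},\qquad
  I_N = \frac{f^2 Am^4}{C\,Q},$$

where $C$ is the speed of sound in the liquid and $I_N$ (the intensity
number) measures the acoustic energy density delivered per unit liquid
throughput. The amplitude follows from the power surface intensity
$I = P/A$ (delivered power over vibrating area) as

$$Am = \frac{1}{2\pi f}\sqrt{\frac{2I}{\rho C}}.$$

### Operating window

Good atomization requires the feed rate to sit between two bounds. Below the
critical flow rate the film cannot cover the whole surface; the critical rate
is defined by $We = 1$, giving $Q_c = \sigma/(f\rho)$. (Printed forms of this
expression in parts of the literature are garbled — one common rendering,
$\sigma/(f\sigma)$, is dimensionally impossible; `sonodrop` uses
$\sigma/(f\rho)$, the only form consistent with the $We_c = 1$ derivation
and with the reference-case value of $2.8\times10^{-9}\ \mathrm{m^3\,s^{-1}}$.)
Above the maximum rate, the volumetric displacement rate of the surface
$Q_{max} = f\,Am\,A$, dripping occurs. `operating_window()` classifies a feed
rate against those bounds.

### Rheology

Alginate solutions are shear-thinning; their apparent viscosity follows the
power law $\mu = K\dot\gamma^{n-1}$. For Manugel GHB sodium alginate the
package ships published concentration fits, valid for $c$ between 1 and 3 %
w/w (a warning, not an error, outside that range, since the bundled property
table extends to 5%):

$$K(c) = 0.0619\,c^{2.953}\ \mathrm{Pa\,s^n},\qquad
  n(c) = 0.9635\,e^{-0.08c}.$$

The shear rate at the wall of the feed tube uses the Rabinowitsch–Mooney
result for a power-law fluid, $\dot\gamma_W = (3 + 1/n)\,Q/(\pi R^3)$. Some
printed versions of this formula carry an outer exponent $n$ on the whole
bracket; that form is dimensionally inconsistent for a shear rate and is
available only behind `wall_shear_rate(..., as_printed = TRUE)` for
comparison. The tube radius is a required user input: with the reference
case's shell feed of $7\times10^{-8}\ \mathrm{m^3\,s^{-1}}$, a radius of about
0.65 mm reproduces the reported wall shear rate of 333 s$^{-1}$.

Because a power-law fluid has no finite viscosity at zero shear, requests for
apparent viscosity at $\dot\gamma = 0$ with $n < 1$ fail with a pointer to
the zero-shear viscosity input (0.13 Pa s for the 1.5% alginate row).

### Droplet-size correlations

Four published correlations are implemented; all scale with the base term
$(\pi\sigma/(\rho f^2))^e$, essentially the Kelvin capillary wavelength.

* **Lang**: $d_p = 0.34\,(8\pi\sigma/(\rho f^2))^{1/3}$ — viscosity- and
  flow-independent; the low-viscosity baseline.
* **Rajan–Pandit**: $d_p = (\pi\sigma/(\rho f^2))^{0.33}
  [1 + a\,We^{0.22} Oh^{0.166} I_N^{-0.0277}]$. The prefactor $a$ was fitted
  case-by-case in the original work and no universal value was published, so
  `a_rp` is a required user parameter; `a_rp = 0` collapses to the base term.
* **Ramisetty**: $d_p = 0.00154\,(\pi\sigma/(\rho f^2))^{0.33}
  [1 + (\pi\sigma/(\rho f^2))^{-0.2} We^{0.154} Oh^{-0.111} I_N^{-0.033}]$,
  with a stated validity envelope ($f$ 20–130 kHz, $\rho$ 912–1151 kg m⁻³,
  $\sigma$ 0.0029–0.073 N m⁻¹, $Oh$ 2.71–161.64, $We$ 14.8–571,
  $I_N$ 3.65×10⁻¹³–1.92×10⁻⁹).
* **Avvaru** (non-Newtonian): $d_p = (\pi\sigma/(\rho f^2))^{e} +
  0.0013\,We^{0.008} Oh^{-0.14/n} I_N^{0.28}$ — the only correlation carrying
  the flow index $n$; the correction term is additive as printed (it is
  ~0.1 µm for the reference case, so the choice is low-impact).
* **Barba**: $d_p = 0.058\,(\pi\sigma/(\rho f^2))^{0.33} We^{0.151}
  Oh^{0.192} I_N^{-0.02}$ — a pure product form tuned on alginate.

Correlations outside their validity envelope are **computed and flagged,
never suppressed**: the flag is the scientific result (for the alginate
case, the Ramisetty prediction of ≈55 µm is reported together with the
$Oh \gg 161.64$ violation that explains its failure). Validity intervals are
treated as closed — a value exactly on a bound passes.

## Design choices

Several inputs of the published worked case are ambiguous; the package makes
each choice explicit, records it in the report provenance, and lets the user
override it.

* **Viscosity policy.** The ultrasonic $Oh$ can be formed with the apparent
  viscosity at the wall shear rate (0.088 Pa s for the reference case,
  $Oh \approx 8.96\times10^3$) or the zero-shear viscosity (0.13 Pa s,
  $Oh \approx 1.32\times10^4$). Both appear in the source literature without
  comment. The default is `"apparent"` — physically, the liquid reaching the
  atomizing surface has just been sheared through the feed line — but when
  the two policies disagree by more than 1% the report carries both values,
  so neither is silently preferred.
* **Effective flow rate.** With a dual-feed (shell-core) nozzle running the
  same solution in both channels, the spray behaves as a single feed
  dominated by the shell channel, so `policy = "shell"` is the default;
  `"core"` and `"total"` are selectable.
* **Base-term exponent.** The correlation family prints the exponent as
  0.33; the Avvaru correlation's published alginate prediction (≈71 µm) is
  reproduced only with exact 1/3, while Ramisetty and Barba fit 0.33 better.
  Default: 0.33 for the bracket/product family (`base_exponent`), exact 1/3
  for Avvaru (`avvaru_exponent`); both are recorded in the report.
* **Amplitude density.** The density in the amplitude formula defaults to
  the atomized liquid's own density (1004 kg m⁻³ reproduces the reference
  $Oh$ and $I_N$ within 0.3%); water can be configured via
  `coupling_density`.
* **Nozzle area geometry.** When the vibrating area is derived from a
  geometry block it is the sum of two truncated-cone lateral areas and an
  annulus; the cone lateral areas use the slant height computed from the
  axial height and the radius difference (the published footnote says only
  "as height"; axial was chosen and is documented here).
* **Shrinkage.** Volumetric shrinkage assumes isotropic spherical volume
  reduction, $S = 100(1 - (d_{dry}/d_{fresh})^3)$. Fresh alginate droplets
  are actually slightly pendant-shaped after impact with the cross-linking
  bath; that deviation is ignored for sizing. JSON reports carry full
  precision; only the human-readable table rounds to the nearest percent
  (note $78\to41$ µm gives 85.5%, which some published tables round to 86%).

## Worked reference case

The bundled case is a 1.5% w/w Manugel GHB alginate solution (with 1%
α-tocopherol and 0.5% Tween 80 in the core channel) atomized by a 25 kHz,
10 W dual-feed nozzle with vibrating area $1.38\times10^{-3}$ m² and sound
speed 1497 m s⁻¹, feeding 1.1 mL min⁻¹ (core) and 4.2 mL min⁻¹ (shell).

```{r reference}
case <- reference_case()
rep <- atomization_report(case$fluid, case$setup, case$flow,
                          shear_rate = case$shear_rate,
                          particles = case$particles)
print(rep)
```

The same run is available through the config file interface
(`load_config(reference_config())` then `run_report()`), and from the shell
via the `inst/cli/sonodrop` script; both produce values identical to the
library calls.

## Numerical and interface notes

* The whole chain is closed-form arithmetic: no iteration, no tolerance
  tuning, no randomness anywhere, so reports are byte-identical across runs.
  The only root-solve in the project is in the test suite, where a tube
  radius is recovered from a target wall shear rate by `uniroot()` on a
  bracketing interval.
* Unit handling at the boundary is a fixed conversion table (mL min⁻¹, kHz,
  mN m⁻¹, cP, µm, …) rather than a general unit algebra; internal
  computation is strictly SI, and every resolved SI value is kept in the
  loaded config and echoed in the report provenance.
* Configs are YAML; unknown keys are rejected so a typo cannot silently
  change a run. One YAML quirk matters: a bare key `n` parses as boolean
  false under YAML 1.1, so the flow-index key must be written `"n"` (the
  loader also repairs the unquoted form).
* Degenerate inputs fail early with field-named errors: non-positive
  physical properties, flow index outside $(0, 1]$, $Q_c \ge Q_{max}$
  (inconsistent configuration), shrinkage ≥ 100%.

## Limitations

* The correlations are empirical fits; outside their calibration ranges the
  package reports, but cannot repair, their predictions — exactly the
  behaviour seen for the Ramisetty correlation on high-viscosity alginate.
* No temperature dependence: residence-time heating of the film on the
  atomizing surface (which lowers viscosity and droplet size) is discussed
  qualitatively in the literature but not modelled.
* No viscoelastic rheology, no acoustic-field or cavitation physics, no
  secondary-atomization dynamics, no drying kinetics — the shrinkage
  transform is purely geometric.
* Surface tension of surfactant-bearing feeds is taken as the supplied
  constant; dynamic surface tension effects (Tween 80 lowering droplet size)
  enter only through the user-provided value.
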