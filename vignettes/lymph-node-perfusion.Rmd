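---
title: "Dual-porosity lymph-node perfusion: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual-porosity lymph-node perfusion: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The physical model

`lymphomog` treats the lymphoid compartment (LC) of a lymph node as a rigid
dual-porosity sphere of radius `R`. Two phases coexist at every macroscale
point: the interstitial conduit network formed by fibroblastic reticular
cells (the *matrix*, volume `V_m_tot`) and the blood microvasculature (the
*vessels*, volume `V_v_tot`, surface `S_tot`). At the microscale the vessel
phase obeys Darcy's law and the matrix a time-dependent Darcy–Brinkman
equation; the two are coupled across the vessel walls by the Starling
exchange law `v·n = L_p (p_m − p_v − p̄)` with `p̄ = σ(π_m − π_v)`, and by
Beavers–Joseph–Saffman slip on the tangential velocity.

Asymptotic homogenization over a periodic unit cell of edge `d` (the
inter-vessel spacing) delivers macroscale equations whose coefficients are
averages of auxiliary *cell-problem* solutions:

* **Vessel phase.** A periodic Darcy cell problem for a vector potential on
  the vessel network gives the constant effective conductivity
  `K̄_v = (d²/μ)⟨K_v(I + (∇_y h_v)ᵀ)⟩` (intrinsic average over the vessel
  voxels). The local `K_v` is estimated by Kozeny–Carman,
  `(1/c₀)(V/S)²/μ` with the classical `c₀ = 5`.
* **Matrix phase.** Because the Darcy–Brinkman equation retains the time
  derivative, the homogenized matrix law is a *Darcy law with memory*: the
  average velocity is a time convolution of a decaying kernel with the
  history of `∇p_m`. In the frequency domain (convention `e^{−2πitω}`, ω in
  Hz) the kernel is the complex effective conductivity
  `K̄^m(ω) = (d²/μ)⟨Q̂_m(y, ω)⟩`, with `Q̂_m` solving a Brinkman-type cell
  problem with oscillatory drag `2πiωη + K_m⁻¹`, no penetration and slip on
  the vessel interface. Hermitian symmetry `K̄^m(−ω) = conj K̄^m(ω)` makes
  the time kernel real; its time integral equals the steady (`ω = 0`)
  conductivity.
* **Exchange.** Mass transfer between phases appears as
  `±L_p S_tot/V_γ (p_m − p_v − p̄)`; the volume-weighted divergence of the
  two average velocities cancels identically (the total coarse flow is
  solenoidal).

On the sphere, axisymmetric boundary data are expanded in Legendre modes
`P_n(ζ)`, `ζ = cos θ`, and discrete frequencies. Per mode and tone the
transmural difference `u = p_m − p_v − p̄` satisfies `Δu = M(ω) u` with
`M = M_v + M_m(ω)`, `M_v = L_p S_tot/(V_v_tot K̄_v)`,
`M_m = L_p S_tot/(V_m_tot K̄^m(ω))` (units mm⁻²). Its regular radial
solution is the modified spherical Bessel function `i_n(√M r)`; each phase
pressure combines this with a harmonic part `rⁿ`.

### The √M convention

Dimensional consistency of the Helmholtz system requires the Bessel argument
`√M·r` (with the principal root, `Re √M ≥ 0`); the package adopts this
reading throughout, together with the coefficient normalization that makes
the boundary recovery `p(R, ζ, t) = boundary data` *exact by construction*.
Internally all radial factors are expressed through the normalized ratio
`ρ_n(r) = i_n(√M r)/i_n(√M R)`, which is finite at the origin, equals 1 at
`r = R`, and avoids overflow without explicit exponential scaling in the
argument range that arises here (|√M·R| ≲ 10 across all configurations,
including the `L_p` sweeps). The classical coefficient families
(`coef_A_tilde()`, `coef_c1()`, `coef_d1()`) are exposed as accessors; the
boundary-recovery and radial-oracle tests pin the convention down.

`L_p = 0` is handled as an exact special case (decoupled harmonic series,
`c1 = b_m/Rⁿ`, `d1 = b_v/Rⁿ`), not as a limit of the Bessel form, avoiding
0/0 in `Ã_n/M`.

## Parameters

All computation uses the self-consistent mm–mg–s–mPa system
(1 mPa = 1 mg mm⁻¹ s⁻²). The packaged defaults (`table1.yaml`) describe an
idealized spherical mouse popliteal lymph node:

| field | default | units | meaning |
|---|---|---|---|
| `R` | 0.49 | mm | LC radius |
| `mu` | 1 | mg mm⁻¹ s⁻¹ | lymph viscosity |
| `phi` | 0.75 | – | conduit porosity; `mu_e = mu/phi` |
| `rho0` | 1 | mg mm⁻³ | density |
| `sigma` | 0.88 | – | Staverman reflection coefficient |
| `pi_v_minus_pi_m` | 1.02e6 | mPa | osmotic pressure difference |
| `Lp` | 5.475e-10 | mm s⁻¹ mPa⁻¹ | vessel-wall conductivity |
| `pbar_v` | 6.66e5 | mPa | mean vessel boundary pressure |
| `S_tot`, `V_v_tot` | 13.4, 0.0322 | mm², mm³ | vessel surface and volume |
| `r_c`, `d` | 1.7e-3, 2e-2 | mm | microscale cylinder radius / spacing |
| `K_m_interstitial` | 3.84e-9 | mm² | local interstitial permeability |
| `eta` | 0.1 | – | inertia number `ρ₀Ud²/(μL)` |

`V_m_tot` is derived as `(4/3)πR³ − V_v_tot` (the LC is the whole sphere).
The characteristic velocity `U` is never needed independently: the
oscillatory drag in the cell problem depends only on the product
`2πω·ρ₀d²/μ = 2πω_nd·η`, which is what the code uses, so `eta` is exposed
directly and `U` only derived for display.

The boundary condition of the pulsatile study is linear in ζ with a
`(1 − cos πt)/2` pulsation (period 2 s). The default `span_calibrated` mode
scales the ζ-coefficient by `(p_max − p_min)/2` so that at `t = 1` s the
boundary spans exactly `[p_min, p_max] = [4×10⁵, 5.2×10⁵]` mPa
(3–3.9 mmHg); the literal unit-amplitude form is available as
`as_printed`.

## Numerical methods

**Cell geometry.** The vessel network is voxelized as three mutually
orthogonal cylinders of nondimensional radius `r_c/d = 0.085` through the
cell center (configurable axes); this is the documented default topology.
Voxel centers at `(i−½)/n` make opposite faces consistent and the phase
periodic by construction.

**Vessel cell solve.** Finite volumes on the voxel grid, harmonic-mean face
conductivities (exact for laminates, which the tests exploit as a closed-form
oracle), flux-form Neumann interface condition, periodic wrap. The singular
Neumann system is grounded by replacing the one redundant continuity row
with `h₁ = 0` and restoring the zero-mean convention afterwards — a dense
zero-mean Lagrange row would destroy the sparsity of the factorization.

**Matrix cell solve.** A staggered voxel grid (velocities on faces between
matrix voxels, pressures at centers). No-penetration is enforced strongly on
wall faces; the slip condition uses a one-sided first-order normal gradient
with slip length `K_m/α` (`α = 1` by default; the slip length is ~10⁻⁵ cell
edges at physiological permeability, i.e. effectively no-slip). Three solver
paths share one assembly:

* `direct` — sparse LU of the (real or real-augmented complex) saddle
  matrix; robust for any drag, used on small validation cells;
* `uzawa` — augmented-Lagrangian iteration on the CHOLMOD Cholesky factor of
  the grad-div augmented SPD operator `A + γDᵀD`, `γ = s + 12μ*/h²`; the
  contraction factor is mesh-independent (~0.03), so a handful of
  back-solves reach 1e-12; iteration stops at tolerance or at the roundoff
  stall;
* `perturbative` — for `|Im s| < 10⁻³ Re s` the solution is expanded to
  second order in the oscillatory drag around the steady solve (three real
  back-solves; relative truncation error `(Im s/Re s)³ ≈ 10⁻²⁴` at the
  0.5 Hz tone). The three paths agree to ~10⁻¹³ where they overlap, which
  the tests assert.

**Kernels.** Spectra are sampled on uniform grids (`ω ≥ 0` plus Hermitian
completion; the Nyquist bin is forced real); the inverse FFT's imaginary
residual is checked against 1e-10 and discarded. The discrete
rectangle-rule kernel integral equals the DC conductivity exactly. The
time-stepping route uses implicit Euler (unconditionally stable) or
Crank–Nicolson; the 1D cylinder analogue used for the frequency/time
consistency study runs Crank–Nicolson with an implicit-Euler start to damp
the `t = 0⁺` kernel discontinuity, and evaluates the kernel from the spatial
operator rather than by differencing.

**Special functions.** `I_{n+1/2}` at complex argument is evaluated through
the power series of the modified spherical Bessel function (all-positive
coefficients, validated range `|z| ≤ 80`), its derivative through the
upward identity `i_n' = i_{n+1} + (n/z)i_n`. The closed-form cylinder
average uses the identity `1 − (2/x)I₁/I₀ = I₂/I₀`, which is
cancellation-free for small `|x|` — evaluating the printed form directly
loses the imaginary part to catastrophic cancellation, which matters because
the validation compares real and imaginary parts separately.

**Time synthesis.** Boundary data are projected by Gauss–Legendre quadrature
in ζ (order ≥ n_max+1, enforced) and a DFT over one period; band-limited
boundaries use their exact tone set (the pulsatile boundary has tones at 0
and 0.5 Hz only), general data the full FFT-bin set. Both backends share one
code path and are cross-validated to 1e-8. Tones with no boundary energy are
dropped (keeping the FFT backend inside the spectrum band). Velocity polar
components use `dP_n(cos θ)/dθ` with the analytic zero limit at the poles;
the `1/r` factor is regularized at `r < 10⁻⁹R`.

**Truncation.** `n_max = 16` by default with convergence observable through
the boundary-recovery error; the pulsatile study needs only `n ≤ 1` (its
boundary is affine in ζ), which the projection tests confirm exactly.

**Bisection.** The flow-inversion threshold brackets `p̄_v` on
`[10⁶, 2×10⁶]` mPa and bisects the predicate "`p_m − p_v − p̄ ≤ 0`
everywhere for all sampled times" to 100 mPa; monotonicity in `p̄_v` holds
because the solution is affine in the boundary data and `p̄_v` enters only
through `b_v⁽⁰⁾`. The same structure gives an exact translation property —
raising `σΔπ` by δ raises the threshold by exactly δ — used as a test.
Reported mmHg values round to 3 significant figures.

## Problem sizes

Unit tests run the 3D cell solvers at 8³–16³ voxels; the effective vessel
conductivity is computed at 64³ (the reference resolution of the
acceptance pipeline) and the matrix conductivity spectrum at 16³ in the
test suite and 24³ in `scripts/acceptance.R`. At 24³ the steady effective
matrix conductivity is within a few percent of the local interstitial
value, as expected for a ~6% vessel volume fraction; the macroscale
pressures depend on it only through `M_m`, so the threshold and sensitivity
results are insensitive to the residual discretization error at these
resolutions. The cylinder validation uses 3000 radial cells; the
kernel-consistency study a 2¹⁵-bin spectrum.

## What the generators emulate — and what they do not

`make_surrogate_spectrum()` produces the single-pole relaxation
`K₀/(1 + 2πiωτ)` (default `K₀` near the homogenized steady value
~3.6×10⁻⁹ mm³ s mg⁻¹, `τ = 0.05` s): Hermitian, positive real part,
monotone decay — the qualitative shape of the homogenized spectrum, with a
known closed-form kernel for transform tests. It does *not* reproduce the
actual relaxation time of the physiological cell problem, which is
`ρ₀K̂_m/μ ≈ 4×10⁻⁹ s`: at heart/lymphangion frequencies the true matrix
response is quasi-steady (the oscillatory drag is ~10⁻⁸ of the Darcy drag),
so memory effects are negligible in the baseline study and the surrogate's
visible relaxation is a deliberately exaggerated test regime. Passing tests
on surrogates therefore validate the transform and solver machinery, not
the physiological magnitude of memory effects. `make_manufactured_boundary()`
generates band-limited Legendre-cosine data with known coefficients for
exact round-trip tests; real sinus pressure distributions are not
band-limited and their truncation error is governed by the `n_max`
convergence behaviour instead.

## Design choices made where the design was open

* **Sensitivity configuration.** The published sensitivity percentages
  (0.012/0.0238/0.0578% for 1/2/5% conductivity scaling) are reproduced by
  this model at the low-permeability configuration
  (`L_p = 5.475×10⁻¹¹ mm s⁻¹ mPa⁻¹`, `p̄_v = 1.06×10⁶ mPa`) — the
  configuration discussed immediately before the sensitivity analysis in
  the source study — and not at the baseline `L_p`, where the response is
  ~20× larger because the interior pressure deficit scales with `M ∝ L_p`.
  The acceptance pipeline therefore evaluates the sensitivity there, with
  the pulsatile boundary, under the max-over-grid metric at times
  {0, 0.5, 1, 1.5, 2} s (a mean-over-grid alternative is provided, since
  the original metric is unstated).
* **Minimum migration.** In the quasi-steady regime the interstitial
  pressure minimum deepens while the boundary pulse grows (t ∈ [0, 1] s,
  because the lower-pole boundary value falls) and rises while it relaxes;
  the directional tests assert the rise on the relaxing half-period and the
  centre-to-lower-pole migration on the growing one.
* **Kozeny constant.** `c₀ = 5` (classical); the resulting
  1.155×10⁻⁶ mm³ s mg⁻¹ rounds to 1.2×10⁻⁶ at two significant figures,
  against a tabulated 1.1×10⁻⁶ — the comparison in the tests therefore
  uses one unit in the last printed digit.
* **Inversion criterion.** "Inversion for every t" is read as non-positivity
  of the transmural difference on the whole grid at all sampled times of
  one period; a `per_time` flag reports the time-resolved criterion (some
  `p̄_v` invert the flow only at early times).

## Limitations

Only the porous LC sphere is modeled: no free-fluid subcapsular-sinus
coupling, no poroelastic (deformable) matrix, no non-spherical geometry,
and no azimuthal (non-axisymmetric) modes. Body forces and initial
velocities are zero — under these assumptions the force/initial-condition
auxiliary cell problems have identically zero solutions and are omitted.
Osmotic pressures are spatially uniform. The voxel interface treatment is
first-order (validated against the cylinder closed form); the cell topology
beyond the three-orthogonal-cylinder default is configurable but not
derived from imaging data.
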