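---
title: "Methods: virtual six-fibre 3x3 Mueller matrix probe"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: virtual six-fibre 3x3 Mueller matrix probe}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(muellerprobe)
```

## The measurement problem

Tissue polarimetry characterizes a sample by its Mueller matrix, the transfer
function mapping input to output Stokes vectors, $S_{out} = M \, S_{in}$.
Linear retardance extracted from $M$ reports tissue anisotropy (collagen,
muscle fibre organization); depolarisation reports micro-structural
scattering. Flexible endoscopic delivery is the hard part: optical fibres
scramble polarisation unpredictably when bent. The instrument modelled here
sidesteps that by terminating six multimode fibres with distal
micro-polarisers — two each at nominally 0°, 90° and −45° (labelled
H$_1$,H$_2$, V$_1$,V$_2$, B$_1$,B$_2$). The polarisation state entering and
leaving the tissue is then fixed by the distal optics; fibre bending only
modulates *intensity*, which a scalar per-pair calibration absorbs.

Because only linear polarisers are present, the instrument senses the
$3\times3$ linear (I, Q, U) block of the sample's Mueller matrix, determined
from nine pair-labelled intensity measurements
(H$_1$H$_2$, H$_1$V$_2$, H$_1$B$_1$, V$_2$H$_1$, V$_2$V$_1$, V$_2$B$_1$,
B$_1$H$_1$, B$_1$V$_2$, B$_1$B$_2$; first channel illuminates, second
collects). This fixed ordering is frozen into every file format and into the
rows of the system matrix.

## Forward model

For illumination channel $i$ and collection channel $c$, the detected
intensity is

$$ I = g_{ic} \cdot \tfrac12 \begin{bmatrix} I_c & Q_c & -U_c \end{bmatrix}
   \, M_{sample} \, \begin{bmatrix} I_i \\ Q_i \\ U_i \end{bmatrix}, $$

where $[I, Q, U]$ are each channel's normalized exit Stokes parameters and
$g_{ic}$ a positive per-pair coupling. Two modelling points deserve emphasis:

* **The collection fibre drops out.** Only the total intensity of the
  collected state is detected, and a (non-diattenuating) fibre's Mueller
  matrix has first row $[1,0,0,0]$, so its polarisation transformation
  cannot change the detected intensity. A property test verifies this by
  comparing the full 4×4 chain — with a random non-depolarising fibre
  matrix — against the reduced analyzer-row form.
* **The U sign flip.** Channel exit states are characterized for light
  travelling *out* of the probe; collected light travels the opposite way,
  which reverses the sense of the 45° axis and hence the sign of $U$ in the
  analyzer row. The same frame reversal makes a twice-traversed element at
  angle $\theta$ appear at $180°-\theta$ on its second pass, and makes the
  mirror $\mathrm{diag}(1,1,-1,-1)$.

All element composition is done in full 4×4 before the linear block is
extracted. This is not pedantry: composing 3×3 blocks pass-by-pass gives
$\cos^2\delta$ where the correct answer is $\cos 2\delta$ for a retarder
double pass (the linear block of a retarder discards its linear↔circular
coupling, which the second pass needs). A regression test pins both values.

## System matrix and inversion

Stacking the nine measurement equations gives $y = \tfrac12 Z m$, where $m$
is the row-major 9-vector of sample elements and each row of $Z$ is the
Kronecker product of the collection triplet $[I_c, Q_c, -U_c]$ with the
illumination triplet $[I_i, Q_i, U_i]$. With the three exit states spanning
the linear polarisation space, $Z$ is invertible and

$$ m = 2\, Z^{-1} (c \circ y), $$

with $c$ the nine calibration coefficients. `reconstruct()` solves by QR
least squares (identical to the inverse for the well-posed nine-row scheme,
but open to redundant schemes), reports a residual, and returns both the raw
and the $m_{11}$-normalized matrix. A conditioning report with a default
warning threshold of $10^6$ — a double-precision safety margin, deliberately
conservative since the ideal cardinal-channel $Z$ has condition number
$\approx 5.8$ — flags degenerate channel configurations.

## Calibration

Real probes violate the equal-coupling assumption: fibre coupling, geometry
and glue interface reflections differ per channel, and a partially polarised
source (the modelled prototype condition is DOP ≈ 15%) makes emitted
intensity depend on each micro-polariser's orientation. Calibration views a
known target — an external linear polariser at angle $\theta$ backed by a
mirror, i.e. the double pass
$M(180°-\theta)\cdot M_{mirror}\cdot M(\theta)$ — at $\theta \in
\{0°, 30°, 60°\}$ (27 intensities), and fits $c$ by minimizing the mean
absolute difference between the $m_{11}$-normalized reconstruction and the
normalized target, averaged over angles and elements with equal weights.

Numerical choices:

* The objective is invariant under a global rescaling of $c$ (normalization
  removes overall scale), so the gauge is fixed afterwards as
  $\mathrm{mean}(c) = 1$. Any gauge yields identical normalized
  reconstructions; consequently the *raw* scale of a reconstructed matrix is
  not identifiable and quantitative comparisons in the tests are made on the
  normalized scale.
* The absolute value is smoothed as $\sqrt{d^2 + \varepsilon^2}$,
  $\varepsilon = 10^{-9}$, and minimized by L-BFGS-B with an analytic
  gradient, bounds $[0.1, 10]$, at most $10^4$ iterations.
* The raw objective landscape has local minima (the normalization couples
  all nine coefficients), so the optimizer starts from a closed-form
  log-linear warm start: per angle, the coefficient-scaled intensities must
  be proportional to the intensities the forward model predicts for the
  target, which is linear least squares in $(\log c, \log \lambda_\theta)$
  after dropping zero intensities. For a noiseless session this start is
  already the global optimum.

Identifiability requires at least two angles (single-angle sessions are
rejected): with two or more angles, matching all normalized targets forces
$c \propto 1/g$, which the tests confirm over random coupling draws
(log-correlation 1 within $10^{-6}$, held-out 45° target reconstructed to
$10^{-6}$ on the normalized scale, and max element error well under 0.03 at
1% multiplicative noise).

## Polar decomposition

`polar_decompose()` factors $M = M_\Delta M_R M_D$ (depolariser ∘ retarder ∘
diattenuator), in the Lu–Chipman lineage restricted to the linear block:

1. $M_D$ is built from the first row ($d = \sqrt{m_{12}^2+m_{13}^2}/m_{11}$,
   rejected when $d \ge 1$); $M' = M M_D^{-1}$.
2. The 2×2 (Q,U) block $B$ of $M'$ is factored as
   $B = \mathrm{diag}(a,b)\, R_2(\theta, \delta)$, with $R_2$ the retarder
   block ($\det R_2 = \cos\delta$). When $B_{12}B_{21} > 0$ this
   factorization is exact and closed-form: with $r = B_{12}/B_{21} = a/b$,
   $P = B_{11} + rB_{22} = a(1+\cos\delta)$ and
   $Q = \sqrt{(B_{11}-rB_{22})^2 + 4B_{12}^2} = a(1-\cos\delta)$, so
   $\cos\delta = (P-Q)/(P+Q)$, $\theta = \tfrac14
   \mathrm{atan2}(2B_{12},\, B_{11}-rB_{22})$, $a = (P+Q)/2$. This recovers
   generator parameters to solver precision even under strong
   depolarisation, which a trace-based estimate applied directly to $M'$
   cannot do (it returns $\arccos(a(1+\cos\delta)-1) \ne \delta$ whenever
   $a<1$). Being exactly identified, the factorization would also fit
   measurement noise perfectly — so it is accepted only when the implied
   depolarisation factors are physical ($0 < a, b \le 1$).
3. For blocks outside that family ($B_{12}B_{21} < 0$, typical of noisy
   tissue matrices with antisymmetric structure, or unphysical implied
   depolarisation), the trace-based fallback
   is used: $\delta = \arccos(\sqrt{(B_{11}+B_{22})^2 +
   (B_{21}-B_{12})^2} - 1)$ and $\theta = \tfrac14\mathrm{atan2}(B_{12} +
   B_{21},\, B_{11}-B_{22})$, with $\arccos$ arguments clamped to $[-1,1]$
   (a warning fires when clamping exceeds $10^{-6}$).
4. $M_\Delta = M' M_R^{-1}$, using a pseudo-inverse plus symmetrization of
   the 2×2 block when the retarder block is singular
   ($|\cos\delta| < 10^{-8}$, i.e. $\delta \approx 90°$). Recomposition
   $M_\Delta M_R M_D$ then reproduces the input exactly for any branch away
   from the singular retardance.

**The diagonal degeneracy.** A diagonal block is genuinely ambiguous: a
cardinal-axis retarder ($\mathrm{diag}(1, \cos\delta)$) and a diagonal
depolariser ($\mathrm{diag}(a, b)$) are indistinguishable in 3×3. The
committed convention reads a diagonal block as a pure retarder when
$B_{11} = 1$ (Q fully preserved — this reproduces the reflection-geometry
worked case below) and otherwise as a pure depolariser with retardance 0°
or 180° by sign. Relatedly, 0° and 90° retarder axes share one 3×3 matrix,
so the reported axis lives in $[0°, 90°)$ and `axis_ambiguous` is always
`TRUE`; resolving it needs circular (4×4) measurements.

Depolarisation is reported as
$100\,(1 - (|\lambda_1| + |\lambda_2|)/2)$ over the eigenvalues of the
$M_\Delta$ block — absolute values tolerate the sign structure of
reflection-mode matrices.

**Reflection geometry.** Reflected light undergoes a helicity flip, so
measured retardance mixes physical and geometrical contributions; for fast
or slow axis vertical or horizontal, $\delta_{phys} = 180° -
\delta_{meas}$. The canonical worked case: an ideal 30° retarder double
pass (physical round trip 60°) with vertical axis yields
$\mathrm{diag}(1, 1, -0.5)$, which decomposes to $\delta_{meas} = 120°$ and
hence $\delta_{phys} = 60°$. `physical_retardance()` applies the rule for
any input but its documentation flags that oblique axes are outside its
derivation.

```{r worked}
m <- linear_submatrix(double_pass("retarder", 90, 30))
polar_decompose(m)
```

## Synthetic data: what it emulates, and what it does not

`make_synthetic_tissue()` composes depolariser ∘ retarder ∘ diattenuator in
4×4 (with a mirrored double pass in reflection mode, where `delta` is the
physical round-trip retardance) — the structure of fixed birefringent tissue
viewed by the probe. `build_probe()` defaults encode the modelled prototype
conditions: source DOP 0.15, and per-pair couplings with a ~±30% spread
(the reciprocals of a representative measured coefficient set, normalized
to mean 1). The noise model is multiplicative Gaussian with a chosen
coefficient of variation plus an additive dark floor, clamped at zero;
property tests use CVs of 0.1–5%, bracketing a well-behaved photodiode
measurement. `ideal_probe()` (exact cardinal angles, unpolarised source,
unit couplings) is the reference instrument for exactness tests.

What the generator does *not* emulate — so passing tests do not certify —
includes volumetric multiple scattering and the resulting sampling-volume
overlap (the footprint utility is a first-order surface estimate on a
hexagonal channel ring, pitch 1000 µm, chosen to match 500 µm polariser
squares separated by ~500 µm holder walls), inter-channel cross-talk
through a translucent holder, fibre-bend intensity drift between
calibration and measurement, and non-ideal micro-polariser leakage (which
enters only through user-supplied measured exit Stokes vectors). Real
tissue matrices also need not factor as diagonal-depolariser models; for
them the decomposition's fallback branch applies and accuracy is bounded by
the model mismatch, not by the solver.

## Problem sizes and determinism

The test suite runs at desk scale by choice: 100-sample reconstruction
round trips, 50 random coupling draws for calibration recovery, 40
decomposition recoveries, and 40-replicate noise Monte Carlo per noise
level — enough to exercise every code path with sub-minute wall time.
Every stochastic path takes an explicit seed (config, argument or CLI
flag) and is reproducible bit-for-bit; the CLI writes a manifest
(command, arguments, config hash, seed, versions) next to every output.
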