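---
title: "A bursting neural field model of anesthetic burst suppression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A bursting neural field model of anesthetic burst suppression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(burstfield)
```

## The model

`burstfield` simulates mean-field electrocortical activity on a
two-dimensional toroidal sheet of cortex discretized at macrocolumn scale
(1 mm spacing by default). Two interacting populations — excitatory and
inhibitory — are described by their mean soma membrane potentials
$h_e(\vec x,t)$ and $h_i(\vec x,t)$, with $h_e$ taken as the quantity
linearly related to the EEG/ECoG. Each population relaxes to its resting
potential with membrane time constant $\tau_k$ and is driven by four
classes of post-synaptic potential (PSP) inputs $I_{lk}$ ($l$ the
pre-synaptic source, $k$ the target), weighted by conductance-like reversal
factors
$$\psi_{lk}(h_k) = \frac{h^{eq}_{lk} - h_k}{|h^{eq}_{lk} - h^r_k|},$$
which are $+1$ for excitation and $-1$ for inhibition at rest and vanish at
the reversal potentials.

Firing rates are sigmoidal in the membrane potential,
$S_k(h) = S^{max}_k / \{1 + \exp[-\sqrt{2}\,(h-\mu_k)/\sigma_k]\}$,
with $\mu_k$ and $\sigma_k$ the mean and spread of the population firing
thresholds. In the deeply anesthetized regime the mean $h_e$ sits several
$\sigma_e$ below $\mu_e$, so near-symmetric $h_e$ oscillations translate
into sharply spiking population firing rates — the model's analogue of the
strong nonlinearity between local field potential and unit firing under
anesthesia.

**PSP kinetics.** Each PSP class is a critically-damped-oscillator
generalization: a bi-exponential response with independent rise time
$\delta_{lk}$ (the time to the peak amplitude $\Gamma_{lk}$) and decay time
$\zeta_{lk}$ (back to $\Gamma_{lk}/e$, measured from PSP onset). The two
rate constants are parameterized by a shape parameter $\varepsilon$:
$$\gamma = \frac{\varepsilon}{e^{\varepsilon}-1}\frac{1}{\delta},\qquad
  \tilde\gamma = e^{\varepsilon}\gamma,$$
so that the response always peaks exactly at $\delta$ with amplitude
$\Gamma$ while $\varepsilon$ stretches the decay only. At
$\varepsilon \to 0$ (a removable limit, handled by an explicit series
branch below $10^{-8}$) the classical alpha function is recovered. The
stepper integrates each class as two cascaded first-order equations
$\dot I = \tilde\gamma (J - I)$, $\dot J = \gamma(gA - J)$ with steady gain
$g = e^{\gamma\delta}\Gamma/\gamma$; tests verify that the discrete impulse
response converges to the closed-form kernel.

**Anesthetic action.** Isoflurane at aqueous concentration $c$ (mM) scales
PSP peak amplitudes by Hill factors,
$$H_e(c) = \frac{0.707^{2.22}}{0.707^{2.22}+c^{2.22}},\qquad
  H_i(c) = \frac{0.79^{2.6}+0.56\,c^{2.6}}{0.79^{2.6}+c^{2.6}},$$
and prolongs the inhibitory decay time by
$\kappa_i(c) = (0.32^{2.7}+4.7c^{2.7})/(0.32^{2.7}+c^{2.7})$, while rise
times and excitatory decay times are unchanged. The shape parameter
$\varepsilon(\kappa)$ is obtained by inverting the decay-time relation
$\zeta(\varepsilon)/\zeta_0 = \kappa$ numerically, where
$\zeta_0 = -W_{-1}(-e^{-2})\,\delta \approx 3.1462\,\delta$ is the
closed-form alpha-kernel decay time through the $-1$ branch of the Lambert
W function (argument domain-checked). The inversion is exact to solver
tolerance; a monotone spline in $\sqrt{\kappa-1}$ (the natural variable,
since $\varepsilon(\kappa)$ has a square-root branch point at
$\kappa = 1$) caches it for cheap vectorized evaluation along concentration
ramps. Concentrations may be given in mM, MAC or volume percent, anchored
linearly at 1 MAC = 0.243 mM = 1.17%.

**Propagation.** Long-range (exclusively excitatory) cortico-cortical
activity propagates by the damped wave equation
$$\Big[\Big(\frac{1}{v}\partial_t + \frac{1}{\lambda}\Big)^2 -
  \nabla^2\Big]\,\Phi_{ek} = \frac{1}{\lambda^2} C_e S_e(h_e),$$
with conduction velocity $v$ and exponential decay scale $\lambda$
(2.4 cm by default). Since the default parameter set has identical
$\lambda$ and $v$ for both target classes, the two fluxes satisfy the same
equation with the same source and are represented by one shared field; the
code splits them automatically if the parameters differ.

**Slow synaptic depletion and recovery.** The burst mechanism is a
rate-based synaptic resource model: peak amplitudes become dynamical,
$\Gamma_{lk}(\vec x,t) = \Gamma^0_{lk} C_l(\vec x,t)$, with the scaled
efficacies obeying
$$\tau^{rec}_l \partial_t C_l = 1 + f_l -
  \Big(1 + \frac{S_l(h_l)}{S_l(h^0_l)} f_l\Big) C_l .$$
$C_l = 1$ is the constructed operating point; without firing, amplitudes
recover to the resting values $\Gamma^r_{lk} = \Gamma^0_{lk}(1+f_l)$.
The reference rates $S^0_l$ are frozen at the zero-anesthesia equilibrium
when the initial state is built and are *not* recomputed as the
concentration changes — this is precisely what makes the initial state an
exact stationary point of the combined system (verified to machine
precision by the staticity test). Under anesthesia the efficacy enters the
synaptic input rates, $A_{ek} = N^\beta_{ek} C_e S_e + N^\alpha_{ek}
\Phi_{ek} + p_{ek}$ and $A_{ik} = N^\beta_{ik} C_i S_i$, with the flux
carrying $C_e$ through its wave source, while amplitudes are additionally
scaled by $H_l(c)$ in the PSP gain. Extracortical inputs are not depleted.

The bursting cycle: anesthesia depresses $h_e$, firing drops, the
reservoirs refill ($C_e$ rises well above 1), excitation strengthens until
the field destabilizes into a burst, the burst's firing spike depletes
$C_e$ within a few hundred milliseconds, and the suppressed field then
recovers over seconds — the recovery time constant sets the inter-burst
interval.

## Numerics

All ODE fields (membrane, PSP cascades, efficacies) advance by forward
Euler at $\Delta t = 0.05$ ms; the wave equation uses a three-level scheme
in which the second time derivative is estimated from the previous,
current and future values and the future value is solved for. The
Laplacian is the five-point stencil with periodic wrap in both dimensions.
Forward Euler is deliberately chosen for robustness over speed; a
step-halving test confirms first-order self-consistency, and a divergence
detector aborts on non-finite fields. The compiled stepper is
cross-checked field-by-field (to $10^{-12}$) against a plain R
implementation assembled from the package's exported right-hand-side
operations.

The homogeneous fixed point is found by damped Newton iteration on the
two-dimensional reduced system in $(h_e, h_i)$ (all other steady fields
are explicit functions of these), started from the resting potentials; a
coarse scan of $[-90,-40]$ mV$^2$ reports any other sign-change candidates
(none for the default set). Runs at fixed non-zero concentration start
from the zero-anesthesia equilibrium with the concentration switched on at
$t = 0$; the first seconds are discarded as a transient (default 5 s).

**Stochastic drive.** The ee extracortical rate is driven by Gaussian
noise with mean $p_{ee}$ and standard deviation 10% of the mean,
spatially low-passed by a radially symmetric Gaussian power transfer with
$-3$ dB at 2 cycles/cm (applied in the discrete Fourier domain,
renormalized deterministically to unit variance), and temporally low-passed
by Catmull-Rom spline interpolation over independent knot fields. The knot
interval is calibrated from the interpolation kernel's Fourier transform so
the power transfer is $-3$ dB at 75 Hz; each interpolation weight row is
normalized to unit sum of squares, so the interpolated field has exactly
the target variance at every instant. The filter *shapes* (Gaussian
spatial transfer, spline interpolation kernel) are this package's own
calibrated choices; only the $-3$ dB points and the 10% amplitude are
model constraints. The spec of the stream is verified by tests: measured
$-3$ dB point within 65–85 Hz, spectral flatness below the cutoff within
1 dB, spatial correlations below 0.05 beyond 5 mm, and per-point standard
deviation within 5% of target. The seed fully determines the stream, and
recordings are bit-reproducible for a fixed seed.

## Analysis chain

Grid PSDs use Welch's method (2.5 s Hann windows, 50% overlap,
per-segment mean removal — window shape and detrending are unstated in the
source literature and are this package's conventional choices), averaged
over all grid points, with an optional unit-area normalization. "Total
power" is the frequency integral of the raw averaged PSD excluding the
0 Hz bin, which makes plateaus with different mean $h_e$ comparable.

Burst peaks are detected on the effective ee amplitude
$\Gamma_{ee} = \Gamma^0_{ee} C_e H_e(c)$: maximal runs with
$\Gamma_{ee} \le 0.05$ (interpreted as an absolute threshold in mV —
about 27% of $\Gamma^0_{ee}$; a normalized mode thresholding $C_e H_e$
directly is available behind a switch) form burst-peak regions; the
deepest minimum of each region is the peak time; and intervals shorter
than 1.0 s are censored by iteratively dropping the shallower of any two
peaks closer than the censoring window, which removes "double-dipping" by
multiple firing spikes within one burst. The censoring estimator
(drop-shallower-until-clean) is one concrete reading of interval removal;
it is stated here and fixed by tests.

## Scaled study designs

The reference configuration in the source literature is a 512×512 grid
(2621.44 cm², roughly a human cortex) simulated for up to 120 s. The
package runs that configuration unchanged, but its test suite and the
bundled acceptance script use smaller designs chosen once as this
package's desk-scale study conditions:

- *Induction protocol* (plateaus at 0, 0.5, 1.0, 1.5 MAC with 10 s linear
  ramps; the ramp to 1.0 MAC is not stated in the source and is taken as
  10 s for symmetry): 64×64 grid for the acceptance script (three seeds),
  48×48 with a 22 s burst-suppression plateau for the test suite. At
  these sizes the bi-phasic power surge and the burst-phase power blow-up
  are preserved; absolute power ratios carry desk-scale spread, which is
  why the acceptance checks quote them with stochastic tolerances.
- *Patch experiment*: the patch keeps its full-scale geometry — radius
  9.6 cm = 4λ at the standard λ = 2.4 cm, so outside influence at the
  center stays below $e^{-4} \approx 2\%$ — while the torus shrinks from
  51.2 cm to 25.6 cm (256×256). Shrinking λ instead is *not* an option:
  pilots showed the deep burst-suppression cycle (efficacies recovering
  well above 1 between bursts) degrades into shallow continuous
  fluctuations for λ below roughly 2 cm, independent of the domain-to-λ
  ratio, and in that regime the constantly battered patch is entrained by
  spill-in. With the standard λ the patch occupies 28% of the reduced
  domain (11% at full scale); the outside still bursts coherently and the
  center stays silent. The test-scale runs use 2 mm grid spacing (128×128
  for the same 25.6 cm torus) — coarser spacing for rapid exploration is
  standard practice for this model, λ = 24 mm is still resolved by a
  factor 12, the noise's 5 mm spatial cutoff remains below the 4 mm
  Nyquist wavelength, and a 256×256 pilot at 1 mm gave the same probe
  phenomenology (center 0.011 vs 0.011 mV fluctuation, rim 0.061 vs
  0.065 mV).
- *Connectivity sweep*: λ ∈ {2.7, 2.4, 2.1} cm with shared noise seeds on
  a 96×96 grid, 16 s runs — λ values inside the regime of deep burst
  cycles. The mean inter-burst interval orders cleanly by λ at this scale
  (and lands close to the full-scale values); the *spread* of the
  intervals does not: on a 9.6 cm torus the bursting is near-globally
  synchronized within the affordable run length, so the IBI standard
  deviation is a few hundredths of a second for the two larger λ and the
  full-scale growth of the spread with shrinking λ (which reflects
  asynchronous spatial patterns on a much larger domain over ~50 s) is
  below measurement resolution — the corresponding check is expected to
  fail at desk scale and documents exactly this.

What these scaled designs do **not** show: quantitative agreement of
spatial statistics with the full-scale run (mean inter-burst intervals
shorten as the domain shrinks), full-scale pattern geometry, or anything
about real cortical geometry and heterogeneity — the torus with
homogeneous isotropic connectivity is an anatomical null model.

## Parameters that matter

- `f_e`, `f_i` (1.25, 0.175): synaptic depletion factors; the resting
  amplitude excess over the operating point. Raising `f_i` (e.g. to 1.25
  in a patch) boosts inhibitory reserve enough to abolish local bursting;
  0.5 is not sufficient.
- `tau_rec_e`, `tau_rec_i` (800, 600 ms): recovery times; set the
  inter-burst timescale.
- `lambda` (24 mm): propagation decay scale; sets burst-pattern size and
  spacing of the IBI statistics.
- Burst threshold 0.05 mV and censoring window 1.0 s: detection
  conventions, exposed as arguments.
- `sigmoid_scale` (√2): the firing-rate exponent convention. The flattened
  source text can be read as plain 2; the parameter lineage uses √2, which
  is the default, with the alternative available for comparison.

## Known limitations

- Desk-scale runs shorten inter-burst intervals relative to the 512×512
  reference (domain comparable to a few λ), so only orderings and windowed
  ranges of IBI statistics are asserted at test scale.
- The propagation-side depletion bookkeeping (modulating conduction-delayed
  inputs by local rather than source-site efficacies) is documented but not
  implemented, matching the source model's choice.
- No pharmacokinetics: the concentration protocol is imposed directly.
- MPI-style domain decomposition is out of scope; the stepper is
  single-process (compiled, single-sweep per step).
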