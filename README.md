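# burstfield

Simulation of spatially heterogeneous **burst suppression** — the
quasi-periodic alternation of high-amplitude EEG bursts and near-isoelectric
suppression seen in deep anesthesia — with a two-dimensional neural field
model of cortex. The package is for computational neuroscientists studying
anesthetic action, burst suppression and spatiotemporal cortical dynamics at
the whole-cortex (EEG/ECoG) scale.

## The model

On a toroidal sheet discretized at 1 mm, mean soma potentials of excitatory
and inhibitory populations evolve as conductance-weighted leaky integrators

$$\tau_k \partial_t h_k = h^r_k - h_k + \sum_{l=e,i}
\frac{h^{eq}_{lk}-h_k}{|h^{eq}_{lk}-h^r_k|}\, I_{lk},$$

driven by bi-exponential PSPs $I_{lk}$ with independent rise and decay
times, sigmoidal firing rates $S_k(h_k)$, damped-wave cortico-cortical
propagation $[(v^{-1}\partial_t + \lambda^{-1})^2 - \nabla^2]\Phi_{ek} =
\lambda^{-2} C_e S_e$, and spatiotemporally filtered stochastic thalamic
drive. Isoflurane concentration $c$ enters through Hill equations that
shrink PSP amplitudes ($H_e$, $H_i$) and prolong the inhibitory decay
($\kappa_i$, translated to a bi-exponential shape parameter via the
Lambert-W closed form of the alpha-kernel decay time). Burst suppression
emerges from a slow synaptic resource system: peak amplitudes
$\Gamma_{lk} = \Gamma^0_{lk} C_l$ deplete with population firing and recover
(time constants $\tau^{rec}_l$) toward resting values
$\Gamma^r_{lk} = \Gamma^0_{lk}(1+f_l)$,

$$\tau^{rec}_l \partial_t C_l = 1 + f_l - \Big(1 +
\tfrac{S_l(h_l)}{S_l(h^0_l)} f_l\Big) C_l .$$

The shipped parameter set is the published "bi-phasic" mean-population set;
see the methods vignette (`vignettes/bursting-field-model.Rmd`) for the full
account of model, numerics and design choices.

## Worked example

A desk-scale run at 1 MAC isoflurane (0.243 mM), started from the
zero-anesthesia equilibrium on a 64×64 grid:

```r
library(burstfield)
p   <- default_parameters()
g   <- grid_spec(64)                      # 6.4 cm torus, dx = 1 mm
rec <- run_simulation(p, g, constant_protocol(0.243, 40, discard = 5),
                      record = record_spec(c("h_e", "C_e"), 0, 40),
                      seed = 3)
st  <- ibi_statistics(rec, window = c(5, 40))
st$points_bursting   # 1      — every grid point bursts
st$mean              # 3.13   — mean inter-burst interval (s)
mean_he <- mean(rec$fields$h_e[, rec$times$h_e >= 20])
(p$mu["e"] - mean_he) / p$sigma["e"]   # 5.48 — h_e sits ~5.5 sigma below
                                       # the mean firing threshold
```

The numbers shown are what this code printed (seed 3): under deep
anesthesia every point shows quasi-periodic bursts roughly 3 s apart at
this domain size, and the mean excitatory potential lies about 5.5
threshold spreads below the mean firing threshold — which is why nearly
symmetric $h_e$ oscillations appear as sharp spikes in firing rate and
sudden drops of the synaptic efficacy $C_e$.

Higher-level drivers reproduce the study designs: `run_figure2()` (staged
induction 0 → 2.5 MAC with plateau PSDs, power ratios and burst
statistics), `run_patch_experiment()` (a circular patch of raised
inhibitory depletion factor that refuses to burst), and
`run_lambda_sweep()` (inter-burst statistics vs. connectivity scale).
`Rscript inst/cli/burstfield.R --help` exposes the same drivers from the
shell.

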