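# spinecap

Calcium-based synaptic plasticity under in-vivo-like cortical input, at desk
scale. `spinecap` simulates how spatiotemporal patterns of correlated,
trial-to-trial-variable excitatory spike trains drive dendritic spine calcium
and thereby long-term potentiation (LTP) and depression (LTD) in a reduced
striatal spiny projection neuron (SPN), and provides the statistical
machinery to relate input patterns to the resulting weight changes.

It is aimed at computational neuroscientists studying corticostriatal
plasticity, synaptic clustering, and the robustness of learning rules to the
spike-timing variability observed in vivo.

## What the package contains

**Synthetic in-vivo-like inputs.** An ensemble of ~tens to hundreds of
excitatory spike trains per 1 s trial, generated as inhomogeneous Poisson
processes with log-normally distributed per-train base rates, one shared
multiplicative latent rate profile (the source of within-trial correlations
between trains), and a late-trial rate ramp resembling motor preparatory
activity. Three trial-to-trial variability surrogates operate on the initial
trial: truncated-normal spike-time jitter (inverse-CDF sampling, per-train
spike counts preserved exactly), spike moving between trains (targets drawn
proportionally to target-train spike counts, aggregate timing preserved),
and interspike-interval (ISI) shuffling. Inhibitory inputs are homogeneous
Poisson trains at 12 Hz (fast-spiking interneurons, proximal) and 8 Hz
(low-threshold-spiking interneurons, distal), active for the whole
experiment.

**A reduced SPN.** Passive multicompartment dendrites (RM 6.02 Ω·m², CM
0.011 F/m², RA 1.3 Ω·m) with explicit spines (0.1/µm distributed, or
0.75+/µm for clustered experiments; head 0.5×0.5 µm, neck 0.12×0.5 µm), a
minimal two-conductance spiking soma, dual-exponential AMPA/NMDA/GABA-A
synapses with voltage-dependent NMDA magnesium block, and one lumped
high-voltage-activated calcium conductance. Integration is a fixed-step
semi-implicit update solved with the Hines tree algorithm (compiled code).

**Mechanistic calcium dynamics.** Spine head/neck axial slabs coupled to
concentric dendritic shells; calbindin, calmodulin N- and C-lobes, and an
immobile buffer with mass-action kinetics; PMCA and (spines only) NCX pumps
with Michaelis–Menten kinetics; 1-D diffusion of free calcium and mobile
buffers. With pumps and influx off, total calcium is conserved to machine
precision.

**The plasticity rule.** The dual amplitude/duration calcium-threshold rule:
spine calcium above the LTD amplitude threshold T_AD = 0.33 µM for longer
than 28 ms drives depression; above the LTP threshold T_AP = 0.53 µM for
longer than 3.3 ms drives potentiation. While a branch is engaged the weight
moves each step by a capped, calcium-proportional gain with soft bounds,

    Δw = min(γ_Pmax, γ_P ([Ca]_sp − T_AP)) · (1 − (w − w_min)/(w_max − w_min))   (LTP)
    Δw = −min(γ_Dmax, γ_D ([Ca]_sp − T_AD)) · (w − w_min)/(w_max − w_min)        (LTD)

so w stays in [0, 2] and asymptotes at the bounds.

**Analyses.** Gaussian-kernel instantaneous firing rates; the weight-change
triggered average (WCTA: per-trial weight changes binned, accompanying rate
or calcium series averaged per bin); combined nearest-neighbor rates
(neighbors by dendritic path distance); 1–5 mean time-sample features;
random-forest regression of weight change with normalized feature
importances (via `ranger`); ANOVA and Welch t-tests across feature sets;
pre/post spike-interval features of instantaneous weight-change events;
correlation statistics.

## Worked example

```r
library(spinecap)

cfg <- experiment_config("variability_sweep", seed = 1,
                         trains = list(n_trains = 50),
                         variability = list(kind = "jitter",
                                            sigmas = c(0, 0.01, 0.1)))
res <- run_experiment(cfg)

tab <- res$dw_table
base <- tab[tab$level == 0, ]
high <- tab[tab$level == 0.1, ]
changed <- abs(base$dw_total) > 0.1
mean(sign(base$dw_total[changed]) == sign(high$dw_total[changed]))
#> [1] 0.875
res$cor_depressing$r
#> [1] 0.3500163
res$cor_depressing$p
#> [1] 0.04584361
```

Each run simulates ten repeated 1 s trials (1 s intertrial intervals, 21 s
total) of the same 50-train input at a given jitter SD, applies the
plasticity rule to every spine's calcium trace, and tabulates cumulative
weight changes. The numbers above say: 87.5% of synapses whose weight
changed by more than 0.1 without jitter kept their plasticity direction
under 100 ms jitter, and the ending weight of depressing synapses increases
significantly with variability (r = 0.35, p = 0.046) — depression shrinks
with jitter while potentiation is unaffected.

For the clustered-input analyses:

```r
cfg2 <- experiment_config("cluster_sweep", seed = 1)
res2 <- run_experiment(cfg2)           # 25 single-trial simulations
fits <- fit_weight_change_regressions(res2$feature_table, cfg2)
round(sapply(fits$results, function(r) r$mean_r2), 3)
#>       ca_1       ca_3       ca_5     rate_1     rate_3     rate_5
#>      0.993      0.996      0.998      0.364      0.375      0.373
#> rate_1_clust rate_3_clust rate_1_spc rate_1_dist  rate_1_nb
#>      0.557      0.487      0.450      0.580      0.386
```

Calcium time samples predict the weight change almost perfectly (they are
the rule's input), direct firing rate alone is a much weaker predictor, and
adding cluster length to the rate features improves the prediction.

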