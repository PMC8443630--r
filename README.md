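# leadsync

Detecting and characterizing **leadership emergence in group
synchronization** from multivariate movement recordings.

When several people perform a joint oscillatory task (swinging pendula,
oscillating a finger over a motion sensor) and try to move in synchrony,
leaders emerge in two distinct senses: a player can lead *in phase* (their
movement cycle runs ahead of the others') and *in influence* (their motion
fluctuations propagate to the group while the reverse flow is weak).
`leadsync` computes both roles per trial and classifies their combination
into the recurring leadership patterns:

* **P1** — the phase leader is the most influential ("the fastest leads"),
* **P2** — the phase laggard is the most influential ("the slowest leads"),
* **P3** — the two phase extremes share influence (shared leadership),
* **NONE** — no consistent pattern.

## What it computes

Given per-player position time series `x_i(t_k)` for one trial:

1. **Phase extraction** — experiment-specific conditioning (moving average
   for 20 Hz pendulum-style data; spline upsampling to 100 Hz plus a 6 Hz
   zero-phase Butterworth low-pass for 10 Hz networked data), then the
   analytic-signal (Hilbert) phase, unwrapped and end-trimmed.
2. **Phase leadership index** — `H_i(t_k) = |{j ≠ i : θ_i − θ_j ≤ 0}| + 1`,
   so `H = 1` marks the instantaneous phase leader and `H = N` the laggard;
   its time average `H̄_i` summarizes the trial.
3. **Directed influence** — causation entropy
   `w_ij = C_{i→j | (j, P∖{i,j})}`, the information flowing from player i to
   player j beyond what j's own past and all other players already convey
   (Gaussian or k-NN estimators; optional oCSE parent discovery with
   surrogate significance testing). The net score
   `NetCaus_i = Σ_j w_ij − Σ_j w_ji` sums to zero across players; its
   maximizer is the influence leader.
4. **Pattern classification** — from the extremes of `H̄` and the top two
   `NetCaus` scores.
5. **Coordination** — the Kuramoto order parameter
   `z = |mean(exp(iθ))|` and its trial mean `z̄`, plus the pooled
   statistics (χ² against the `2/N` chance level, pooled t-test with
   Cohen's d, one-way ANOVA with η², per-pattern linear/parabolic fits).

A seeded coupled-oscillator generator
(`oscillator_config` / `plant_pattern` / `simulate_trial`) plants each
pattern via "stubborn" agents (attenuated incoming coupling) on the four
visual-coupling topologies (complete, path, ring, star) and provides ground
truth for every stage.

## A worked example

```r
library(leadsync)

cfg   <- oscillator_config(seed = 7)             # 7 players, 30 s at 20 Hz
trial <- simulate_trial(plant_pattern("P1", cfg))  # fastest player is stubborn
fit   <- leadership(trial)
summary(fit)
```

```
Per-player leadership indices:
 player h_bar  netcaus delta_out delta_in
      1 1.187  0.12720   0.13816  0.01096
      2 4.183  0.01291   0.03042  0.01750
      3 5.043 -0.03096   0.02689  0.05785
      4 5.298 -0.04573   0.03009  0.07582
      5 4.656 -0.01713   0.02084  0.03797
      6 3.020 -0.01916   0.01850  0.03766
      7 4.614 -0.02713   0.01984  0.04696

Pattern: P1 (phase leader 1, laggard 4)
Group coordination z_bar = 0.9943
Planted ground truth: P1 (leaders: 1)
```

Player 1 — the planted stubborn agent with the highest natural frequency —
has the lowest mean leadership index (`h_bar = 1.19`: nearly always first
in phase) and by far the largest net information outflow
(`netcaus = 0.127` nats: it sends `delta_out = 0.138` and receives almost
nothing). The trial is therefore classified P1, matching the planted ground
truth, and the group is tightly coordinated (`z_bar = 0.994`).

Batches pool into a report:

```r
trials <- simulate_batch("P1", n_trials = 12, root_seed = 42)
report <- leadership_report(trials)
report            # pattern counts, χ² vs the 2/N chance level, z̄ t-test
write_report(report, "report.json")
```

Trials round-trip through a wide CSV (`t, p1..pN`) plus a JSON sidecar via
`write_trial` / `read_trial`, so external recordings in that format can be
analysed with the same pipeline.

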