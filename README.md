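# zebrapref

A seedable, desk-scale simulator and analysis pipeline for **closed-loop
social-preference experiments in zebrafish**. In the physical paradigm this
package re-creates, an animated conspecific is displayed on a monitor at
each end of a 45 × 15 cm aquarium; its on-screen motion is recomputed 30
times per second from the tracked 3D position of the experimental fish
(chasing it, fleeing from it, mirroring it, jittering in place, or replaying
a recording); and preference is scored as the relative time spent in the
compartment near each stimulus. zebrapref implements the whole loop in
software — virtual stimulus controllers, an agent-based fish, a synthetic
overhead color+depth camera with a detector-gated tracker, the full
within-subject session schedules, and the complete statistics chain — so the
experimental contingencies and the preference index can be property-tested
and used for parameter-recovery studies without live animals.

It is intended for behavioral scientists and methods developers who want to
probe what this widely used closed-loop assay can and cannot measure: how
the preference index behaves under a known generative bias, how the
inferential chain is calibrated, and how tracking imperfection propagates
into stimulus control.

## The measurement model

For each 5-min period of a session, the time the fish's head spends in the
left/center/right compartments is accumulated at 1/30 s per frame. Within a
condition (8 sessions, each stimulus on the left for 4 and the right for 4),
times are pooled **before** the ratio:

```
preference = log10( Σ_sessions T_A / Σ_sessions T_B )
```

and per-condition arithmetic means of these log ratios are back-transformed
(`10^mean`, the geometric-mean fold preference) for interpretation. A mean
log ratio of 0.15 is a 1.41-fold preference; 0.39 is 2.45-fold.

Inference follows the published chain: AICc-selected random-effects
structure (`AICc = −2ℓ + 2k + 2k(k+1)/(n−k−1)`), a linear mixed model of
`log_ratio ~ Period × Condition` with treatment contrasts at Period 2 and
the blank-monitor control, likelihood-ratio tests of the fixed effects,
estimated marginal means, and Holm–Bonferroni-adjusted post hoc families.

The stimulus controllers implement the published rules exactly: pursuit with
a 16-px deadband and speed `distance/650` px/ms updated every 0.033 s;
fleeing triggered within 350 px horizontally and 150 px vertically;
0–2 px idle jitter about the monitor center; left/right-mirrored pursuit;
and fixed-order playback.

## Worked example

Simulate one 20-min closed-loop session — chasing stimulus on the left
monitor, motionless on the right — and score it:

```r
library(zebrapref)
log <- simulate_session("chasing", "motionless", seed = 1)
summary(log)
#> time in compartments (s) per period:
#>  period   left_s  center_s  right_s
#>       1  99.7000 108.73333 91.56667
#>       2 212.0333  72.26667 15.70000
#>       3  91.7000 125.53333 82.76667
```

Periods 1 and 3 (blank monitors) split roughly evenly; in Period 2 the fish
spends 212 s near the chasing stimulus against 16 s near the motionless one
— the stimulus-contingent bias the assay is built to detect. The
blank-monitor control stays null through the full scheduler:

```r
plan <- build_experiment1_plan(seed = 20230628)
plan$sessions <- subset(plan$sessions, condition == "Absent-vs-Absent")
rec <- preference_table(run_experiment(plan))   # 8 fish x 8 sessions
mean_log_ratio(rec)
#>          condition period mean_log_ratio          se n
#> 1 Absent-vs-Absent      1   -0.008584385 0.016054350 8
#> 2 Absent-vs-Absent      2   -0.037803130 0.008103706 8
#> 3 Absent-vs-Absent      3    0.012483510 0.023529650 8
```

A full replicate — schedule, 256 simulated sessions, preference records,
and the mixed-model chain — is one call (or one CLI invocation,
`inst/cli/zebrapref replicate --experiment 1 --out DIR`):

```r
rep1 <- replicate_experiment(1, seed = 20230628)
rep1$scale          # Period-2 fold preferences per condition
rep1$analysis       # selection table, REML fit, LRTs, emmeans, post hocs
```

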