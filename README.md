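# dyadtempo

Temporal microstructure of dyadic agonistic behavior: how pairs of
animals (the motivating case is male laboratory mice meeting daily in
20-minute sessions) go from symmetric contests to stable
dominant–subordinate roles, analysed from coded behavioral event logs.

For behavioral neuroscientists and computational ethologists who have
bout-level codings — one row per behavior bout with dyad, day, subject,
behavior label, onset and offset in seconds — and want the temporal
structure, not just totals.

## What it computes

1. **Burst detection.** Aggressive + subordinate onsets of both
   partners, pooled per dyad-day, are segmented with Kleinberg's burst
   automaton (gap costs −ln α_i + α_i x with α_i = (n/T)·s^i, climb
   cost γ(j−i)ln n; defaults γ = 0.3, s = 2). Second-order bursts
   (state ≥ 2) are the analysis unit.
2. **Relationship resolution.** Each burst yields a 2×2 matrix
   (a, b = aggressive, subordinate counts by the eventual dominant;
   c, d = by the subordinate). Two criteria locate the resolving burst:
   the stringent phi-coefficient method
   (φ = (ad−bc)/√((a+b)(c+d)(a+c)(b+d)), X² = Nφ², resolved at the
   first burst from which all evaluable bursts keep φ > 0, p < 0.1)
   and the lenient difference method ((a−c) ≥ (b−d) from some burst
   onward). Together they split each dyad's timeline into
   pre-resolution, middle, and post-resolution phases, with paired
   Wilcoxon comparisons of phase-time budgets between roles.
3. **First-order Markov transitions** within each subject and phase:
   no-repeat sequences, quasi-independence expected counts by iterative
   proportional fitting over the structural-zero diagonal, G² tests
   with adjusted df, and per-transition permutation p-values from
   no-adjacent-repeat rearrangements; group medians with significance
   (median p ≤ 0.01) and meaningfulness (median probability ≥ 0.075)
   flags, exported as kinetograms (GraphML/DOT).
4. **Forward Spike Time Tiling Coefficient** between partners:
   FSTTC(A→B) = ½·((P−T_B)/(1−P·T_B) + (P−T_A)/(1−P·T_A)), with P the
   proportion of B onsets within Δt = 2 s after an A onset and T_A,
   T_B the forward-tile time coverages — a frequency-corrected,
   directional contingency per phase, with paired direction tests.
5. **A synthetic dyad generator** with planted ground truth (bursts,
   resolution burst, role fidelity, transition structure, forward
   contingency θ), so every stage has an end-to-end recovery test
   without any external data.

## Worked example

```r
library(dyadtempo)
cfg <- synthetic_config(n_dyads = 3, n_days = 3,
                        bursts_per_day = c(4, 2, 1), resolution_burst = 4)
cohort <- simulate_cohort(cfg, seed = 9)
res <- run_pipeline(cohort$log, out_dir = NULL, n_perm = 200, seed = 9,
                    fsttc_groups = list(
                      lunge_bite = c("lunge", "bite"),
                      subordinate = c("flee", "freeze", "subordinate_posture")))
res$resolution
#>   dyad_id     method resolved resolution_burst_index resolution_day
#> 1     D01        phi     TRUE                      4              1
#> 2     D01 difference     TRUE                      1              1
#> 3     D02        phi     TRUE                      4              1
#> 4     D02 difference     TRUE                      3              1
#> 5     D03        phi     TRUE                      4              1
#> 6     D03 difference     TRUE                      4              1
#>   cumulative_interaction_s first_burst_phi
#> 1                      967          0.0849
#> 2                      339          0.0849
#> ...
```

All three dyads resolve by the stringent criterion exactly at the
planted fourth burst; the lenient criterion resolves at or before it
(burst 1 for D01 — chance role-consistency in early symmetric bursts,
which is why that criterion is the phase *lower* bound). First-burst
phi-coefficients sit near 0: relationships are not resolved at the
first contest. The directional contingency shows the planted
asymmetry:

```r
ft <- res$fsttc_tests
ft[ft$phase == "post" & ft$given_group == "lunge_bite" &
     ft$target_group == "subordinate", ]
#>   given_group target_group phase n_pairs median_dom_sub median_sub_dom V    p
#>    lunge_bite  subordinate  post       3          0.212        -0.0019 6 0.25
```

Post-resolution, subordinate behavior follows the dominant's
lunge/bite within 2 s far above chance (median FSTTC 0.21) while the
reverse direction sits at chance; with only 3 dyads the paired
Wilcoxon p bottoms out at 0.25 (at the study scale of 21 dyads the
same asymmetry is decisive). The uniform filler kernel used here
plants no transition structure, so no Markov transition is flagged —
the expected null outcome.

## Command line

```sh
CLI=$(Rscript -e 'cat(system.file("cli/dyadtempo.R", package = "dyadtempo"))')
Rscript $CLI simulate --n-dyads 21 --n-days 5 --seed 42 \
    --out events.csv --truth truth.json
Rscript $CLI bursts --input events.csv --gamma 0.3 --s 2 --level 2 \
    --out bursts.csv
Rscript $CLI run --input events.csv --out-dir results --seed 1
```

`run` writes bursts.csv, roles.csv, resolution.csv, phases.csv,
phase_stats.csv, fsttc.csv, fsttc_tests.csv, flags.csv, markov/
(per-individual and group tables, kinetograms) and a manifest.json
echoing the configuration and seed; re-running with the same manifest
seed reproduces the outputs byte for byte.
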