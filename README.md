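# tonguekin

Objective quantification of tongue motor function from short videos of a
lateral tongue-movement task, for researchers studying bulbar involvement
in motor-neuron disease (and anyone who needs a tested, self-contained
video-kinematics pipeline).

A participant protrudes the tongue and moves it side to side as fast as
possible for five seconds in front of a phone camera (30 frames/s). The
package then:

1. **segments** the tongue in every frame with a U-Net++ (nested dense
   skip pathways; combined binary cross-entropy + soft-Dice loss;
   participant-grouped cross-validation with Dice/IoU reporting) — the
   convolutional machinery is implemented natively on BLAS, with exact
   backpropagation verified against finite differences;
2. **tracks** the tongue tip, operationally the most lateral point of
   the binary mask, into a millimetre displacement series d(t);
3. **extracts kinematic features** over a T = 5 s window:

   - frequency `f = N_cycles / T` (complete left–right–left cycles only,
     hysteresis detector),
   - maximum amplitude `A = max |d(t)|` (mm),
   - **normalized frequency `f / A` (Hz/mm)** — the primary biomarker;

4. **validates at cohort level**: gated Student-t / Mann–Whitney group
   comparisons, multiple regression of the ordinal speech score on age,
   normalized frequency and clinical signs (VIF, Student-t CIs),
   Harrell bootstrap optimism correction of R², and a proportional-odds
   ordinal sensitivity fit.

Because the motivating study's recordings are private, the package ships
a first-class synthetic-data module: rendered task clips with per-frame
ground-truth masks and known frequency/amplitude, heterogeneous
segmentation training sets with participant keys, and clinical cohorts
calibrated to the published group means (0.138 vs 0.395 Hz/mm), sign
prevalences, and regression coefficients.

## Worked example

```r
library(tonguekin)

# render a 5-s synthetic task clip: 2 Hz oscillation, 10 mm excursion
clip <- render_clip(clip_spec(freq_true = 2, amp_true = 10, seed = 3),
                    return_frames = FALSE)

# track the tip on the ground-truth masks and score the task
traj <- extract_tip_series(clip$truth$masks, fps = 30, mm_per_px = 0.25)
compute_features(traj)
#> kinematic features: 10.0 cycles / 5 s -> 2.00 Hz; A_max 22.02 mm; normalized 0.091 Hz/mm
```

Ten complete cycles in five seconds recovers the true 2 Hz exactly. The
measured amplitude (22.02 mm) is the excursion of the most lateral mask
point — the 10 mm centre motion plus the tongue's own lateral extent —
which is precisely what a mask-based tracker measures; the normalized
frequency divides the cycle rate by that amplitude.

A cohort-level run:

```r
res <- run_pipeline(run_config(out_dir = "demo", seed = 7,
                               n_per_group = 5, trials = 2))
res$stats$group_means
#> $ALS
#> [1] 0.08392316
#> $control
#> [1] 0.1607856
```

The simulated patient group moves markedly slower per millimetre of
excursion than the control group, as expected from the presets. A
command-line front end with subcommands (`synth-clip`, `synth-dataset`,
`synth-cohort`, `train`, `segment`, `features`, `stats`, `e2e`) is
installed under `inst/cli/tonguekin.R`.

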