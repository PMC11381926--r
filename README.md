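# usprf

Analysis of **pulse-repetition-frequency (PRF) tuning in transcranial
ultrasound neuromodulation**, from single-cell calcium imaging.

Low-intensity transcranial ultrasound pulsed at physiologic PRFs (10, 40,
140 Hz) can activate individual cortical neurons, and different neurons prefer
different PRFs. Establishing that from GCaMP7f imaging requires a chain of
statistics: detecting spike-related calcium events in noisy dF/F traces,
testing each neuron's stimulation-window event density against a shuffled
baseline, excluding neurons already active just before stimulation,
classifying responders as PRF-specific or not, measuring pairwise network
synchrony with the asymmetric correlation coefficient (ACC), characterizing
evoked response shapes, and comparing single-cell expression of
mechanosensitive channels between neuron populations. `usprf` implements that
whole chain as composable, tested R functions, together with a ground-truthed
synthetic-data generator used to validate every step by parameter recovery.

The core inference: a neuron is **modulated** by a PRF when its mean event
density in the 1 s stimulation windows exceeds the 95th percentile of a null
distribution built from 1000 resamples of *n* one-second baseline windows
(*n* = trials per condition; baseline = whole recording minus the 5 s after
every onset), unless its density in the 1 s *before* onset already exceeds
that percentile. Network synchrony between binarized event trains *A*, *B*:

    ACC(A, B) = 1/2 * ( |A∩B| / |A|  +  |A∩B| / |B| )

Effect sizes between expression distributions use Cliff's delta,
δ = [#(x>y) − #(x<y)]/(nm), with |δ| < 0.147 negligible, < 0.330 small,
< 0.474 medium, else large.

## Worked example

Simulate an alternating-PRF session (25 blocks x three 21 s trials at 10, 40,
140 Hz; 30 neurons, 15% preferring each PRF, evoked probability 0.5), run the
full pipeline, and compare with the planted ground truth:

```r
library(usprf)

cfg <- session_config("alternating", n_neurons = 30, seed = 42)
ses <- simulate_session(cfg)
ses
#> <us_session> alternating: 30 neurons, 75 trials (PRFs 10/140/40 Hz), 1612.0 s at 20 Hz

res <- analyze_session(ses, seed = 42)   # detect -> shuffle test -> classify
dplyr::count(res$responders, class)
#> # A tibble: 3 × 2
#>   class             n
#>   <chr>         <int>
#> 1 non_responder    11
#> 2 non_specific      1
#> 3 specific         18

proportion_report(res$modulation, prf_hz)
#> # A tibble: 3 × 4
#>   prf_hz n_modulated n_total percent
#>    <dbl>       <int>   <int>   <dbl>
#> 1     10           6      30    20
#> 2     40           7      30    23.3
#> 3    140           7      30    23.3
```

Of the 16 neurons generated with a preferred PRF, 15 are recovered as
"specific" responders (modulated by exactly one PRF); the ~20% modulated per
PRF reflects the planted 15% preferring fraction plus the test's nominal 5%
false-positive rate. Acoustic intensity utilities and the expression effect
size work the same way:

```r
isppa(522e3)                 # 522 kPa peak pressure in water
#> [1] 9.0828                 # W/cm^2
ispta(isppa(522e3), 0.2)     # 20% duty cycle
#> [1] 1.81656

cliffs_delta(c(3.1, 4.0, 5.2), c(2.9, 3.0, 3.3))
#> # A tibble: 1 × 4
#>   delta magnitude   n_x   n_y
#>   <dbl> <fct>     <int> <int>
#> 1 0.778 large         3     3
```

Each stage is also available separately — `detect_events()`,
`shuffle_baseline()`, `classify_modulation()`, `sustained_acc()`,
`transient_acc()`, `response_profile()`, `glm_compare()`,
`expression_summary()` — and ggplot helpers (`plot_session_traces()`,
`plot_shuffle()`, `plot_transient_acc()`, `plot_expression_density()`)
visualize the intermediate objects. The methods vignette
(`vignettes/usprf-methods.Rmd`) documents the models, parameter defaults and
numerical choices.

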