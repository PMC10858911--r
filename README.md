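# fireflash

Automated analysis of firefly bioluminescent flash patterns. Nocturnal
fireflies advertise their species with precisely timed light pulses;
monitoring the thousands of threatened populations requires replacing
expert stopwatch measurements with automated classification from cheap
stereoscopic video. `fireflash` implements that pipeline for ecologists and
conservation researchers working from 3D flash localizations recorded at
30 frames per second:

1. **Trajectorization** — flash detections at consecutive frames within a
   small radius are concatenated into *streaks*; streaks occurring within
   both 1 s and 1 m of each other are transitively connected into
   *trajectories*, each attributed to one firefly.
2. **Binarization and cleaning** — each trajectory becomes a 0/1 time
   series at 30 bits per second (1 = light), spanning its first to last
   flash. Interflash gaps of 1–2 bits (< 0.07 s) are tracking artifacts and
   are filled; single-flash trajectories and species with fewer than 100
   trajectories are thresholded away.
3. **Classification** — a 2-layer gated recurrent unit (GRU) network with
   128-dimensional hidden states reads one bit per timestep and predicts
   the species, alongside four reference-based baselines: Jaccard index,
   dot product, dynamic time warping (DTW), and an RBF-kernel SVM on the
   3-vector (flash count, mean flash duration, mean inter-flash gap).
4. **Evaluation** — 60-fold stratified cross-validation with undersampling
   to equal class counts, weighted precision/recall, row-normalized
   confusion matrices, one-vs-rest ROC curves, and artificial-sympatry
   experiments mixing two species at proportions from 0.5 % (2 of 400
   sequences) to 50 % (200/200).
5. **Characterization** — the 100 most confidently *correct*
   classifications per population feed normalized distributions and
   mean ± sd of the three flash statistics, a data-driven replacement for
   single pictorial reference patterns.

A fully seeded synthetic generator (`species_params()`, `preset_table2()`,
`generate_population()`, `generate_swarm_events()`) emulates the twelve
field-characterized populations, so every stage is testable without the
field recordings.

## The model

The recurrent core updates a hidden state from the binary input
`x^(t) ∈ {0,1}`:

    h^(t) = f(W_hh h^(t-1) + W_xh x^(t) + b)

with gated recurrent units supplying the nonlinearity `f`: a reset gate
`r = σ(W_ir x + b_ir + W_hr h + b_hr)`, an update gate
`z = σ(W_iz x + b_iz + W_hz h + b_hz)`, and candidate state
`n = tanh(W_in x + b_in + r ⊙ (W_hn h + b_hn))`, giving
`h' = (1 − z) ⊙ n + z ⊙ h`. The final hidden state passes through a
LeakyReLU (negative slope 0.1) and an affine readout to species logits;
softmax probabilities are trained with Adam on the cross-entropy loss
(batch size 8, learning rate 1e-5, gradient norms clipped at 0.1, early
stopping on validation loss with patience 50). The GRU, backpropagation
through time, Adam, and t-SNE are implemented in-package in plain R matrix
code; analytic gradients are verified against numerical differentiation in
the test suite.

## Worked example

Simulate a small swarm from a field-characterized preset, recover the
individual fireflies, and characterize their flash patterns:

```r
library(fireflash)

events <- generate_swarm_events(preset_table2()[3, ], n_fireflies = 4,
                                swarm_config(speed_m_per_frame = 0.005),
                                seed = 21,
                                positions = cbind(c(0, 4, 8, 4), c(0, 0, 0, 4), 0))
seqs <- events[, c("recording_id", "frame", "x", "y", "z")] |>
  link_streaks(radius_m = 0.2) |>
  link_trajectories(max_gap_s = 1, max_dist_m = 1) |>
  trajectories_to_sequences() |>
  clean_short_gaps() |>
  filter_single_flash()
seqs
#> # A tibble: 4 × 4
#>   recording_id trajectory start_frame bits
#>   <chr>             <int>       <int> <chr>
#> 1 synth                 1          46 1111000000000011110000000000111
#> 2 synth                 2          72 11100000000000000111100000000000001111000…
#> 3 synth                 3          97 11111000000000011111100000000000000111000…
#> 4 synth                 4         111 11111000000000000011110000000000000011110…

characterize_population(seqs, population = "P. carolinus, TN, Jun. 2020 (synthetic)")
#> <firefly_characterization> P. carolinus, TN, Jun. 2020 (synthetic) (4 sequences)
#> # A tibble: 3 × 4
#>   statistic   mean     sd     n
#>   <chr>      <dbl>  <dbl> <int>
#> 1 n_flashes  6.75  2.87       4
#> 2 gap_s      0.419 0.0459    23
#> 3 duration_s 0.146 0.0348    27
```

All four planted fireflies are recovered as separate trajectories, and the
pooled statistics sit near the preset's generative means (7.2 flashes,
0.42 s gap, 0.14 s duration). Training a classifier is one call:
`train_gru(train, val, gru_config(n_species = 2, ...))`, then
`predict(model, test)`, `weighted_metrics()`, `roc_curves()`,
`sympatry_experiment()`, `top_confident_subset()` compose downstream. A
thin command-line wrapper with the same verbs lives at `exec/fireflash`
(subcommands `simulate`, `trajectorize`, `classify`, `train`, `predict`,
`evaluate`, `sympatry`, `characterize`).

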