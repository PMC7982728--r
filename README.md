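# riembci

Riemannian tangent-space decoding of multiclass motor-imagery EEG, with
subject-specific discriminative filter banks.

Motor imagery (imagined left-hand, right-hand, foot, or tongue movement)
modulates narrow-band EEG power over sensorimotor cortex (ERD/ERS, mostly in
the mu 8–12 Hz and beta 13–30 Hz rhythms), but *which* bands carry the
discriminative signal differs from subject to subject. `riembci` implements a
decoding pipeline for brain–computer interface research that

1. represents each trial by its sample covariance matrix
   `P_i = X_i X_i' / (N_s − 1)`, a symmetric positive-definite (SPD) matrix;
2. works on the SPD manifold under the affine-invariant Riemannian metric,
   with geodesic distance
   `δ_R(P_1, P_2) = ‖logm(P_1⁻¹ P_2)‖_F = sqrt(Σ log² λ_i)`,
   exponential/logarithmic maps, and the Karcher (Fréchet) mean
   `argmin_P Σ δ_R²(P, P_i)`;
3. screens a 2 Hz filter-bank grid over 2–40 Hz (19 sub-bands) with a
   distance-based one-way MANOVA pseudo-F computed directly from the pairwise
   trial distance matrix:
   `SS_T = Σ_{i<j} d_ij² / N`, `SS_W = Σ_{i<j, same class} d_ij² / n`,
   `F = (SS_A/(a−1)) / (SS_W/(N−a))` with `SS_A = SS_T − SS_W`;
4. keeps the top-G sub-bands, merges adjacent ones, and expands the merged
   bands into a discriminative multi-scale filter bank (widths 2/4/8 Hz);
5. maps the per-cell trial covariances to the tangent space at their
   Riemannian mean, `s_i = upper(P_𝔊^{−1/2} Log_{P_𝔊}(P_i) P_𝔊^{−1/2})`
   (√2-weighted upper triangle, so ‖s_i‖ = δ_R(P_𝔊, P_i)), and
6. classifies the concatenated tangent features with a cross-validated
   one-vs-rest linear SVM.

A seeded generator of motor-imagery-like EEG (1/f background, class-specific
band-limited sources, sensor noise) makes the entire pipeline testable with
no recorded data. Results come back as tibbles with `tidy()`, `glance()` and
`autoplot()` methods; a command-line interface is included for shell use.

## Worked example

```r
library(riembci)

cfg   <- sim_config(trials_per_class = 12, n_channels = 8, seed = 7)
bench <- default_benchmark(7, cfg)     # two sessions: train + test
bench$train
#> <epoch_set> 48 trials x 8 channels x 1000 samples @ 250 Hz, t0 = 0 s
#>   classes: 1 (n=12), 2 (n=12), 3 (n=12), 4 (n=12)

model <- mi_fit(bench$train,
                mi_config(G = 6, n_folds = 4,
                          time_windows = time_window(0.5, 3.5), seed = 7))
model
#> <mi_tsm> tangent-space motor-imagery decoder
#>   channels: 8 @ 250 Hz | classes: 1, 2, 3, 4
#>   G = 6 selected sub-bands -> 3 merged band(s) -> 9 multi-scale window(s)
#>   1 time window(s) x 9 bands x 36 = 324 tangent features; SVM C = 0.001

head(dplyr::arrange(tidy(model), rank), 4)
#>    f_lo  f_hi  SS_T  SS_W  SS_A F_stat  rank selected
#> 1    20    22 1230.  341.  889.   38.3     1 TRUE
#> 2    12    14 1157.  322.  835.   38.0     2 TRUE
#> 3    22    24 1151.  322.  830.   37.9     3 TRUE
#> 4    14    16 1098.  323.  775.   35.1     4 TRUE

evaluate_session_transfer(bench$train, bench$test, model = model)
#> <mi_eval> accuracy 100.0% over 48 trials
```

The band table shows the screening pseudo-F per 2 Hz sub-band: the generator
planted class-dependent power in 8–12, 12–16, 20–24 and 26–30 Hz, and those
sub-bands dominate the ranking. `F_stat` is the ratio of between- to
within-class dispersion measured by geodesic distances between trial
covariance matrices; `selected` marks the G sub-bands that enter the
multi-scale filter bank. The transfer evaluation fits on session 1 and
scores session 2; at the generator's default signal-to-noise level the four
classes separate completely.

Scale-sensitive callers can plot `autoplot(tidy(model))` (pseudo-F per band,
selection highlighted) and `autoplot(eval_result)` (confusion heatmap).

The CLI mirrors the R API:

```sh
Rscript inst/cli/riembci.R simulate --seed 7 --out sim/
Rscript inst/cli/riembci.R select-bands --epochs sim/train.rds --out bands/
Rscript inst/cli/riembci.R evaluate --train sim/train.rds --test sim/test.rds --out eval/
```

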