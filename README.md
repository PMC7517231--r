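# sampenprof

Sample Entropy profiles across a whole range of tolerance radii, and the
machinery to test whether two signals keep the same entropy ordering at
every tolerance — the *relative consistency* assumption that underlies
almost every applied comparison of Sample Entropy values (heart-rate
variability, gait, economic series). `sampenprof` is for researchers who
want to check that assumption on their own signal class instead of
trusting it.

## What it computes

For a series `u(1), ..., u(N)`, embedding dimension `m`, lag `tau` and
tolerance `r`, Sample Entropy is

```
SampEn(m, r, N) = -ln( C^{m+1}(r) / C^m(r) ),
```

where `C^m(r)` is the fraction of ordered template pairs (self-matches
excluded) whose Chebyshev distance is at most `r`. The package provides:

* a brute-force reference implementation (`correlation_sum()`,
  `sample_entropy()`), and a single-pass look-up-table engine
  (`sampen_profile()`) that bins every template-pair distance into a
  uniform threshold grid and reads the whole *entropy profile* —
  SampEn as a function of `r` — off cumulative bin counts, with
  exact (integer) agreement between the two paths;
* seeded generators for the classical test processes: `generate_mix()`
  (a sinusoid whose samples are replaced by `U(-3, 3)` noise with
  probability `p` — tunes *how much* of the signal is random) and
  `generate_mixture()` (a sinusoid plus `lambda`-wide uniform noise at
  every sample — tunes *how large* the randomness is);
* the crossing experiment (`experiment_spec()`, `run_experiment()`,
  `crossing_table()`, `consistency_region()`): mean entropy profiles per
  parameter level on per-signal `(0, 4*SD]` grids, pairwise crossing
  detection by sign-change counting with linear-interpolation
  localization, and a map of the `(r, parameter)` region where profile
  orderings are preserved.

The headline phenomenon the tooling reproduces: MIX entropy profiles
*cross* (the entropy ordering of two parameter levels reverses on a
finite window of `r`, violating relative consistency), while MIXTURE
profiles never cross, no matter how much noise is added.

## Worked example

```r
library(sampenprof)

x <- generate_mix(0.9, N = 4000, seed = 1)
prof <- sampen_profile(x, m = 1, tau = 1,
                       grid = threshold_grid(0.02 * sd(x), 4 * sd(x), 200))
prof[c(25, 100, 150), ]
#>             r       c_m       c_m1     sampen
#> 25  0.8489367 0.2681962 0.07192744 1.31606116
#> 100 3.3957468 0.8205975 0.67384042 0.19703938
#> 150 5.0936202 0.9823605 0.96503441 0.01779462
```

(`c_m`/`c_m1` are the correlation sums at each radius; `sampen` is their
negative log-ratio — one row per tolerance, 200 tolerances from one pass
over the 4000-sample series.)

The crossing experiment, scaled down to run in seconds:

```r
spec <- experiment_spec("mix", levels = c(0.8, 0.9, 1.0), replicates = 20,
                        N = 4000, m = 1, base_seed = 1)
ct <- crossing_table(run_experiment(spec))
subset(ct, level_a == 0.9 & r_cross > 0.6 & sampen_cross > 0.03)
#>    level_a level_b r_cross sampen_cross bracket_lo bracket_hi
#> 13     0.9       1 1.33910      0.47196       1.32       1.34
#> 14     0.9       1 2.12032      0.16299       2.12       2.14
```

The MIX(0.9) and MIX(1.0) mean profiles swap order near `r = 1.34*SD`
and swap back near `2.12*SD`: between those radii the *noisier* process
measures as the *less* complex one, so a single-tolerance comparison
there would rank the signals backwards. (The unfiltered table also lists
sign changes at tiny radii and near `r = 3*SD`, where the profiles
differ by less than the 20-replicate noise; the methods vignette
discusses this resolvable-reversal window.) Running the same spec with
`process = "mixture"` returns an empty table — MIXTURE keeps its
ordering everywhere. `run_paper_experiment(out_dir)` executes the full
protocol for both processes (levels 0.1-1.0, 100 replicates of 4000
samples) and writes profile CSVs, crossing reports (JSON + CSV), the
consistency-region matrices and a checksummed manifest.

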