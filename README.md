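# iceemdan

Adaptive decomposition of nonstationary signals — EEG in particular — into
intrinsic mode functions (IMFs), for researchers who need data-driven
time–frequency analysis where fixed-basis methods (Fourier, fixed
wavelets) smear drifting oscillations. The package implements empirical
mode decomposition (EMD), ensemble EMD (EEMD), and its main entry point,
the improved complete ensemble EMD with adaptive noise (ICEEMDAN), plus
the fixtures, metrics, file formats and command-line interface around
them.

## The method

EMD extracts IMFs by *sifting*: detect the extrema of a working copy, fit
natural cubic-spline envelopes through the maxima and minima (a strictly
diagonally dominant tridiagonal system, solved without pivoting), subtract
the envelope mean, and repeat; the converged copy is one mode, which is
subtracted from the signal before extracting the next. Plain EMD mixes
intermittent oscillations across modes. ICEEMDAN removes that mode mixing
by averaging over an ensemble of noise-perturbed copies, injecting at
stage *k* the *k*-th EMD mode of the noise so the perturbation's spectrum
matches the scale being extracted. Writing M(·) for the local-mean
operator, E\_k(·) for the k-th EMD mode of its argument, ⟨·⟩ for the
average over I noise realizations w⁽ⁱ⁾, and β\_k = ε₀·std(r\_k):

    r1 = ⟨M(x + β0·E1(w(i)))⟩        d1 = x − r1
    rk = ⟨M(rk−1 + βk−1·Ek(w(i)))⟩   dk = rk−1 − rk     (k = 2, …, K)

Each mode is a difference of consecutive residues, so the decomposition is
invertible by construction: Σ dk + rK = x exactly up to float rounding.
The sifting core is compiled (Rcpp) and operates on whole batches of
realizations; batched and per-realization results are bit-identical, and
a fixed (input, configuration, seed) reproduces every result bitwise.

## Worked example

The built-in validation fixture is a 1000-sample dual-tone signal: an
intermittent 255 Hz burst `s1` (nonzero only on samples 501–750, 1-based)
riding on a continuous 65 Hz tone `s2`, at a nominal 1 kHz sampling rate.

```r
library(iceemdan)

dt  <- make_dual_tone()
cfg <- ensemble_config(n_realizations = 500, max_modes = 12, seed = 1)
dec <- iceemdan(dt$s, cfg)
dec
#> <iceemdan_result> 8 modes, N = 1000

report <- match_modes(dec, list(dt$s1, dt$s2))
report
#> <similarity_report>
#>  reference mode similarity
#>          1    1  0.9885374
#>          2    2  0.9975300
#> mean similarity: 0.993034

reconstruction_error(dt$s, dec)
#> [1] 1.110223e-16
```

Mode 1 recovers the intermittent burst with similarity index 0.989 (the
normalized absolute covariance with the ground-truth component; 1 means
identical shape) and mode 2 the continuous tone with 0.998; the modes plus
residue reconstruct the input to machine precision. The matched modes peak
at the component carriers:

```r
win <- dt$active_window[1]:dt$active_window[2]
dominant_frequency(dec$modes[1, ][win], 1000)  # 255.127 Hz
dominant_frequency(dec$modes[2, ], 1000)       # 64.94141 Hz
```

## Command line

A launcher is installed at `inst/cli/iceemdan` (or call `run_cli()` from
R). `decompose` runs any of the three algorithms per channel of a
delimited, raw-binary or EDF recording and writes mode matrices with a
JSON run manifest that `replay_manifest()` can reproduce bit for bit;
`validate` runs the dual-tone fixture end to end and prints the
similarity report; `simulate` emits fixtures.

```sh
inst/cli/iceemdan decompose --input rec.edf --algorithm iceemdan \
    --realizations 500 --sift-iterations 10 --seed 42 --output out/rec
inst/cli/iceemdan validate --seed 42 --realizations 500
```

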