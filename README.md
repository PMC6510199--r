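# sinoup — convolutional angular upsampling of X-ray CT sinograms

Time-resolved (4D) X-ray tomography collects each tomogram of a series
with few projections — e.g. 91 over 180° — to freeze fast processes such
as corrosion or bubble formation, and reconstructions from so few angles
are noisy and streaked. One *fully sampled* tomogram (e.g. 3601
projections) is routinely captured at the start or end of the series.
`sinoup` trains a lightweight convolutional network on that single fully
sampled scan and uses it to predict the skipped intermediate projections
of every undersampled tomogram, upscaling each sinogram along its angle
(θ) axis by 2× or 4×.

## The method

For each sample height, the detector rows of all projections are stacked
into a sinogram (θ × x image). An 11-row input patch `I` (rows spaced `g`
apart in the fully sampled sinogram, `g = 40` at full scale) is mapped to
the intermediate rows `O` by three convolutional layers separated by two
rectified linear units:

    F1 = max(0, W1 * I + B1)      n1 kernels, 10 × 17, zero-padded (4, 8)
    F2 = max(0, W2 * F1 + B2)     n2 kernels,  7 × 13, zero-padded (3, 6)
    F(I) = W3 * F2 + B3           N_out kernels, 7 × 13, zero-padded (3, 6)

`N_out` = upscaling factor − 1 output channels, each predicting one of the
evenly spaced intermediate rows per gap; padding keeps every feature map
at the output's size (input height − 1, width preserved). Training
minimizes the mean squared error `(1/N) Σ (F(I) − O)²` with Adam under two
learning-rate groups (layers 1–2 and the error-sensitive layer 3).
At inference the undersampled sinogram is tiled into overlapping 11-row
windows, predictions for the same inter-row gap are averaged, and the
result is interlaced with the input rows: 91 rows → 181 (2×) → 361 (4×).

The package also provides an analytic quadric-phantom simulator with
Poisson counting noise (so the whole pipeline runs without external data),
NeXus-style HDF5 I/O, a per-column cubic-spline baseline, parallel-beam
filtered back projection, and a PSNR/SSIM benchmark harness.

## Worked example

Simulate a pin-corrosion phantom tomogram (64 heights × 721 angles × 256
detector pixels), train a reduced network on its odd heights, and compare
against cubic interpolation on held-out heights:

```r
library(sinoup)

sim <- simulate_tomogram(seed = 1)          # noisy + noiseless stacks
H <- dim(sim$noisy$data)[1]
train <- lapply(seq(1, H, 2), function(h) sim$noisy$data[h, , ])
val   <- lapply(seq(2, H, 2), function(h) sim$noisy$data[h, , ])

fit <- udnn_train(train, val,
                  udnn_config("udnn-128", feature_scale = 1/16),
                  geom = patch_geometry(gap = 8),
                  schedule = train_schedule(lr_first_two = 0.001,
                                            lr_last = 0.001,
                                            max_iterations = 480,
                                            seed = 1))

rep <- run_benchmark(sim$noisy, sim$noiseless,
                     methods = list(cubic = "cubic", udnn = fit$params),
                     down = 8, factor = 2, hold_every = 10)
aggregate(cbind(psnr_db, ssim) ~ method, rep, mean)
#>   method  psnr_db      ssim
#> 1  cubic 34.46961 0.7139363
#> 2   udnn 36.91272 0.9035513
```

Each row averages the held-out heights (1, 11, …, 61): the 721-row
sinograms are downsampled 8× to 91 rows, upscaled back to 181 by each
method, and the *predicted* intermediate rows are scored against the
noiseless ground truth (PSNR in dB, higher is better; SSIM in [−1, 1]).
Cubic interpolation passes the acquisition noise straight through
(the noisy rows themselves score 33.2 dB against the clean ones), while
the network, trained toward the conditional mean, simultaneously
interpolates and denoises — hence its margin. Exact numbers for `udnn`
depend on the training seed; the ordering does not.

A shell front end wrapping the same functions is installed as the
`sinoup` executable (`simulate`, `convert`, `downscale`, `train`,
`upscale`, `reconstruct`, `evaluate`, `demo`).

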