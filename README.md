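# pivae

Prior-encoding variational autoencoders: learned stochastic-process priors
for fully Bayesian MCMC inference, in R.

## The problem

Stochastic-process priors — Gaussian processes, monotone function families,
Cox-process intensities — are the natural way to encode domain knowledge
about unknown functions, but exact Bayesian inference with them is
expensive (cubic solves for GPs, intractable integrals for point
processes) and MCMC over their highly correlated parameterisations mixes
poorly. `pivae` implements a two-stage alternative for statisticians and
epidemiological modellers:

1. **Encode the prior.** Draw many function realisations from the prior you
   actually believe in, and train a variational autoencoder over
   per-realisation basis coefficients together with a shared, trainable
   feature map Φ(s) (a kernel layer with trainable centres plus a small
   neural network). Writing f(s) = βᵀΦ(s), the encoder/decoder pair learns
   a low-dimensional latent representation z of the function class —
   a learnable, finite-rank analogue of a Karhunen–Loève expansion.
2. **Infer with the frozen decoder.** The pair (Φ, d) defines a new,
   Kolmogorov-consistent stochastic process: f(s) = d(z)ᵀΦ(s) with
   z ~ N(0, I). Given new data, the posterior p(z | y) ∝ p(y | f_z) N(z; 0, I)
   lives in a few nearly uncorrelated dimensions, and the built-in
   No-U-Turn sampler explores it with effective sample sizes that routinely
   exceed the number of retained draws.

Everything is self-contained: prior samplers (GP, monotone cubic,
log-Gaussian Cox process), the training loop (compiled minibatch
backpropagation), the NUTS sampler, split rank-normalised R-hat / ESS
diagnostics, posterior predictives, serialisation, a command-line front end
(`inst/cli/pivae`), and seeded benchmark experiments.

## A worked example

Train a prior on monotone cubic functions, then fit 20 noisy observations
of y = x³ + ε by NUTS:

```r
library(pivae)

draws <- draw_cubic_functions(n_draws = 10000, k_points = 20,
                              domain = c(-6, 6), seed = 1)
model <- pivae(draws, latent_dim = 10, seed = 2)
model
#> <pivae> stochastic-process prior (latent dim 10, basis dim 20, 1 channel)
#>   trained on 10000 draws x 20 points from prior 'cubic'
#>   final losses: loss1 0.001115, loss2 0.02563, kl 0.04731 (epoch 200)

set.seed(3)
x <- runif(20, -4, 4)
y <- rnorm(20, x^3, 3)
fit <- fit_pivae(model, x, y, likelihood_gaussian(noise_scale = 10),
                 chains = 4, warmup = 1000, iter = 5000, seed = 4)
fit
#> <pivae_fit> posterior over 10 latent dims + noise sd: 4 chains x 5000 draws
#>   likelihood: gaussian; observations: 20
#>   worst R-hat 1.0000, min ESS 86021
#>   sigma posterior: median 2.569, 95% CI [1.907, 3.736]

round(predict(fit, c(-5, 0, 5)), 3)   # posterior mean, 95% interval
#>       mean    lower    upper
#> 1 -114.481 -124.407 -104.712
#> 2    0.000   -0.119    0.125
#> 3  113.627  103.970  123.380
```

`loss1` is the mean squared error of the per-draw basis fits, `loss2` the
same through the latent bottleneck, `kl` the divergence of the latents from
N(0, I) (all per observation). The noise sd posterior brackets the true 3;
the latent posterior mixes essentially perfectly (R-hat at 1.0000, ESS far
above the 20,000 retained draws); and the extrapolated predictions at
x = ±5 land within about 8% of the truth (±125) with suitably wide
intervals, while the interior prediction at 0 is pinned tightly.

The packaged benchmark compares this fit against a pi-VAE trained on
GP draws and against exact GP regression (hyperparameters sampled by NUTS)
on a held-out grid over (−6, 6), which includes extrapolation beyond the
training inputs:

```r
report <- run_cubic_benchmark(seed = 1)
report$metrics
#>         method  test_mae
#> 1  pivae_cubic  5.675809
#> 2 pivae_gp_rbf 32.359566
#> 3       gp_rbf 43.085001
```

The informative monotone-cubic prior wins by a wide margin; the GP-prior
pi-VAE still beats the generic exact-GP baseline, whose off-the-shelf
unit-scale hyperpriors cannot reach the data's amplitude (the methods
vignette discusses that choice of baseline configuration).

Other entry points: `gridvae()` (fixed-grid VAE precursor),
`run_lgcp_experiment()` (two-channel intensity + integral inference for a
log-Gaussian Cox process), `run_spatial_interpolation()` and
`run_completion_curve()` (2-D field reconstruction), `export_model()`
(backend-agnostic export of the frozen prior for probabilistic-programming
systems), `save_pivae()`/`load_pivae()` (versioned single-file bundles).

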