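# epiwalsh

Sparse Walsh-Hadamard (WH) spectral analysis and regularization of fitness
landscapes.

## The problem

Combinatorial mutagenesis experiments measure a fitness value for
combinations of mutations at `d` sites. Writing a genotype as
`x ∈ {-1,+1}^d`, any such landscape is uniquely a multilinear polynomial

    f(x) = Σ_S α_S Π_{i∈S} x_i,        S ⊆ {1..d}

whose coefficients `α_S` — the WH transform of the landscape — are exactly
the epistatic interaction coefficients (|S| = 1: additive site effects,
|S| ≥ 2: genuine interactions). Measured landscapes are typically
*spectrally sparse*: a few large interactions plus a band of small ones.

`epiwalsh` is for researchers who want to (i) read epistasis out of
measured or modelled landscapes, (ii) recover sparse spectra of black-box
functions in **sublinear** time via sparse-graph-code subsampling and a
peeling decoder, and (iii) train neural sequence-fitness models whose
spectrum is explicitly regularized to be sparse:

    min_θ  Σ_i (y_i − g_θ(x_i))² + α ‖H g_θ(X)‖₁        (exact, d ≤ 25)

with `H` the unitary WH matrix and `g_θ(X)` the model's full landscape —
plus a scalable ADMM variant that alternates network updates with a
peeling-based sparse-spectrum projection at subsampled points only, so `d`
can be in the hundreds.

## Worked example

A five-site landscape with three interactions — an enriching pairwise
interaction between sites 1 and 4, a depleting additive effect at site 3,
and an enriching third-order interaction among sites 1, 2, 5:

```r
library(epiwalsh)
f <- pbf(c(mask_from_sites(c(1, 4), 5),
           mask_from_sites(3, 5),
           mask_from_sites(c(1, 2, 5), 5)),
         c(12, -3, 6), 5)

X <- enumerate_inputs(5)                      # all 2^5 = 32 genotypes
spec <- spectrum_nonzero(fwht(wh_landscape(eval_pbf(f, X))))
spec$coefficients
#> 00100 10010 11001
#>    -3    12     6
```

The exact transform of the 32-point evaluation returns exactly the three
generating coefficients (masks are bitstrings, site 1 leftmost). Their
squared magnitudes give the variance-explained curve — the largest
coefficient alone explains 144/189 ≈ 76% of the non-constant variance:

```r
round(variance_explained_curve(spec, 3), 4)
#>  10010  11001  00100
#> 0.7619 0.9524 1.0000
```

The same spectrum is recovered *without* enumerating the cube, by hashing
coefficients into bins through random GF(2) subsampling maps and peeling
singleton bins:

```r
res <- recover_sparse_wht(function(Xq) eval_pbf(f, Xq),
                          d = 5, k_estimate = 3, C = 3, b = 3, seed = 7)
res$spectrum$coefficients
#> 00100 10010 11001
#>    -3    12     6
```

At `d = 5` this saves nothing, but the query budget is
`C (d+1) 2^b = O(k log² 2^d)`: at `d = 40`, `k = 8` the decoder recovers
spectra exactly from under 2,000 queries of a space of size `2^40 ≈ 10^12`.

Model training: `build_dnn()` (a `d → fd → fd → d → 1` batchnorm/leaky-ReLU
network), `train_en()` (exact spectral-l1 penalty), `train_ens()` (scalable
ADMM with peeling), `lasso_wh_baseline()` (l1 over WH monomial features with
OLS debiasing), `run_benchmark()` (paired synthetic comparisons reporting
test R² and spectrum NMSE). `generate_sparse_landscape()` simulates the
sparse-epistasis world; `boxcox_preprocess()` removes global monotone
nonlinearities from measured fitness values. See the methods vignette
(`vignettes/spectral-regularization.Rmd`) for the model, conventions,
parameter defaults and limitations.

## Command line

```sh
Rscript -e 'epiwalsh::epiwalsh_cli(commandArgs(TRUE))' \
    simulate --d 10 --k-large 5 --k-small 20 --sigma 1 --n 200 --seed 1 --out sim
```

Subcommands: `simulate`, `transform`, `recover-spectrum`, `train-en`,
`train-ens`, `baseline-lasso`, `benchmark` (also via the
`inst/exec/epiwalsh` script).

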