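# perfusr

Voxel-wise quantification of myocardial blood flow from dynamic
contrast-enhanced (DCE) MRI by hierarchical Bayesian fitting of the
two-compartment exchange model (2CXM), with a multi-start nonlinear
least-squares baseline, simulation phantoms for validation, and a
Monte-Carlo evaluation harness. It is aimed at researchers in quantitative
cardiac perfusion imaging who need pixel-wise maps of blood flow and
microvascular function together with an honest account of their
uncertainty.

## The problem and the model

A myocardial voxel is modelled as exchanging plasma and interstitial
compartments driven by the arterial input function (AIF) $C_a(t)$ sampled
in the left ventricle:

$$
v_p \dot C_p = F_p (C_a(t-\tau_0) - C_p) + PS (C_e - C_p), \qquad
v_e \dot C_e = PS (C_p - C_e), \qquad F_p = \frac{F_b}{1-\mathrm{Hct}},
$$

with observed tissue concentration $C = v_p C_p + v_e C_e =
F_p (R * C_a)(t-\tau_0)$, $R$ the bi-exponential residue function. The
parameters are blood flow $F_b$ (mL/min/mL), plasma and interstitial
volume fractions $v_p, v_e$, and the permeability–surface-area product
$PS$ (mL/min/mL).

Least-squares estimation of these parameters is notoriously unreliable:
the likelihood has long flat ridges (flow trades off against plasma
volume) and local optima under noise. The package therefore implements,
alongside the classical multi-start box-constrained fit, a Metropolis–
Hastings sampler for a hierarchical Bayesian model: weakly informative
priors on all parameters, per-voxel hyperpriors on the flow and PS prior
means (so healthy and ischaemic tissue can pull their priors apart
without labelling either in advance), an exact conjugate update for the
noise variance, and an edge-preserving Laplace Markov-random-field prior
tying neighbouring voxels together. Maps are posterior medians with
per-voxel coefficients of variation.

## Worked example

```r
library(perfusr)

ph    <- build_phantom("stress_defect")          # 6x6 truth maps, Fb 3.5 / defect 1.0
ser   <- simulate_series(ph, snr = 15, seed = 42) # gamma-variate AIF, Rician noise
chain <- run_mcmc(ser, n_steps = 2000, burn_in = 1000, seed = 5)
summ  <- summarize_posterior(chain)

round(summ$median$fb, 2)
#>      [,1] [,2] [,3] [,4] [,5] [,6]
#> [1,] 2.37 2.44 2.40 2.40 2.52 2.71
#> [2,] 2.41 1.09 1.09 2.48 2.56 2.66
#> [3,] 2.53 1.10 1.07 2.52 2.63 2.81
#> [4,] 2.61 2.66 2.83 2.91 2.63 2.55
#> [5,] 2.79 2.85 2.88 2.92 0.91 0.91
#> [6,] 2.75 2.76 2.80 2.82 2.77 2.37

chain$acceptance_fraction         # 0.242  -- post-burn-in block acceptance
nmse(summ$median$fb, ph$maps$fb)  # 0.0613 -- normalised mean-squared error
```

Both low-flow blocks (the simulated perfusion defect) are cleanly
recovered at $F_b \approx 1$ and sharply delineated against the healthy
surround. The surround itself sits at 2.4–2.9 rather than the true 3.5 on
this noise realisation — the flow/plasma-volume likelihood ridge discussed
in the methods vignette, which is exactly the unreliability the Bayesian
treatment is designed to expose rather than hide; the multi-start
least-squares map of the same realisation
(`fit_slice_nlls(ser, fit_config(n_starts = 100, seed = 5))`) scatters far
more widely voxel-to-voxel. The chain's acceptance fraction lands near
the 0.234 random-walk optimum by construction of the burn-in tuning rule,
and overall NMSEs of a few percent are typical for these phantoms.

A thin command-line wrapper over the same functions is installed at
`inst/cli/perfbayes.R`
(`simulate`, `fit-nlls`, `fit-bayes`, `evaluate`, `demo-costsurface`),
reading and writing NIfTI series with JSON sidecars, CSV curves and YAML
configs; every run writes a manifest sufficient to reproduce it.

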