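# tideclock

Coalescent phylogeography and **expansion dating** for mitochondrial
control-region data.

Shallow-water marine populations expanded when post-glacial sea-level rise
re-flooded their habitat. If a population's transition from long-term
constant size to growth can be dated genetically — in mutation-scaled time,
substitutions per site — and identified with a dated environmental event
*c* years ago, the substitution rate follows without any external clock:

```
μ = t_transition / c        (substitutions · site⁻¹ · year⁻¹)
```

tideclock implements the full analysis chain that supports this estimate on
an aligned mtDNA matrix with georeferenced sampling localities:

* **Summary statistics** — haplotype collapsing, haplotype and nucleotide
  diversity, Tajima's *D* and Fu's *F*ₛ (log-space Ewens sampling formula)
  with coalescent-simulation p-values;
* **Statistical-parsimony haplotype network** with a 95% connection limit
  and a star-likeness score (the classic expansion signature);
* **Genetic landscape shape interpolation** — Delaunay connectivity among
  localities, residuals of genetic on geographic distance, inverse-distance-
  weighted surface on a 0.05° grid;
* **Bayesian demographic inference on a fixed genealogy** — UPGMA genealogy,
  Bayesian skyline, and a two-epoch coalescent model (ancient constant size
  fNeμ₀, recent exponential growth at rate *r* from *t*₍transition₎ to a
  present size fNeμ₁) sampled by Metropolis–Hastings under 1/x and uniform
  priors;
* **Model choice** — path-sampling and stepping-stone marginal likelihoods
  over a power-posterior schedule, compared as 2 ln BF;
* **Expansion dating** — the posterior of *t*₍transition₎ calibrated over a
  geological window (default 18–13 ka BP), reported in % substitutions /
  site / MY;
* a first-class **coalescent simulator** (two-epoch demography, HKY+I
  sequence evolution, georeferenced localities) used as the test bed for
  every stage.

## Worked example

Simulate a study-scale dataset (84 sequences × 352 sites, 10 coastal
localities, two-epoch truth with growth onset at 4.7 × 10⁻⁴
substitutions/site), then date the expansion from the genealogy:

```r
library(tideclock)

ds <- generate_dataset(sim_config(seed = 7))
diversity(ds$alignment)
#> # A tibble: 1 × 7
#>       n     L n_haplotypes    Hd      pi     S k_bar
#>   <int> <int>        <int> <dbl>   <dbl> <int> <dbl>
#> 1    84   352            5 0.664 0.00246     4 0.867

fit <- mh_sample(ds$genealogy, "two_epoch",
                 priors = list(N0 = prior_one_over_x(1e-5, 0.1),
                               N1 = prior_one_over_x(1e-5, 0.5),
                               r  = prior_uniform(10, 2e4),
                               t_trans = prior_uniform(1e-5, 2e-3)),
                 iterations = 20000, thin = 10, seed = 1)
tidy(fit)
#> # A tibble: 4 × 6
#>   term       estimate   std.error  hpd_lower   hpd_upper   ess
#>   <chr>         <dbl>       <dbl>      <dbl>       <dbl> <dbl>
#> 1 N0         0.00247     0.00146    0.000831    0.00528   489.
#> 2 N1         0.00708     0.00133    0.00481     0.00976   827.
#> 3 r       3188.       1089.       942.       5320.        749.
#> 4 t_trans    0.000568    0.000208   0.000182    0.000865  403.

rate_window(fit$draws$t_trans, c_low = 13000, c_high = 18000)
#> # A tibble: 3 × 6
#>   calibration c_years mean_rate hpd_lower hpd_upper unit
#>   <chr>         <dbl>     <dbl>     <dbl>     <dbl> <chr>
#> 1 c_high        18000      3.16      1.01      4.81 %/site/MY
#> 2 c_low         13000      4.37      1.40      6.66 %/site/MY
#> 3 envelope         NA      3.76      1.01      6.66 %/site/MY
```

The `tidy()` table shows the posterior bracketing the generating values
(N0 = 0.002, t_trans = 4.7e-4 inside their 95% HPDs; the chain reports
per-parameter effective sample sizes). The final table reads: calibrating the
growth onset with the sea-level rise (18 ka) gives a mean rate of
3.2 %/site/MY, with the warming calibration (13 ka) 4.4 %/site/MY, and the
envelope of the two 95% HPDs spans 1.0–6.7 %/site/MY for this one simulated
genealogy (the generating rate, 4.7e-4 / 15 000 yr × 10⁸ ≈ 3.1 %/site/MY,
lies inside it).

The same chain runs end to end on files via

```r
cfg <- pipeline_config(fasta = "aln.fasta", metadata = "meta.csv",
                       out_dir = "run1", seed = 1)
res <- run_pipeline(cfg)
```

writing per-stage artefacts (haplotypes, summary statistics, network,
landscape surface, genealogy, skyline, traces, Bayes factors, rates) plus a
manifest with per-stage seeds. `autoplot()` methods draw the skyline, the
network and the landscape surface; `tidy()`/`glance()` summarise fitted
objects.

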