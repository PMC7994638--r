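# stateRSF

Behavioral-state movement modelling and resource selection for GPS
telemetry, built around the analysis of invasive wild pig (*Sus scrofa*)
movement in the southeastern United States.

Wildlife managers need to know not just *where* animals occur but *what
they are doing there*: the habitat an animal rests in is not the habitat it
travels through. stateRSF answers this in two stages:

1. **Hidden Markov segmentation of movement paths.** Hourly GPS fixes are
   reduced to step lengths ℓₜ and turning angles φₜ. Conditional on a
   latent behavioral state *k*, ℓₜ ~ Gamma(mean μₖ, sd σₖ) and
   φₜ ~ wrapped Cauchy(μφₖ, ρₖ); transition probabilities follow a
   multinomial logit with a first-order cosinor in the hour of day,
   ηᵢⱼ(h) = β⁰ᵢⱼ + βᶜᵢⱼ cos(2πh/24) + βˢᵢⱼ sin(2πh/24), so the propensity
   to switch behaviors tracks the diel cycle. Models with 2 and 3 states
   are fitted by direct likelihood maximization from 25 random starts,
   compared by AIC, and decoded with the Viterbi algorithm; with states
   ordered by step mean, 1/2/3 read as resting / foraging / traveling.
2. **Used-available resource selection functions (RSFs).** Second-order
   selection (home-range placement) contrasts systematic 90-m samples of
   each animal's 95% fixed-kernel home range (reference bandwidth href)
   against samples of the buffered study-area MCP in a logistic GLM per
   sex and season. Third-order selection (behavior-specific use within the
   home range) contrasts the decoded GPS fixes of each behavioral state
   against home-range samples in a logistic GLMM with a per-animal random
   intercept. Coefficients on standardized covariates (Euclidean distance
   to vegetation classes, streams and roads; percent canopy) are reported
   as odds ratios per 100 m (distances) or per 10 percentage points
   (canopy), with Wald 95% intervals and rank-based AUC.

A synthetic study system (`make_landscape()`, `simulate_study()`,
`simulate_rsf_points()`) generates landscapes, telemetry and selection
patterns with known parameters, so the entire workflow is testable without
field data. See the methods vignette
(`vignettes/behavioral-state-rsf.Rmd`) for the model details and design
choices.

## Worked example

Simulate one low-forage season of hourly telemetry for three females, fit
2- and 3-state HMMs, select by AIC, and decode:

```r
library(stateRSF)
set.seed(1)
sim <- simulate_study(n_per_sex = 3, n_steps = 400, season = "low_forage")
steps <- sim$steps[sim$steps$sex == "female", ]
fits <- lapply(2:3, function(K) fit_hmm(steps, K, n_starts = 8, seed = 2))
sel <- select_states(fits)
print(sel)
steps$state <- viterbi(sel, steps)
state_summaries(steps, steps$state)$by_state
```

```
K = 2: AIC = 16230.5
K = 3: AIC = 16088.6
3-state movement HMM (tod = cosinor): logL = -8012.312, AIC = 16088.623
  1200 observations, 7/8 starts converged
 state     mu   sigma     muphi    rho
     1  13.06   8.566  3.089183 0.4555
     2  41.72  23.711 -2.963714 0.2848
     3 244.00 217.625 -0.007139 0.7639
  state   n mean_step se_step mean_turn
1     1 416      12.8   0.383    3.1046
2     2 389      42.8   1.152   -3.0095
3     3 395     249.5  11.258   -0.0129
```

The 3-state model wins by 142 AIC units and recovers the generating
emission parameters (true step means 11.4 / 37.7 / 244.3 m): a resting
state of ~13-m steps with turns concentrated at ±π (back-and-forth jitter),
a foraging state of ~42-m steps, and a traveling state of ~244-m
directionally persistent steps (ρ = 0.76 near μφ = 0). Viterbi decoding
matches the simulation's true states at 89% of steps. `run_pipeline()`
chains this with home ranges, covariates and the full RSF model grid
(8 HMMs, 4 GLMs, 12 GLMMs over two sexes × two seasons × three states).

## The analysis workflow

Numbered drivers under `analysis/` run the whole study on the synthetic
system and write their tables under `results/`:

```sh
Rscript analysis/01_simulate_study.R      # landscape + telemetry fixture
Rscript analysis/02_fit_hmms.R            # HMM grid, AIC table, decoding, diel profiles
Rscript analysis/03_home_ranges.R         # MCP + buffer, kernel home ranges, 90-m samples
Rscript analysis/04_resource_selection.R  # covariates, screen, 4 GLMs + 12 GLMMs, odds + AUC
```

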