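# mimicrEMG

A tested re-implementation of the analysis pipeline of a
placebo-controlled psychopharmacology study of **facial mimicry** —
the spontaneous, low-intensity imitation of an observed emotional
facial expression, measured with surface electromyography (EMG) of the
*zygomaticus major* (ZM, smiling) and *corrugator supercilii* (CS,
frowning) muscles while participants watch 5-s videos of faces morphing
between happiness and anger. Three between-subject arms (amisulpride, a
dopamine D2/D3 antagonist; naltrexone, an opioid antagonist; placebo)
allow a test of whether mimicry is a reward-driven response: the
study's headline result is a **null** — clear mimicry, no drug
modulation.

Because the original recordings are not required, the package ships a
synthetic-data generator that emulates the full design at the raw-signal
level (amplitude-modulated band-limited noise, 50 Hz line interference,
tonic baseline, injected outlier trials) with known ground truth, so
every stage of the pipeline can be validated by parameter recovery.

## The pipeline

1. **Preprocessing** — 20–400 Hz band-pass, 50 Hz notch, full-wave
   rectification, 40 Hz low-pass smoothing; epochs from −0.5 to 5 s;
   normalisation to the mean envelope of the 500 ms before stimulus
   onset; 2-SD outlier rejection per subject × muscle (epoch mean, epoch
   peak, and the same rules on the baseline segment); natural-log window
   means over five 1-s windows.
2. **Behavioural statistics** — χ² goodness-of-fit checks of group
   composition, one-way ANOVAs of demographics, pooled table summaries,
   within-subject RT z-scores with 2-SD outlier flags, and an
   emotion × drug mixed model on z-scored response times.
3. **Frequentist mixed models** — per muscle,
   `log_emg ~ emotion * drug * time` with by-subject random slopes for
   emotion, time and their interaction plus stimulus-face intercepts
   (lme4, REML, Satterthwaite F tests; a documented reduction ladder
   handles non-convergence), followed by per-emotion simple slopes.
4. **Hierarchical Bayesian asymptotic regression** — the within-trial
   time course is modelled as

   $$y = a - (a - b)\,e^{-e^{c}\,(t-1)}$$

   with asymptote `a` and log-rate `c` given one coefficient per
   drug × muscle × emotion cell (12 cells, no intercept), starting value
   `b` fixed at 0 (data are proportion of baseline at t = 1), and
   per-subject random coefficients for a, b, c in every
   muscle × emotion cell. Priors: Normal(0, 0.2) on `a`, Normal(−1, 1)
   on `c`, Half-Normal(0, 0.1) on random-effect SDs, Half-Normal(0, 0.5)
   on the residual SD. Sampling: 4 chains × 5000 iterations (first half
   warmup) with the package's blocked Gibbs sampler (an independent JAGS
   backend is provided as a cross-check); convergence is reported as
   split-R-hat for every parameter.
5. **Model comparison** — the nested family (full; drug on asymptote
   only; drug on rate only; no drug) compared by WAIC and PSIS-LOO,
   converted to normalized weights `exp(-Δ/2) / Σ exp(-Δ/2)`.

## Worked example

```r
library(mimicrEMG)

config <- desk_config(seed = 1)      # 12 subjects/arm, 24 trials, 600 Hz
truth  <- ground_truth()             # null drug effect, clear mimicry
sim    <- simulate_emg(config, truth, seed = 1)
prep   <- preprocess_emg(sim)
prep$outliers$excluded_fraction
#> [1] 0.1712963

fit <- fit_emg_lmm(prep$binned, "ZM")
round(fit$anova["emotion:time_c", c("F value", "Pr(>F)")], 4)
#>                F value Pr(>F)
#> emotion:time_c  49.529      0
simple_slopes(prep$binned, "ZM")
#>        emotion           b          SE         z            p
#> 1 HappyToAngry -0.02530274 0.004115792 -6.147721 7.860419e-10
#> 2 AngryToHappy  0.01785214 0.004087310  4.367700 1.255621e-05
```

About 17% of trial × muscle epochs are rejected by the 2-SD rules, and
the ZM shows the mimicry signature: activation rises over the five
windows for AngryToHappy videos (positive slope per window on the log
proportion-of-baseline scale) and falls for HappyToAngry, with a strong
emotion × time interaction. The Bayesian stage on the same data
(`sample_posterior(bayes_data(prep$binned), asymptotic_model_spec(), seed = 1)`)
mixes with a maximum split-R-hat of 1.0067 over all 469 parameters, and
the generating asymptotes fall inside the 90% posterior intervals for
11 of the 12 cells.

The numbered drivers under `analysis/` run the stages end to end at
desk scale and write their tables under `results/`:

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_preprocess.R
...
Rscript analysis/06_model_compare.R
```

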