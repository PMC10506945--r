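Package: mimicrEMG
Title: Facial-Mimicry EMG Pipeline: Preprocessing, Mixed Models, and
    Hierarchical Asymptotic Bayesian Regression
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A tested re-implementation of a placebo-controlled
    psychopharmacology analysis of facial mimicry measured with surface
    electromyography (EMG) of the zygomaticus major and corrugator
    supercilii muscles. Provides a synthetic-data generator emulating the
    study design (three drug arms, dynamic emotional face stimuli, raw
    EMG at the sample level), the full EMG preprocessing chain (bandpass,
    notch, rectification, smoothing, baseline normalisation, 2-SD outlier
    rejection, log proportion-of-baseline binning into 1-s windows),
    behavioural group statistics, frequentist linear mixed-effects models
    with Satterthwaite tests, a hierarchical non-linear Bayesian
    asymptotic-regression model of the within-trial activation time
    course, and WAIC / PSIS-LOO model comparison with normalized model
    weights over a nested family of drug-effect models.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    signal,
    lme4,
    lmerTest,
    rjags,
    coda,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
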