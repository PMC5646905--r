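Package: lost
Title: Latent Oscillatory Spike Train Models for Neural Point Processes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Bayesian inference of irregular oscillatory modulation in neural
    spike trains. A binned spike raster is modelled as a Bernoulli point
    process whose log-odds combine a latent autoregressive oscillation,
    a spline spike-history (refractory) term, a spline trial-average effect,
    and trial-specific baseline offsets. Posterior simulation uses Gibbs
    sampling with Polya-Gamma data augmentation and forward-filter
    backward-sampling of the latent path, with the autoregressive process
    parameterised by its characteristic roots under a structural
    stationarity prior. Includes stochastic-oscillation and spiking
    simulators (renewal and leaky integrate-and-fire), a mixture extension
    for trial-to-trial changes in modulation strength, circular-statistics
    diagnostics, and a spiking-history GLM baseline with time-rescaling
    goodness of fit.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    splines,
    tibble,
    ggplot2,
    generics,
    signal,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    dplyr,
    jsonlite
Config/testthat/edition: 3
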