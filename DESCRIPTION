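Package: gabadmf
Title: Whole-Brain Dynamic Mean Field Modelling with Receptor-Driven
    Inhibitory Gain
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates whole-brain resting-state activity with a dynamic
    mean field (DMF) model of coupled excitatory and inhibitory neural
    masses on a structural connectome, with feedback inhibition control
    (FIC) tuning, PET-map-driven modulation of inhibitory gain, and a
    Balloon-Windkessel haemodynamic forward model producing band-limited
    BOLD signals.  Provides sliding-window functional connectivity
    dynamics (FCD), one- and two-dimensional Kolmogorov-Smirnov model
    fitting, consensus connectome construction, weight-preserving random
    and lattice connectome null models, autocorrelation-preserving
    receptor-map surrogates, connectome-replacement experiments, and
    synthetic fixtures so the full pipeline runs end-to-end without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    tools,
    Rcpp,
    signal,
    stats,
    utils,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
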