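Package: proarisk
Title: Global Sensitivity Analysis of Myocyte-Derived Proarrhythmia Metrics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An analysis pipeline for variance-based and regional global
    sensitivity analysis of ventricular-myocyte model-derived torsades de
    pointes (TdP) risk metrics. Provides a pluggable paced-cell model
    interface with a bundled minimal ventricular model (MinCell) featuring
    dynamic hERG-drug binding, virtual-drug population generators (Saltelli
    low-discrepancy and kernel-density resampling), derived-feature
    extraction (qNet, APD, calcium-transient features), an
    early-afterdepolarization threshold protocol, Sobol, Monte Carlo
    filtering and permutation-importance sensitivity ranking, and tertiary
    torsadogenic risk classification of the 28 CiPA reference compounds.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: deSolve, stats, utils, jsonlite, yaml, ranger, nnet
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
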