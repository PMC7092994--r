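Package: cvreact
Title: Cerebrovascular Reactivity from Breath-by-Breath Gas Exchange
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for assessing cerebrovascular reactivity (CVR) under
    breath-hold and exogenous CO2 challenges. Extracts breath-by-breath
    respiratory gas-exchange metrics -- including the O2-CO2 exchange ratio
    (bER = dPO2/dPCO2) -- from sampled PO2/PCO2 traces, couples them with
    cerebral hemodynamic time series (transcranial Doppler blood flow
    velocity, BOLD fMRI) via Pearson correlation and Morlet wavelet
    transform coherence with Monte Carlo red-noise significance and a
    time-averaged coherence statistic, and maps regional CVR by voxelwise
    regression with Monte Carlo cluster-extent correction. Includes a
    synthetic-data module that simulates breath-hold protocols, gas traces,
    Doppler beat series and small 4D BOLD datasets with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    RNifti,
    signal,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    igraph,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
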