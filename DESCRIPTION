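Package: azogp
Title: Tanimoto-Kernel Gaussian Processes for Photoswitch Discovery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Prediction of the electronic transition wavelengths of
    azobenzene-derived photoswitches from SMILES. Molecules are represented
    as "fragprints" (a circular binary fingerprint concatenated with
    functional-group fragment counts) and modelled with exact Gaussian
    process regression under the Tanimoto kernel, either per task or
    jointly over the four pi-pi*/n-pi* transition wavelengths of the E and
    Z isomers via the intrinsic model of coregionalisation. Includes a
    benchmarking harness (repeated random splits, leave-one-out validation,
    confidence-error curves, paired Wilcoxon comparison), a sparse linear
    (Lasso) correction of physics-based TD-DFT wavelength predictions, and
    criterion-based virtual screening of SMILES libraries with ranked
    candidate reports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ChemmineOB,
    glmnet,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
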