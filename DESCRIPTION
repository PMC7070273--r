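Package: flavorfuse
Title: Electronic Tongue and Nose Data Fusion for Wine Age Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Feature-level fusion of electronic-tongue (pulse voltammetry)
    and electronic-nose (metal-oxide gas sensor) signals for discriminating
    and predicting the marked age of rice wines. Provides a seeded synthetic
    signal generator for both instruments, area-method feature extraction,
    direct and sensory-weighted feature fusion with Pearson/VIF
    multicollinearity pruning, PCA and locality preserving projections for
    class visualisation, and PLSR (NIPALS), extreme learning machine and
    RBF-kernel support vector regression of wine age with squared-correlation
    and mean-squared-error evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    e1071,
    jsonlite,
    pracma,
    stats,
    tools,
    utils
Suggests:
    ggplot2,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
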