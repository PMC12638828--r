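Package: dimstretch
Title: Task-Driven Dimensional Stretching of Neural Representations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
                  role = c("aut", "cre"))
Description: Tools for asking whether neural population codes stretch along
    task-relevant stimulus dimensions. Implements bivariate spike-train
    dissimilarity measures (ISI- and SPIKE-distance) with exact piecewise
    profiles, rate-coding distances with multi-site pooling, construction of
    representational dissimilarity matrices (RDMs) from multi-site session
    recordings, representational similarity analysis (RSA) with Spearman rank
    correlation over whole periods and sliding windows, a model-free
    dimensional-stretching test on mismatch stimulus pairs, an
    attention-weighted stimulus-geometry model fitted by cross-validated grid
    search with a mixed-context baseline, a seeded synthetic-recording
    generator with planted representational geometry, and a scaled-down
    rendered visuomotor task with a stacked recurrent (LSTM) classifier whose
    per-layer hidden states feed the same RDM machinery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils, graphics, grDevices, jsonlite, Rcpp
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
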