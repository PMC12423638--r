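Package: resectr
Title: Automated Delineation of Epilepsy-Surgery Resection Cavities in
    Pre-Operative MRI
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Automated generation of binary resection masks in pre-operative
    image space from paired pre- and post-operative T1-weighted MRI. Implements
    a three-part pipeline (data preparation with lobe-atlas assembly and bias
    correction; rigid plus deformable registration of the post-operative image
    into pre-operative space; prior-guided finite-mixture cavity classification
    with subtraction-image expansion and constrained morphological cleaning),
    together with mask-agreement statistics (Dice, Jaccard overlap, miss rate,
    false discovery rate, exact paired Wilcoxon signed-rank tests) and a
    synthetic 3D brain-phantom generator with known ground-truth resections for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    Rcpp,
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
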