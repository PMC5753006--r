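Package: lvfuse
Title: Rigid Registration and Quality Metrics for Fusing CT and 3-D
    Echocardiographic Left-Ventricular Geometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Feature-based rigid registration of segmented left-ventricular
    (LV) geometry between coronary computed tomography angiography (CCTA) and
    three-dimensional echocardiography (3DE). Implements three registration
    methods operating on segmentation outputs (a closed triangulated
    endocardial surface plus apex, mitral valve center and outflow tract
    landmarks): landmark distance minimization (rigid Procrustes/Kabsch
    without scaling or reflection), endocardial-surface iterative closest
    point initialized from the landmark fit, and three-chamber alignment via
    anatomical frame mapping. Provides the registration-quality metric suite
    (landmark distances, long-axis and transverse-plane angles, mean
    point-to-surface distance, cross-sectional Dice coefficient in the
    three-chamber plane), observer-variability measures on repeated
    segmentations, paired Wilcoxon signed-rank method comparison with exact
    p-values, a synthetic LV phantom generator with known ground-truth
    transform for validation, mesh and landmark file I/O (PLY, OBJ, VTK
    legacy, JSON), and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    pracma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
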