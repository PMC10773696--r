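Package: endofuse
Title: Endoscopy Frame Classification with Fused Handcrafted and Deep Features
Version: 0.1.0
Authors@R: person("Endofuse", "Authors", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A desk-scale pipeline for classifying gastrointestinal endoscopy
    frames into anatomical landmarks and abnormalities. Provides specular
    reflection detection and inpainting (fast-marching and diffusion based),
    class-balancing augmentation for severely imbalanced datasets, a bank of
    handcrafted texture and color descriptors (LBP, LTP, GLCM/Haralick, color
    histograms, auto color correlogram, MPEG-7 style color layout and edge
    histogram, Tamura, CEDD, FCTH, JCD, Gabor, PHOG), a MobileNet-V2 style
    deep feature extractor implemented in base R, a three-layer sigmoid
    classification network trained with a Nadam-style optimizer, per-class
    decision thresholds learned by a genetic algorithm, multiclass evaluation
    (macro F1, MCC, sensitivity, specificity, one-vs-rest AUC-ROC), and a
    synthetic endoscopy-image generator so the whole pipeline is verifiable
    offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    png,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
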