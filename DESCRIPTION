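Package: ansaedge
Title: Shallow Attention-Guided CNNs for Brain Tumor MRI Classification
    with Model Compression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Builds, trains and compresses a shallow attention-guided
    convolutional neural network for classifying brain tumors (glioma,
    meningioma, pituitary, no tumor) in 2D MRI slices. The architecture
    combines an l2-normalized spatial attention block (l2-SAB) with the
    parameter-free Gaussian Context Transformer (GCT) channel gate on a
    four-stage convolutional backbone. Five model-compression transforms
    are provided as model-to-model rewrites: depthwise-separable
    convolutions, reduced feature maps, low-rank adaptation (LoRA),
    canonical polyadic tensor decomposition of convolution kernels, and
    global magnitude pruning with masked fine-tuning. Evaluation support
    includes multi-class accuracy, precision, recall, F1 and specificity,
    Monte Carlo repeats, five-fold cross-validation, an accuracy/latency
    tradeoff factor, cross-dataset head adaptation, and Grad-CAM
    heatmaps. A synthetic head-phantom generator with ground-truth lesion
    masks makes the full pipeline runnable without any data download.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    EBImage,
    rhdf5,
    png,
    jsonlite,
    yaml,
    stats,
    utils,
    grDevices
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jpeg
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
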