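Package: chromqc
Title: Quality Evaluation of Extracted Ion Chromatograms and
    Chromatographic Peaks in LC/MS Metabolomics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for quality evaluation of extracted ion chromatograms
    (EICs) and chromatographic peaks in centroided liquid
    chromatography/mass spectrometry (LC/MS) metabolomics data.
    Implements region-of-interest (mass trace) EIC extraction, the mass
    chromatographic quality (MCQ) index family and a global zigzag index
    for EIC quality scoring, continuous-wavelet-transform ridge-line peak
    detection, six peak-level quality metrics (sharpness, Gaussian
    similarity, signal-to-noise ratio, peak significance level, triangle
    peak area similarity ratio, local zigzag index) with threshold
    filtering, consensus ground-truth benchmarking with
    Recall/Precision/F-Score, threshold-sweep drivers, and a synthetic
    chromatogram simulator with planted, fully known peaks.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    minpack.lm,
    mzR,
    stats,
    utils,
    withr
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    xml2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
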