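Package: vnschrono
Title: Cardiac-Synchronized Vagus Nerve Stimulation Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for designing and analysing cardiac-synchronized vagus
    nerve stimulation (VNS) experiments across cardiac innervation states
    (intact innervation, bilateral rostral vagotomy, isolated Langendorff
    hearts). Provides Latin hypercube sampling of burst parameters within
    configurable ranges, a synthetic generator of ECG recordings with
    stimulation logs and ground truth, Pan-Tompkins-lineage R-peak detection
    plus an online dynamic-threshold trigger, chronotropic response markers
    (relative heart rate reduction, stimulation charge, physiological
    threshold charge and charge normalization), and the group-comparison and
    correlation layer (Shapiro-Wilk gating, Kruskal-Wallis, Wilcoxon
    signed-rank, Spearman).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lhs,
    signal,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
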