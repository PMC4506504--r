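Package: lrclock
Title: Circadian Structure in Lateral Root Development Time Courses
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detection of circadian structure in short developmental
    transcriptome time courses, built around the analysis of a
    gravistimulated Arabidopsis lateral-root series (18 arrays x 4
    replicates spanning 54 h). Provides expressed/differentially-expressed
    gene filtering with pooled Benjamini-Hochberg correction, penalized
    smoothing-spline profile standardization, a hybrid block-wise
    Ward/k-means clustering with transcription-factor-guided centre
    merging, turning-point period estimation for oscillatory cluster
    means, a Kendall-tau rhythmicity screen against cosine rank templates
    with an exact small-sample null, PCA-based oscillation QC, and a
    seeded synthetic time-course generator with planted oscillatory,
    trend and flat gene classes for ground-truth benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3), SummarizedExperiment
Imports: methods, stats, utils, S4Vectors, jsonlite
Suggests: testthat (>= 3.0.0), mclust
Config/testthat/edition: 3
biocViews: TimeCourse, Clustering, GeneExpression, Transcriptomics
RoxygenNote: 7.3.3
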