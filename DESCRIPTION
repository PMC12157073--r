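Package: methydeep
Title: Deep-Learning Imputation of Plant Cytosine Methylation States
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts and imputes binary 5mC methylation states at plant
    cytosine sites in all three sequence contexts (CpG, CHG, CHH) from
    bisulfite cytosine reports. Combines a convolutional network over a
    1001 bp one-hot DNA window, a bidirectional-GRU model over the states
    and distances of the 25 nearest labeled cytosines on each side, and a
    joint classifier over both embeddings. Includes a self-contained
    neural-network engine, a synthetic methylome generator with planted
    sequence motifs and an autocorrelated latent methylation field, an
    imbalance-aware evaluation panel (ACC, ROC AUC, average precision, F1,
    MCC, TNR, TPR), and extraction of methylation-associated motifs from
    first-layer convolutional filters (PWMs, MEME export, activity PCA).
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
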