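Package: rffr
Title: Reduced Fully Flexible Receptor Ensembles from Binding-Cavity Clustering
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reduces a fully flexible receptor (FFR) model -- the full ensemble
    of molecular-dynamics snapshots of a receptor -- to a small representative
    ensemble (RFFR) for ensemble docking. Snapshots are described by four
    substrate-binding-cavity features (accessible surface area, cavity volume,
    heavy-atom count, backbone RMSD), min-max normalised, and clustered with
    k-means across a range of cluster counts. The optimal partition is chosen
    with the Davies-Bouldin index, Dunn's index, and the gap statistic, the gap
    statistic acting as the decisive criterion, and is validated against
    docking results by per-cluster median free energy of binding (FEB) across
    ligands. Includes a synthetic-data generator with planted cluster structure
    and cluster-dependent FEB means for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    bio3d,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
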