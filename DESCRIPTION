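Package: adlearn
Title: Exploitative Active Learning on Molecular Pairs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Active learning for potency optimization on small molecular
    datasets. Implements the ActiveDelta acquisition strategy, which trains a
    regressor on cross-merged molecular pairs labeled with potency differences
    and, at each iteration, acquires the candidate predicted to improve most
    over the current best training compound. Includes standard single-molecule
    exploitative and random baselines, Morgan/MACCS/atom-pair fingerprints,
    Bemis-Murcko scaffold analysis, Tanimoto nearest-neighbor similarity,
    top-decile hit-retrieval evaluation, chemical-space embedding (PCA followed
    by t-SNE), Wilcoxon signed-rank strategy comparison, and a seeded synthetic
    SMILES landscape generator so the whole pipeline is testable offline.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ChemmineR,
    ChemmineOB,
    Matrix,
    jsonlite,
    randomForest,
    tools,
    stats,
    utils,
    xgboost
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
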