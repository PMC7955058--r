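Package: me2vec
Title: Hierarchical Graph Embedding of Medical Services, Doctors, and Patients
Version: 0.1.0
Authors@R: person("EHR", "Embeddings", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Learns continuous low-dimensional embeddings for the three core
    entities of electronic health record (EHR) journey data. Medical services
    are embedded by biased second-order random walks over a time-windowed
    co-occurrence graph followed by skip-gram with negative sampling; doctors
    are embedded with a single graph-attention layer trained on an auxiliary
    primary-specialty prediction task; patients are embedded by converting the
    attributed patient-service-doctor multigraph into a simple patient-hybrid
    bipartite graph (duplication and annotation) and minimizing a second-order
    proximity Kullback-Leibler objective with negative sampling. Includes a
    synthetic patient-journey generator with planted ground truth, node
    classification and link prediction evaluation protocols, and a
    reproducible pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    glmnet,
    igraph,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
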