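Package: grnscore
Title: Inferability-Aware Assessment of Gene Regulatory Network Inference
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Benchmark scoring of gene regulatory network (GRN) inference
    methods that accounts for which edges are inferable from steady-state
    single-gene knock-out/knock-down data. Computes ensemble bounds on the set
    of networks indistinguishable from such data (transitive-closure upper
    bound, modified transitive-reduction lower bound), identifies non-inferable
    edges, scores ranked edge-list predictions with a redefined confusion
    matrix that excludes non-inferable edges, builds ROC/PR curves and AUCs,
    and ranks submissions against an empirical random-prediction null. Includes
    readers and writers for DREAM-style edge-list files, a synthetic generator
    of motif-structured gold standards and error-controlled predictions, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
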