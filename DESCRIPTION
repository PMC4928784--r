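Package: ploidytree
Title: Ploidy-Based Copy-Number Progression Trees from Single-Cell FISH Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers models of tumor progression from single-cell fluorescence
    in situ hybridization (FISH) copy-number counts that include a ploidy
    probe. For each gene probe a rooted (ploidy, gene) progression tree is
    estimated by expectation maximization over maximum-weight branchings,
    with unobserved (Steiner) intermediate states inserted along
    minimum-weight mutation paths. Per-gene trees are merged into a joint
    multi-probe tree by an exact mixed-integer linear program, and trees from
    paired samples of the same patient are compared through consensus graphs
    and node-, reachability- and path-sharing statistics. Includes a
    simulator of copy-number evolution under the same event model and the
    validation statistics used to assess parameter recovery, topology
    reconstruction, tree weight, and tree complexity (Shannon entropy,
    Simpson index, expected depth).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    boot,
    testthat (>= 3.0.0)
SystemRequirements: Python (>= 3.8) with scipy (>= 1.9) on the PATH, used to
    solve the tree-merging mixed-integer linear programs.
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
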