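Package: fs2ltgc
Title: Mechanism Inference for Long-Tract Gene Conversion at Yeast Fragile Site FS2
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Forward simulation and rule-based inference for the repair
    mechanisms that produce long-tract gene conversion (LTGC) at the yeast
    fragile site FS2 in an S288c x YJM789 experimental diploid. The package
    models the diploid genome as haplotype-blocked chromosomes, simulates
    candidate repair mechanisms (break-induced replication with late template
    switch, half-crossover resolution, gap repair including ectopic dual-BIR),
    generates per-SNP allele-fraction and depth-of-coverage observables,
    calls zygosity tracts, copy-number variants and abrupt allele transitions,
    emulates the physical assays (CHEF karyotype sizing, Southern probing,
    PCR-RFLP genotyping, junction microhomology analysis), and classifies each
    strain into the Coupling, Repulsion or Disjoined evidence group with its
    compatible mechanisms.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    Biostrings,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
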