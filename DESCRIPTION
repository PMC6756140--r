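Package: draftmap
Title: Pseudo-Testcross Linkage Mapping, Scaffold Anchoring and Genome
    Profiling for Draft Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for building genetic linkage maps from a single
    outcrossed pedigree (one heterozygous maternal plant, open-pollinated
    full-sib families) and for anchoring draft-genome scaffolds to the
    resulting linkage groups.  Implements VCF genotype filtering for
    maternal-testcross and single-parent-informative (sibling) marker
    sets, two-point recombination fraction and LOD estimation with
    single-linkage clustering into linkage groups, Kosambi map distances,
    marker ordering, consolidation of perfectly linked markers, and an
    iterative vote-ratio algorithm that propagates core linkage-group
    assignments to additional scaffolds.  Also provides macrosynteny
    comparison of linkage groups against reference pseudochromosomes
    (scaffold count matrices, mutual-best pairing, genetic-versus-physical
    dot series and monotone-run decomposition), assembler-bubble SNP probe
    selection for targeted enrichment, and k-mer based genome size and
    heterozygosity estimation.  A seeded simulator generates karyotypes,
    pedigrees, genotype observations, probe candidates and k-mer
    histograms so the whole pipeline can be exercised without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    Biostrings,
    igraph,
    methods,
    stats,
    utils,
    vcfR
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
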