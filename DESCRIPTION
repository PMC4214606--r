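Package: scaftier
Title: Ortholog-Guided Scaffold Curation, Tiered Chromosome Placement and
    Annotation Quality Control
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Toolkit for upgrading a fragmented draft genome assembly to
    chromosome level using comparative evidence from a well-annotated
    reference species.  Detects chimeric scaffolds from ortholog exon
    placements and breaks them at gap-aware coordinates; assigns, orders
    and orients scaffolds on chromosomes by a three-tier evidence scheme
    (radiation-hybrid marker order, FISH synteny blocks with ortholog
    positions, and reference-chromosome segment tiling) and emits AGP v2.0
    plus chromosome FASTA; evaluates gene models against ortholog proteins
    by global alignment with an explicit acceptance rule; validates GTF
    structure; filters mRNA reads for genomic contamination by best
    alignment length; and ships a seedable synthetic-genome simulator with
    complete truth tables so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    data.table,
    rtracklayer,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
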