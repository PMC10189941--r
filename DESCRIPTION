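Package: seqdbkit
Title: Proteoform-Aware Protein Sequence Database Management and Analysis
Version: 1.0.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for building, converting, filtering and analysing protein
    sequence databases for shotgun proteomics. Implements two derived
    database formats: SQPD, an SQLite-backed protein database whose tables
    mirror PEFF (PSI Extended FASTA Format) proteoform semantics, and SET, a
    JSON manifest naming a subset of entries of a parent database. Around
    these formats it provides FASTA and PEFF 1.0 readers/writers, UniProt
    feature-table ingestion, reversed-decoy generation, mature-proteoform
    extraction, small-ORF/SEP prediction on linear and circular transcripts,
    physicochemical property prediction (isoelectric point, instability
    index, GRAVY, extinction coefficients and more), motif counting, residue
    window extraction, and a registry of eighteen command-line tools.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    DBI,
    RSQLite,
    jsonlite,
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
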