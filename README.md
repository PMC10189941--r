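# seqdbkit

Protein sequence databases are the reference against which shotgun-proteomics
search engines interpret spectra, but plain FASTA cannot express what real
proteins look like in a sample: precursors lose signal peptides and initiator
methionines, chains are cleaved, residues vary and carry modifications
("proteoforms"). PEFF (the PSI Extended FASTA Format) encodes these as
structured key-value tags in header lines, yet as pure text it is slow to
create and parse at proteome scale.

`seqdbkit` is an R toolkit for building, converting, filtering and analysing
proteoform-aware protein sequence databases. It implements two derived
formats and the tooling around them:

* **SQPD** — a protein sequence database stored as a single SQLite 3.x file
  whose tables mirror PEFF semantics (`meta` key-values; `entries` with
  accession, sequence, precomputed length and average mass; `features` with
  a controlled kind, a 1-based inclusive range and a payload). Queries by
  accession, length, mass or feature kind run through SQL indices instead of
  reparsing text.
* **SET** — a JSON manifest naming a subset of a parent database: database
  identity plus an ordered list of unique accessions, no sequence text, so a
  subset of any proteome is a few kilobytes and resolves back to sequences
  against the SQPD.

Around these sit FASTA/PEFF readers and writers (UniProt, NCBI, Ensembl and
generic header dialects), UniProt annotation-table ingestion with the
UniProt→PEFF controlled-vocabulary mapping, reversed-decoy generation for
FDR estimation, mature-proteoform extraction, small-ORF/SEP prediction on
linear and circular transcripts (with back-splice junction-crossing counts),
ten physicochemical property predictors, motif counting, residue-window
extraction, and a registry of 18 command-line tools in five categories
(retrieval 7, generation 3, conversion 3, filter 2, analysis 3).

## Core models

* **Charge / isoelectric point.** Henderson–Hasselbalch over the ionizable
  groups: at pH $p$ a basic group of p$K_a$ $k$ contributes
  $+1/(1+10^{p-k})$, an acidic group $-1/(1+10^{k-p})$; the EMBOSS p$K_a$
  set is the default. The net charge is strictly decreasing in pH, and the
  pI is its unique root, found by bisection on $[0, 14]$.
* **Instability index** (Guruprasad): $\frac{10}{L}\sum_{i=1}^{L-1}
  \mathrm{DIWV}(s_i, s_{i+1})$ over the published dipeptide weights.
* **GRAVY**: mean Kyte–Doolittle hydropathy; **extinction at 280 nm** (Pace):
  $5500\,n_W + 1490\,n_Y$ reduced, $+125\lfloor n_C/2\rfloor$ with cystines.
* **Circular ORFs**: translation advances with the nucleotide index taken
  modulo the circle length $L$ and is bounded by frame closure — after at
  most three traversals (one when $3\mid L$) the reading frame repeats. Each
  passage over the $L\to 1$ back-splice junction from start through stop
  codon counts one junction crossing.

## Worked example

```r
library(seqdbkit)
set.seed(1)

# build a toy annotated proteome and store it as SQPD
entries <- random_proteome(50)
h <- create_sqpd("demo.sqpd", database_meta("demo", "1"))
add_entries(h, entries)
h
#> <SQPD demo v1 (custom): 50 entries at demo.sqpd>

# filter secreted-looking proteins under 20 kDa into a SET
s <- seq_filter(h, filter_spec(clause("feature_key", "has", "SIGNAL"),
                               clause("mass", "le", 20000)))
s
#> <entry_set 'filtered' (demo v1): 13 accession(s)>

# physicochemical report for one entry
annotate_properties(get_entry(h, s$entries[1]))
#> Property report for P00004
#>   length      104 aa
#>   mol. weight 12456.21 Da
#>   pI          6.49
#>   charge(7.4) -2.77
#>   ext (red)   35410 /M/cm
#>   ext (S-S)   35660 /M/cm
#>   aromaticity 0.173
#>   instability 88.57
#>   GRAVY       -0.438

# sORF prediction on a circular transcript
r <- find_sorfs_circular("circ1", "ATGAAAAAAA", min_pep = 1)
cat(sorf_name(r[[1]]), "->", r[[1]]$peptide, "\n")
#> circ1|F1|ATG|cir|1-24|J2 -> MKKNEKK
close_sqpd(h)
```

The 13 accessions are the entries carrying a `SIGNAL` feature whose stored
average mass is at most 20 kDa; the SET records only their accessions plus
the parent database identity. The circular ORF starts at position 1 of a
10-nt circle, reaches its stop on the third pass (linearized range 1–24),
crosses the back-splice junction twice (`J2`) and encodes the 7-residue
peptide `MKKNEKK`.

## Command-line tools

The umbrella script `exec/seqdbkit` exposes every registered tool as a
subcommand (`seqdbkit SeqFilter --help`); `--list-tools --json` dumps the
machine-readable registry. The same functionality is available in R through
`run_tool(name, argv)`.

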