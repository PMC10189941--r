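---
title: "seqdbkit: formats, models and design decisions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{seqdbkit: formats, models and design decisions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette is the package's own account of what it computes and why the
open design choices were made the way they were. It states no empirical
result that the test suite or `scripts/acceptance.R` does not itself
compute.

## The data model

Everything revolves around three record types. A `protein_entry` is one
database record: a unique accession, a source prefix (`sp`, `tr`, `ncbi`,
`generic`, ...), a description, an upper-case residue sequence and a list of
features. A `feature` is one proteoform annotation — a controlled kind
(`SIGNAL`, `CHAIN`, `PROPEP`, `TRANSIT`, `INIT_MET`, `VARIANT`, `MOD_RES`,
`CONFLICT`), a 1-based inclusive residue range, and a payload (the
replacement residue of a variant, or a modification name). A
`database_meta` carries the database identity (name, version, source,
sequence type, entry count, creation time) plus a free key-value map that
PEFF file headers pass through untouched.

Coordinates are 1-based inclusive throughout, following UniProt and PEFF
convention; any slicing converts at the call site. The amino-acid alphabet
is the 20 standard residues plus B, Z, X, U, O, J; these ambiguity/rare
letters are accepted on ingest but handled per consumer (see the property
model below). Nucleotide input is normalized RNA→DNA (`U`→`T`).

## SQPD: the relational rendering of PEFF

An SQPD file is a single SQLite 3.x database with three tables:

* `meta(key, value)` — identity rows (`db_name`, `db_version`, `db_source`,
  `sequence_type`, `n_entries`, `created`), a frozen `schema_version` row
  (`"sqpd-1"`, so a future migration is detectable), and pass-through
  extras.
* `entries(id, prefix, accession UNIQUE, description, sequence, length,
  mass, meta)` — one row per protein, with the length and the average
  molecular mass precomputed at insert time so that filters never
  recompute them, and the header key-values serialized as JSON in `meta`.
* `features(id, entry_id, key, start, "end", payload)` — one row per
  feature.

Indices cover `entries(accession)`, `entries(length)`, `entries(mass)`,
`features(entry_id)` and `features(key)`: fetching one of *n* entries by
accession is an index lookup, never a scan, which the tests assert through
`EXPLAIN QUERY PLAN` and a timing comparison against reparsing an
equivalent PEFF text file. Batch insertion is transactional — a duplicate
accession (under the default `error` policy) rolls the whole batch back,
so `n_entries` can never disagree with the table.

Table and column names are this package's own design; the schema version
row exists precisely because other renderings of the same idea exist.

## The UniProt ↔ PEFF vocabulary bridge

UniProt annotation tables (TSV downloads) carry feature cells in the
grammar `TYPE start..end; /qualifier="v"; ...`, with single positions as
`TYPE pos` and multiple intervals concatenated in one cell. The mapping
onto the feature model is: Signal peptide→`SIGNAL`, Chain→`CHAIN`,
Propeptide→`PROPEP`, Transit peptide→`TRANSIT`, Initiator
methionine→`INIT_MET`, Natural variant→`VARIANT` (payload = the
replacement parsed from `/note="X -> Y"`), Modified residue→`MOD_RES`
(payload = the note text), Sequence conflict→`CONFLICT`. Unknown types and
uncertain bounds (`<`, `>`, `?`) are skipped with a warning rather than
failing the row — a proteome-scale ingest should not die on one fuzzy
annotation.

On the PEFF side, processing features render as `Processed`
tuples `(start|end|term)` with the PEFF 1.0 terms (`signal peptide`,
`mature protein`, `propeptide`, `transit peptide`, `initiator
methionine`), single-residue variants as `VariantSimple (pos|residue)`,
and modified residues as `ModRes (pos|pos|name)`. The inverse mapping
recovers the feature list, which is what makes the
FASTA+table→SQPD→PEFF→SQPD round-trip lossless on (accession, sequence,
feature) triples. `CONFLICT` has no PEFF controlled term; exporting an
entry with one drops it with a warning. Multi-residue
insertions/deletions (`VariantComplex`) are passed through as raw tag text
in the entry metadata, not modeled.

## SET: subsets without sequences

A SET file is one JSON object with the frozen key set `{"format":"SET",
"set_name", "db_name", "db_version", "created", "description",
"entries"}`. The accession list is ordered (a list, not a set) so that a
downstream FASTA export is deterministic, and duplicates are rejected on
both write and read. Because no sequence text is stored, the file size
depends only on the number of accessions — the tests check that a SET over
a long-sequence proteome is byte-for-byte the same size as one over a
short-sequence proteome.

## The ORF model

Linear transcripts are scanned per frame (1–3 forward, 4–6 on the reverse
complement, coordinates on the scanned strand): each in-frame start codon
opens an ORF that extends codon by codon to the first stop. For a
terminated ORF, `3·|peptide| + 3 = end − start + 1` by construction.

Circular transcripts (mature circRNAs) are scanned at every forward
position — all three phases — with the read head advancing modulo the
circle length *L*. Translation stops at a stop codon or when the frame
closes: after exactly one traversal when 3 | *L*, and after three
traversals otherwise, because the phase at the start position cycles with
period 3. Junction crossings count the passages over the *L*→1 boundary
from the start codon through the stop codon inclusive; equivalently, with
linearized coordinates `start..end`, the number of multiples of *L* in
`[start, end − 1]`. Non-terminating ORFs are reported with
`terminated = FALSE` and the peptide truncated at frame closure (one
residue per nucleotide over three wraps when 3 ∤ *L*) rather than silently
dropped. Rotation of the circle permutes but never changes the set of
emitted peptides, which the tests exercise directly.

Defaults: start-codon set `{ATG}`, with a `near-cognate` preset
`{ATG, CTG, GTG, TTG, ACG}` reflecting common sORF practice; peptide
length bounds 7–100 (the shortest routinely identifiable tryptic-scale
peptide up to the conventional "small" ORF ceiling); forward strand only
for circles (the deposited circRNA sequence is the mature circle);
NCBI genetic-code table 1, other table ids accepted. Codons containing `N`
translate to `X`. ORF names are
`<transcript>|F<frame>|<start codon>|<lin|cir>|<start>-<end>[|J<crossings>]`,
made unique within a run by `_2`, `_3`, ... suffixes; this composed format
is frozen here and documented rather than inherited from elsewhere.

## The property model

Ten properties per entry. Mass is the sum of average residue masses plus
one water (18.0153 Da); a monoisotopic flag switches the table. Charge
follows Henderson–Hasselbalch over N-terminus, C-terminus and the K, R, H
(basic) and D, E, C, Y (acidic) side chains. The default p$K_a$ set is
EMBOSS (N-term 8.6, C-term 3.6, K 10.8, R 12.5, H 6.5, D 3.9, E 4.1,
C 8.5, Y 10.1); Bjellqvist is selectable. The model names the property but
not its parametrization, so the set is explicit, shipped as data, and a
flag. The net charge is strictly decreasing in pH, so the pI is found by
bisection on pH ∈ [0, 14]. The bisection converges on the pH axis (final
interval < 10⁻⁶) rather than stopping at a small residual charge: the
charge curve is nearly flat around the root, so a charge-only stopping
rule would return a pH several 10⁻³ away from the true root while already
satisfying |charge| < 10⁻⁴. For a peptide with exactly one acidic and one
basic group the result equals the closed form (p$K_{a1}$+p$K_{a2}$)/2,
which the tests check at 10⁻³.

Physiological charge is the net charge at pH 7.4 (flag to change).
Extinction coefficients use the Pace values (5500 W, 1490 Y, 125 per
cystine, with ⌊n_C/2⌋ pairs). Aromaticity is the F+W+Y fraction. The
instability index uses the published Guruprasad dipeptide weights,
averaged as (10/L)·ΣDIWV over the L−1 dipeptides. Grouped composition uses
the groups aliphatic AVLIMG, aromatic FWY, polar STCNQ, positive KRH,
negative DE, special P — one reasonable chemistry-based partition, frozen
and documented because the property list does not pin one down.

Nonstandard residues (B, Z, X, U, O, J) still count toward length and
composition but contribute zero to mass, charge, pI, GRAVY and
instability, with a warning; dipeptides touching one contribute zero
weight. This keeps proteome-scale annotation total rather than failing on
the occasional `X`.

## Filters, motifs, windows

Filters are conjunctions only — the disjunction-free design keeps every
clause pushable into an indexed SQL predicate (length, mass, feature kind,
accession list), with motif clauses evaluated in R on the SQL-narrowed
candidates; a disjunction is two runs and a manual merge. Filter output is
always a SET (ascending accession order), never sequences. Mass clauses
compare against the stored average mass with plain between/≥/≤ semantics,
not ppm windows. The motif grammar is residue letters, `x` for any
residue, and bracket classes (`N x [ST]` written `Nx[ST]`); counting is
fully overlapping (every start position tested). The same grammar serves
`count_motifs()` and the motif filter clause. Windows are always exactly
2·flank+1 wide, padded with `-` beyond the termini, so downstream
sequence-logo or kinase-motif tooling gets fixed-width input.

## Retrieval and the registry layout

All network logic goes through an injectable transport (a function from a
request description to `(status, body)`), so every parser is pure and
testable offline against canned payloads; endpoint URLs are configuration,
not constants, because REST APIs drift. Live HTTP uses base R connections
and is exercised only if a user points a tool at the network. The local
registry keeps `seqdbs/<db>/<version>/{classic,next}` with text formats
under `classic` and SQPD/SET under `next`; registration stages into a
temporary directory and atomically renames, so a failed build never leaves
a half-registered version.

## Command-line layer

All 18 tools are declared in one introspectable registry; a single
declarative argument model drives parsing, validation and the rendered
`--help` of every tool, so the self-describing property holds by
construction rather than by convention. The umbrella `exec/seqdbkit`
script maps each registered tool to a subcommand; per-tool invocation and
the umbrella dispatch share the same `run_tool()` path. Exit codes: 0
success, 1 usage error, 2 data error; diagnostics go to standard error and
outputs only to user-named paths.

## What the synthetic generator does and does not show

`random_proteome()` and `random_transcripts()` emulate the *shape* of real
inputs: UniProt-style headers and meta tags, signal/chain geometry
(signal peptides of 15–25 residues followed by the mature chain on about
half of entries), Poisson-placed single-residue variants and modified
residues, and the UniProt TSV cell grammar via
`synthetic_annotation_table()`. Residue usage is uniform and feature
placement random, so passing tests demonstrate parser, storage and
algorithm correctness — round-trips, oracle equivalence, invariants — but
say nothing about real-proteome statistics (residue frequencies, length
distributions, annotation density) or live endpoint behaviour.

Problem sizes used by the suite and the acceptance script, chosen to make
the checks decisive while keeping a full run in the order of a minute:
200-entry proteomes for round-trips, 50 transcripts of 30–600 nt for the
linear ORF oracle under both start-codon sets, 20 random circles for
rotation invariance, 100 randomized filter specifications against a
60-entry database, and a 10,000-entry featureless database for the
indexed-access timing comparison.

## Known limitations

* PEFF CRC64 tags are passed through, never computed or verified.
* `VariantComplex` (insertions/deletions) is passthrough text, not a
  modeled feature; `CONFLICT` features do not survive PEFF export.
* One PEFF file-header block per file; multi-database PEFF files are out
  of scope.
* No gzip transparency; no concurrent SQPD writers.
* Retrieval covers a single streamed request per payload — no pagination,
  mirroring or resumable downloads.
* The sORF predictor enumerates and translates; it does not score coding
  potential, Kozak context or ribosome-profiling evidence.
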