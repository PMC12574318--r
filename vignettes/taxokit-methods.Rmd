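---
title: "taxokit: models, algorithms and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{taxokit: models, algorithms and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(taxokit)
```

This vignette explains what each component of `taxokit` computes, the
assumptions baked into it, and the decisions taken where the design was
genuinely open. It states no empirical result that the test suite and
`scripts/acceptance.R` do not themselves compute.

## The report model and its conservation law

A Kraken-format report encodes a tree through indentation: each row's
parent is the nearest preceding row at a smaller depth (two spaces per
level). `taxokit` treats the report as the authoritative exchange object
and stores every row losslessly — the percent column as printed
(`percentText`), counts, rank code, taxid, name, depth, original row
index, and any extra trailing columns as an opaque string. Two invariants
are enforced on every read and construction:

* conservation: `cladeReads = taxonReads + sum(children cladeReads)`,
  exactly, with the "unclassified" pseudo-row (taxid 0) outside the
  hierarchy;
* printed-percent consistency: `|percent - 100 * cladeReads / total|`
  at most 0.01, i.e. twice the half-ulp of a two-decimal rendering, which
  tolerates both rounding and truncating writer dialects.

When a report is synthesized in code and no percent text exists yet, the
percent is formatted to two decimals, rounding half away from zero — the
convention of common report writers. A tiny epsilon (1e-9) is added before
the floor to keep values that are exactly representable halves from being
misrounded by binary floating point; this affects only formatting, never
counts. Counts are held as doubles (exact to 2^53), so reports far beyond
32-bit read counts survive round trips.

Rank codes are never normalized: digit-suffixed codes such as `S1` filter
under their leading letter but are stored and rewritten verbatim, because
NCBI, GTDB and ICTV taxonomies disagree on rank vocabularies and
normalization is a display concern. Merged-taxid resolution is deliberately
not implemented; a taxid absent from a loaded taxonomy fails lookup loudly
rather than being silently remapped.

## The Sankey graph and its round-trip validation

The graph is a view of the report, never a recomputation: each node copies
its row's proportion and clade count. Rows whose rank code's leading letter
is on the configured rank ladder become nodes at that ladder index; the
default ladder D, K, P, C, O, F, G, S covers the eight canonical ranks and
is configurable because GTDB and ICTV ladders differ. A node's parent is
its nearest report-tree ancestor that is on the ladder *at a strictly
smaller layer*, so a report that skips intermediate ranks produces links
spanning layers. A node with no such ancestor that is not itself at the
first layer hangs off a synthetic root (layer −1), keeping the graph
connected without inventing counts.

Everything not on the ladder — including the unclassified row — is carried
in a verbatim side table. This is what makes the validation possible: the
JSON document (`taxoview-json/1`, deterministic key and row order) contains
every field needed to rebuild each original line, and
`reconstructReport()` must reproduce the source report byte-for-byte. A
filtered graph has row-index gaps and reconstruction refuses it with a
completeness error rather than guessing.

Filtering decisions that the underlying idea leaves open:

* **Threshold semantics.** The proportion filter uses the *clade*
  proportion, matching the emphasis on clade read counts in the report
  model; a taxon-proportion filter would hide internal nodes whose reads
  sit in their children.
* **Composition order.** Thresholds (proportion, clade count, rank
  selection) apply first; the per-rank top-N cap applies to what remains.
  "Most abundant per rank" reads naturally as a cap on the displayed set.
* **Ties.** Top-N ties on clade reads break toward the smaller taxid —
  an arbitrary but total and stable order.
* **Orphaned descendants re-attach** to their nearest surviving ancestor,
  with the link still carrying the descendant's own clade count, instead
  of whole clades vanishing with a filtered-out parent. This keeps flow
  conservation displayable (every surviving node's incoming value equals
  its clade reads) at the cost of links that jump layers. A renderer that
  drops orphaned clades instead would show smaller graphs; this is a
  documented divergence risk.
* **Subtree re-rooting** gathers the chosen node's descendant closure,
  re-bases layers so the new root is layer 0, and then applies the same
  filters — except to the root itself, which the user explicitly asked
  for; filtering it away would make the operation's result degenerate in a
  confusing way. Proportions remain relative to the *original* total read
  count, so a subtree view still answers "how much of the sample is this?"
  rather than renormalizing to 100%.

## Read extraction by line number

The classification file preserves read order: line *i* describes read
(pair) *i*. Extraction therefore never matches id strings; it collects the
line numbers whose taxid falls in the target taxon's descendant closure
and copies exactly those records, verbatim, in order. Read ids serve only
diagnostics. Paired-end data has one classification line per pair and both
mates of a selected pair are written, which is the only reading consistent
with a classifier that treats the pair as a single query. Output format,
multi-line FASTA layout and gzip compression mirror the input. A line
number beyond the read file's record count is a hard consistency error —
it means the classification file and read file do not belong together.

The record reader is intentionally minimal (4-line FASTQ, multi-line
FASTA, whole-file in memory): extraction fidelity, not streaming
throughput, is the contract here.

## Incremental k-mer database updates

A database list holds (key, species taxid) records sorted ascending by
key then taxid with no duplicate pair. The update path builds the sorted
list of the new sequences only and merges it with the existing list in a
single streaming pass (implemented in C++): the smaller record is copied
out, records equal in both fields collapse, equal keys from different
species are all kept, and each input's sortedness is verified as it is
consumed. The concatenation of the two lists is never materialized. From
these mechanics follow the properties the tests assert: idempotence of
self-updates, commutativity and associativity up to record multisets, and
order-independence of successive updates.

Key encoding choices:

* Keys are plain 2-bit DNA codes (A=0, C=1, G=2, T=3) at fixed k
  (default 12). The merge is totally-ordered-key-agnostic, so correctness
  transfers to richer encodings (e.g. joint amino-acid/DNA keys); the
  simple code keeps the enumerate-sort-dedup oracle trivial.
* Forward strand only by default; `canonical = TRUE` takes the smaller of
  a window's forward and reverse-complement keys.
* Keys live in R doubles, exact for k ≤ 26 (4^26 < 2^53); larger k is
  rejected rather than silently losing precision. On disk each key is a
  little-endian 8-byte unsigned integer (written as two 4-byte halves),
  each taxid a 4-byte integer, with a JSON sidecar holding k, the record
  count and a format version — fixed-width, bit-exact, and inspectable
  via the TSV debug format.
* Windows containing a non-ACGT character are skipped; a k longer than
  every sequence yields an empty list, not an error.

The on-disk layout is this package's own model, not a reimplementation of
any production database format.

## Chain assembly: oracle and single-pass algorithm

A match is a (query codon position, diagonal) pair; the diagonal is query
position minus subject position, so equal diagonals mean co-linear
placement. Two matches are *consecutive* exactly when the second is one
codon to the right on the same diagonal. A chain scores its first match's
`fullScore` plus the `extScore` (the one added codon's contribution) of
every subsequent match. Scores are caller-supplied integers with
`fullScore >= extScore >= 0`; decoupling assembly from any particular
scoring function is deliberate, since the assembly logic is the
contribution being modeled.

The **oracle** is the classic two-scan formulation: build the digraph of
consecutive pairs, then depth-first-search from every source node and keep
the best-scoring path to a terminal (ties: earlier end). The
**single-pass** replacement sweeps the list once, keyed by diagonal: a
match at position n+1 extends the best chain that ended at n on its
diagonal (inheriting that chain's start and adding its own `extScore`),
or opens a new chain at its `fullScore`; chains with no consecutive
successor terminate and are emitted. An instrumentation mode counts match
inspections and the tests assert the count equals the list length.

Match lists must be unique on (query position, diagonal). With
consecutiveness defined purely by diagonal equality, duplicate cells would
make the two formulations disagree by construction (the graph spawns one
path per duplicated source, the sweep merges them), and a real k-mer match
cannot occupy the same read position and diagonal twice. The oracle emits
the best path *per source*; with the uniqueness precondition the
consecutive-match graph decomposes into disjoint simple paths, so
"per-source best" and "all terminated chains" coincide — which is exactly
why the two algorithms can be required to agree record-for-record.

Downstream selection sorts chains by score (ties: smaller start, then
smaller end) and greedily accepts chains whose closed codon intervals do
not overlap an accepted one — maximizing covered-region score in the
standard greedy sense, checked in the tests against an independent
re-implementation.

## What the generators simulate — and what they do not

`fixtureSpec()` states the simulated world once: 200 taxa on the canonical
eight-rank ladder, 1000 reads of 150 bp, 10% unclassified, and log-normal
leaf abundances (meanlog 0, sdlog 1) — the heavy-tailed
few-dominant-many-rare shape typical of microbial communities; uniform and
geometric models are available for tests that need controlled extremes.
Random taxonomies attach each new node to a uniformly chosen existing node
above the deepest rank, so trees are shallow-heavy like real taxonomies
but make no claim to realistic branching statistics. Reads are uniform
random DNA with constant quality: sufficient for positional extraction and
k-mer bookkeeping, useless for benchmarking classification accuracy — no
error model, no real genomic sequence, no abundance-length coupling.
Consequently, a green suite establishes format fidelity, algorithmic
equivalence and conservation laws; it says nothing about biological
classification performance.

Every generator seeds its own PRNG stream from (seed, generator name), so
adding a generator never changes existing fixtures and identical specs
yield byte-identical files. Match-list fixtures plant known chains and
then place noise matches only in cells that are not adjacent (on the same
diagonal) to anything already placed, so the planted (start, end, score)
triples must appear verbatim in any correct assembler's output.

## Degenerate inputs and numerical corners

* Empty report files parse to an empty report; an empty report yields an
  empty (but schema-valid) Sankey document.
* Zero-clade rows are legal and preserved; a report with all reads
  unclassified has a zero-count root row.
* Zero reads make all percents 0.00 and disable the percent-consistency
  check (there is no total to divide by).
* Empty FASTA input to a database update is an identity operation.
* Extraction of an empty line set writes empty files with zero counts.
* An empty match list assembles to an empty chain set.

## Known limitations

* The whole data model is in-memory; reports with millions of rows or
  read files beyond available RAM are out of scope.
* The classification-file dialect is the three-column prefix (flag, read
  id, taxid); extra columns are ignored, and richer per-read output
  layouts are not interpreted.
* The Sankey model covers data and filtering semantics only — no layout,
  coordinates, colors or interactivity.
* `--threads` on the command line is accepted for interface parity but is
  a no-op: every operation here is deterministic and single-threaded by
  design, so results can never depend on thread count.
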