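# taxokit

Post-processing toolkit for metagenomic taxonomic profiling — the headless
data layer behind interactive profiling applications (result tables, Sankey
taxonomy plots, taxon-specific read extraction, incremental reference-database
updates), built for people who analyze shotgun metagenomes with
Kraken-style classifiers.

## What it does

A taxonomic classifier assigns each sequencing read a taxid and summarizes
the sample in a **Kraken-format report**: one row per taxon with the percent
of reads, clade read count $c(t)$ (reads anywhere in the subtree rooted at
$t$), direct taxon read count $d(t)$, rank code, taxid, and a name indented
two spaces per hierarchy level. The format's invariant is the conservation
law

$$c(t) \;=\; d(t) \;+\; \sum_{u \,\in\, \mathrm{children}(t)} c(u),$$

which `taxokit` validates on every read and write. On top of this exchange
format the package implements:

- **Sankey graph model** — the report is mapped onto a configurable rank
  ladder (default D, K, P, C, O, F, G, S): on-ladder rows become nodes at
  their ladder layer, each linked from its nearest on-ladder ancestor with
  flow width $c(t)$. Filters (minimum clade proportion, minimum clade
  reads, top-N most abundant taxa per rank, rank selection) and subtree
  re-rooting reshape the graph. The model is validated by reconstructing
  the original report **byte-for-byte** from the graph's JSON document.
- **Taxon-specific read extraction** — reads classified under a taxon or
  any of its descendants are pulled out of FASTA/FASTQ files (gzipped or
  not, single- or paired-end) purely by classification line number, since
  the classification file preserves read order; records are copied
  verbatim.
- **Incremental k-mer database updates** — a database is a list of
  (k-mer key, species taxid) records sorted by key then taxid. Updating it
  builds the sorted list of the new sequences and merges the two lists in
  one streaming pass, collapsing records identical in both fields
  (same k-mer, same species) while keeping equal k-mers from different
  species. The original database sequences are never needed; the taxonomy
  can be extended with new taxa at the same time.
- **Match-chain assembly** — given a species' k-mer match list sorted by
  read position, co-linear matches (consecutive codon positions, equal
  diagonal) are assembled into chains scored as the first match's full
  score plus each extension's additional-codon score. Both the classic
  graph + depth-first-search formulation (kept as a reference oracle) and
  a single-pass algorithm that visits each match exactly once are
  implemented, and the test suite proves they emit identical chains.
- **Fixture generators** — seeded, fully deterministic generators for
  taxonomies, reports, classification files, reads and match lists, each
  with machine-readable ground truth, so everything above is testable with
  no downloads.

## Worked example

```r
library(taxokit)

spec <- fixtureSpec(seed = 42, nTaxa = 80, nReads = 2000)
taxo <- makeTaxonomy(spec)
prof <- makeProfile(spec, taxo)
prof$report
#> KrakenReport: 81 rows, 2000 total reads
#>   10.10  202  U  0  unclassified
#>   89.90  1798 R  1  root
#>   80.05  1601 D  2    superkingdom_2
#>   45.80  916  K  3      kingdom_3
#>   10.80  216  P  10       phylum_10
#>   ...
```

81 report rows summarize 2000 simulated reads: 202 (10.10%) unclassified,
1798 under the root, of which 1601 fall in superkingdom_2. Build the Sankey
graph, filter it, and verify the round trip:

```r
g <- buildSankey(prof$report)
g
#> SankeyGraph: 79 nodes, 76 links; ladder D>K>P>C>O>F>G>S ; total reads 2000 (unfiltered)
applyFilters(g, sankeyFilters(minProportion = 1, maxTaxaPerRank = 5))
#> SankeyGraph: 31 nodes, 29 links; ladder D>K>P>C>O>F>G>S ; total reads 2000 (filtered)
reconstructReport(sankeyToJSON(g))   # byte-identical to prof$report
```

The 79 on-ladder taxa shrink to the 31 that hold at least 1% of reads and
rank among the 5 most abundant of their rank; descendants of removed nodes
re-attach to their nearest surviving ancestor so flow is conserved. Rank
filtering of the table view and clade read lookup:

```r
head(filterRowsByRank(prof$report, "P")[,
       c("percentText", "cladeReads", "rankCode", "taxid", "name")], 4)
#>    percentText cladeReads rankCode taxid      name
#> 5        10.80        216        P    10 phylum_10
#> 15       10.60        212        P    44 phylum_44
#> 16        8.00        160        P    12 phylum_12
#> 23        7.40        148        P    45 phylum_45

length(matchingLines(prof$classifications, taxo$tree, 3L))
#> [1] 916    # reads classified under kingdom_3 or its descendants
```

Chain assembly on a three-match list (two matches on diagonal 0 at
positions 0 and 1, one on diagonal 3): the consecutive pair fuses into one
chain scoring 8 + 2, the isolated match stands alone at its full score:

```r
m <- matchList(queryPos = c(0, 1, 1), diagonal = c(0, 0, 3),
               fullScore = c(8, 8, 8), extScore = c(1, 2, 5))
assembleChains(m)
#>   startPos endPos score
#> 1        0      1    10
#> 2        1      1     8
```

## Command line

A thin wrapper around the same functions ships in `inst/scripts/taxokit`:

```sh
taxokit report validate report.tsv
taxokit sankey build report.tsv --min-prop 0.01 --top-n 10 -o graph.json
taxokit sankey roundtrip report.tsv        # exit 0 iff reconstruction exact
taxokit extract --classifications c.tsv --taxid 561 \
        --nodes nodes.dmp --names names.dmp --reads r1.fq.gz -o ecoli
taxokit db update db/ --fasta new.fa --map id2taxid.tsv --new-taxa taxa.tsv
taxokit chains fuzz --n 1000 --seed 7      # exit 0 iff oracle equivalence
```

## Acceptance script

`scripts/acceptance.R` re-runs the package's core computations from scratch
on seeded synthetic data — the byte-exact report/Sankey/report round trip,
single-pass vs graph+DFS chain-assembly equivalence, streaming merge vs
sort-and-deduplicate, extraction vs transitive-closure filtering, and
conservation/filter-monotonicity checks — and writes a JSON summary:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

A non-zero exit means one of the checks failed; diagnostics go to standard
error.

## Scope

The package is a data layer: no GUI, no plot rendering (D3/SVG/Krona), no
read quality control, and no classification engine — it consumes and
produces the classifier's standard output formats. The k-mer key encoding
is a plain 2-bit DNA code (the merge algorithm is encoding-agnostic);
on-disk layouts are this package's own and not compatible with any
external database format.
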