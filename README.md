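# varkv

A desk-scale query engine for genomic variation data, built on a
column-family key-value data model. `varkv` stores variants (SNVs, indels,
structural variants, translocation breakends), per-base coverage, genomic
features and coding consequences for many genomes in a single embedded,
byte-ordered store; loads them from SAMtools (classic) pileup, BED, GFF and
key-value annotation files; answers region, field and tag queries; exports
BED and WIG tracks; runs map-reduce-style analyses (variant-type counting,
tumor/normal somatic subtraction); and serves every query as a stateless,
bookmarkable HTTP URL.

It is aimed at people who want BigTable-style genome-database semantics —
position-keyed rows, column families, per-genome labels, cell versions,
secondary tag indexes, scan-based analysis — on a laptop, with no cluster
and no daemon.

## The data model

The store is a flat ordered map emulating a column-family table:

* **Row key** — a fixed-width, order-preserving encoding of
  `(contig index, 0-based start position)`. Sorting keys bytewise *is*
  genomic order, so a range scan is a genomic interval scan.
* **Column families** — `variant`, `coverage`, `feature`, `consequence`,
  fixed at table creation.
* **Labels** — one dynamic column qualifier per genome (e.g.
  `variant:genome7`), so identical variants in different genomes share a
  row and cross-genome comparison is a per-row operation.
* **Versions** — integer cell versions distinguish co-located variants in
  one genome (two alternate alleles at one locus are versions 1 and 2).
* **Tag index** — one secondary table per genome, keyed
  `tag ∥ 0x01 ∥ object-ID`, whose values point back at primary-table rows;
  tag queries never walk the primary table.

Coverage is stored sparsely: fixed-width blocks (default 1000 bases) hold a
map from in-block offset to read depth; uncovered bases are absent, never
zero. All internal coordinates are 0-based half-open; pileup (1-based), GFF
(1-based inclusive) and WIG (1-based) are converted at the I/O boundary.

The somatic detector is a map/reduce over the shared table: the map phase
keeps tumor variants that pass user-set quality criteria (supporting reads,
allele fraction, optional p-value) and have no same-allele call in the
matched normal; the reduce phase checks the normal's per-base coverage at
each surviving locus, and only loci where the normal was adequately covered
(default ≥ 10 reads) are reported as putative somatic mutations.

## Worked example

```r
library(varkv)

# a 100 kb synthetic reference and a pileup with planted variants
ref <- generate_reference(c(chrT = 100000L), seed = 42)
gp  <- generate_pileup(ref, mean_depth = 20, snv_rate = 1e-3,
                       indel_rate = 1e-4, seed = 42)

st <- store_create("mystore", "synth-ref")
load_pileup(st, gp$lines, "genomeA", min_observations = 1)
#> $variants_written
#> [1] 139
#> $blocks_written
#> [1] 100
#> $lines_read
#> [1] 100000

vs <- query_variants(st, "genomeA", region = "chrT:0-5000",
                     filter = variant_filter(min_observations = 5))
length(vs)
#> [1] 9
vs[[1]]
#> <variant SNV chrT:1139 A>G obs=13 depth=21 genome=genomeA v1

cat(export_bed(vs[1], NULL))
#> chrT	1139	1140	SNV|A>G|obs:13|depth:21|v:1

cov <- query_coverage(st, "genomeA", "chrT:0-6")
cat(head(export_wig(cov, NULL), 4), sep = "\n")
#> fixedStep chrom=chrT start=1 step=1
#> 26
#> 17
#> 20
```

139 variants were called from 100,000 pileup lines (every alternate allele
seen at least once), and per-base depths land in 100 coverage blocks of
1000 bases. The BED line shows the 0-based half-open locus and a name field
encoding type, alleles, supporting reads, total depth and cell version; the
WIG section is 1-based, so internal position 0 prints as `start=1`.

Tumor/normal subtraction on a synthetic pair:

```r
tn <- generate_tumor_normal(ref, germline_n = 200, somatic_n = 50,
                            mean_depth = 30, seed = 42)
st2 <- store_create("pairstore", "synth-ref")
load_pileup(st2, tn$tumor_lines, "tumor")
load_pileup(st2, tn$normal_lines, "normal")
calls <- detect_somatic(st2, "tumor", "normal")
length(calls)
#> [1] 50
```

All 50 planted somatic variants are recovered and none of the 200 germline
variants leak through (they are vetoed by their normal-sample calls).

## Command line

A thin `qe` script over the same functions ships in `inst/cli/`:

```sh
QE=$(Rscript -e 'cat(system.file("cli", "qe", package = "varkv"))')
Rscript $QE create --store mystore --reference synth-ref
Rscript $QE load pileup sample.pileup --store mystore --genome genomeA
Rscript $QE query variants --store mystore --genome genomeA \
    --region chrT:0-5000 --min-obs 5 --format bed
Rscript $QE somatic --store pairstore --tumor tumor --normal normal
Rscript $QE serve --store mystore --port 8470
```

With the server running, every query is a URL —
`http://localhost:8470/genomes/genomeA/variants?region=chrT:0-5000&format=bed`
returns exactly the CLI's BED bytes, `/genomes` lists all resources as XML,
and `browser_link("ucsc", url)` wraps a query as a UCSC custom-track link.

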