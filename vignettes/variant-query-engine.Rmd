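---
title: "A column-family key-value query engine for genomic variants"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A column-family key-value query engine for genomic variants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(varkv)
```

## The problem and the model

Whole-genome resequencing produces sparse, heavily annotated per-position
data: single-nucleotide variants, small indels, structural variants and
translocations, each with read support, quality metrics and free-form
annotations, alongside per-base read depth, interval features and coding
consequences — and usually for many genomes at once. Relational schemas fit
this badly; BigTable-style column-family stores fit it naturally, because
the data *is* a sparse matrix keyed by genomic position.

`varkv` implements that model at desk scale, in one process:

* The **row key** is the genomic start position, encoded order-preservingly
  (4-byte contig index, 8-byte position, big-endian), so bytewise key order
  equals genomic order and interval queries are range scans.
* Four **column families** — variant, coverage, feature, consequence — are
  fixed at table creation; new **labels** (one per genome) can be added at
  any time, so one table holds many genomes and identical variants in
  different genomes share a row. That co-location is what makes
  cross-genome operations (notably tumor/normal subtraction) simple per-row
  map/reduce operations rather than joins.
* Integer **cell versions** distinguish multiple values at one
  row/family/label — concretely, co-located variants in one genome, such as
  two alternate alleles at one site. Versions are assigned in load order,
  starting at 1, which keeps them deterministic and testable; all versions
  are retained.
* A **secondary tag table per genome** maps `tag ∥ 0x01 ∥ object-ID` to the
  primary row, so tag lookups (dbSNP membership, gene names, annotation
  flags) never scan the primary table. The 0x01 separator guarantees tag
  `a` can never prefix-match entries for tag `ab`. All four families are
  indexed uniformly. The index keys on the tag key only; tag-*value*
  filtering happens client-side after lookup.

The backing store is an environment-based ordered map, flushed to
plain-text table files; it honours the cell semantics above behind a small
generic interface (`put_cell`, `get_cells`, `scan_range`, plus typed
`write_*`/`query_*` wrappers), so a different embedded backend could be
substituted without touching loaders, queries or analyses. Values are
opaque single-line strings with a leading schema tag (`VAR1`, `COV1`,
`FEA1`, `CSQ1`); this versioned record encoding was chosen over per-record
JSON because both directions vectorise, which is what makes whole-table
operations at millions of records practical in R. Concurrency contract:
single writer, readers see flushed snapshots.

## Coordinates and conversions

All internal coordinates are 0-based, half-open. Conversions happen only at
the I/O boundary: pileup positions (1-based) lose one on entry; GFF
(1-based, inclusive) becomes `[start-1, end)`; BED is stored as-is; WIG
output adds one (`fixedStep` starts are 1-based). Region strings are
0-based half-open (`contig:start-stop`); `one_based = TRUE` accepts the
browser convention.

## Pileup loading and variant calling

The loader consumes classic 6-column single-sample SAMtools pileup
(multi-sample and mpileup dialects are rejected with a clear message). The
read-bases grammar is handled by a single-pass compiled tokenizer: `.`/`,`
are reference calls, letters are alternate calls (case-folded to the
forward strand), `^X` consumes a mapping-quality character, `$` closes a
read, `+n⟨seq⟩`/`-n⟨seq⟩` attach an indel to the preceding call, and `*` is
a deletion placeholder — a call token tracked separately that never becomes
a variant itself, since the deletion was recorded on its anchoring base's
line. **Token conservation** — call tokens consumed equals the depth
column — is enforced per line and doubles as the file-integrity check.

Every alternate allele observed at least `min_observations` times becomes a
variant (default 1: raw, unfiltered loading; filtering belongs to query and
analysis time, and the somatic detector in particular relies on unfiltered
normals so that any normal evidence can veto a call). Co-located calls get
versions in a fixed order — SNVs by alternate base, then insertions, then
deletions, each lexicographic. Deletions are anchored at the base carrying
the `-n⟨seq⟩` token, with `stop` spanning the deleted bases. Base qualities
are stored but not used for calling. Depths ≥ 1 accumulate into coverage
blocks (default width 1000 bases — large enough to amortise per-block
overhead, small enough that regional queries touch little excess data).

## Queries and export

Filters (`min_observations`, `min_depth`, `max_p_value`, `variant_types`,
`tag`/`tag_value`) combine by conjunction; an empty filter passes
everything. A `max_p_value` clause rejects variants with *no* stored
p-value — an absent value cannot demonstrate significance. When a tag
clause is present the query routes through the secondary index and applies
the remaining clauses afterwards; both routes return identical results, and
the test suite pins that equivalence.

BED export writes `chrom start end name` with the variant's metadata
encoded in the name (`type|ref>alt|obs:n|depth:n|v:version`); the encoding
is this package's own convention, stable and byte-deterministic. WIG export
has two modes: per-base `fixedStep step=1` runs, and block averages, where
each block's value is the arithmetic mean over the block's *covered* bases
only — uncovered bases are unstored, and dividing by the block width
instead would silently change every value, so the choice is documented
prominently. `export_genome_bed()` is a column-wise bulk path for
whole-table exports; it produces byte-identical output to
`export_bed(query_variants(...))` and exists because per-object
construction dominates at millions of records.

## Analysis: traversal, counting, somatic subtraction

`map_reduce()` is an in-process contract, not a distributed runtime: scan
rows in genomic order, map each row to keyed emissions, group by key with
values in emission order, reduce per key. Rows are internally processed in
contiguous partitions and the result is provably independent of the
partition count — the property a cluster backend would need, pinned by
property tests against a sequential oracle.

`detect_somatic(tumor, normal)` evaluates each tumor variant in the map
phase against user-specified criteria — minimum supporting reads (default
4), minimum allele fraction (default 0.1), optional p-value cap — and
vetoes it if the normal genome carries *any* call of the same type and
alleles at the locus, at any observation count. The reduce phase looks up
the normal's per-base depth at each surviving locus and reports
`PUTATIVE_SOMATIC` only where that depth reaches `min_normal_coverage`
(default 10): absence of evidence in an uncovered normal proves nothing.
"Good coverage" has no canonical numeric value, so the default is an
explicit stand-in and every threshold is exposed in the API and CLI.
Rejected calls carry their rejection reason when `report_rejected = TRUE`.

## The web service

The service is a pure function from `(store, path, parameters)` to a
response; the socket loop around it is a minimal single-threaded HTTP/1.1
server on base-R sockets, bound to localhost, with no authentication.
Statelessness is by construction: identical URLs return identical bytes for
an unchanged store, so queries can be bookmarked, mailed, or embedded in
UCSC/IGV custom-track links (`browser_link()`). BED/WIG/tags bodies are
produced by the same export functions the CLI uses, making service/library
equivalence byte-exact. Endpoint paths and parameter names are this
package's own (frozen in the route table at the top of `R/webservice.R`);
unknown parameters are rejected rather than ignored, so typos fail loudly.
XML documents are minimal and carry a `schemaVersion` attribute. The
paging offered on XML results is simple offset/limit.

## The synthetic-data generator

Every fixture is generated, seeded and self-describing; nothing is
downloaded. `generate_reference()` draws uniform ACGT contigs.
`generate_pileup()` draws per-base depths Poisson around `mean_depth`
(floored where variants are planted so counts fit), plants SNVs and short
indels at per-base rates with supporting counts binomial at an allele
fraction of 0.5, injects sequencing-error alleles at a per-read rate at
non-variant positions (uniform over the three non-reference bases; indel
errors are not simulated), decorates lines with read starts/ends, and
returns a truth set: planted variants with counts, a per-base depth map,
and the full error log. `generate_tumor_normal()` plants germline variants
in both genomes and somatic variants in the tumor only (distinct loci, 80%
SNVs), with counts that satisfy the default somatic criteria by
construction and normal depth floored (default 10) at somatic loci so
detector completeness is testable.

Study conditions used by the tests and the acceptance script: a 100 kb
reference at mean depth 20 with SNV rate 10⁻³ and indel rate 10⁻⁴ (about a
hundred planted variants), seed 42; a 10,000-variant tagged fixture for
query/index checks; a 200-germline/50-somatic pair at mean depth 30; and a
million-variant bulk load for the capacity exercise. These sizes keep a
full run in minutes on one CPU while leaving each property non-trivial.

What the generator does *not* emulate: real read simulation (no read
lengths, mapping qualities or alignment artifacts), strand bias, indel
sequencing errors, GC-dependent coverage, or contamination. Passing tests
therefore demonstrate the engine's bookkeeping — storage, indexing,
querying, subtraction — is exact under known inputs; they say nothing about
caller accuracy on real sequencing noise, which is out of scope (this
engine stores and queries calls, it does not make them beyond allele
counting).

## Numerical and design choices

* Positions are carried in doubles; the row-key codec refuses positions at
  or above 2⁵³, where doubles stop being exact. Chromosome coordinates are
  orders of magnitude below this.
* Contig order is a persisted dictionary, fixed at first sight of each
  contig (or declared up front at store creation). Row keys need a total
  order on contigs; registration order is deterministic for sorted input.
* Translocations are stored one record per breakend, with a `mate` tag
  naming the partner — a single-record representation would force an
  asymmetric choice of "home" locus.
* Block averages use covered bases only (see above).
* Tag keys may not contain control bytes (0x01 is the index separator);
  values are free text, percent-escaped in storage.
* Dangling index entries and dangling consequence back-references are
  skipped with warnings at query time rather than erroring — deletion
  support is minimal and a stale pointer should not poison a scan.
* Ties and ordering: query results are `(contig, position, version)`
  sorted; co-located calls from one pileup line order SNVs, insertions,
  deletions, each lexicographic.

## Known limitations

Single-writer, in-memory store with whole-table flush: suited to desk
scale (millions of rows), not to concurrent or out-of-core use. No VCF
import/export, no haplotype phasing, no genotype likelihoods, no
consequence *prediction* (a key-value consequence loader links annotations
produced elsewhere). The HTTP server is a convenience for local browser
integration, not a hardened public service.
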