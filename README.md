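# compactaln

Schema-evolvable, structured compression of high-throughput sequencing
reads and alignments, with lossless round-trip fidelity as the central
contract.

## What problem this solves, and for whom

Alignment files (BAM) and compressed FASTQ dominate the storage bill of a
sequencing lab, and the formats resist two things at once: *strong
compression* and *schema evolution* (new analysis methods need new fields,
but every tool that reads the format must not destroy data it does not
understand). `compactaln` is for bioinformaticians and pipeline authors who
need both: it stores reads and alignments in a chunked container with
pluggable codecs, and its structured codec compresses alignment data well
below general-purpose compressors while guaranteeing that fields added by
newer schemas survive read–modify–write cycles byte-identically.

## The method in brief

Records follow a tag–length–value schema; unknown tags are carved into an
opaque buffer and re-emitted verbatim (the schema-evolution mechanism).
Collections are stored as chunks of K ≤ 100,000 records, each framed with a
delimiter, codec registration code, length and CRC32, so a reader can seek
anywhere and scan to the next verifiable chunk (false-positive delimiters
are detected and skipped). Termination is `8×0xFF 4×0x00` at end of file.

Three codecs are registered: whole-chunk **gzip** and **bzip2** over the
serialized records, and **hybrid-1** — the ACT (Arithmetic Coding and
Template) codec:

* **separate field encoding** — transpose a chunk into per-field lists;
* **field modeling** — store residuals: position → successive deltas Δpᵢ =
  pᵢ − pᵢ₋₁; aligned length → L_query − L_aligned; target span →
  L_target − L_aligned;
* **template compression** — remove the fast-changing fields (query index,
  position, quality bytes), run-length collapse consecutive byte-identical
  templates (counts cᵣ with Σcᵣ = n);
* **domain modeling** — replace intra-chunk link triples (position, target,
  fragment) by signed entry offsets δ = j − i;
* each integer list is entropy-coded: RLE decision, then a symbol table +
  adaptive arithmetic coding (nibble and minimal binary codes for counts
  and uniform columns).

Method labels: **H** (neither), **H+T** (template), **H+T+D** (both).
Multi-tier layout: `.compact-reads` (Tier I), `.entries/.header/.index/.tmh`
(Tier II, stand-alone), `.perm` (Tier III query-index permutation).
Byte-level format: `inst/docs/FORMAT.md`.

## Worked example

```r
library(compactaln)

fx <- generate_alignment_fixture(fixture_rnaseq(100000, seed = 1))
cmd_benchmark(fx$entries, methods = c("bzip2", "H", "H+T", "H+T+D"))
#>   method   bytes ratio_vs_baseline
#> 1  bzip2 1217714         100.00000
#> 2      H 1263540         103.76328
#> 3    H+T 1144885          94.01920
#> 4  H+T+D  689791          56.64639
```

The fixture is a sorted, paired, spliced RNA-Seq-like collection of 100,000
alignment entries. `bytes` is the container size under each method;
`ratio_vs_baseline` is size(A)/size(bzip2)×100, so H+T+D stores the
collection in 56.7% of the space the bzip2 chunk codec needs. H alone is
*larger* than bzip2 here: explicit mate-pair triples are nearly
incompressible until template (T) and link (D) modeling remove their
redundancy — the reason the combined method exists. Every method is
verified lossless:

```r
cont <- write_collection(fx$entries, NULL, codec = "hybrid-1",
                         options = list(template = TRUE, domain = TRUE))
identical(read_collection(cont, "alignment")$entries, fx$entries)
#> [1] TRUE
```

SAM and FASTQ interop:

```r
sam <- generate_sam_fixture(fixture_exome(200, seed = 2))
imp <- import_sam(sam$sam, preserve_all_mapped_qualities = TRUE)
write_tier2(imp, "sample")            # sample.entries/.header/.index
out <- export_sam(imp$entries, imp$header, reference = sam$reference)
```

A thin command-line dispatcher ships in `inst/cli/compactaln`
(`sam-to-compact`, `export-sam`, `fastq-to-compact`, `export-fastq`,
`sort`, `recompress`, `stats`, `benchmark`, `fixtures`).

## Acceptance script

`scripts/acceptance.R` re-runs the package's end-to-end pipeline from
scratch: it generates the default sorted paired fixture from the given
seed, compresses it with all five methods, verifies that every round trip
is lossless, and writes a results JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

## Documentation

* `vignettes/alignment-compression.Rmd` — the methods vignette: model,
  parameter rationale, design decisions, what the synthetic generator does
  and does not emulate, limitations.
* `inst/docs/FORMAT.md` — normative byte-level format specification.
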