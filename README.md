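# moRquant

Detection and quantification of miRNAs, microRNA-offset RNAs (moRNAs) and
their sequence isoforms from small RNA-seq data.

## What problem does this solve, and for whom?

MicroRNA hairpin precursors produce more than the annotated mature miRNA:
the complementary **star** miRNA from the opposite arm, **moRNAs** from the
regions immediately flanking the hairpin, reads from the terminal **loop**,
and end/sequence variants of all of these (**isomiRs/isomoRs**). Standard
miRNA quantifiers leave moRNAs and loop reads uncharacterized. moRquant is
for transcriptomics researchers who want every product of each precursor
detected and counted with homogeneous, tunable criteria — from raw FASTQ, a
reference genome (FASTA) and a miRBase-style GFF3 annotation.

## Method in brief

Per sample:

1. **Preprocess** — 3' adapter trimming (error rate ≤ 0.1, partial match at
   the read end), length filter (18–30 nt), mean Phred ≥ 30, ≤ 2 bases below
   Phred 20; reads collapse to unique counted tags; tags with count <
   `MIN_COUNT` (10) are discarded as background.
2. **Genome filter** — exact both-strand matching; tags with > 5 exact hits
   *outside* precursor loci are discarded (multi-mappers); hits inside
   precursors never count against a tag, preserving multi-locus miRNAs.
3. **Hairpin** — each precursor is extended by 30 genomic nt per side and
   folded (maximum base-pairing, Watson–Crick + G:U, min loop 3; or an
   external dot-bracket per precursor). For a mature m with pairing partners
   p(·), the star is projected as the partner span shifted by the canonical
   2-nt 3' overhang:
   `star = [min p(m) + 2, max p(m) + 3)` (0-based half-open, transcript
   orientation), accepted when ≥ 60% of m is paired.
4. **Assign** — tags align to extended precursors with ≤ 2 mismatches
   (2-mm only at the two 3'-terminal read positions, i.e. non-templated
   addition); perfect alignments cluster into blocks seeded by the most
   abundant tag; blocks call expressed miRs, star-derived new miRs,
   data-driven moR coordinates (blocks in the flank windows, length ≥
   `MIN_MORNA_LEN`) and the loop sRNA; a conservative filter removes moRs
   sharing sequence with any miR; every alignment is assigned to the sRNA
   whose ends it matches within `ALLOWED_OVERHANG` (3 nt) or reported
   unassigned.
5. **Quantify** — each read gets one of 8 isoform labels (`canonical`,
   `mm1`, `mm2_3p`, `short5p`, `short3p`, `long5p`, `long3p`, `len_both`);
   counts aggregate per isoform and per sRNA; CPM = count / total × 1e6,
   optionally after dropping loop rows.

A seeded simulator (`simulate_dataset()`) generates genomes, hairpins,
annotations and FASTQ reads with planted truth for all five product types,
and is the basis of the package's end-to-end tests.

## Worked example

```r
library(moRquant)

dir <- tempfile()
sd  <- simulate_dataset(dir, seed = 1)        # 5 precursors, planted truth
cfg <- run_config(samples    = c(sample_1 = unname(sd$paths[["fastq"]])),
                  genome     = unname(sd$paths[["genome"]]),
                  annotation = unname(sd$paths[["annotation"]]),
                  ADAPTER    = "TGGAATTCTCGGGTGCCAAGG",
                  outdir     = file.path(dir, "out"))
res <- run_pipeline(cfg)

head(res$catalog[, c("name", "class", "chrom", "gstart", "gend", "strand")], 6)
#>       name   class  chrom gstart gend strand
#> 1 moR-1-5p     mor chrSim    288  308      +
#> 2 miR-1-5p new_mir chrSim    306  328      +
#> 3   loop-1    loop chrSim    328  348      +
#> 4 miR-1-3p     mir chrSim    348  370      +
#> 5 moR-1-3p     mor chrSim    368  388      +
#> 6 moR-2-3p     mor chrSim    832  852      -

head(res$counts, 8)
#>          sample_1
#> loop-1         25
#> loop-2         25
#> loop-3         25
#> loop-4         25
#> loop-5         25
#> miR-1-3p      500
#> miR-1-5p      120
#> miR-2-3p      120
```

The catalog lists every sRNA called for precursor `sim-mir-1`: the
annotated `miR-1-3p` (class `mir`), the structure-projected complementary
`miR-1-5p` (class `new_mir`), both flank moRs and the loop, with genomic
coordinates (minus-strand entries for `sim-mir-2`). The count matrix
reproduces the planted read counts exactly (500 per annotated miR, 120 per
star, 50 per moR, 25 per loop). CPM normalization excluding loop rows:

```r
round(head(cpm_normalize(res$counts, res$row_meta$is_loop), 3))
#>          sample_1
#> miR-1-3p   125628
#> miR-1-5p    30151
#> miR-2-3p    30151
```

Output files under `cfg$outdir`: `srna_catalog.gff3` (genomic catalog with
class attributes), `srna_counts.tsv` (sRNA × sample counts),
`isoforms.tsv` (per-isoform detail: offsets, mismatch positions, sequence,
count), `unassigned.tsv`, and `run_log.txt` (stage-wise in/out counts).

A command-line wrapper is exposed as `morquant_cli()`:

```sh
Rscript -e 'moRquant::morquant_cli()' run config.txt
Rscript -e 'moRquant::morquant_cli()' simulate simdir 42
```

where `config.txt` is flat `KEY=value` lines plus a `[samples]` section.

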