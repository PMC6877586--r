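# hybridscope

Parent-of-origin analysis of an interspecies hybrid's transcriptome,
sequenced as a trio with both parents.

When a hybrid animal (here modelled on a buck × ewe cross, a "geep") is
RNA-sequenced together with its sire and dam, two independent signals
reveal which parental genome each transcript is expressed from:

1. **Competitive dual-reference mapping.** Every read is aligned against
   both parental reference genomes and arbitrated read-by-read with a
   hierarchical score computed from the SAM CIGAR string alone:

   * matching bases `m = Σ len(M) + Σ len(=)` — more wins;
   * if equal, indel operations `i = #I + #D` — fewer wins;
   * if still equal, clipped bases `c = Σ len(S) + Σ len(H)` — fewer wins;
   * full ties are discarded.

   Reads mapped on one side only are unique to that side without scoring.
   The resulting unique-read partitions feed an FPKM-based transcriptome
   comparison (`FPKM = count · 10⁹ / (length · total mapped)`, threshold
   FPKM ≥ 1, uncharacterized `LOC…` symbols removed, top-N overlaps,
   four-set intersection counts, reference-set cross-references).

2. **Trio variant calls with allelic depths.** Sites where the parents
   are *alternatively homozygous* (one 0/0, the other 1/1) make every
   hybrid read diagnostic. The allelic depth ratio
   `r = |AD_ref − AD_alt| / (AD_ref + AD_alt)` is 1 for monoallelic and 0
   for balanced biallelic expression; signed 0.1-wide bins encode which
   parent carries the alternate allele. Homozygous hybrid calls yield
   per-variant parental origins that are merged into maximal same-origin
   blocks along the genome, and gene-level origins are cross-referenced
   against an imprinting database (concordant / discordant /
   unresolvable).

A synthetic-data module simulates the whole study design — two parental
genomes at configurable divergence, transcripts with expression levels
and planted parent-of-origin, indel-prone hybrid reads, analytic dual
alignments in two CIGAR dialects, and trio VCFs with planted
alternatively-monoallelic sites — with a full truth table, so every stage
is testable with known ground truth and no external data.

## Worked example

```r
library(hybridscope)
cfg <- run_config(sim = sim_config(seed = 1), top_n = 20)
rep <- run_pipeline(cfg, "geep_demo")
```

```
[simulate] 2000 reads, 4373 diagnostic sites, 3984/3984 VCF records
[assign] unique_a 882, unique_b 903, unmapped_both 0, discarded_tie 215
[quantify] 30 A-expressed, 27 B-expressed genes
[compare] venn over 36 genes
[alleles] alt-monoallelic sites: A=1168, B=1168
[imprint] 14 matched, 9 discordant
```

At the default 2% parental divergence, 100 bp reads and 0.5%/0.1%
substitution/indel sequencing error, 44.1% of hybrid reads are uniquely
assigned to genome A and 45.2% to genome B; the 10.8% discarded ties are
reads whose span contains no diagnostic difference between the genomes.
The planted hybrid biallelic fraction at alternatively homozygous sites
(0.74) is recovered from the simulated allelic depths as 0.745, and the
packaged imprinting cross-reference classifies its 14 matched genes into
4 concordant, 9 discordant and 1 unresolvable.

Per-stage functions are exported individually (`score_cigar`,
`assign_reads`, `compute_fpkm`, `venn4`, `select_alt_monoallelic`,
`signed_bin`, `build_blocks`, `crossref_imprint`, …); see the package
vignette for the model, parameter and design details.

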