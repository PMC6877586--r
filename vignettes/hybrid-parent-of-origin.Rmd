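---
title: "Parent-of-origin analysis of a hybrid transcriptome: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Parent-of-origin analysis of a hybrid transcriptome: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hybridscope)
```

# The problem

An interspecies hybrid carries one chromosome set from each parent
species. When the hybrid and both parents are RNA-sequenced, two largely
independent computations recover which parental genome each transcript is
expressed from: competitive mapping of the hybrid's reads against both
parental reference genomes, and allele-specific analysis of trio variant
calls at sites where the parents are fixed for different alleles. This
package implements both, plus the set-level transcriptome comparisons and
the imprinting cross-reference that interpret their output, and a
simulator that generates every input with known ground truth.

The two parental genomes are labelled A and B throughout. By the
conventions of the modelled cross, genome A is the maternal (dam) genome
and genome B the paternal (sire) genome; `origin_from_variant()` takes
this mapping as an argument (`parent_of_reference`) so other crosses can
flip it.

# Read arbitration by hierarchical CIGAR score

`score_cigar()` reduces an alignment to three non-negative integers read
off the CIGAR string alone:

* **matching bases**: summed lengths of `M` and `=` operations. `X` is an
  explicit mismatch and never counts. Aligners that emit the legacy
  dialect write every aligned base as `M`, so under that dialect
  "matching" really means "aligned"; the comparison is still informative
  because a mismatch-dense end is typically soft-clipped, and clipped
  bases are penalized at the third level.
* **indels**: the number of `I`/`D` operations (events). Counting events
  rather than bases is a genuine modelling choice — the alternative is
  kept behind `indel_metric = "bases"` — because a single 3 bp indel is
  one mutational/sequencing event, not three.
* **clipped bases**: summed lengths of `S` and `H`. Fewer clipped bases
  win the final tie-break: clipping removes evidence, so the less-clipped
  alignment is the better supported one. This direction is fixed, not
  configurable.

`N` (introns) and `P` contribute nothing at any level. `compare_scores()`
applies the strict lexicographic order (matches ↓, indels ↑, clips ↑);
`assign_reads()` sends reads mapped on one side only to that side without
scoring, discards full ties, and counts reads unmapped on both sides.
The four categories partition the input by construction, and the
partition, the A/B swap symmetry, and agreement with a brute-force
three-key comparator are enforced by property tests.

Percentages in `summarize_assignment()` are rounded half-up to one
decimal (`round_half_up()`), matching the reporting style of the study
this pipeline is designed after; base R's banker's rounding would make
printed percentages depend on neighbouring-digit parity.

# Expression comparison

`compute_fpkm()` is a deliberate stand-in for a full transcript
assembler: FPKM = count × 10⁹ / (length × total mapped), over transcripts
supplied as GFF3. The downstream comparisons operate on FPKM-thresholded
*gene symbol sets*, so assembly structure would add nothing testable
here.

Two boundary conventions deserve note:

* **The FPKM = 1 boundary.** "Neglect below 1" and "keep above 1" differ
  exactly at 1; `filter_expressed()` keeps the boundary by default and
  offers `strict_greater` to flip. No simulated quantity ever lands
  exactly on 1, so the choice matters only for real data.
* **Top-N rank ties.** `top_n_overlap()` breaks FPKM ties at the rank-N
  boundary by lexicographic symbol order, making the overlap
  deterministic.

Symbols are matched case-insensitively and stored upper-case;
uncharacterized genes (default pattern `^LOC\d+$` or anything containing
"uncharacterized") are removed before set comparisons because they cannot
be matched across species annotations. `venn4()` computes all 15 regions
of the four-set intersection via a membership bitmask and is checked
against per-gene enumeration.

# Trio-allele analysis

`select_alt_monoallelic()` keeps biallelic SNV sites where one parent is
0/0 and the other 1/1. At such sites every hybrid read is diagnostic:

* the **allelic depth ratio** |ref − alt| / (ref + alt) was chosen as the
  unique simple statistic that is 1 when all reads support one allele and
  0 when support is balanced. Zero total depth is a hard error — such
  sites must be filtered upstream.
* **binning**: magnitude = ceil(ratio × 10)/10 with a floor bin of 0.1,
  so a perfectly balanced site lands in ±0.1 and bin 1.0 is exactly
  monoallelic. A ratio landing exactly on an edge (e.g. 0.2 from depths
  6/4) stays in the lower bin. The ratio is rounded to 9 decimals before
  the ceiling so that binary floating-point noise cannot push an exact
  edge upward.
* **sign**: which parent's 1/1 is positive is genuinely ambiguous in the
  source material (its prose and its figure caption disagree), so both
  conventions are implemented — `"results"` (dam/maternal alternate
  positive, the default) and `"figure"` (sire/paternal positive) — and
  neither is declared correct. Swapping the parents' genotype columns
  exactly mirrors the histogram; this antisymmetry is a property test.

`origin_from_variant()` applies only where the hybrid is also homozygous:
a 0/0 call means the expressed transcript matches the reference the VCF
was called against, hence the parent whose genome that reference is; 1/1
points to the opposite parent. Heterozygous hybrid sites are excluded
with a counter. `build_blocks()` merges maximal runs of same-origin calls
per chromosome. Output intervals are 0-based half-open `[first_pos − 1,
last_pos)`, so an isolated call spans 1 bp; `min_variants` (default 1)
drops small blocks *after* merging, and surviving same-origin neighbours
are deliberately not re-merged, so the dropped evidence is never
silently bridged.

Multiallelic records are dropped with a counter; genotypes are
normalized to unphased form (1/0 ≡ 0/1); GT and AD are taken from the
VCF as given — no re-genotyping happens outside the simulator.
`impact_fractions()` tabulates snpEff-style impact classes (HIGH,
MODERATE, LOW, MODIFIER) per zygosity partition; sites lacking an
annotation are counted separately, never imputed.

# Imprinting cross-reference

`crossref_imprint()` classifies each gene present in both the origin
calls and the database: concordant when the poles agree, discordant when
they are opposite, unresolvable when the database reports biallelic or
conflicting evidence. Unresolvable entries are never counted as
discordant, and predicted database entries are treated exactly like
experimental ones; both rules are required for the packaged fixture's
counts (14 matched: 4/9/1) to be internally consistent. Species
qualifiers on database entries are annotation only — concordance is
judged on the pole alone.

# The simulator

`sim_config()` collects every tunable:

| parameter | default | meaning |
|---|---|---|
| `divergence` | 0.02 | substitutions/bp between parental genomes |
| `indel_divergence` | 0.002 | 1–3 bp indels/bp between genomes |
| `n_chromosomes`, `chrom_length` | 2 × 100 kb | genome geometry |
| `read_length` | 100 bp | hybrid read length |
| `n_reads` | 2000 | hybrid reads |
| `seq_error_sub`, `seq_error_indel` | 0.005 / 0.001 | per-base sequencing error rates |
| `frac_monoallelic_sites` | 0.3 | sites planted alternatively homozygous |
| `frac_hybrid_biallelic` | 0.74 | planted biallelic fraction at those sites |
| `mean_depth` | 50 | Poisson mean depth per site and sample |

No quantitative sheep–goat transcriptome divergence is established in
the source material, so 2% is a placeholder chosen to be comfortably
inside the regime where ~100 bp reads usually span at least one
diagnostic site; `divergence > 0.2` is rejected outright because the
A↔B coordinate maps become ambiguous. The error model is indel-prone
(semiconductor-sequencing-like) but deliberately crude: constant rates,
1–3 bp events, constant base quality. The planted biallelic fraction
default of 0.74 sits mid-way in the 72–76% regime the trio analysis is
expected to operate in.

Design points worth knowing:

* **Alignments are constructed from truth, not by running an aligner.**
  Against its genome of origin a read's CIGAR is exactly the recorded
  sequencing-error edit script. Against the other genome the read is
  aligned (Needleman–Wunsch, read-global, match 2 / mismatch −3 / gap
  open 5 / extend 2) to the truth-mapped window padded by 12 bp, so the
  CIGAR additionally reflects every diagnostic site the read spans.
  Placement is therefore always anchored at the known locus, and the
  zero-error regime admits exact statements: a read spanning ≥1
  diagnostic substitution is always assigned to its true genome, and a
  read spanning none is always a discarded tie (a property test).
* **Two CIGAR dialects.** `"extended"` distinguishes `=`/`X` and enables
  the exact-recovery proofs; `"legacy"` writes all aligned bases as `M`
  and soft-clips mismatch-dense read ends, reproducing the operating
  regime of older aligner output. The clipping rule: a run triggers when
  the outermost mismatch lies within 10 bp of the read end and at least
  2 mismatches chain with inter-mismatch gaps ≤ 10 bp; the clip extends
  from the read end through the innermost chained mismatch, and POS is
  shifted past left-clipped reference bases.
* **Trio VCFs are planted at the allele level** (A-genome vs B-genome
  allele per parental chromosome), so the two per-reference VCFs are
  automatically consistent with each other. The hybrid's genotype is
  re-derived from its simulated depths with a minor-fraction < 0.1
  threshold, mimicking a depth-driven caller; sites drawing zero depth
  are omitted. About 2% of sites get a missing parental genotype so the
  downstream counters are exercised.
* **Determinism.** All randomness flows from `sim_config(seed)`; each
  generator stage seeds itself from a fixed offset of that seed, so
  stages are reproducible individually and in any call order (arguments
  are forced before seeding — a lazily evaluated argument expression
  must not consume the seeded stream). Identical configurations produce
  byte-identical FASTA/FASTQ/SAM/VCF/TSV outputs and identical pipeline
  reports; both are asserted by tests.

What the simulator does *not* emulate — and what passing tests therefore
do not certify about real data: splicing and isoforms, strandedness,
empirical platform error profiles and quality strings, PCR duplicates,
mapping ambiguity from repeats or paralogs (alignments are
truth-anchored), multiallelic variation, and caller artefacts beyond the
simple depth threshold. The arbitration and trio statistics are exact
set/arithmetic operations, so their correctness transfers; the
*performance* figures (fractions assigned, discarded, recovered) are
properties of the simulation regime only.

# Problem sizes and tolerances

The test suite runs on 2 × 30–50 kb genomes with a few hundred to a
thousand reads per scenario, 10⁴ random score triples against the
comparator oracle, 10⁵ synthetic dual alignments for the partition and
swap-symmetry properties, and ~1.2 × 10⁴ planted trio sites at depth
Poisson(50) for the biallelic-fraction recovery at f = 0.72 and 0.76 —
sizes chosen so the whole suite completes in about a minute while every
binomial acceptance band (all set at ±3 SD) retains discriminating
power. Deterministic checks use exact equality; nothing is compared with
a hand-tuned numeric tolerance.

# Limitations

* FPKM is computed per supplied transcript annotation; overlapping
  transcripts double-count reads by design (`countOverlaps`).
* Origin blocks interpolate between variant calls; a block's bp span is
  evidence-bounded, not a claim that every base in between is expressed
  from that parent.
* The imprinting database fixture is a 14-gene table; the reader accepts
  any TSV in the same layout for larger databases.
* `run_pipeline()` currently always starts from simulation; applying the
  stages to external alignments/VCFs means calling the per-stage
  functions directly, which the per-stage readers (`pair_records`,
  `read_trio_vcf`, `count_reads_per_transcript`) support.
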