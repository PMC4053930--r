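---
title: "Assembling heterozygous diploid genomes and locating hemizygous sequence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assembling heterozygous diploid genomes and locating hemizygous sequence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hetasm)
```

## The problem

Short-read assembly of a diploid genome treats the two haplotypes as one
sequence. Wherever they differ — at heterozygous SNVs, or across diverged
chromosome pairs such as a neo-X/neo-Y system — the de Bruijn graph forks
and re-joins, producing *bubbles* that fragment the assembly. Conversely,
regions present in only one copy (the ancestral-X block of a male's neo-X,
with no homologue on the neo-Y) assemble cleanly and betray themselves
afterwards by their lack of allelic variation: near-zero SNV density when
the individual's own reads are mapped back.

`hetasm` implements this whole arc at desk scale: a de Bruijn assembler with
explicit bubble rules, mate-pair orientation filtering and s/n scaffolding,
transcript-evidence merging, per-scaffold SNV-density classification of
hemizygous candidates, and pooled-population SNP calling — driven by a
diploid genome simulator whose truth tables make every stage testable.

## The assembly model

Reads are decomposed into canonical k-mers (a k-mer and its reverse
complement are one node, represented by the lexicographic minimum; default
k = 25 for desk-scale genomes, with 64 the conventional choice for real
76–150 bp short-read data). Edges require an observed (k+1)-mer. Nodes
below `min_multiplicity` (default 2, the minimal setting that removes
isolated error k-mers) are pruned. Maximal non-branching paths become
unitigs, oriented and sorted canonically so the result is independent of
read order.

### Bubble rules

A bubble is a source/sink pair (u, v) where every walk leaving u
re-converges at v through a non-empty acyclic interior. The detector
requires at least two branches out of u, at least two branches converging
at v, interior closure (interior vertices reach only interior vertices or
v, and are reached only from interior vertices or u), and no interior dead
ends. Simple bubbles are the two-branch case in which the
out-neighbourhood of u equals the in-neighbourhood of v; everything else
is complex. Cyclic interiors are never bubbles. The detector is validated
against a brute-force oracle that enumerates every path on random graphs.

Three resolution rules apply, mirroring how heterozygosity expresses
itself in the graph:

* **Short rule.** Branches shorter than 3k that are substitution-only
  variants — equal length, at most two mismatches, all within one k-base
  window — are popped; SNVs further apart than k form separate bubbles and
  are popped individually. "Shorter than 3k" is measured on the branch
  sequences (the larger of the two), which keeps the short and long rules
  complementary: an isolated SNV yields branches of exactly 2k−1 bases,
  and two SNVs within k of each other at most 3k−2.
* **Long rule.** Branches of 3k or more are popped when a global alignment
  shows at least 90% identity. The alignment uses unit
  match/mismatch/gap costs, and identity is matches over alignment
  columns, so a 3-base indel in a 100-base branch scores 97%. Alignments
  whose length ratio already caps identity below the threshold are skipped
  without computing the DP.
* **Complex bubbles** are not collapsed to a representative branch.
  The whole interior is replaced by a span of Ns whose length is the
  longest u-to-v path through the bubble (interior bases only, computed by
  dynamic programming over a topological order, each junction absorbing
  the k−1 overlap); the span is floored at one N. The driver only
  N-spans bubbles whose interior vertices are each shorter than
  `max_span` (default 10k): a larger interior vertex is genuine unique
  sequence — a hemizygous block forms exactly such a "deletion bubble"
  against the other haplotype — and must stay in the assembly.

In every pop the branch with the most coverage is retained; coverage ties
retain the lexicographically smaller sequence (determinism). The other
branch is archived in the popped-record table and the auxiliary
popped-branch FASTA, never discarded silently. Nested bubbles resolve
innermost-first, with compaction and a re-scan between rounds.

### Scaffolding

Mate-pair libraries carry a chimeric short-fragment contaminant that
aligns forward-reverse instead of the expected reverse-forward.
`filter_matepairs()` partitions pairs into kept and removed: same-scaffold
pairs are classified FR/RF/other from strand-position geometry; unaligned
pairs are removed. Pairs whose mates land on two different scaffolds
cannot be FR/RF-classified at all (the scaffolds' relative layout is
unknown), so they receive their own `cross_contig` class and are kept by
default — they are the linking evidence scaffolding consumes. This is a
deliberate extension of the three-way orientation scheme; dropping them
(`keep_cross_contig = FALSE`) reproduces the stricter behaviour.

`build_scaffold_graph()` turns cross-scaffold pairs into ordered, oriented
links under two thresholds: `s`, the minimum contig size to consider
placing in a scaffold, and `n`, the minimum number of supporting pairs per
link. The published large-genome settings are s=500/n=10 for paired-end
assembly, s=1100/n=25 for a 6 kbp mate-pair library, and s=3400/n=3 for
10–12 kbp libraries; the package defaults are scaled to desk-size genomes
and both are plain arguments. Mate roles come from read order (read 1
reads the fragment start), which keeps links correct for
reverse-complemented contigs. The gap estimate is the mean over supporting
pairs of (fragment mean − flank spans) — the original estimator is not
published, so this package uses the simplest consistent one — with
negative estimates clipped to a single N. Because chimeras that straddle a
junction can fabricate a weak link in a wrong orientation, a link must
out-support any competing link on the same contig pair two-fold.
Chains are conservative: any side with two or more surviving links
terminates the chain, and link cycles are broken at the weakest link.

Transcript evidence merges scaffolds that expressed sequences span:
at least two spanning transcripts from at least two distinct libraries,
joined with exactly 100 Ns. "Spanning" requires at least 50 aligned bases
per scaffold within 10 kbp of the facing scaffold edge (both
configurable; the original criteria are unpublished). A transcript across
three or more scaffolds contributes evidence to each adjacent pair.

## SNV density and hemizygous scaffolds

The individual's own reads are mapped back to the assembly (a deliberately
minimal exact-seed/ungapped-extension mapper with the conventional
similarity 0.9 and length-fraction 0.5 filters; ties map nowhere — real
data would normally arrive as external SAM) and SNVs are called by pileup:
depth of at least 10, and at least two alleles each supported by two or
more reads making up at least 20% of the depth. That evidence rule is a
documented, configurable stand-in for genotype-likelihood internals.
Density is SNVs per kbp of non-N scaffold length.

Hemizygous candidates are scaffolds at least `min_classify_length` long
whose density falls at or below `threshold_fraction` (default 0.1) of the
median density of comparably long scaffolds. A relative threshold is used
because no absolute boundary between "very low" and background density is
published; the two-order-of-magnitude separation observed between
hemizygous-candidate and background densities in real data makes the
choice insensitive. The 50 kbp default classify length reflects
real-genome scaffold scales; the desk-scale simulations in the tests use
10 kbp.

## Pooled SNP calling

Pools of diploid individuals mapped as one dataset expose population
variation as allele fractions. A site is reported when the central base
quality reaches 20, depth reaches 20, and at least one non-consensus
allele has count ≥ 3 and frequency ≥ 6.25% — one chromosome in a pool of
eight diploids (1/16). The frequency denominator is total site depth. The
neighbourhood filter (window length 51) requires every base a read
contributes inside the centred window to meet the quality threshold; the
original tool's exact window semantics are proprietary, so the filter is
switchable (`window`, `central`, `off`). Morphism is the number of
distinct passing alleles, with "monomorphic" meaning fixed for a
non-consensus base. Region classification (exon > intron > intergenic,
GFF3 1-based inclusive coordinates converted internally to half-open)
partitions both the SNP catalogue and the non-N base count exactly, so
per-region densities are directly comparable.

## The simulator and what it does not emulate

`simulate_diploid_genome()` draws i.i.d. uniform ACGT chromosomes,
substitution-only heterozygous sites at a per-base rate (default 0.5%, a
plausible rate for a highly heterozygous insect; the organism's true rate
is not known), an optional repeat fraction as exact copies of a 500 bp
motif, and one contiguous hemizygous block centred on the first
chromosome so that haplotype B carries a clean deletion junction — the
ancestral-X analogue. Libraries emit FR paired-end or RF mate-pair reads
with Normal fragment lengths, a configurable chimera fraction (FR,
short-fragment), constant Phred qualities, and truth encoded in read
names (`sim:pair:hap:chrom:start:end:kind:chimera`).
`simulate_population()` plants population SNPs with known chromosome
counts (optionally tri-allelic) and `simulate_pool()` samples reads evenly
across all 2n chromosomes, returning an exact allele-frequency truth
table.

Real data differ in ways the simulator deliberately ignores: realistic
error profiles and quality ramps, indels and structural variation beyond
the hemizygous block, GC-biased coverage, and repeat families more complex
than exact motif copies. Passing tests therefore demonstrate the
correctness of the algorithms under their stated assumptions, not
robustness to every artefact of real sequencing.

## Numerical and design choices

* Canonical k-mer = lexicographic min of k-mer and reverse complement;
  unitig output is sorted by sequence; all tie-breaks (branch retention,
  chain starts) are lexicographic or id-ordered, making every stage
  byte-reproducible under a fixed seed.
* All randomness flows from explicit seeds; no stage touches global
  entropy.
* Coordinates are 0-based half-open internally and 1-based inclusive in
  every user-facing table, VCF and GFF3 surface.
* The k-mer counter packs k ≤ 31 into 64-bit words and falls back to
  string keys for larger k; both paths produce identical graphs.
* Degenerate inputs: zero-length scaffolds error in density computation;
  an even SNP window errors (it cannot centre); an empty assembly errors
  in the mapper; bubbles whose branches are too long to align are kept
  with a warning.
* Problem sizes in the tests — 200 kbp genomes at 40-fold coverage for
  assembly recovery, twenty 60 kbp genomes for heterozygosity recovery,
  30 kbp pools at 200-fold for SNP calling — were chosen as the smallest
  scales at which the statistical claims are meaningful.
* Tabular results (truth tables, alignments, site calls, summaries) are
  tibbles designed for dplyr/ggplot2 workflows; sequences stay plain
  character vectors and FASTA/FASTQ pass through Biostrings, because a
  genome and an assembly graph are not naturally tabular objects.

## Known limitations

Gap filling, misassembly correction and haplotype phasing are out of
scope. The internal mapper is ungapped and exact-seeded; highly divergent
or indel-rich reads should be mapped externally and supplied as SAM. The
N-span rule resolves only modest complex bubbles (`max_span`); large
tangles are left for mate-pair scaffolding. Pooled calling reports
allele fractions, not population-genetic statistics.

## A worked example

```{r example, eval = FALSE}
cfg <- pipeline_config(
  simulate = list(genome_length = 50000, heterozygosity = 0.005,
                  hemizygous_fraction = 0.2, seed = 5),
  mp_library = list(enabled = TRUE, fragment_mean = 5000,
                    fragment_sd = 400, coverage = 15,
                    chimera_fraction = 0.3),
  sexscan = list(min_classify_length = 5000))
res <- run_pipeline(cfg, out_dir = "hetasm_demo")
res$summary$overall_snv_density
res$sexscan$summaries
plot_snv_density(res$sexscan$summaries)
```
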