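---
title: "Methods: RNA-guided selection of neoantigen vaccine peptides"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: RNA-guided selection of neoantigen vaccine peptides}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The model

`neopept` selects synthetic-long-peptide vaccine candidates by combining
two independent prerequisites for immunogenicity — that the mutant
protein is actually made, and that its processed epitopes are presented —
into a single multiplicative score per somatic variant:

$$\mathrm{TotalScore} = \mathrm{ExpressionScore} \times \mathrm{BindingScore}.$$

**ExpressionScore** is a concave transform (default $\sqrt{\cdot}$) of the
count of RNA reads that support the mutant allele at the variant locus.
Using mutation-supporting reads rather than bulk gene expression (FPKM
or similar) makes the estimate allele-specific: a highly expressed gene
whose reads are all wild type contributes nothing. The score is not
normalized across samples because candidates are only ever compared
within one patient.

**BindingScore** sums, over every mutant epitope (all subpeptides of the
configured lengths that overlap at least one mutant residue) and every
patient HLA Class I allele, a logistic normalization of the predicted
IC50 affinity $a$ (nM):

$$s(a) = \frac{1}{1 + \exp\!\big(\beta(\ln a - \ln m)\big)},$$

with midpoint $m = 500$ nM and slope $\beta = 1$ by default. The midpoint
is the classical peptide–MHC binder threshold, so $s(500) = 0.5$ exactly;
the function is strictly decreasing, maps $(0,\infty)$ into $(0,1)$, and
is symmetric on the log scale: $s(mx) + s(m/x) = 1$. The published
description of this scoring leaves the fitted scale and offset to a
figure, so both parameters are explicit, defaulted, and configurable
here; every numerical claim the package makes about them is what the
code computes, nothing more.

There is no deep justification for the product form beyond independence
of the two prerequisites; a variant with zero expression or zero
predicted binding cannot rank, which is the intended behaviour.

## Why the mutant sequence comes from RNA

Protein-effect annotation of a DNA variant in isolation is not
sufficient to write down the vaccine peptide. The transcript actually
expressed decides the reading frame, and other variants — germline or
somatic — within the peptide window co-determine the sequence. A single
RNA read spanning both loci proves they co-occur on one molecule, so the
package assembles the coding sequence directly from the
mutation-supporting reads:

1. **Read evidence.** Reads overlapping the locus are decomposed via
   their CIGAR into (prefix, allele, suffix) around the variant interval
   and partitioned into alt / ref / other by exact allele match. Filters
   (defaults: MAPQ ≥ 1, no duplicate/secondary/supplementary flags, base
   quality ≥ 20 over the locus) are config-exposed; they are common
   practice, not published values. Reads that span the locus through a
   splice (`N`) gap carry no base evidence and are never counted as
   deletion support. Soft-clipped bases are excluded: unaligned sequence
   cannot be placed confidently. Two mates of one template that both
   support the mutation count once (fragment counting) unless
   `count_mates_separately` is set.
2. **Grouping.** Alt reads are grouped by agreement on every overlapping
   base relative to the variant anchor. For ≤ 20 reads the largest
   mutually-compatible set is found exactly (maximal-clique search,
   iterated); beyond that a deterministic greedy insertion (longest span
   first, then lexicographic) is used. The exact path exists because an
   order-greedy pass can absorb a read into a group whose consensus it
   only accidentally agrees with, which would break the package's own
   maximality invariant.
3. **Assembly.** The most abundant group wins; ties break by longer
   consensus, then lexicographically smaller sequence — determinism over
   biological judgement, since a tie carries no evidence either way.
   Whatever neighbor alleles the supporting reads carry are thereby
   retained: phasing is a property of the data structure, not a separate
   algorithm. Germline and somatic neighbors are deliberately not
   distinguished at assembly time.
4. **Anchoring and translation.** The consensus is reoriented to the
   coding strand, trimmed to the CDS overlap, and its frame offset
   computed by positional arithmetic from the variant's CDS coordinate
   (read prefixes are contiguous in spliced-transcript coordinates, so
   the arithmetic survives exon junctions). Among multiple coding
   transcripts the longest in-frame CDS overlap wins (ties: longer CDS,
   then lexicographic id). Translation stops at the first stop codon;
   codons containing `N` become `X` to preserve positional alignment.
   For frameshifts, every residue downstream of the shift is mutant
   until the stop. The protein is trimmed to 12 residues either side of
   the mutant interval, supporting 25-mer windows downstream; trimming
   is by residues, not nucleotides (the source description does not say
   which; residues keep window arithmetic exact).

Variants are dropped — with a logged reason, one record per variant — at
the first stage that disqualifies them: silent/non-coding effect, fewer
mutation-supporting reads than `min_alt_rna_reads` (default 3; a
tunable, not a published value), no group meeting that threshold, no
transcript yielding a frame, or a stop codon before the mutant interval.
Stop-gained variants are excluded outright: no novel residues exist
downstream of a premature stop, so there is nothing to vaccinate
against.

# Tunable parameters

| parameter | default | unit | rationale |
|---|---|---|---|
| `peptide_length` | 25 | residues | published SLP length; 25 residues = 75 coding nt |
| `epitope_lengths` | 8–11 | residues | published Class I ligand lengths |
| `max_candidates` | 15 | peptides | published synthesis order size |
| `binding_midpoint_nm` | 500 | nM | the only published calibration anchor |
| `binding_slope` | 1 | – | log-scale logistic slope; published fit not reproduced in text |
| `expression_transform` | `sqrt` | – | concavity keeps expression from swamping binding; `identity`, `log1p` available |
| `min_alt_rna_reads` | 3 | reads | tunable floor, not a published value |
| `min_mapq`, `min_baseq` | 1, 20 | – | common-practice read filters |
| manufacturability thresholds | 3 Cys, 2.5 KD, 7-residue C-window | – | standard solid-phase failure modes |

Manufacturability flags (excess cysteine, Q/E/C N-terminus, N–P bond,
extreme mean Kyte–Doolittle hydropathy, hydrophobic C-terminus) never
alter a score: by default they are reported and break exact score ties;
`manufacturability = "strict"` excludes flagged windows, `"off"`
disables screening. Only cysteine minimization is published; the other
four are standard synthesis failure modes, individually visible in the
report and disableable.

# The synthetic data generator

`generate_fixture()` emulates exactly the world the pipeline claims to
handle: a small multi-transcript genome (60-codon CDSs beginning `ATG`,
free of internal stops), plus- and minus-strand transcripts, single- and
two-exon structures (90-nt introns), planted somatic SNVs and small
indels with configurable depth (default 60), alt fraction (default 0.5,
matching an assumed heterozygous variant in a pure expressed tumor
clone), base error rate (default 0.001, Illumina-like), 125-bp
single-end reads (the published protocol read length), and optional
germline neighbors 21 nt (7 codons) from the somatic variant — within
one read length, mirroring the published phasing example. Alt-haplotype
counts are exact (`round(depth × alt_fraction)`), reads carry correct
spliced CIGARs (`M/I/D/N`), indels are left-aligned at generation so
read CIGARs agree with VCF normalization, and a JSON manifest records
per-read haplotype labels and per-variant expected protein windows
computed by editing the annotated CDS directly — an independent route
from the read-assembly path the tests exercise.

What the generator does **not** model, and hence what a green test does
not establish: alignment artifacts (the reads are emitted pre-aligned),
soft-clipping, strand bias, duplicate structure, realistic quality-score
profiles, FFPE damage, paired-end fragment geometry (a paired mode
exists only to exercise fragment counting), heterozygous germline
variants on the reference haplotype, isoform mixtures, and fusions.
Results on real tumor data depend on upstream callers and aligners in
ways these fixtures cannot probe.

# Numerical and degenerate-input choices

* Coordinates are 0-based half-open everywhere internally; conversions
  live only in the GTF/VCF readers and report writers.
* Variant normalization trims shared prefix/suffix bases and left-aligns
  pure indels until a mismatching base blocks the shift; it is
  idempotent and errors loudly on reference mismatch.
* All orderings that could depend on session locale use C-locale radix
  sorting; two runs with identical inputs produce byte-identical reports
  (the echoed configuration contains input paths, which the determinism
  tests exclude when inputs live in different directories).
* Empty inputs degrade, they do not crash: an empty VCF yields an empty
  report with a warning; fewer surviving variants than `max_candidates`
  is logged (the published protocol's "fewer than 15" rerun condition is
  upstream of this package and out of scope).
* The toy MHC predictor is a documented closed form — anchor-position
  weights per allele mapped log-linearly onto [1, 50000] nM — chosen for
  determinism and monotonicity, with no claim of predictive accuracy.
  Real predictions enter through the TSV affinity table.

# Known limitations

* One candidate is reported per variant (its best window); splicing
  multiplicity is collapsed to the best-anchoring transcript rather than
  emitting one candidate per distinct protein.
* Wild-type epitope subtraction (penalizing epitopes identical to self)
  is not performed.
* Splice-site disruption is not modelled; variants near intron
  boundaries are classified by their CDS edit and noted in messages.
* The greedy grouping path (> 20 alt reads) is heuristic; its exactness
  guarantee holds only at or below the clique-search threshold.
* Identical peptides arising from different variants are kept, not
  deduplicated.
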