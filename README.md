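# neopept

Selection and ranking of candidate synthetic-long-peptide (SLP) vaccine
sequences for personalized cancer neoantigen vaccines, in R.

## The problem

A therapeutic neoantigen vaccine is built from ~25-residue peptides, each
containing a somatic mutation from the patient's tumor. Choosing those
peptides well requires more than annotating a VCF:

* the **actual mutant protein sequence** depends on which transcripts are
  expressed and on *other* variants (germline or somatic) lying near the
  mutation on the same molecule — a variant 7 codons away changes the
  vaccine peptide, and ignoring it produces a peptide the tumor never
  makes. Single RNA reads spanning both loci phase them for free;
* **abundance** should be allele-specific: all reads over a gene can be
  wild type while none support the mutation;
* peptides must bind the patient's **HLA Class I** molecules as 8–11-mer
  processed epitopes;
* peptides must survive **solid-phase synthesis** (cysteine content,
  problematic termini, hydrophobic stretches).

`neopept` implements this selection core: from somatic variants (VCF),
tumor RNA alignments (SAM/BAM), a reference genome (FASTA), transcript
annotations (GTF) and the patient's HLA alleles, it

1. classifies protein-level effects per transcript and discards silent /
   non-coding variants;
2. collects RNA reads over each variant locus, partitions them by
   supported allele (CIGAR-aware, quality-filtered), and assembles the
   most abundant mutant coding sequence from the mutation-supporting
   reads — retaining any phased neighbor alleles those reads carry;
3. anchors the assembled sequence to a transcript reading frame and
   translates it;
4. scores every candidate 25-mer window containing the mutation:

   ```
   TotalScore = ExpressionScore x BindingScore
   ExpressionScore = sqrt(# mutation-supporting RNA reads)
   BindingScore    = sum over mutant epitopes (lengths 8-11) and patient
                     alleles of 1 / (1 + exp(slope * (ln aff - ln 500 nM)))
   ```

   The logistic normalization is anchored so that the classical 500-nM
   binder threshold scores exactly 0.5;
5. flags manufacturability problems and emits a ranked report truncated
   to the top 15 candidates.

MHC affinity prediction is pluggable: a deterministic built-in toy
predictor (position-weight anchor scoring) keeps the pipeline
self-contained, and pre-computed predictions (e.g. NetMHCpan output) can
be supplied as a TSV affinity table.

A deterministic synthetic-data generator (`generate_fixture()`) builds
toy genomes, annotations, somatic VCFs and spliced, aligned RNA reads —
with per-read ground truth — so the whole pipeline is testable offline.

## Worked example

```r
library(neopept)

# a synthetic patient: 3 somatic SNVs, each with a phased germline SNP
# 21 nt downstream, 60x RNA depth at 50% allele fraction
fx <- generate_fixture(
  simple_fixture_spec(n_variants = 3, seed = 7, base_error_rate = 0,
                      with_neighbor = TRUE),
  "fx")

cfg <- pipeline_config(vcf = fx$vcf, bam = fx$sam, ref = fx$fasta,
                       gtf = fx$gtf, hla = c("HLA-A*02:01", "HLA-B*07:02"),
                       out_dir = "out")
rep <- run_pipeline(cfg)
print(rep)
```

```
RankedReport: 3 candidate(s)
  1. chr1:291 T>A  RAFNPSLVPRCMNDFFSWPSLLRFV  total=98.3117 (expr=5.477 x bind=17.9492)  [asparagine_proline_bond]
  2. chr1:597 G>C  SYPCSILNPVRMMSPMAHGPTLISV  total=78.6932 (expr=5.477 x bind=14.3673)  [asparagine_proline_bond]
  3. chr1:1000 G>A  SPFDSVTRPGCTRVQRDSHKSLLDT  total=53.6822 (expr=5.477 x bind=9.8010)
```

Each line is one variant's best 25-mer window: `expr` is
`sqrt(30)` ≈ 5.477 from the 30 mutation-supporting reads the generator
planted; `bind` sums the normalized toy-predictor affinities of all
mutant 8–11-mers across the two alleles; the bracketed tag is a
manufacturability flag (it breaks score ties and is reported, but never
changes the score). The top peptide carries *both* the somatic allele
and its phased germline neighbor — the naive single-variant edit
(`...SWPYLLRFV`) is exactly what the pipeline does **not** report.

`out/` receives `candidates.csv`, `candidates.json` (full nested detail),
`drops.jsonl` (one record per excluded variant, with stage and reason)
and `effective_config.json`.

The same run from a shell:

```sh
neopept run --vcf fx/somatic.vcf --bam fx/reads.sam --ref fx/genome.fasta \
    --gtf fx/annotations.gtf --hla 'HLA-A*02:01,HLA-B*07:02' --out out
```

## Scope

Upstream of this package sit alignment, GATK preprocessing, somatic
calling and HLA typing; downstream sit peptide synthesis and
immunological validation. Class II MHC, proteasomal cleavage, fusion
transcripts and clonality weighting are out of scope. See the methods
vignette (`vignettes/methods.Rmd`) for the model, parameter defaults and
known limitations.
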