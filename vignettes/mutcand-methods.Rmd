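---
title: "Methods: candidate-gene discovery from mutant multi-omics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: candidate-gene discovery from mutant multi-omics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`mutcand` formalizes a common forward-genetics design: a wild-type plant
and sibling mutants derived from it by mutagenesis are whole-genome
resequenced and RNA-sequenced, and candidate genes are those that both
carry a mutant-private variant predicted to damage the gene product and
show a reproducible expression change. This vignette records the models,
conventions and design choices behind each stage, and what the synthetic
validation does and does not demonstrate.

## Variant sets

A variant record is identified by its `(chrom, pos, ref, alt)` key; the
genotype call is deliberately ignored, because the downstream arithmetic
(per-sample presence/absence, subtraction against the wild type) is set
arithmetic. Records are made comparable by normalization: multi-allelic
rows are split, MNPs are decomposed into per-base SNPs, shared
prefix/suffix bases are trimmed to a single anchor base, and indels are
left-aligned against the reference until no further shift is possible.
Normalization is idempotent, and any two VCF spellings of the same allele
map to one key — the property the set subtraction relies on.

Hard filtering applies the GATK short-variant bounds
(`QD < 2.0`, `FS > 200.0`, `SOR > 10.0`, `MQRankSum < −12.5`,
`ReadPosRankSum < −8.0`), each strict, each evaluated only when the metric
is present. Filtering precedes subtraction; a mutant record masked by a
*filtered* wild-type record therefore still counts as private. The
opposite convention (subtract the unfiltered wild type) is defensible;
we chose filter-first because the private set should be built from the
same quality stratum on both sides.

## Consequence annotation

Element classification uses seven classes — coding exon, 5′ UTR, 3′ UTR,
intron, promoter, terminator, intergenic — with a fixed precedence
(listed order) so that every position gets exactly one summary label and
class counts over a variant set sum to the set size. Promoter and
terminator are strand-aware 2,000-bp flanks; the span is a convention,
not a biological constant, and is exposed as a parameter.

Consequence calls are local and deterministic: splice donor/acceptor are
the first/last two intronic bases in transcription order (the GT/AG
positions); a CDS SNP is classified by rebuilding its codon (start-codon
disruption → `start_lost`, new in-frame stop → `stop_gained`, destroyed
terminal stop → `stop_lost`, otherwise missense/synonymous by the genetic
code); a CDS indel is a `frameshift` iff its length change is not a
multiple of 3, and an in-frame indel is reported as `none` unless it
removes the start or stop codon. Indels are anchored at their normalized
position; an indel whose anchored change sits on a feature boundary is
classified by that anchored position. All of this is strand-aware by
construction (minus-strand alleles are complemented into transcript
space).

The annotator is verified against an independent oracle that applies the
variant to the raw chromosome string, re-extracts the (coordinate-shifted)
CDS, translates it whole, and classifies by comparing proteins. The two
routes share no code and agree on 100% of 10⁴ random CDS variants
(SNPs and frameshifting indels, both strands) in the test suite.

Two large-effect category sets exist on purpose. The *annotation default*
is {splice acceptor/donor, start lost, stop gained/lost, frameshift} —
variants that abolish a gene product. The *integration default* adds
`missense`, because a candidate gene whose evidence is an amino-acid
substitution is still a gene-product mutation worth reporting; the
candidate report records which consequence each gene carries, so the
distinction stays visible.

## Windowed genome statistics

The deletion screen computes `log10((d_mut + ε)/(d_WT + ε))` per
non-overlapping 100-kb window. The pseudocount ε defaults to 0.1× the
mean wild-type depth: it keeps zero-depth windows finite while leaving a
homozygous deletion at roughly `log10(ε / d_WT) ≈ −1` — far below the
default flagging threshold of −0.8 (≈ copy ratio 0.16). Flagging requires
a run of at least 5 consecutive windows (≥ 500 kb), half the scale of the
megabase deletions the screen targets, so a true ≥ 1 Mb event cannot be
missed by run-length while isolated noisy windows cannot fire. An
optional centered moving-average smoother (width `smooth_k`, default off)
is available for display-quality tracks; the screen itself operates on
raw window ratios, which keeps the flagged interval aligned with the
event boundaries. With multiplicative depth noise up to CV 0.1 the
no-deletion ratio has a standard deviation of ≈ 0.06 log₁₀ units, so the
−0.8 threshold sits more than 10 standard deviations out — the measured
false-flag count over 100 simulated no-deletion genomes is 0, and
sensitivity on planted ≥ 1 Mb homozygous deletions is 100%.

Variant-density tracks count private SNPs and indels per 5-Mb window;
totals are conserved by construction.

## Observed/expected element enrichment

Enrichment of variant classes follows the control-site design: draw the
same number of single-base positions uniformly over the genome, classify
them with the same element classifier, and take `ratio =
observed / expected` with `expected` the mean class count over resamples.
The number of resamples defaults to 100 and the mean ± sd over resamples
is reported, making the stability of the "expected" denominator visible
rather than relying on a single draw. Classes with zero expected count
are flagged undefined instead of producing infinities. Control sites are
points even when the observed set contains indels — there is no
length-matched indel null here, a deliberate simplification. The term
over-representation test is the standard hypergeometric upper tail with
BH adjustment over a flat gene→term map; no ontology-graph propagation is
attempted.

## Differential expression

Counts are modeled as negative binomial. Normalization is the
median-of-ratios estimator (the geometric-mean reference), computed on
genes with nonzero counts in every sample. The test, per gene, is a
likelihood-ratio test with size factors as offsets: full model with one
mean per condition, reduced model with a common mean, shared gene-wise
dispersion estimated by method of moments on normalized counts pooled
within conditions and floored at 10⁻⁸, p from χ²₁. The reported effect is
`log2FC = log2((m_mut + c)/(m_WT + c))` on normalized group means with
pseudo-mean `c = 0.5 / median(size factor)`. DEGs require FDR < 0.05
(strict) and linear fold change ≥ 2 or ≤ 0.5. By default the tested
universe is the FPKM-filtered gene set (genes with FPKM < 0.1 in all
samples removed); a flag tests all genes instead.

No dispersion shrinkage, outlier filtering, or independent filtering is
performed — the estimator is the plain gene-wise plug-in. A known
consequence, visible in the null simulations, is that raw p-values are
anticonservative at three replicates per group (≈ 12% of null genes at
nominal p < 0.05, because a 4-df variance estimate is noisy); this is
precisely the problem dispersion shrinkage exists to fix. After BH
adjustment the *called* set remains controlled: across 200 null
simulations of 2,000 genes the mean fraction of genes with FDR < 0.05 is
≈ 0.036 ≤ 0.05, and that adjusted-scale property — not raw-p
uniformity — is what the DEG thresholds consume. Planted effects of
|log2FC| = 2 at base mean 500 and dispersion 0.05 are detected with the
correct sign in ≈ 99% of cases.

FPKM is `count · 10⁹ / (gene length · library size)` with gene length the
union of exon intervals; abundance categories use the bounds ≥ 50 (very
high), [10, 50) (high), [2, 10) (moderate), [0.1, 2) (low), assigned
per sample.

## Integration

Candidates are `(shared_up ∪ shared_down) ∩ shared large-effect genes`,
where "shared" DEGs must agree in direction between the two mutants —
genes up in one and down in the other are reported separately and never
integrated. Concordance is the default because a causal gene disrupted in
both siblings should move the same way; a flag relaxes the intersection
to the union for exploratory use. Reports are ordered by (chromosome,
position), and each candidate carries its most severe qualifying variant
plus per-mutant log2 fold changes.

The small downstream utilities are exact where feasible: the Mann–Whitney
U test enumerates all rank assignments for combined sizes ≤ 12 (midrank
ties included; two-sided probability by distance from the null mean) and
otherwise uses the tie-corrected normal approximation with continuity
correction; relative qPCR expression is plain 2^−ΔΔCt.

## The synthetic-data generator

The generator emulates the study design end to end: a multi-chromosome
genome (A/B naming as in an allotetraploid, naming only); multi-exon gene
models on both strands with valid start/stop codons, no internal stops
and GT..AG introns; a shared-background + mutant-private variant trio;
engineered effect variants guaranteed to produce their intended
consequence (e.g. a stop gain is planted by finding a codon one
substitution away from TAA/TAG/TGA; a frameshift is a C→CA
insertion where a C is available); gamma-noise depth tracks with planted
deletions scaled by copy ratio; and NB counts with planted fold changes,
three replicates per condition.

Deliberate generator conventions, chosen once:

* **Background variants are intergenic.** Non-engineered variants are
  placed outside transcript spans so that the planted truth enumerates
  *exactly* the large-effect genes — a random background SNP landing in a
  splice site would otherwise create an unplanted large-effect gene and
  make exact-recovery tests ill-posed. Consequently synthetic
  genic class counts are driven by the planted variants only.
* **Planted variants are homozygous-ALT by convention** and genotypes are
  never consulted; INFO metrics are drawn uniformly inside passing ranges,
  with a configurable fraction planted to fail one filter bound.
* **End-to-end candidates are planted at |log2FC| = 3** (with base means
  ≥ 500). The end-to-end test asks for *exact* recovery of planted
  candidates against single-criterion decoys across many seeds; that is a
  test of the pipeline's set logic, and it presupposes candidates whose
  expression change is unambiguous — "highly differentially expressed"
  genes in the source design. Detection *power* at the DEG threshold
  effect size |log2FC| = 2 is characterized separately and is ≈ 99%, not
  100%, which is exactly why the logic test does not sit at the threshold.
* **Depth tracks and variant sets are independent channels.** A planted
  deletion changes coverage but does not delete variants from the VCFs;
  the screen and the set arithmetic are validated separately.

What passing tests show — and what they do not: the synthetic genome has
uniform base composition, uniform variant placement, clean biallelic
records, exactly-NB counts and exactly-gamma depth noise. Passing tests
therefore demonstrate correctness of the *logic and the statistics under
their stated models*, not robustness to alignment artifacts, mapping-bias
hotspots, GC-dependent coverage, overdispersion beyond NB, or annotation
errors in real genomes.

## Problem sizes and numerics

The shipped validation uses sizes chosen to make the checks sharp but
cheap: 10⁴ oracle comparisons on a 2 × 50-kb genome; 20-seed private-set
recovery; 100-seed deletion screens on 2 × 3-Mb window grids; null
enrichment on 2 × 250-kb genomes with 60 genes and up to 5 × 10⁴ control
sites × 100 resamples; DE calibration over 200 × 2,000-gene null
matrices; and 20 end-to-end runs on 2 × 2.5-Mb genomes with 40 genes.
Numerical conventions worth noting: all internal interval arithmetic is
1-based closed with conversion at the GFF3/VCF/BedGraph boundaries;
the NB mean fits use eight damped Fisher-scoring steps on log-mean with a
Poisson MLE start (ample for 1-df contrasts); LRT statistics are clamped
at zero; BH adjustment passes NAs through without counting them toward
`m`; and every stochastic routine takes an explicit seed and restores the
caller's RNG state.

## Known limitations

* Gene-wise MoM dispersion makes raw p-values anticonservative at n = 3
  (documented above); interpret raw p only through the BH-adjusted calls.
* The splice model is the 2-bp GT/AG core; extended splice regions,
  branch points and NMD are out of scope.
* Junction-spanning indels are classified by anchored position only.
* The enrichment null is positional and ignores indel length and local
  sequence composition.
* No attempt is made to reproduce caller-specific behaviors (GATK vs
  bcftools) — the pipeline consumes whatever VCF it is given after its
  own normalization.
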