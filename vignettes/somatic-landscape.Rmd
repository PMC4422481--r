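---
title: "Methods: somatic copy-number and mutation landscape analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: somatic copy-number and mutation landscape analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mesoscape)
```

# Scope and model

`mesoscape` analyses the somatic landscape of a small tumor cohort from two
independent evidence streams and integrates them per gene:

1. **SNP-array copy number.** Probe-level LogR (log2 intensity ratio, 0 =
   diploid) and B-allele frequency (BAF) are segmented into
   constant-copy-number intervals; segments are called amplified, deleted or
   neutral and flagged for loss of heterozygosity (LOH); recurrence is
   scored per cytoband and per gene across samples.
2. **Paired tumor–normal sequencing.** Per-site allele counts are classified
   as germline, somatic, LOH or unknown with exact tests, and passed through
   a staged filter cascade before mutation-rate and recurrence summaries.

The central quantity connecting both streams is tumor purity $p$ (tumor cell
fraction of the specimen). For a locus carrying $c$ copies in a fraction $f$
of tumor cells, the expected total copy number of the specimen is

$$T = 2(1-p) + p\,(fc + 2(1-f)), \qquad \mathrm{LogR} = \log_2(T/2),$$

so a clonal one-copy loss ($c=1$, $f=1$) at $p=0.7$ sits at
$\log_2(1-p/2) = \log_2 0.65 \approx -0.62$, and a clonal heterozygous
somatic mutation is expected at allelic fraction $p/2 = 0.35$. Both the
simulator and the integration stage use these expectations; tumors in this
kind of study are selected for high tumor content, hence the default
$p = 0.7$.

# Copy-number analysis

**Probe filtering and recentring.** A probe is kept only if its LogR is
non-missing in every sample. Profiles are then median-centred per sample —
but the centring median is computed only over chromosomes whose
heterozygous-informative mirrored BAF shows no allelic imbalance (mean
$\le$ 0.55). A whole-chromosome loss would otherwise drag the global median
toward itself and be partially normalised away; restricting the reference to
allelically balanced chromosomes removes that artifact without any manual
review step.

**Segmentation.** Per chromosome the probe sequence $y_1,\dots,y_n$ is
partitioned by exactly minimising

$$\sum_{\text{segments } s}\ \sum_{i \in s} (y_i - \bar y_s)^2 \;+\;
\beta \cdot \#\{\text{breakpoints}\}$$

with an $O(n^2)$ dynamic program (ties resolve deterministically to the
earlier segment start). The default penalty follows a Bayesian-style rule
$\beta = \gamma\,\hat\sigma^2 \log n$ with $\gamma = 40$ and $\hat\sigma$
estimated robustly as $\mathrm{MAD}(\Delta y)/\sqrt2$. The exact optimum is
oracle-checkable: the test suite compares it against exhaustive breakpoint
search on profiles of up to 50 probes. Segment counts are non-increasing in
$\beta$, and segments always tile the probed span, cut at inter-probe
midpoints.

**Calling.** A segment is amplified when mean LogR $> 0.25$, deleted when
$< -0.25$ (both strict), else neutral. LOH is flagged when the mean
*mirrored* BAF, $\max(b, 1-b)$ averaged over probes with BAF in the
heterozygous-informative band $(0.15, 0.85)$, strictly exceeds 0.55. Raw
BAF splits symmetrically around 0.5 under allelic imbalance, so a one-sided
reading of a BAF threshold would miss half of the signal; mirroring folds
both branches into one tail. At purity 0.7 a clonal one-copy loss puts
heterozygous probes at $0.3/1.3 \approx 0.23$ and $1/1.3 \approx 0.77$, i.e.
mirrored $0.77$ — comfortably above the 0.55 threshold. The informative
band is taken on the tumor's own BAF, which is the right choice for
tumor-only arrays at moderate purity; at purity near 1 LOH probes collapse
onto the homozygous clusters and the flag loses sensitivity (a known
limitation, not relevant at the default purity).

**Burden, cytobands, genes.** The per-sample burden counts base pairs in
non-neutral segments strictly longer than 1 Mb. A cytoband is called
deleted (amplified) when strictly more than 75% of its *physical length*
lies in deleted (amplified) segments — length, not probe count, because the
rule is stated on the band's extent. A band is recurrently lost when at
least 3 samples support it, where support is a deleted call or strong LOH
($\ge 75\%$ of the band in LOH-flagged segments). Per-gene scores assign
each gene to the segment containing its midpoint and sum over samples the
segment's mean LogR (net LogR) and mean mirrored BAF (net BAF). A sample
whose segments do not cover a gene contributes the neutral baseline, 0 and
0.5. Summation (rather than averaging) is a declared convention: it makes
the score scale with the number of affected samples, which is what a
recurrence ranking needs; with a fixed cohort the two orderings agree.

# Variant classification and filtering

Sites first pass basic thresholds: tumor and normal depth $\ge 10$ each
(the coverage rule is applied per sample), tumor allele fraction
$\ge 0.10$, and mean base quality of variant-supporting reads $\ge 17$
(variant-supporting, since those are the reads whose quality bears on the
call). Surviving sites are classified from the 2×2 table
$[[n_{ref}, n_{alt}], [t_{ref}, t_{alt}]]$:

* **somatic** — normal allele fraction below the heterozygous band
  $[0.15, 0.85]$ and one-sided Fisher exact $p < 0.05$ for tumor alt
  enrichment (the upper hypergeometric tail $P(X \ge t_{alt})$; one-sided
  because the somatic question is directional);
* **loh** — normal heterozygous, tumor fraction outside the band, exact
  two-direction $p < 0.05$ (loss of either allele qualifies);
* **germline** — both fractions in the same genotype band;
* **unknown** — anything else.

The heterozygous band bounds are conventional and configurable; nothing in
the data dictates 0.15/0.85 specifically.

The cascade then applies, in this order, with a site removed at one stage
never re-tested downstream: (1) somatic indels need depth $\ge 10$,
$\ge 3$ supporting reads and germline fraction $\le 5\%$ (strict "more
than"); (2a) SNVs within 3 bp of a retained indel and (2b) runs of
$\ge 3$ SNVs spanning $\le 10$ bp are removed (the $\ge 10\%$ allele
fraction rule of 2c is already enforced by the basic filter); (3) somatic
calls are retained only when significant *and* normal-clean ($\le 5\%$
normal alt for SNVs, zero normal alt reads for indels) — the retained set
is the significant one, since discarding exactly the significant calls
would invert the stage's purpose; (4) a read-level artifact filter applied
to germline and somatic calls checks, in order: variant reads $\ge 4$,
variant fraction $\ge 0.05$, mean relative read position in $[0.1, 0.9]$,
mean relative distance to the 3' end $\ge 0.1$, strand bias (two-sided
binomial $p < 0.01$ against 0.5, only with $\ge 10$ variant reads),
homopolymer run $< 5$ bp, mapping-quality difference $\ge -10$. The named
criteria are standard; the numeric defaults are declared here because the
criteria are conventionally published without values, and all are
configurable. A combined read-length / mismatch-quality delta test exists
but is off by default since the distilled count record carries no per-read
mismatch sums.

Consequences come from a toy codon model on the synthetic gene set: SNVs
are translated through the standard genetic code; coding indels are
frameshift iff length mod 3 ≠ 0. By that arithmetic a 42-bp deletion is
an in-frame indel even though such events can be functionally
loss-of-function; the annotator follows the arithmetic and leaves the
interpretation to the analyst. The per-sample mutation rate is count /
callable bp, with the cohort median taken as the lower median so that an
even cohort reports an attained value.

# Evidence integration

For a target gene, each sample's evidence is combined into one status:

* **loss** — a deleted segment containing the gene midpoint; annotated
  with its size, as a whole-chromosome event when it covers $> 95\%$ of the
  chromosome's probed span (robust to edge probes), or as subclonal when
  its amplitude is less than half the clonal one-copy expectation
  $|\log_2(1-p/2)|$;
* **somatic mutations** — passed non-silent calls in the gene with
  per-assay allelic fractions; a mutation is subclonal when its fraction is
  below half the clonal heterozygous expectation $p/2$ (both subclonality
  factors are configurable; "half the clonal expectation" is a declared
  quantitative reading of an inherently qualitative judgement);
* **germline variants** — recorded, but they never make a sample count as
  altered: the category (`mutation_only` / `loss_only` / `both` / `none`)
  reflects somatic evidence only, which is what makes the cohort
  decomposition arithmetic reproducible.

Evidence is gated by the declared assays (array `A`, exome `E`, targeted
`T`): a sample without array or exome data cannot carry loss evidence and
renders `NA` in that cell, while an assayed sample with no finding renders
an empty cell. The rendered table round-trips: parsing it back and
re-deriving categories reproduces the statuses exactly, which the test
suite checks on the bundled 12-sample cohort table (3 mutation-only, 3
loss-only, 2 both, 8/12 = 66% altered — percentages are truncated to the
integer, as such tables conventionally print them).

# The synthetic cohort

The generator is first-class, tested code; its defaults are the study
conditions used throughout the tests:

* 3 chromosomes (60/50/40 Mb), 8 cytobands and 30 genes per chromosome,
  probes every 20 kb — a desk-scale stand-in for a genome-wide array
  (the real platform's effective probe density is a free parameter here,
  so spacing is configurable, dense and uniform by default);
* purity 0.7; LogR noise SD 0.05 (typical array noise), BAF noise half
  that; 0.1% missing probes;
* sequencing depth Poisson with mean 100; per-base error rate $10^{-3}$, a
  conventional post-filter substitution-error scale;
* a 12-sample cohort with one target tumor-suppressor gene altered as
  3 mutation-only / 3 loss-only (one whole-chromosome loss whose carrier
  also has a germline nonsense variant, one focal 5 Mb loss) / 2 both (one
  with a subclonal loss at cell fraction 0.5 and a correspondingly low-AF
  mutation) / 4 none, plus ~8 somatic passengers and 150 germline
  heterozygous variants per sample;
* long-indel alignment dropout is emulated by a per-variant
  detection-efficiency multiplier that thins alt reads, reproducing the
  allelic-fraction underestimation of long deletions without a read
  aligner.

What the simulator deliberately does **not** model: read-level artifacts
beyond the summarised quality fields, capture bias, GC waves, population
haplotypes, and overlapping copy-number events. Passing tests therefore
demonstrate correctness of the statistical machinery under a clean
generative model, not robustness to every failure mode of real arrays and
aligners.

# Numerical choices and problem sizes

* Segmentation ties and band/gene orderings break deterministically
  (earliest start; lexicographic names), so identical configuration and
  seed give byte-identical outputs; a master seed fans out to per-stage
  child seeds through a fixed affine derivation, keeping stages
  independently rerunnable.
* Coordinates are 0-based half-open in memory (BED-compatible) and 1-based
  inclusive in every emitted table.
* Degenerate inputs: an empty probe set segments to nothing; a segment
  with no heterozygous-informative probe has missing mirrored BAF and can
  never be LOH-flagged; zero-depth sites must be removed by the basic
  filter before classification and are rejected otherwise.
* Test and acceptance problem sizes, chosen as comfortable desk-scale
  checks: oracle equivalence on $\le 50$-probe profiles and 2×2 tables
  with margins $\le 60$ (1,000 random tables at $10^{-9}$); specificity on
  $10^5$ simulated no-variant sites; end-to-end recovery on the 12-sample
  cohort across 10 seeds (7,500 probes and ~300 count rows per sample).

# Known limitations

* No allele-specific integer copy-number inference and no purity/ploidy
  estimation: purity is a known parameter, as in the simulated design.
* LOH detection relies on the tumor's own BAF band and loses sensitivity
  as purity approaches 1 (see above).
* The consequence annotator is a toy by construction — single-transcript
  genes, genomic-orientation coding sequences, no splice effects.
* Cohort-scale sequencing summaries (mutation counts per tumor, recurrent
  gene lists) are validated against planted truth on synthetic cohorts,
  not against any external dataset.
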