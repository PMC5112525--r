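---
title: "Reconstructing pedigree ancestry and tracing inherited alleles with pedtrace"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing pedigree ancestry and tracing inherited alleles with pedtrace}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Backcross breeding introduces a target trait from a donor line into an
elite recurrent parent. After the program ends, a natural question is
*which ancestor contributed each piece of the offspring's genome*, and
which donor-side alleles survived selection. Given whole-genome SNP
genotypes of the offspring and its ancestors — for example a rice
maintainer line bred from two upland grandparents through an intermediate
donor, backcrossed into an elite recurrent parent — pedtrace reconstructs
the offspring genome as a mosaic of ancestor-of-origin haplotype blocks,
traces specifically inherited alleles to genes, classifies SNPs by genomic
feature and coding effect, and intersects the inherited-allele genes with
drought-responsive differentially expressed gene (DEG) sets and promoter
transcription-factor-binding-site (TFBS) networks.

All stages run end to end on a built-in pedigree simulator with exact
block truth, so the method can be validated without any external data.

## Genetic similarity

For two inbred lines, genotype diversity $\pi$ is the proportion of
compared SNP sites at which the lines differ; the similarity index is
$1 - \pi$ (the Nei–Li index applied to homozygous genotypes). Missing
calls are excluded pairwise, so each pair uses its maximal informative
site set. The default heterozygote policy is `exclude`: a site
heterozygous in either member is dropped from that pair's comparison,
because on (nearly) inbred material a heterozygous call is ambiguous —
it usually marks residual heterozygosity or a calling artefact rather
than a countable allele difference. The alternative `half` policy scores
het-vs-hom as half a difference for material where heterozygosity is
real. Pairs with fewer than `minSites` (default 100) comparable sites are
reported as undefined rather than as noisy numbers.

## The diversity-decreased level and block calling

The core statistic is computed in sliding windows (default 100 kb,
step 10 kb). For a descendant $d$ and candidate ancestor $a$:

* $D_{pair}(w, a)$ — the diversity between $d$ and $a$ in window $w$,
  with the same counting rules as the similarity index;
* $D_{arv}(w)$ — the mean of the pairwise diversities over *all*
  unordered pairs of samples in the panel (the descendant, its
  candidate ancestors, and any other genotyped relatives supplied);
* the **diversity-decreased level**
  $(D_{arv} - D_{pair}) / D_{arv}$.

Inside a block inherited from ancestor $a$, $D_{pair}(a) \approx 0$ and
the decrease approaches 1; outside it, $D_{pair}$ reverts to the panel
average and the decrease falls to about 0 (or goes negative for a
distant ancestor). Windows with fewer than `minSnps` (default 10)
compared sites, or with $D_{arv} = 0$, are uninformative and never
produce NaNs.

The per-ancestor decrease values over all windows are strongly bimodal:
one mode for "inherited here", one for "not inherited here". The
threshold between them is estimated by a two-component Gaussian mixture
fitted by EM. Initialisation is deterministic (component means at the
10% and 90% quantiles, equal weights, pooled spread), so the same data
always give the same threshold. If the fitted components are closer than
`delta` (default 0.1) or either weight falls below 0.05, the
distribution is declared unimodal and a fixed fallback threshold
(default 0.5) is used and flagged. Thresholds are fitted per ancestor,
not globally, because the decrease scale depends on how related each
ancestor is to the rest of the panel.

Windows are then labelled with the ancestor whose decrease passes its
threshold and is maximal. A window where no ancestor passes, or where
the top two passing ancestors lie within `tieMargin` (default 0.05) of
each other, is *uncertain*. Overlapping windows are resolved on the
step-sized tiling: each 10-kb tile takes the label of the window whose
centre is nearest the tile centre. Centre matching keeps breakpoint
placement symmetric — a window's label describes its middle better than
its leading edge — and halves the boundary bias of leading-edge
assignment.

Uncertain runs are apportioned by type:

* a run whose windows are consistently tied between the **same two
  ancestors** is a residual heterozygous region — one homolog from each
  ancestor, the expected leftover of a backcross program before full
  fixation — and is split equally between those two ancestors. This is
  the diploid-correct accounting: without it, a heterozygous region
  flanked by blocks of one ancestor would be attributed entirely to that
  ancestor, biasing contribution fractions by up to half the residual
  heterozygosity. At a genuine boundary between an $X$ block and a $Y$
  block the rule coincides with the midpoint split below.
* any other uncertain run strictly between two determinate blocks is
  split at its midpoint, half to each neighbour;
* uncertain runs at chromosome ends attach to their single neighbour;
* a chromosome with no determinate window at all is reported unassigned
  with a warning.

Contribution fractions are reported over the assigned genome, with the
unassigned length disclosed separately, since unassignable regions have
no defensible owner. Per-ancestor fractions always sum to 1 over the
assigned length.

## Tracing specific inherited alleles

A *specific inherited allele* is an offspring allele identical to at
least one donor-side parent and different from the recurrent parent. A
site qualifies only when the offspring, the recurrent parent, and at
least one donor are all homozygous and non-missing; heterozygous sites
are excluded as origin-ambiguous. All donors matching the offspring call
are recorded per site — grandparents frequently share alleles, so
collapsing to a single donor would fabricate certainty.

Traced SNPs are assigned to genes in two location classes: `genebody`
(within the gene span) and `promoter` (within `promoterBp` upstream of
the TSS, strand-aware, default 2000 bp — deliberately independent of the
3000-bp promoter used for motif scanning, since "proximal promoter" for
gene assignment and "scanable promoter" for TFBS discovery are different
questions). Concordance between traced sites and the block mosaic — the
fraction of traced sites lying inside a block whose origin is among the
site's matching donors — is the cross-check between the two halves of
the method; on simulated data it should be near 1, with discrepancies
confined to block boundaries.

## SNP annotation

Each SNP receives exactly one feature: splice site > 5'UTR/3'UTR >
exon > intron within a gene, the highest-priority feature across genes
when genes overlap, `promoter` only for SNPs outside all genebodies, and
`intergenic` otherwise. The priority order is a convention (fixed so
counts are reproducible); splice sites are the first/last `spliceBp`
bases of each intron (default 2, the GT–AG dinucleotides).

Coding effects splice the reference codon from the representative
transcript (the longest-CDS transcript per gene), substitute the
alternate allele in transcript orientation, and compare residues under
the standard nuclear codon table: synonymous, nonsynonymous, stop gain,
or stop loss. Genes whose CDS length is not a multiple of 3 are flagged
and skipped rather than mistranslated. The nonsynonymous/synonymous
ratio excludes stop variants from both numerator and denominator — the
count-arithmetic of published exonic SNP tabulations is reproduced
exactly under this convention, and including stop variants is
inconsistent with those printed ratios.

## Expression filtering and integration

The DE filter is deliberately simple because testing happens upstream:
a gene is differentially expressed when fold change $> 2$ **and**
$p < 0.05$, both strict. Fold changes are computed on
pseudocount-stabilised FPKM (default 0.1) so zero-expression genes
neither explode nor vanish; the drought/watered comparison is the
symmetric $\log_2$ ratio of the same stabilised values. Per-variety DEG
totals are unions over the three time-course contrasts
(drought vs well-watered at T1; T1 vs T2; T2 vs T3 under drought), and
"common DEGs" between two varieties counts genes up in both plus genes
down in both. The module consumes p-values; it never computes them —
synthetic fixtures plant DEGs with known truth and placeholder p-values.

## Promoter scanning and TF–target networks

Promoters are the 3000 bp upstream of the TSS, strand-aware
(reverse-complemented for minus-strand genes), truncated — with the
actual length reported — at chromosome ends. JASPAR-format count
matrices are converted to log2-odds with a total pseudocount of 0.8 per
column against a uniform background, and both strands are scanned at
every offset; windows containing N are skipped, overlapping hits are all
reported. A hit requires a score of at least `thresholdFraction`
(default 0.8) of the maximum attainable score; a relative threshold was
chosen over a p-value threshold because it is self-calibrating across
motifs of different lengths and information content. Each
(motif, gene, hit) becomes a network edge with its TSS-relative
position; edge existence depends only on sequence, with expression data
available to annotate edges downstream.

## The simulator: what it emulates and what it does not

The synthetic pedigree mirrors a three-founder introgression program:
two grandparents crossed to an F1, selfed three generations into a donor
line; donor × recurrent, one backcross into the recurrent parent (BC1),
then two selfings. Expectation: ~75% recurrent-parent genome, unequal
grandparent remainders, ~12% residual heterozygosity — the regime the
block caller must handle.

Model choices:

* **Haldane meiosis** — crossover counts Poisson in the genetic length,
  positions uniform, no interference. The simplest defensible model;
  interference sharpens block-length distributions but does not change
  what the window statistic sees at 100-kb scale.
* **Fully homozygous founders** — the emulated material is inbred
  varieties and maintainer lines.
* **Site model** — SNP positions are a Poisson process at `snpDensity`
  (default 1e-3/bp, giving ~100 SNPs per 100-kb window, comparable to a
  few SNPs per kb in a resequenced rice pedigree); founder alleles are
  i.i.d. Bernoulli(q) per site with q solving $2q(1-q) = $
  `polymorphismRate` (default 0.5), so every founder pair diverges at
  the stated rate. Sites at which all founders happen to share the
  non-reference state are retained (they are variants against the
  reference, as in joint calling against an external reference genome).
* **Genetic lengths** — 1 Morgan per 10-Mb chromosome by default, a
  typical whole-chromosome genetic length that keeps per-generation
  breakpoint counts realistic.
* **Determinism** — one global seed; each meiosis draws from a
  deterministically derived substream (seed + event counter), so adding
  lines to a pedigree never reshuffles earlier lines, and identical
  configurations are byte-identical on disk.

Not emulated: phenotypic selection during breeding (real introgression
programs retain donor segments preferentially around selected loci;
simulated segment survival is neutral), mutation, gene conversion,
genotyping error beyond an optional uniform missing-call rate, linkage
disequilibrium structure within founders, and SNP density variation
along the genome. Passing the simulation-recovery tests therefore shows
the statistic and its thresholds recover *neutral* mosaic structure from
clean biallelic calls; it does not certify behaviour under reference
bias, calling error, or segmental duplication, which real resequencing
data add on top.

## Numerical choices and degenerate inputs

* EM: at most 500 iterations, log-likelihood tolerance 1e-8, variance
  floor 1e-8; the decision boundary is found by root-finding on the
  posterior log-ratio between the two means, falling back to the
  mid-mean point if the ratio does not change sign there.
* Windows with no usable sites, pairs with no shared non-missing sites,
  empty traced-allele sets, zero-length promoters, and all-N sequences
  all produce explicit flags/warnings or empty results, never NaNs.
* Ties everywhere are broken deterministically (first by decreasing
  score, then by input order / alphabetical origin), so outputs are
  stable across runs.

## Problem sizes used for validation

The test suite exercises randomized fixtures of up to 20 samples × 200
sites (similarity), 2 × 50-kb genomes (window diversity), a hand-built
two-gene/6-kb genome (annotation, promoters), and ≤200-bp sequences
(scanning oracles). Simulation-recovery checks use ten replicates of the
default pedigree on 2 chromosomes × 10 Mb at SNP density 1e-3 with
100-kb/10-kb windows; simulator calibration uses 1000 meioses and 500
BC1 replicates. These sizes give stable statistics (binomial/Poisson
standard errors well below the asserted tolerances) while a full run of
suite plus acceptance script completes in minutes on one core.

## Known limitations

* Block resolution is window-limited: breakpoints are located to about
  one window; blocks shorter than a window are invisible.
* The method assumes the candidate ancestor panel is complete; genomic
  content from an ungenotyped ancestor is absorbed into "uncertain" or
  mis-assigned to the closest relative in the panel.
* Contribution fractions are genome-length based over assigned regions
  only; they are not comparable to block-count-based percentages.
* The DE filter inherits whatever multiple-testing behaviour the
  upstream p-values carry; no correction is applied in-package.
* PWM scanning uses a uniform background and a relative score cutoff;
  absolute binding affinity or p-value calibration is out of scope.
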