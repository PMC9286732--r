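---
title: "Dissecting the allele-specific Pol II transcription cycle"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dissecting the allele-specific Pol II transcription cycle}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(allelicTx)
```

## The problem

In an F1 hybrid between two divergent inbred strains, every transcribed
locus is an internally controlled experiment: the two alleles share one
nucleus, one pool of polymerase and transcription factors, and differ only
in cis — in DNA sequence and in parental origin. Nascent-RNA run-on
protocols (ChRO-seq/PRO-seq style) read out both ends of each engaged
transcript: the 5' end marks where that RNA initiated, and the 3' end marks
the RNA polymerase II (Pol II) active site. Reads overlapping a strain
variant can be assigned to their allele of origin. This package takes such
allele-assigned read ends and dissects, stage by stage, how DNA sequence
and parental origin shape the Pol II transcription cycle: initiation site
choice, promoter-proximal pausing, transcription-unit extent (termination),
and downstream mRNA stability.

Because the pipeline's claims are about *recovering* allelic structure, the
package carries a diploid-genome simulator that plants known truth —
initiator hierarchies, pause-site energetics, allelic effect classes,
termination extensions — and every stage is validated by how faithfully it
recovers what was planted.

## Data model and conventions

All intervals are 0-based, half-open; conversion to 1-based formats happens
only in the readers and writers. Strand-aware "downstream" means increasing
coordinates on `+` and decreasing on `-`. Alleles are `A1` (the
reference-like haplotype on whose coordinates results are reported) and
`A2`; reads that carry no allele-informative variant are `untagged` and
contribute to combined signal only. A cross label `A1xA2` means strain A1
is the mother, so parent-of-origin effects flip their strain direction
between the reciprocal crosses while strain (cis) effects do not.

## The simulator as a generative model

`sim_config()` + `simulate_dataset()` produce a diploid contig, planted
loci, allele-tagged read ends and exon-level mRNA counts. The generative
assumptions mirror what the analyses assume:

* **Initiation.** Each locus has 1–5 TSSs within a 60 bp cluster. The
  per-TSS initiation rate is
  `base_rate * w[initiator] * exp(alpha * AT10)`, where the initiator is
  the pyrimidine–purine dinucleotide at positions (−1, 0), with default
  weights CA = 1, TA = 0.5, TG = 0.25, CG = 0.1 (the literature supports
  only the ordering, not numerical values; the defaults are free
  parameters), and `AT10` is the AT fraction of the ±5 bp window with the
  initiator masked (a DNA-melting proxy, `alpha = 0.5`). Promoters are
  sharp by default (members at 0.15–0.5 of the maxTSS); multi-TSS shape
  loci are broad (members at 0.5–0.9), reflecting the sharp/broad promoter
  dichotomy.
* **Pausing.** The pause site on each haplotype is the offset
  `o ∈ [20, 60]` downstream of the maxTSS maximising
  `w_C·[base(o) = C] + w_G·#G(o−10..o−1) − w_D·|o − d0|`,
  computed on that haplotype's own sequence. The first two terms encode
  pausing on a C immediately after a G-rich stretch; the third is a
  distance tether to the preferred pre-initiation-complex (PIC) distance
  `d0` (drawn 30–45 bp per locus). The tether is what makes short
  insertions/deletions between TSS and pause shift the *projected* pause
  position by their length while the local energy landscape still selects
  a C: pausing is treated as a compromise between sequence energetics and
  the physical link of paused Pol II to the PIC. A pure sequence argmax
  (no tether) cannot produce the indel–offset relationship, because after
  an indel it simply re-finds the same physical base. Each locus carries a
  planted pause box (a 14 bp G-run followed by a C-run) so the energy
  landscape has a well-defined optimum; active-site C SNP loci use a
  gapped C-run so that disrupting the C causes a short downstream slip.
* **Read ends.** Per sample (organ × cross × replicate), per-TSS counts
  are Poisson (optionally negative binomial); each read's 3' end is its
  allele's pause position plus symmetric geometric jitter truncated to
  ±4 bp; gene-body reads are uniform over each allele's own unit extent.
  Reads are allele-tagged with probability `tagging_p` (default 0.25);
  allele2 coordinates are projected onto allele1 through the variant map
  and also retained allele-locally.
* **Allelic effects.** Effect classes are assigned at configured
  proportions: `abundance` (one allele's rate scaled, default 3:1),
  `imprinted` (maternal/paternal multiplier applied per cross direction,
  default 4:1), `shape_single` (one member TSS 4-fold on one allele),
  `shape_multi` (the three strongest TSSs 2-fold, directions straddling
  both alleles so the change is in shape, not abundance), `termination`
  (one allele transcribes 15–45% of the unit length further; half of
  these also gain a novel 3' exon on the long allele, changing the mature
  mRNA), and `none`. Sequence-level plantings (initiator SNPs, active-site
  C SNPs, TSS–pause deletions) go on class-`none` loci so that the
  determinant analyses are not confounded by global expression changes.
* **Stability.** Per-gene mRNA counts are Poisson with mean transcription
  rate × allelic stability multiplier × exon length; structure-changed
  loci draw wider log2 allelic stability ratios (sd 0.8) than others
  (sd 0.15).

What the simulator does **not** model: mappability and alignment bias,
ligation and fragment-length bias, enhancer grammar, polymerase dynamics
within gene bodies, or linkage between neighbouring genes. Passing
recovery tests therefore demonstrates the pipeline's correctness under its
own generative assumptions — not robustness to every artefact of real
libraries.

## The analysis pipeline

**TSS/TSC/TSR calling.** A TSS is any base with ≥ 5 combined reads sharing
a 5' end inside a candidate regulatory region (e.g. dREG output, consumed
as BED). TSSs within 60 bp are chained into transcription start clusters
(TSCs); the maxTSS is the member with maximal combined signal (ties all
retained; per-site analyses use the 5'-most tie deterministically). TSCs
group into transcription start regions (TSRs) by candidate region and
strand.

**Allelic tests.** Abundance: exact binomial test of summed allelic counts
against 0.5, Benjamini–Hochberg per organ, allele-specific at q ≤ 0.1, with
q > 0.9 defining the ascertainment-matched no-change control set used by
every sequence-level comparison. Shape: weighted two-sample
Kolmogorov–Smirnov between the allelic 5'-end distributions (≥ 5 tagged
reads per allele). Because single-base positional data are massively tied,
the default p-value is a Monte-Carlo permutation (B = 499, conditional on
position totals); the asymptotic formula is available but conservative
here. Significant clusters are re-tested after masking the TSS with the
largest absolute allelic difference: if the masked cluster no longer beats
the most lenient first-pass detection p (the highest nominal p achieving
the 10% FDR), the change was driven by a single TSS, otherwise by several.

**Sequence determinants of initiation.** For maxTSSs whose initiator
dinucleotide differs between alleles, the allelic bias ratio is
log2(reads on the stronger-initiator allele / other allele), with
categories oriented by the CA > TA > TG > CG hierarchy (the source figure
does not print its ratio orientation; this is our convention). Positional
SNP profiles (5 bp display bins, 10 bp Fisher-test bins at FDR 0.05),
high-vs-low-allele base composition and AT content (5 bp windows,
initiator positions −1/0 masked), and TATA-box scoring (−35..−20 window,
maximal log-likelihood ratio against a first-order Markov background,
conditioned on score > 3 on at least one allele; two bundled PWMs, one
degenerate and one strict) all compare the significant set against the
q > 0.9 control set, never against genome-wide expectation. The
redistribution ("shooting-gallery") analysis asks whether signal lost at a
disrupted CA initiator reappears at neighbouring YR dinucleotides within
±20 bp but not across the whole TSR, using clusters outside allelic
blocks, with the control set defined as initiator-identical sites (the
source's Methods and figure captions disagree on this control; we follow
the captions).

**Allelic blocks and domains.** Allele-informative positions (≥ 1 tagged
read) feed a three-state HMM — balanced (allele1 probability 0.5),
allele1-biased (ρ = 0.9), allele2-biased (0.1) — with binomial emissions,
symmetric switch probability τ, and a chain that starts balanced (hence
τ = 0 yields no blocks). Viterbi runs of a biased state become blocks;
each block's p-value is the exact binomial on its summed counts. τ is
selected on labelled reference units by maximising sensitivity +
specificity over a grid (ties to the smaller τ; the published analogue
used 1e−5 or 1e−4 per organ, driven mainly by depth). Blocks are kept when
all replicates agree in direction and their Fisher-combined p ≤ 0.05 (no
further multiplicity correction at this step, as in the source), then
intersected across reciprocal crosses: same strain biased in both crosses
is a strain effect, same parent (strain flips with the cross) is
imprinted; same-class overlapping regions merge across organs into
domains. Gene-level states follow the same direction logic on binomial
q ≤ 0.1 calls per cross.

**Pause determinants.** Per candidate region, allelic 3'-end distributions
are compared by the weighted KS test (≥ 5 reads per allele, FDR 0.1 /
control 0.9). Within valid TSS–pause pairs (allelic maxPause 10–50 bp
downstream of the allelic maxTSS on both alleles, ≥ 5 allelic reads,
allelic ratio within 0.5–2) sharing the same maxTSS, the test set has
distinct allelic maxPause at q ≤ 0.1 and the control set identical
maxPause at q > 0.9. The "short allele" is the one with the smaller
projected TSS→pause distance. Determinants are tagged per record: SNP at
the short-pause active site, in the transcription bubble (−10..−1), just
downstream (+1..+10), or an indel between the maxTSS and the long pause
(windows chosen to match the base-composition blocks; the source does not
define exclusive windows for its event accounting, so this partition is an
interpretation). The signed indel length is oriented positive when the
projected-long allele carries the deletion, which makes the expected
regression slope of projected pause difference on indel length +1.

**Termination and stability.** An allelic termination (AT) window is the
intersection of a transcription unit with a same-strand block that starts
(5' edge) inside the unit, ends in the final 10% of the unit or beyond,
and leaves a window ≤ 50% of the unit length; multiple qualifying blocks
contribute the union (one window per unit), and the long allele is the
block's biased allele. mRNA primary-structure changes are flagged when an
mRNA-level block (HMM on exon-level allelic counts) intersects the window
extended 10 kb upstream, strand-aware. Stability is allele-specific mRNA
exon reads over nascent gene-body reads (≥ 10 nascent reads per allele);
the coupling test is a one-sided KS asking whether structure-changed units
have larger allelic stability differences.

**Expression support.** Gene-body counts skip the first 500 bp of each
annotation strand-aware, normalise to RPKM, and filter genes ≥ 10 kb with
≥ 5 reads in every sample; allelic log-ratios use a 0.5 pseudocount (the
source is silent on zero handling) and the per-organ requirement of
allele-specificity in ≥ 3 samples.

## Numerical and design choices

* MaxTSS/maxPause ties break to the 5'-most position (strand-aware) for
  determinism; the source does not state its tie rule.
* The binomial, BH, Fisher-exact, Fisher-combination and correlation steps
  delegate to base R (`binom.test`, `p.adjust`, `fisher.test`, `pchisq`,
  `cor.test`); the weighted KS and the rank-sum test are implemented here
  because the base versions reject or approximate ties, and both have
  exact enumeration modes that the test suite checks against independent
  brute-force oracles.
* Every simulation stage seeds deterministically from `config$seed` plus a
  fixed per-stage offset, so identical (seed, config) gives byte-identical
  genomes, truth, reads and counts.
* Degenerate inputs return sentinels rather than errors where the science
  calls for it: zero-total binomial tests, under-covered KS inputs,
  constant-score correlations, empty Fisher strata.

## Validation experiments

The `experiment_*()` functions (also driven by `scripts/acceptance.R`)
fix the study conditions:

| experiment | conditions | scored quantity |
|---|---|---|
| `experiment_abundance` | 500 clusters, 20% planted 3:1, ~40 tagged reads (organ-pooled), variant-free genome | sensitivity, empirical FDR at q ≤ 0.1 |
| `experiment_null` | 500 clusters, no effects | false-call fraction; null SNP-profile bins |
| `experiment_shape` | 150 clusters, 20% single (4-fold), 20% multi (2-fold × 3), 60 tagged reads | single/multi label accuracy among detected |
| `experiment_hierarchy` | 250 single-TSS loci, initiator SNPs at weights 1/0.5/0.25/0.1 | median log2 ratios per category |
| `experiment_hmm_recovery` | 9:1 blocks, 5 reads/position, ≥ 10 positions | median Jaccard |
| `experiment_domains` | reciprocal crosses, 4:1 strain and imprinted loci | per-locus recall and class accuracy |
| `experiment_pause` | 500 loci, 20% C-SNP, 20% deletion, 80 tagged reads | modal pause base, bubble G excess, indel slope, distance contrast |
| `experiment_termination` | 16 loci, dense gene bodies (0.5 tagged reads/bp pooled) | AT-window Jaccard, long-allele accuracy |
| `experiment_stability` | 200 units, half with termination changes | structure-flag accuracy, one-sided KS p |

Problem sizes were chosen so the full suite runs on a laptop in minutes.
The sharpest known limitation is the single/multi shape classifier: with
2-fold effects spread over three TSSs at realistic promoter depths, the
masking re-test keeps only ~half of the detected multi-TSS events above
the nominal threshold whenever masking removes the singleton-direction
TSS, so label accuracy pools around 0.65–0.75 — the masking procedure is
faithful to its published description, and the residual-significance
hurdle is intrinsic to it at these depths.

## A worked example

```{r example, eval = FALSE}
cfg <- sim_config(seed = 7, n_loci = 60, promoter_only = TRUE)
ds <- simulate_dataset(cfg)

regions <- with(ds$truth$loci,
                data.frame(contig = contig, start = tsr_start, end = tsr_end,
                           region_id = locus))
c5 <- make_base_counts(ds$reads, "five_prime")
tsc <- cluster_tsc(call_tss(c5, regions, min_reads = 5), merge_gap = 60)
ab <- tsc_abundance_test(tsc)
table(significant = ab$significant,
      truth = ds$truth$loci$class[tsc$tsc$region_id])
```

## Known limitations

Beyond the simulator's idealisations listed above: the block caller uses a
fixed biased emission ρ rather than estimating it (the published tool's
full parameterisation is not described in our source, and the
re-implementation is validated on synthetic truth, not against the
original code); domain merging across organs requires identical direction
on the strain axis; and the pause analyses inherit the single-base mode
estimator's noise at low allelic depth, which is why the pause validation
uses deeper libraries than the abundance validation.
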