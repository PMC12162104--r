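---
title: "Characterizing chemically induced mutations in selfing lines"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Characterizing chemically induced mutations in selfing lines}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(azidemut)
```

## The problem

Chemical mutagens such as sodium azide are used to generate heritable
variation in crops. A mutagenized line carried through several
generations of self-fertilization accumulates a mixture of variants:
mutations induced by the treatment, spontaneous mutations arising during
line maintenance, and pre-existing heterogeneity between the treated
seed stock and the reference assembly. Separating these classes, and
then characterizing what the mutagen actually does — which base changes,
in which sequence context, with what coding consequences — is the
analysis this package implements. In barley, sodium azide predominantly
induces C→T transitions at cytosines followed by another cytosine (a CC
dinucleotide on either strand), which concentrates the resulting
amino-acid changes on a small set of substitutions.

`azidemut` provides four connected components:

1. an **expectation model** for spontaneous mutation accumulation under
   selfing, the baseline against which induced counts are judged;
2. a **two-part variant isolation pipeline** that removes everything a
   mutagen did not cause;
3. **spectrum and sequence-context statistics** (collapsed substitution
   classes, Ts/Tv, indel lengths, flanking-base relative entropy and
   G-test deviance, genome k-mer composition);
4. **coding-effect summaries** (consequence classification, CC/GG codon
   motifs, Bonferroni-thresholded constraint labels, per-window
   deleterious load, load–phenotype correlation).

A synthetic-data generator emulating the statistical structure of such
an experiment drives all end-to-end tests.

## The accumulation model under selfing

Each generation, new mutations appear in the heterozygous state with
expectation

$$N_{het} = \mathrm{diploid\ bp} \times \mu,$$

where $\mu$ is the per-site, per-generation rate. Under
self-fertilization a heterozygous mutation is transmitted heterozygous
with probability 1/2, fixed homozygous with probability 1/4, and lost
with probability 1/4. Inherited expectations follow

$$I_{het}(x) = 0.5\,N_{het} + 0.5\,I_{het}(x-1), \qquad I_{het}(0)=0,$$
$$I_{hom}(x) = I_{hom}(x-1) + 0.25\,I_{het}(x-1), \qquad I_{hom}(x<2)=0,$$

with the total at generation $T$ being $I_{het}(T) + I_{hom}(T)$. Two
conventions matter and are fixed here deliberately:

* **Generation indexing.** The treated generation is $G_0$ and
  contributes no inherited mutations itself; "seven generations of
  self-fertilization" maps to $T = 7$. This convention reproduces all
  four published expectations simultaneously (~124 spontaneous SNVs on
  the full diploid genome, ~3.5 and ~18 indels on the callable and full
  genomes, and the 88×/17×/139× enrichment ratios).
* **First transmission.** A newly arisen mutation's first transmission
  retains it heterozygous with probability 1/2 or loses it — it cannot
  be homozygous one generation after arising, which is exactly what the
  $I_{hom}$ recursion encodes. Every later step uses 1/2 : 1/4 : 1/4.
  The gene-dropping Monte Carlo (`simulate()` on the fitted object)
  implements this faithfully and agrees with the recursion within
  Monte-Carlo error; it is the model's independent check.

$N_{het}$ is held constant across generations (rates do not deplete
sites at these magnitudes). Closed forms
$I_{het}(x) = N(1-2^{-x})$ and
$I_{hom}(x) = 0.25N[(x-1)-(1-2^{-(x-1)})]$ are used as exact test
oracles.

```{r}
fit <- selfing_expectation(diploid_bp = 8451211438, mu = 6.53e-9,
                           generations = 7)
fit
```

Fold enrichments are reported with full precision and displayed
truncated toward zero to an integer — the convention that reproduces
quoted "88-fold / 17× / 139×" figures from their underlying ratios
(88.1, 17.1, 139.6).

## Isolating de novo variants

The pipeline (`run_isolation_pipeline()`) serializes the two filtering
stages:

* **Part 1 — the parent difference set.** Variants called in the
  untreated parent against the reference are restricted to callable
  regions (complement of repeat, N-stretch and high-copy masks;
  optionally low-complexity), hard-filtered, SV-support-filtered, and
  passed through a diversity-window filter: tumbling 100-bp windows
  containing more than 2 SNV positions are discarded wholesale, since
  >2% divergence is implausible when a line is aligned to its own
  reference. What survives marks positions where de novo calls are
  forbidden.
* **Part 2 — the mutagenized lines.** Line variants are restricted to
  callable regions, hard-filtered jointly as a cohort,
  SV-support-filtered, purged of anything intersecting the parent
  difference spans, purged of known genotyping-panel positions (exact
  anchor-position match), and finally reduced to *private* variants —
  alleles carried by exactly one line.

Numerical and semantic choices:

* Coordinates are VCF 1-based for variants and BED 0-based half-open
  for intervals; every overlap goes through `GenomicRanges` with an
  indel's reference span `[pos, pos + nchar(ref) - 1]`.
* Diversity windows are tumbling (anchored at position 1), not sliding:
  deterministic, O(n), and sufficient for the screening purpose; the
  window width and count threshold are arguments.
* Privacy is keyed on (chrom, pos, ref, alt), not position alone: two
  lines struck at the same site by *different* changes are independent
  mutational events and both survive.
* Per-sample hard-filter failures (depth outside [5, 158], GQ < 9,
  heterozygous allele balance deviating from 0.5 by more than 0.1)
  invalidate the genotype rather than the site; site-level rules
  (QUAL < 30, >10% heterozygous genotypes, >30% missing) are then
  re-evaluated. The heterozygosity and missingness proportions use the
  cohort size as denominator, as in joint calling — applied per single
  sample the heterozygosity rule would be degenerate (any het call
  would be 100% het).
* Every filter is a pure subset operation and idempotent; a
  `FilterReport` records input/removed/surviving counts at each stage
  and is conserved by construction.

Landrace (untreated) variants are classified **rare** (non-reference
allele count ≤ 2 over diploid genotypes, het = 1, hom = 2) or
**common** (≥ 3); monomorphic sites are flagged invariant and belong to
neither stratum.

## Spectrum and sequence context

Substitutions are collapsed into six classes by pooling each change
with its reverse complement and representing the pair by the member
whose reference base is A or C (so G→A counts as C→T\*). Ts/Tv is
transitions (A↔G, C↔T) over all other changes, flagged undefined — not
infinite — when no transversions exist. Indel spectra are signed-length
histograms with the 1-bp fraction reported separately for insertions
and deletions.

Context analysis compares the 5-bp neighborhood of each focal mutation
(default flank 2) against a matched control: one position drawn
uniformly within ±100 bp carrying the same reference base, excluding
the focal site itself (mutations with no eligible control are excluded
and counted). Analysis operates on forward-strand focal changes (e.g.
literal C→T rows), matching how reference-relative context logos are
built. Per flanking position, the relative-entropy term for base $b$ is
$p_m(b)\log_2(p_m(b)/p_c(b))$ with zero-frequency mutation bases
contributing 0 (pseudocount 0 by default, configurable for small
samples); the position total is a KL divergence, non-negative, and the
signed terms mark over/under-representation for logo rendering. The
accompanying deviance is the likelihood-ratio G-statistic of the
2 × 4 (set × base) table with 3 degrees of freedom — equivalent to the
position effect of a single-position log-linear model, and calibrated:
under the null its p-values reject at the nominal rate (checked by
simulation in the test suite).

K-mer composition uses overlapping forward-strand windows; windows
containing N are excluded from numerator and denominator.

## Coding effects and deleterious load

Consequences are assigned against gene models by a fixed precedence —
splice donor/acceptor > stop-gained/stop-lost/start-lost >
frameshift/inframe-indel > missense/synonymous > intron >
upstream/downstream (5 kb default flank) > intergenic — with
minus-strand genes evaluated on the reverse complement. The precedence
order and flank distance follow standard annotation practice and are
configurable. Nonsynonymous means missense + start-lost + stop-gained +
stop-lost. The CC-motif flag marks coding SNVs whose reference base and
immediate 3′ neighbor read CC on the forward strand, or whose base and
5′ neighbor read GG (the reverse-complement motif).

Phylogenetic-constraint p-values are consumed, never computed: a call
is deleterious iff p is strictly below the Bonferroni threshold
(α/n over tested codons) *and* the auxiliary criteria pass (≥10 aligned
sequences; allele unseen in other species). The displayed threshold is
truncated toward zero at two significant digits — 0.05/611 = 8.18e-5 is
reported as 8.1e-5 — because truncation, not rounding, reproduces all
three published cutoffs (8.1e-5, 5.1e-6, 3.4e-6); full precision is
kept for the comparison itself. The same truncation convention (two
decimals) governs the amino-acid-change percentage tables, where it
uniquely reproduces the published 12.25% for 19/155; the exact
percentages are retained alongside and sum to 100 within each stratum.

Deleterious load is summarized per sample (nSNV:sSNV ratios) and per
tumbling 10-Mb window as deleterious variants per covered codon
(callable CDS bp / 3), with zero-codon windows flagged rather than
divided. Load–phenotype association uses Spearman (default) or Pearson
correlation via `cor.test()`.

## What the synthetic generator emulates — and what it does not

`simulate_study()` builds toy genomes with the statistical structure
the analysis assumes. Defaults are fixed once and are not tuning knobs:

* induced SNV spectrum: 79.1% C→T\*, remainder uniform over the other
  five classes — the published induced-spectrum headline used as a
  generator parameter;
* induced indels: 28.3% of insertions and 36.4% of deletions are 1 bp
  (published values); 58.3% of indels are deletions; longer lengths
  follow a geometric-like tail to 20 bp;
* landrace spectrum: 0.400 C→T\* and 0.235 A→G\* (transitions 0.635),
  chosen so Ts/Tv = 0.635/0.365 = 1.74 in expectation, the published
  landrace ratio; allele counts follow a neutral 1/i site-frequency
  spectrum over 2n−1 haplotypes;
* CC-context enrichment: induced C→T draws choose the
  C-followed-by-C pool (or the G-preceded-by-G mirror) with odds
  multiplied by 6. The observed +1=C fraction among induced C→T is not
  published, so this is a free parameter, set once to make the context
  signal unambiguous without saturating it; with the multiplier at 1
  the +1 composition provably matches the genome background;
* scale: 2 Mb genomes on 2 chromosomes, 11 lines, ~200 induced SNVs
  and ~45 indels per line, 13 landraces, 5,000 segregating sites,
  500 parent differences — sized so the full pipeline runs in seconds
  while keeping ≥5,000-event strata where the tests need binomial
  precision (those tests raise the per-line means to ~500);
* masks cover 20% of each chromosome. Real barley is ~80% uncallable,
  but that fraction is driven by repeat content the toy genome does not
  have; the masks here exist to exercise interval logic, not to
  reproduce repeat biology;
* residual heterozygosity of induced variants is 3% (survivors of five
  to seven selfing generations are overwhelmingly homozygous);
  spontaneous variants are added per line with Poisson means taken from
  the expectation model at the study's rates, so "induced + spontaneous
  mixture" is structural, not assumed away.

Every emitted variant is recorded in a ground-truth table
(sample, position, alleles, class, context flag, origin), which is what
end-to-end recovery is measured against: with default settings the
pipeline recovers ≥99% of induced variants and zero heterogeneity
variants survive.

The generator is deliberately not a population-genetic simulator: no
recombination, linkage, coalescent history, or demographic structure;
landraces only need allele-count strata and spectrum control. Induced
variants are placed uniformly at matching reference bases rather than
through any chemistry model. Passing tests therefore demonstrate that
the *pipeline and statistics* behave correctly under the stated
structure — not that real sequencing noise, alignment artifacts, or
caller-specific biases are handled; those enter real analyses upstream
of this package.

## Degenerate inputs and edge conventions

Zero-transversion sets, empty indel sets, zero-codon windows, constant
phenotype vectors and monomorphic sites are flagged (NA + warning)
rather than returned as infinities or errors; a single-line cohort
passes the privacy filter vacuously with a warning; variants at
sequence edges get a FALSE motif flag with a warning; a CDS whose
length is not a multiple of 3 is an annotation error for that gene.
Determinism is end-to-end: a config seed fixes every byte of generator
output, and control sampling is reproducible under its seed argument.
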