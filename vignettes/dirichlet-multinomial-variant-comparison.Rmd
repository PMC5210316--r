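---
title: "Calling RNA-DNA and RNA-RNA differences with a replicate-aware Dirichlet-Multinomial test"
author: "rddiff"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling RNA-DNA and RNA-RNA differences}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rddiff)
```

## The problem

RNA editing — most commonly ADAR-catalyzed A→I deamination, read as A→G by
sequencers — shows up as a difference between the base spectrum of a
transcriptome read stack and the matching genomic DNA (an RNA-DNA
difference, RDD), or between two RNA samples from different conditions (an
RNA-RNA difference, RRD). Naive per-site tests on allele counts are wrecked
by two things: allele counts across biological replicates are
*overdispersed* relative to a multinomial, and short-read artifacts (edge
effects, misalignment around INDELs and splice junctions, homopolymer
slippage, PCR duplicates, germline heterozygosity) masquerade as editing.
`rddiff` addresses both: an overdispersion-aware likelihood-ratio score and
an explicit artifact filter panel.

## The model

At one genomic site, let \(x = (x_A, x_C, x_G, x_T)\) be the base-call
counts of one replicate, \(n = \sum_k x_k\). Replicate-to-replicate
variability is modelled hierarchically: a base-probability vector
\(p \sim \mathrm{Dirichlet}(\alpha)\), then
\(x \sim \mathrm{Multinomial}(n, p)\). Marginalizing \(p\) gives the
Dirichlet-Multinomial

\[
P(x \mid \alpha) \;=\;
\frac{\Gamma(n+1)\,\Gamma(\alpha_0)}{\Gamma(n+\alpha_0)}
\prod_{k}\frac{\Gamma(x_k+\alpha_k)}{\Gamma(x_k+1)\,\Gamma(\alpha_k)},
\qquad \alpha_0 = \sum_k \alpha_k ,
\]

where \(\alpha/\alpha_0\) is the mean base-probability vector and
\(\alpha_0\) controls dispersion (large \(\alpha_0\): nearly multinomial).
All factorials are generalized through \(\Gamma\), because the counts the
likelihood actually sees are *real-valued*: base-call uncertainty enters as
a pseudocount \(\tilde{x} = x + x_P\). Each call with Phred score \(q\)
(error probability \(e = 10^{-q/10}\)) contributes \(\epsilon + e/3\) to
each of the three channels it did **not** call and nothing to its own
channel; \(\epsilon = 0.01\) is a fixed sequencing-independent noise floor.
The added mass is \(3n\epsilon + \sum_l e_l\), every channel becomes
strictly positive, and low-quality calls smear more mass onto the
alternatives. We read the pseudocount definition as per-call and
per-uncalled-channel additive — the only reading under which the "0 for the
called base" clause and the \(e/3\) uniform-miscall assumption are
simultaneously consistent — and leave the called channel's integer count
untouched (a flag for alternative behavior is deliberately *not* exposed:
nothing downstream ever uses the called-base probability).

## The test

For samples \(I\) and \(II\) with replicate sets
\(\tilde{D}^{I}, \tilde{D}^{II}\), concentration vectors are estimated by
maximum likelihood separately (\(\hat\alpha^{I}\), \(\hat\alpha^{II}\)) and
on the pooled union (\(\hat\alpha^{I,II}\)); the score is the
log-likelihood ratio

\[
z = \left[\ell(\hat\alpha^{I}) + \ell(\hat\alpha^{II})\right]
  - \left[\ell_I(\hat\alpha^{I,II}) + \ell_{II}(\hat\alpha^{I,II})\right].
\]

\(z\) is symmetric in the samples, invariant to replicate order, zero for
identical samples and non-negative because the pooled model is nested. No
p-value is attached; sites are called against score thresholds selected on
the in-silico benchmark: **1.15** for RDD (genome vs RNA) and **1.56** for
RRD comparisons, both user-overridable.

### Optimization

The MLE uses a Minka-style fixed-point iteration

\[
\alpha_k \leftarrow \alpha_k\,
\frac{\sum_i \psi(x_{ik}+\alpha_k) - N\psi(\alpha_k)}
     {\sum_i \psi(n_i+\alpha_0) - N\psi(\alpha_0)}
\]

with a method-of-moments start, relative log-likelihood tolerance 1e-6 and
a 100-iteration cap; a bounded quasi-Newton polish on \(\log\alpha\) runs if
the fixed point stalls early. Each update is a minorize-maximize step, so
the trajectory never decreases. Two numerical choices matter and were made
deliberately:

* **Duplication invariance.** The moment start uses population (\(1/N\))
  variances, so both the start and the fixed-point map are unchanged when a
  replicate set is duplicated. The pooled fit of two identical samples then
  reproduces the separate fits *exactly*, and \(z(D, D) = 0\) even when the
  MLE does not exist at finite \(\alpha_0\) (a single replicate, or no
  observed overdispersion, push \(\alpha_0 \to \infty\); the capped iterate
  is still a perfectly usable score anchor).
* **Dominance guard.** If a separate-sample fit ends below the pooled
  parameters evaluated on its own data (possible when the cap bites), it is
  refit starting from the pooled optimum; monotone ascent then guarantees
  \(z \ge 0\). A slack of 1e-6 prevents refits triggered by mere round-off,
  which would break the duplication symmetry above.

Channels with essentially no mass are floored at \(\alpha_k = 10^{-6}\),
and all \(\Gamma\)/\(\psi\) evaluations are in log space, so scores remain
finite at coverages of thousands.

### Coverage balancing

A very deep mono-allelic stack (typically 30x–1000x genomic DNA) paired
with a shallow RNA stack overstates the DNA side's confidence. When exactly
one side shows a single observed base across its replicates *and* its total
coverage exceeds the other side's by more than a trigger ratio (default 2,
configurable; the trigger is assessed on raw counts), that side is replaced
by a copy of the partner's stacks with every non-reference call reassigned
to the reference channel — the balanced side thereby inherits the partner's
replicate count, which is our literal reading of "a copy of the
heterogeneous stack". Balanced sites are flagged in the output
(`balanced=1`) for auditability, and balancing can be disabled.

## The filter panel

| Flag | Feature | Rule |
|------|---------|------|
| D | read edge | distance filter (below) |
| B | homopolymer run | distance filter |
| I | INDEL | distance filter |
| Y | splice junction | distance filter |
| H | genomic homozygosity | pooled gDNA coverage ≥ 10 and minor fraction ≤ 0.05 |
| M | maximum allele | < 3 distinct observed RNA bases |
| V | variant pre-screen | optional, off by default |

A distance filter removes a site when at least a proportion `r` (default
0.5) of its RNA calls lies within `d` nt (default 5, per-feature
overridable) of the feature; calls whose read lacks the feature count as
infinitely distant. The letters follow the original tool's conventions; the
feature names are the primary configuration vocabulary, so any cosmetic
mispairing of letters is harmless. Distance conventions: read-edge
distances are 0 at the terminal base; a base immediately adjacent to an
INDEL boundary or splice junction has distance 1; homopolymer distance is 0
inside a run of ≥ 7 identical reference bases (length configurable) and
counts from the run boundary outside. The paper defines neither the
homopolymer run length nor `d`/`r`; 7, 5 nt and 0.5 are common practice for
edge-artifact pruning and are exposed as configuration.

The H filter is only defined in RDD mode (it inspects the genomic sample);
for RRD comparisons the documented substitute is a post-hoc genomic
homozygosity check, exactly as done in the HEK-293 analyses. The optional V
screen (coverage ≥ 10, variant frequency ≥ 10%, ≥ 2 variant reads)
reproduces the classic threshold-based baseline and is off by default.

PCR duplicates: reads flagged 0x400 are always excluded; *marking*
duplicates is the upstream aligner/dedup tool's job and strongly
recommended. Overlapping mate pairs are counted twice (documented; collapse
upstream if needed). Deletions and reference skips contribute no call at a
site; ambiguous (N) calls are dropped before counting.

## The synthetic benchmark

`simulateDataset()` reproduces the in-silico study design at desk scale
(default 2,000 sites against the original 60,000): count stacks, not reads.

* **RDD**: one mono-allelic gDNA sample (reference + sequencing error)
  versus 1–5 cDNA replicates; half the sites carry an implanted variant in
  the cDNA only.
* **RRD**: two cDNA replicate sets; variant sites differ in expected
  frequency by at least Δ = 0.1, and SNP sites — implanted only in this
  scenario, as noise — carry pairwise-equal frequencies (heterozygous 0.5
  or homozygous 1.0, equal probability).

Per-replicate realized frequencies are Beta-distributed around the site
target with concentration β ∈ {10, 50, 100} (default 100); coverage is
uniform on [5, 1000] (the printed "5≥c≥1000" of the source design is read
as 5 ≤ c ≤ 1000, the only consistent reading); sequencing error is uniform
at rate 0.001 with constant simulated quality q=30 (the two are chosen to
be mutually consistent). Expected variant frequencies are not printed in
the source beyond the Δ constraints; the generator draws them once as:
RDD variants uniform on [0.05, 0.95]; RRD variants a base frequency uniform
on [0.05, 0.45] plus a gap uniform on [0.1, 0.5], side-swapped at random.
These are realistic editing-frequency ranges and are fixed, not tuned.
`variantFreqI/II` override them for controlled effect-size sweeps.

What a green benchmark test does and does not establish: the generator
emulates replicate count stacks with Beta-induced biological variability
and uniform sequencing error. It does **not** emulate mapping artifacts,
positional error profiles along reads, strand bias, or PCR duplication —
precisely the failure modes the filter panel targets on real BAMs, which
are exercised separately on synthetic SAM fixtures. Benchmark metrics are
therefore computed with the filter panel disabled: at simulated coverages
up to 1000x, pooled stacks almost always contain a third base type by
sheer error sampling, so the M filter would dominate the confusion matrix
with a property of the simulator rather than of the score. The evaluation
counts a site as true positive when its truth class is `variant` and it
passed; SNP and clean sites are negatives; precision at zero predicted
positives is reported as NaN with a warning.

## Degenerate inputs and ties

* Sites where any replicate has zero retained coverage are skipped with a
  message, not called.
* All-zero replicate vectors are an error in the fitting layer.
* Count tables carry no read context: positional filters are disabled with
  a single warning, and per-call qualities are imputed at a constant
  (default q=30).
* Output z is printed with 6 decimals under decimal round-half-even,
  implemented by string rounding on the `%.12f` representation so printed
  ties resolve by the half-even rule rather than binary representation
  accidents.
* Output ordering is total (contig, then position, then strand);
  multi-threaded runs partition by site ranges and merge in order, so the
  result bytes are independent of the thread count.

## Known limitations

* No p-value / FDR calibration for z — thresholds are benchmark-selected
  score cutoffs, as in the original method.
* No local realignment around INDELs (delegate to upstream tools), no CRAM,
  no mate-overlap deduplication, no VCF export (the score describes a
  two-sample difference, not a genotype).
* The single-replicate likelihood has its supremum at infinite
  concentration; fits there are capped, flagged `converged = FALSE`, and
  still usable — but single-replicate scores are systematically less
  stable, which is exactly the replicate-benefit the benchmark quantifies.

## A worked example

```{r example}
sim <- simulateDataset("RRD", nSites = 60, replicates = 3, seed = 7)
calls <- callSites(sim$tally, panel = FilterPanel(enabled = character(0)))
evaluateCalls(calls, sim$truth)
```
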