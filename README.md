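# rddiff

Replicate-aware detection of single-nucleotide differences between two
sets of sequencing samples: genomic DNA versus RNA (**RDD**, the classic
signature of RNA editing, e.g. ADAR-catalyzed A→I read as A→G), or RNA
versus RNA across conditions (**RRD**, differential editing). Intended for
anyone calling editing sites or condition-specific base changes from
replicate Illumina data — BAM files in, a BED-like score table out.

## The statistic

Base-call count vectors `x = (x_A, x_C, x_G, x_T)` at a site are modelled
with a Dirichlet-Multinomial `DirMult(x | α)` to absorb the overdispersion
of allele counts across biological replicates (`α/α₀` is the mean base
probability, `α₀` the dispersion scale). Base-call qualities enter through
a pseudocount `x̃ = x + x_P`, where each call of error probability
`e = 10^(−q/10)` adds `ε + e/3` (ε = 0.01) to each of its three uncalled
channels. Each sample's concentration vector is fitted by maximum
likelihood (Minka fixed point, method-of-moments start), and a site is
scored with the likelihood ratio against the pooled null that both samples
share one distribution:

    z = [ℓ_I(α̂_I) + ℓ_II(α̂_II)] − [ℓ_I(α̂_I,II) + ℓ_II(α̂_I,II)]

Sites pass at z ≥ 1.15 (RDD) or z ≥ 1.56 (RRD) — thresholds selected on an
in-silico benchmark — provided no artifact filter fires: positional
distance filters against read edges (D), homopolymer runs (B), INDELs (I)
and splice junctions (Y), genomic homozygosity (H) and a maximum-allele
filter (M). A deep mono-allelic DNA stack facing a shallow RNA stack is
first rebalanced (coverage balancing) so its depth cannot masquerade as
evidence.

The package also ships the in-silico benchmark generator (Beta-distributed
variant frequencies, RDD/RRD designs, SNP noise sites) and its
TPR/precision/accuracy/F evaluation, plus a small CLI.

## Worked example

```r
library(rddiff)

sim   <- simulateDataset("RRD", nSites = 60, replicates = 3, seed = 7)
calls <- callSites(sim$tally, panel = FilterPanel(enabled = character(0)))
head(calls, 3)
#> GRanges object with 3 ranges and 7 metadata columns:
#>       seqnames    ranges strand |         ref          z      filter  balanced
#>   [1]     sim1       100      * |           T  0.0116549           .     FALSE
#>   [2]     sim1       110      * |           C 23.5788212           .     FALSE
#>   [3]     sim1       120      * |           G  4.5749102           .     FALSE
#>          passed  ...
#>   [1]     FALSE  ...
#>   [2]      TRUE  ...
#>   [3]      TRUE  ...

evaluateCalls(calls, sim$truth)
#>   TP FP TN FN TPR precision  accuracy         F threshold
#> 1 30 11 19  0   1 0.7317073 0.8166667 0.8450704        NA
```

The first site is a clean site (z ≈ 0: the pooled model explains both
samples), the second a variant site with a frequency difference between
the RNA pools (z ≈ 23.6, well above the RRD threshold 1.56). The
evaluation line reads: all 30 implanted variants recovered (TPR 1.0), 11
of the 30 SNP/clean negatives leak through at this threshold (precision
0.73) — RRD comparisons trade precision for recall exactly because SNP
sites are present on both sides as noise.

Scoring one site directly:

```r
gdna <- list(makeRecord(c(30, 0, 0, 0)), makeRecord(c(28, 0, 0, 0)))
cdna <- list(makeRecord(c(22, 8, 0, 0)), makeRecord(c(24, 6, 0, 0)))
zScore(gdna, cdna)$z
#> [1] 7.489038
```

(Here `makeRecord` stands for any per-replicate record of counts and
qualities, as produced by `tallyBam()`, `readCountTable()` or the
simulator.)

From the shell, via the bundled wrapper (`inst/scripts/rddiff.R`):

```sh
Rscript inst/scripts/rddiff.R simulate --scenario RRD --sites 200 \
    --seed 7 --out-table counts.tsv --out-truth truth.tsv
Rscript inst/scripts/rddiff.R call-2 --table counts.tsv --mode RRD \
    --output calls.tsv
Rscript inst/scripts/rddiff.R evaluate --results calls.tsv \
    --truth truth.tsv --output report.tsv
```

BAM input (`call-2 --bams1 ... --bams2 ... --reference ref.fa --region
chr1:1-1000000`) additionally populates the per-call read context that the
positional filters need; count-table input disables those filters with a
warning.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes the package's main pipeline from scratch: it simulates the RDD
and RRD benchmark designs at desk scale (1,000 sites, 3 replicates,
β = 100), scores every site with the likelihood-ratio statistic at the
default thresholds, evaluates the calls against the simulation truth,
prints the per-scenario summary metrics, and writes the result JSON to the
`--out` path.
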