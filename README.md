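# genomesurvey

Survey statistics for large, highly heterozygous animal genomes — the
computational companion of a marine-invertebrate genome project such as
the sea cucumber, where high polymorphism complicates assembly and
tandem-duplicated gene clusters light up during visceral regeneration.
The package is aimed at genome-project analysts who need the survey
arithmetic to be *testable*: every estimator here can be exercised on
synthetic data the package generates itself, with known ground truth.

## What it computes

**k-mer spectrum.** Reads are split into odd-length k-mers (default
k = 17) counted under their canonical form (lexicographic minimum of
k-mer and reverse complement). The depth histogram of a diploid read set
is bimodal: homozygous k-mers at the k-mer coverage, haplotype-specific
k-mers at half that depth. The package locates the error cutoff (first
local minimum), the two peaks, and estimates haploid genome size as
genomic k-mer instances over the homozygous peak depth.

**Heterozygosity, three ways.**

- *Matching*: simulate diploid read sets over a grid of heterozygosity
  values and report the grid value whose spectrum is closest (L1 on
  normalized species frequencies) to the observed one.
- *Formula*: from the heterozygous species fraction `a1`,
  `KHR = (a1/2) / (2 − a1/2)` and `BHR = KHR / k`.
- *Mapping*: variant density on the assembly,
  `100 × (SNPs + indels) / length`.

**Assembly arithmetic.** N50/N90 (`nx`), counts above thresholds,
half-up-rounded percentage ratios, the Kosambi map function
`d = 25 ln((1+2r)/(1−2r))` cM, and the standard post-prediction
gene-model filter (CDS < 150 bp, or ab-initio-only + UniRef-only +
FPKM < 5).

**Tandem clusters and the regeneration screen.** Needleman–Wunsch
protein identity drives a greedy scan for runs of ≥ 6 adjacent paralogs
(up to one intervening gene); expression matrices over the nine
regeneration stages (control, 0.5 h–21 d post evisceration) convert to
FPKM and are screened for early-window fold changes, with
average-linkage clustering of log10(FPKM+1) profiles.

**Codon usage.** RSCU, CAI against a highly expressed reference set
(Sharp–Li 0.5 guard), Wright's effective number of codons
`Nc = 2 + 9/F̄2 + 1/F̄3 + 5/F̄4 + 3/F̄6`, and SVD-based correspondence
analysis with explicit labelling of the CAI-correlated axis.

## A worked example

```r
library(genomesurvey)

# a 1 Mb diploid genome at 2% heterozygosity, sequenced to 30x
ref <- simulate_reference(1e6, gc = 0.37, seed = 7)
dg  <- simulate_diploid(ref, het_rate = 0.02, seed = 3)
rs  <- simulate_reads(dg, coverage = 30, read_length = 100,
                      error_rate = 0.001, seed = 11)

hist  <- count_kmers(rs, k = 17)
peaks <- detect_peaks(hist)
peaks
#> <spectrum_peaks> error cutoff 3 | het 12 | hom 24
estimate_genome_size(hist, peaks)
#> [1] 1032359
tidy(estimate_het_formula(hist))
#> # A tibble: 1 × 6
#>   method     a1   khr     bhr     k grid_step
#>   <chr>   <dbl> <dbl>   <dbl> <int>     <dbl>
#> 1 formula 0.451 0.127 0.00748    17        NA
```

The spectrum shows the haplotype-specific peak at depth 12 — half the
homozygous depth of 24 (the k-mer coverage, `30 × 84/100`, shaved
slightly by the error rate) — and the genome size comes back within ~3%
of the planted 1 Mb. The formula route compresses the scale at high
heterozygosity (0.75% here for a planted 2%); the matching route
recovers the planted value exactly:

```r
sp <- list(genome_length = 1e6, coverage = 30, read_length = 100,
           error_rate = 0.001, k = 17)
est <- match_simulated_spectra(hist, seq(0.005, 0.045, 0.005), sp, seed = 77)
est$bhr
#> [1] 0.02
```

The printed survey percentages are one call each:

```r
mapping_heterozygosity(5379554, 486341, 804993085)   # 0.73
percent_ratio(28144, 30350, 2)                        # 92.73
kosambi_cm(0.25)                                      # 27.46531
```

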