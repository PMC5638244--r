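---
title: "Survey statistics for a heterozygous marine invertebrate genome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Survey statistics for a heterozygous marine invertebrate genome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(genomesurvey)
```

# What this package computes

`genomesurvey` re-implements, as tested and reusable functions, the
computational survey of a large, highly heterozygous animal genome — the
kind of analysis that accompanies the assembly of a marine invertebrate
such as the sea cucumber *Apostichopus japonicus*, an organism whose
eviscerated gut regenerates completely within weeks and whose genome
carries both high polymorphism and regeneration-associated tandem gene
clusters. Every analysis here runs on data the package can generate
itself, with known ground truth, so each estimator is validated by
parameter recovery rather than by fiat.

The pipeline covers five areas:

1. **k-mer spectrum analysis** — canonical k-mer counting, error cutoff,
   peak detection, spectral genome size;
2. **heterozygosity**, estimated three independent ways;
3. **assembly continuity and completeness arithmetic** — Nx statistics,
   printed percentage reproduction, the Kosambi map function, gene-model
   filtering;
4. **tandem-duplicated gene clusters** and a regeneration expression
   screen;
5. **codon-usage bias** — RSCU, CAI, the effective number of codons, and
   correspondence analysis.

# The k-mer spectrum model

Reads are decomposed into overlapping windows of odd length $k$ (default
17), and each window is counted under its *canonical* form, the
lexicographic minimum of the k-mer and its reverse complement; odd $k$
guarantees no window is its own reverse complement, so canonicalization
is unambiguous. The spectrum is the count of distinct k-mer species at
each depth. Counting is exact and in memory, with the histogram capped at
depth 10,000 (deeper species accumulate in the cap bin — a bounded-memory
contract, not an approximation anywhere the survey statistics look).

In a diploid read set, k-mers from homozygous sequence appear at a depth
near the k-mer coverage $C_k = C\,(L_r - k + 1)/L_r$, while k-mers
spanning heterozygous sites are specific to one haplotype and stack at
about $C_k/2$: the spectrum is bimodal, and the relative mass of the
half-depth component measures heterozygosity. Sequencing errors create a
third component of near-singleton k-mers at the low-depth end.

Three numerical choices matter here.

* **Error cutoff.** The boundary between the error mass and the genomic
  peaks is the depth of the first local minimum of the species counts,
  scanning upward (ties to the lower depth); a monotone-decreasing
  histogram falls back to depth 1. No counting tool prescribes this rule,
  so it is our own, and it is deliberately simple and deterministic.
* **Peak detection.** Candidate maxima are found on a centered moving
  average (window 3) of the zero-filled spectrum — a bare argmax is too
  noise-sensitive at desk-scale coverage — and each candidate is then
  refined to the raw-count argmax within one depth unit, which repairs
  the plateaus that smoothing creates at histogram boundaries. The
  homozygous peak is the highest-depth prominent maximum (prominence:
  at least 5% of the tallest smoothed bin); a heterozygous peak is
  reported when a prominent maximum lies within 0.35–0.65 times the
  homozygous depth. Ties always break toward the lower depth.
* **Genome size.** Haploid size is estimated as the total number of
  genomic k-mer instances (depth × species, summed from the error cutoff
  up) divided by the homozygous peak depth. Because the peak depth is an
  integer, the estimate carries a granularity of roughly $1/C_k$
  (about 4% at 30-fold coverage); the recovery tests accept 5%.

# Heterozygosity three ways

**Formula route.** The heterozygous species fraction `a1` is the share of
genomic k-mer species (depth at or above the error cutoff) lying below
the midpoint of the two peaks, rounded down. It feeds the k-mer
heterozygous ratio

$$\mathrm{KHR} = \frac{a_1/2}{\,2 - a_1/2\,},$$

and the per-base rate $\mathrm{BHR} = \mathrm{KHR}/k$, under the
approximation that each SNP creates $k$ new k-mers. The extraction rule
for `a1` is not uniquely fixed by the formula's provenance; we define it
over k-mer *species* (not instances) with the peak-midpoint boundary,
because species fractions are invariant to sequencing depth and give
values of the right order (a fraction near 0.85 yields a per-base rate
near 1.6% at $k = 17$). The choice is recorded in every report. The
formula route underestimates the planted rate at low heterozygosity —
at $h = 0.005$ the half-depth component is often too weak for a separate
peak and the route degrades to 0 — which is why it is validated as a
monotone trend, not an unbiased estimator.

**Matching route.** For each candidate $h$ on a grid, the package
simulates a diploid genome and read set under the same conditions as the
observed data, builds the simulated spectrum, and reports the grid value
minimizing the $L_1$ distance between the two normalized
species-frequency distributions (each over depths at or above its own
error cutoff; ties to the lower $h$). Normalized distributions make the
comparison robust to the different total k-mer counts of observed and
simulated runs. One simulation per grid point is the default;
`simulate_grid_spectra()` lets many observed spectra share one set of
reference simulations.

**Mapping route.** Variant density on the assembly:
$100\,(n_\mathrm{SNP} + n_\mathrm{indel})/L$, with indel events counted
once. This route systematically underestimates the spectrum-based values
because the best-assembled regions are the least heterozygous;
`het_report()` therefore presents all three routes side by side without
adjudicating.

# Assembly arithmetic

`nx()` sorts lengths descending and returns the length at which the
cumulative sum first reaches $x$% of the total — the standard N50/N90
convention, whose tie behaviour (first index reaching the threshold) is
fixed and oracle-tested. Every percentage the package prints uses
**half-up decimal rounding** (`percent_ratio()`), not R's round-half-even,
because that is how published survey tables are rounded.

The Kosambi map function
$d = 25 \ln\!\big((1+2r)/(1-2r)\big)$ cM converts recombination
fractions to genetic distances allowing for crossover interference; it is
linear ($d \approx 100r$) below $r = 0.01$ and diverges at $r = 0.5$.

`filter_gene_models()` implements the post-prediction filter as two
independent removal rules: coding region shorter than 150 bp, or
(ab-initio-only evidence AND no hit beyond UniRef AND FPKM < 5). The
source sentence for this filter is grammatically ambiguous; reading it as
two independent rules is our decision, and both flags and thresholds are
arguments.

# Tandem clusters and the regeneration screen

**Homology criterion.** Protein pairs are compared by global
Needleman–Wunsch alignment with match +1, mismatch 0, linear gap −1 and a
deterministic diagonal-preferring traceback; identity is matched columns
over alignment length. Identity (rather than similarity-matrix scoring)
keeps the criterion simple and reproducible; the default detection floor
of 0.3 reflects clearly detectable paralogy — random proteins align near
0.12 identity under this scheme, planted duplicates far above it.

**Cluster scan.** Within each scaffold's gene order, a run is extended
greedily while the next gene — allowing up to one intervening non-member
by default — aligns at or above the identity floor to *any* current
member; maximal runs of at least 6 members ("more than 5 repeats", read
strictly) are reported, and clusters are disjoint. The repeat-count
threshold, identity floor and intervening tolerance are all arguments,
because the counting conventions behind published cluster tallies are
rarely stated; the genome-wide count of such clusters is therefore not a
quantity this package tries to reproduce.

**Screen.** Counts convert to FPKM
($10^9 c / (\ell\,N)$), and each gene's fold change is the window maximum
over the baseline, both offset by a 0.01-FPKM pseudocount (a zero-aware
default; configurable). The baseline is the noneviscerated control; the
default window spans 0.5 h–3 d post evisceration. Profiles are clustered
on $\log_{10}(\mathrm{FPKM}+1)$ with Euclidean distances and
average-linkage (UPGMA) agglomeration via `stats::hclust`; genes are
sorted by id first so the dendrogram is independent of input order, and
average linkage cannot produce merge-height inversions.

# Codon usage

RSCU is each codon's count over its synonymous-family mean (stops
excluded; empty families score 0). CAI weights come from a highly
expressed reference set — classically ribosomal-protein genes — as
pooled counts scaled by the family maximum, with zero counts replaced by
0.5 before division (the Sharp–Li small-sample guard, which keeps a
single absent codon from annihilating the geometric mean). CAI itself is
the geometric mean of weights over a gene's codons, excluding Met, Trp
and stops.

The effective number of codons follows Wright: per-family homozygosity
$\hat F = (n\sum p_i^2 - 1)/(n-1)$, averaged within degeneracy classes,
then $N_c = 2 + 9/\bar F_2 + 1/\bar F_3 + 5/\bar F_4 + 3/\bar F_6$,
clamped to $[20, 61]$. The 6-fold families (Leu, Ser, Arg) form their own
class, as in Wright's original scheme. Families observed at most once are
excluded from their class mean; a missing 3-fold class (isoleucine
unused) is imputed as the mean of the 2- and 4-fold classes — Wright's
own recommendation — while any other missing class leaves the statistic
undefined rather than silently extrapolated.

Correspondence analysis is the standard SVD recipe: correspondence
matrix, double centering by the row/column-mass outer product, scaling by
square-root masses, singular decomposition; row principal coordinates and
inertia shares are returned. Which axis tracks expression-driven bias is
data-dependent, so `cai_axis()` labels the CAI-correlated axis explicitly
instead of assuming it is axis 2; axis signs are arbitrary, so
correlations are reported sign-corrected.

# The synthetic-data generators

The generators define the conditions under which every estimator is
validated:

* **Diploid genomes** mutate each reference position independently at the
  requested rate to a uniformly chosen different base, substitution-only
  by default (`indel_fraction` exists but defaults to 0: the KHR/BHR
  arithmetic concerns SNP-like k-mer splitting). The alphabet is strict
  ACGT — no N bases — which keeps the k-mer counting contract simple.
* **Reads** are single-end, uniformly placed, haplotype chosen fairly per
  read, with i.i.d. substitution errors and constant qualities. There is
  deliberately no machine error profile, quality model, duplicate
  structure or insert-size model; the spectrum statistics under test do
  not depend on them, and passing recovery tests therefore says nothing
  about such artifacts in real data.
* **Annotations** plant each requested cluster as adjacent mutated copies
  of one template protein on its own scaffold, mutating copies at
  per-residue rate $(1-\mathrm{identity})/2$ so the *pairwise* identity
  between members is about the requested value.
* **Count matrices** draw negative-binomial counts (dispersion 0.1 by
  default, the usual RNA-seq overdispersion scale) around log-normal
  per-gene baselines over the nine regeneration stages (control, 0.5 h,
  2 h, 6 h, then 3, 5, 7, 14, 21 d post evisceration). The default
  baseline scale (~2,000 fragments per gene, i.e. a realistically deep
  library) and the near-silent baseline of planted genes (mean 100,
  applied when fold > 1) reproduce the geometry that makes four-digit
  FPKM fold changes observable in real data: induced genes start from
  almost nothing, and the rest of the transcriptome is large enough that
  the induction inflates per-stage library sizes only a few-fold. With
  toy-sized libraries, FPKM normalisation itself would cancel most of a
  planted 10,000-fold induction — a composition artifact, not a property
  of the screen.
* **Coding sequences** draw amino acids uniformly and choose synonymous
  codons with probability $1/f + b\,(1 - 1/f)$ for one designated optimal
  codon per family (bias $b$), interpolating from uniform usage at
  $b = 0$ to maximal bias at $b = 1$.

Every generator takes an explicit seed and is byte-reproducible; every
generated object can be written to its standard format (FASTA, FASTQ with
Sanger+33 qualities, GFF3 with 1-based inclusive `gene` features, TSV
matrices and histograms) alongside a JSON ground-truth sidecar.

# Problem sizes and determinism in the test suite

The recovery suites run at 1 Mb genomes, 30-fold coverage, 100 bp reads
and 0.001 error — large enough that the spectrum peaks are well formed,
small enough to run on a laptop. The heterozygosity-matching benchmark
evaluates 20 observed/grid seed pairs over planted rates
{0.5%, 1%, 2%, 4%} on a 0.5%-step grid, sharing each set of grid
simulations across the four planted rates. Unit tests use smaller
genomes (100–200 kb) where only correctness, not resolution, is at
stake. All stochastic tests fix their seeds; stochastic acceptance
bounds (e.g. 90% recovery, ±2 on a limiting Nc) are set by the
concentration of the statistic, not tuned to runs.

# Known limitations

* The formula route's `a1` definition is one defensible choice among
  several; its absolute scale should not be compared across packages
  without checking that choice.
* The spectral genome-size estimate inherits the integer granularity of
  the peak depth (~4% at 30-fold coverage).
* Tandem detection is greedy and single-pass; pathological identity
  structures (chains that are pairwise-similar only through
  intermediates) can extend a run further than an all-pairs criterion
  would.
* The expression model plants a shared fold across the whole window;
  stage-shaped induction profiles are not modelled.
* Correspondence analysis assumes a complete, non-degenerate RSCU
  matrix; genes short enough to miss entire codon families should be
  filtered before interpretation.
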