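---
title: "Methods: inversion validation and introgression analysis in invintro"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: inversion validation and introgression analysis in invintro}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`invintro` analyses chromosomal inversions and introgression in diploid
colony panels. This vignette documents the models and decision rules,
the parameters that matter, what the synthetic-data generator does and
does not emulate, and the numerical choices made where the design was
genuinely open. It states no empirical result that the package's tests
and acceptance script do not themselves compute.

## Coordinates and containers

All intervals are 0-based half-open. VCF positions convert at the I/O
boundary; published call-table position strings (`chrom:start-end`) are
taken verbatim, because those tables' own arithmetic is
`size = end - start`. The central container, `genotype_panel`, holds an
ordered biallelic site table, two allele matrices (haplotype-resolved
when phased), and sample→colony→role maps.

## Site filtering and callsets

`filter_sites()` applies strict GATK-style thresholds: QD > 5, FS < 60,
|ReadPosRankSum| < 8, biallelic SNPs only. Rank-sum annotations are
signed, so the absolute-value reading is the default; a config switch
(`signed_ranksum`) gives the literal one-sided reading, and the rank-sum
field itself is configurable (`ReadPosRankSum` default, `MQRankSum`
accepted) since either may be meant by an unqualified "RankSum".
`build_callsets()` forms the *colony* callset (sites reliably called in
every colony — by default ≥ 1 non-missing genotype per colony, a
configurable rate, since no explicit rate is standard) and the
*conserved* callset (additionally called in every outgroup panel, whose
samples are appended so derived-allele polarization can use them). The
conserved site list is a subset of the colony list by construction.

## Candidate merging

Two callers' per-sample inversion candidates are merged when their
reciprocal overlap — `min(|a∩b|/|a|, |a∩b|/|b|)`, the symmetric reading
of "95% pairwise overlap" — reaches 0.95, with single-linkage clustering
across samples and callers (a one-directional variant is available via
the threshold flag). The merged interval is the union span of members;
breakpoint coordinates for validation are the medians of member
endpoints. Microinversions are calls strictly under 500 kb. Call ids
follow the arm-letter convention (`3qau`), with arm assignment pluggable.

## Breakpoint validation

For an inversion segment `[s, e)` with flank `F` (default 10 kb —
comfortably above the 1-kb span rule and half a typical long read), the
pan-genome holds four junction contigs (reference and inverted allele of
each breakpoint) plus, optionally, the chromosome with both true
junction neighborhoods masked to `N` so background reads are not forced
onto a junction.

Reads longer than 5 kb are competitively aligned. The built-in aligner
is a k-mer seed / diagonal-band scorer (Rcpp; k = 15, stride 3, repeat
k-mers above 8 contig occurrences ignored, 64-bp bands merged with their
right neighbor). It is substitution-tolerant and sufficient for
junction-orientation classification at percent-scale error;
indel-realistic external aligners plug in through `table_aligner()`,
which consumes PAF-like records. Decision rules, in order: an alignment
must span the junction by ≥ 1 kb on both sides or the read stays
unassigned; exact score ties between the reference and inverted contig
make it ambiguous (excluded from both numerator and denominator of the
inverted fraction); otherwise the best contig's orientation counts.

The null calibration samples 1000 artificial uninverted breakpoint
pairs whose junction-flank repeat content matches the candidate set's
distribution (per-locus target drawn from the candidates, rejection
sampling within ±10 percentage points, tolerance doubled with a warning
if matching stalls). Coverage quartiles use the type-7 (linear
interpolation) convention, stated explicitly because IQR fences depend
on it. A breakpoint is discarded below 10× coverage or above
Q3 + 2×IQR of the null coverage distribution (upper fence only by
default — high coverage signals collapsed repeats; a both-tails flag
exists), and passes when the inverted fraction strictly exceeds 0.37.
The 37% constant is a config value, not derived from the null at run
time. An inversion is valid only when both breakpoints pass. The
misassignment rate reported by `calibrate_null()` is the fraction of
coverage-surviving null junctions that would pass the fraction rule.

Assembly validation classifies realigned supercontig segments:
contigs > 10 kb, segments with score > 60 (strict), and an inverted
junction is supported when adjacent segments join the same-side flanks
of the two breakpoints with opposite strands; both junctions across all
supercontigs validate the call.

## Population genetics

Windowed π sums the unbiased per-site heterozygosity
`2p(1−p)·n/(n−1)` and divides by window length (1 Mb default), matching
the windowed-tool convention; a callable-sites denominator sits behind a
flag. ROH detection is a density scan declared on its own terms (the
reference tool's internals are unpublished): seed intervals between
consecutive heterozygous calls are greedily extended while the
heterozygous density stays ≤ 5/Mb (inclusive), and intervals ≥ 1 Mb are
reported; masking removes sites but keeps the window-length denominator,
so masking can only lower π. F_st is Weir–Cockerham (1984), windowed as
the ratio of summed variance components; monomorphic windows are
missing, not zero, and the estimator is allowed to be negative. AIMs
require pooled-subspecies F_st strictly above 0.8, callability in both
callsets, and differing pool-major alleles; "predominantly donor" in
ancestry scoring means donor-allele frequency strictly above 0.5.
Founder-haplotype clustering is greedy in descending length with the
longest member as cluster representative; a haplotype is novel at more
than 1 difference per kb of overlap, and overlaps under 1 kb leave it
unassigned.

## Introgression

The frequency (population-sample) form of Patterson's D is used — the
colonies contribute multiple diploids, so site-pattern counting on
single sequences would waste information. The outgroup polarizes:
where its alternate-allele frequency exceeds 0.5 the site is flipped,
and sites with polarized outgroup frequency above 0.1 are excluded.
Jackknife blocks are contiguous coordinate slabs; the full-scale
default is 5 Mb, and the toy pipeline uses 1 Mb so ≥ 10 blocks exist on
a 15-Mb genome. SD is the standard delete-one-block formula and
|Z| ≥ 2 (inclusive) is significant. ƒD replaces p2 and p3 by
`pD = max(p2, p3)` per site in the denominator sum; windows with
non-positive numerator are missing. Peaks require ƒD above
Q3 + 1.5×IQR of all non-missing windows (a Tukey fence; a median anchor
is available) *and* at least 90% of the rolling maximum over a centered
neighborhood. The neighborhood is 200 Mb at full genome scale and
scales proportionally — 2 Mb at the generator's 1/100 toy scale, where
the package also uses 250-kb ƒD windows so that enough windows exist
for stable quartiles (at full scale 1-Mb windows match the
heterozygosity convention).

A property worth documenting: with realistic finite panels
(≈ 6–20 chromosomes per population), mean ƒD inside introgressed tracts
is a *conservative* estimate of the admixture fraction — sampling noise
in `max(p2, p3)` inflates the denominator, and we observe ≈ 0.6–0.7 of
the simulated fraction across drift settings. The package's recovery
tests therefore assert strict monotonicity of tract ƒD in the simulated
fraction and a band well above zero, not unbiased equality.

## Phylogenies

Characters are binary (biallelic SNPs); missing data is the universal
state set and never forces a change. Before scoring, trees are rooted
deterministically at the lexicographically first tip so every internal
node is binary and the Fitch pass is exact — which also makes the score
provably invariant to the rooting the caller supplies. Search is
exhaustive over all unrooted topologies up to 9 taxa, and stepwise
addition (seeded random order) with NNI hill-climbing and restarts
above. Co-optimal topologies are reported and reduced to a strict
consensus; bootstrap support (100 replicates by default) is the
percentage of replicate best trees containing each bipartition, mapped
onto the consensus. Genome-wide trees use one representative per sample
(heterozygotes take the majority allele, exact ties resolved randomly
under the seed); regional trees use phased haplotypes over the
inversion span expanded symmetrically to at least 1 Mb ("around" an
inversion is operationalized as centered expansion, no shrink for
larger spans). Clade-nesting classification roots at the outgroup
(falling back to the first outgroup tip if the outgroup is not
monophyletic), finds each group's smallest containing clade, and flags
foreign non-outgroup taxa inside it — the operational signature of an
introgressed haplotype.

## The synthetic-data generator

The generator emulates the structure of a two-subspecies colony study
at 1/100 coordinate scale: 3 chromosomes × 5 Mb with 30% planted
tandem-repeat arrays; eight colonies (two pure pools per subspecies, a
three-colony hybrid zone, a sister-species outgroup; 23 diploids total)
drawn from small founder pools. Differentiation is Balding–Nichols
drift (chosen over coalescent simulation because it directly
parameterizes the subspecies differentiation that AIM and F_st recovery
need, with no external simulator): ancestral frequencies are Beta(0.6,
0.6), subspecies pools drift with F = 0.35 (Aaa) and 0.22 (Aaf) — the
globally derived subspecies is the more drifted, so its colonies show
lower π — colonies add F = 0.05, the outgroup F = 0.75. Introgression
is tract copy-paste after drift, producing the block structure a
windowed scan assumes. The default hybrid-zone configuration mirrors
the study design qualitatively: one *shared* (swept) donor tract per
chromosome covering 6% of it into the Kenyan Aaa colony — localized
signal that peak calling must find — over 5% diffuse per-haplotype gene
flow, with heavier diffuse admixture into the hybrid colony (35%) and a
weaker reverse flow (10%). Inversions (6 micro, 2 large by default) are
auto-placed at repeat-poor flanks and spiked into haplotypes at
per-colony frequencies; long reads are log-normal with
`meanlog = log(N50) − sdlog²` so the length-biased median matches the
Nanopore-like N50 of 6789 bp, with uniform substitution errors (5%
default); two caller profiles differ in size-class sensitivity,
breakpoint jitter, and repeat-located false positives.

What the generator does **not** emulate: linkage disequilibrium decay
within colonies (founder haplotypes are whole chromosomes),
barcode-level linked-read structure, indel or homopolymer read errors,
TE mobilization, and reference mis-assembly. Passing recovery tests
therefore demonstrates the pipeline's decision rules and calibration,
not robustness to indel-heavy alignment or assembly artifacts — for
real data the aligner adapter should wrap a production long-read
aligner.

## Problem sizes

The test-suite and acceptance experiments use the toy scale throughout:
3 × 5 Mb genomes, ~50k sites, 1000 artificial breakpoints at ~30× read
coverage for the null calibration, 10-taxon/200-site bootstrap panels
with 100 replicates, and 10-seed sweeps for the D significance checks —
sizes chosen so the full suite completes on a single CPU in minutes
while keeping every rule (coverage fences, quartiles, jackknife block
counts) statistically meaningful.

## Known limitations

- The built-in aligner is substitution-only; indel-dominant error
  profiles need the adapter.
- ƒD attenuation (above) means absolute admixture fractions from small
  panels should be read as lower bounds.
- The exhaustive/heuristic parsimony search returns co-optimal sets but
  makes no claim of completeness for the heuristic regime beyond its
  restarts.
- Colony panels carry founder effects by design; population-genetic
  estimates from them describe the colonies, not wild populations.
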