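---
title: "Methods: recombination-landscape analyses in recland"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: recombination-landscape analyses in recland}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`recland` implements three interval-based analyses of fine-scale
recombination landscapes — hotspot density by meiotic expression, metagene
profiles of recombination rate around genes, and repeat-family enrichment
of DSB hotspots under a constrained permutation null — together with a
synthetic-data generator that makes every stage verifiable against planted
ground truth. This vignette is the package's account of the models, the
parameters that matter, the numerical choices, and what the tests do and do
not establish.

## Coordinates and containers

Interval files follow the BED convention (0-based starts, exclusive ends);
GTF is 1-based inclusive and converted on read. Internally intervals live
in `GRanges`, the standard R/Bioconductor container, which is 1-based and
closed; `bed_ranges()` and every reader/writer do the conversion, and all
documented arithmetic (centers, windows, distances) is specified in 0-based
terms. Readers *reject* coordinates outside the declared genome layout
rather than clipping them: silent clipping is how peak files acquire
phantom peaks at chromosome ends.

The center of a peak spanning `[start, end)` is `floor((start + end) / 2)`;
for an even-length peak this is the left of the two middle candidates,
which keeps the arithmetic deterministic. A center window of halfwidth
`h > 0` is `[center - h, center + h)`, clipped to the chromosome; `h = 0`
degenerates to the single center base, so "overlap" remains well defined.

## The callable genome and the constrained shuffle

Peaks can only be called where the assay can see them. The callable mask is
the genome minus the union of (i) an ENCODE-style blacklist and (ii)
zero-coverage runs longer than `min_zero_run` (default 1000 bp,
configurable): a long run with no reads could hide a real hotspot, so
leaving it in the null space would bias every enrichment downward.
Zero-coverage runs are consumed as intervals; computing them from
alignments is out of scope.

`shuffle_peaks()` draws a placement for every peak uniformly over *all
legal placements* genome-wide: a mask segment of length `L` offers
`L − w + 1` start positions to a peak of length `w`, so a segment is chosen
with probability proportional to that count and the offset uniformly within
it. This is implemented as a single uniform integer draw over the total
placement count, inverted by a vectorised binary search over segments
sorted by length — one RNG call per peak set, which keeps a
40-permutation null over thousands of peaks inside interactive running
times. Peak count and the exact multiset of peak lengths are conserved;
shuffled peaks may overlap each other (the least-constrained faithful
reading of a genome-wide shuffle), and shuffling is not restricted to the
chromosome of origin. Each permutation `i` of an enrichment run uses seed
`seed + i`, so the full null is reproducible from one integer.

## Repeat-family enrichment and the range rule

For each repeat family, the observed statistic is the number of peaks whose
center ± 100 bp window touches at least one element of the family (a peak
may count toward several families; the per-family window semantics are also
available as a strict center-to-element distance rule, `< 200` bp, matching
the alternative published phrasing). The chance expectation is the mean of
the same statistic over 40 shuffles; the enrichment ratio is
observed / null mean. Significance is deliberately the permutation *range
rule*: a family is `enriched` (or `depleted`) only if the observed count
lies strictly above the maximum (below the minimum) of the 40 null counts,
and `NS` otherwise. Under exchangeability this has a false-call probability
of exactly `2/(n+1) = 2/41 ≈ 0.049` per family when counts do not tie —
a property the test suite verifies by simulation. A one-sided empirical
p-value `(1 + #{null ≥ obs})/(n + 1)` is reported alongside as a
diagnostic, not as the decision rule. When the null mean is zero with a
positive observed count the ratio is reported as `Inf` rather than being
silently dropped; zero observed over zero expected is `NA` and `NS`.

Counts are integers, so the 2/41 calibration assumes the null distribution
is spread over enough values that ties at the extremes are rare. The
calibration experiments therefore use 2000-peak sets (tests) over a 20 Mb
toy genome, where per-family null standard deviations are ≳ 5 counts; with
much smaller peak sets the realised false-call rate falls below 2/41
because ties at the null maximum cannot be exceeded.

## Density by expression category

Genes are ranked by expression — ties broken by gene id so the split is
reproducible — and cut into `n` nearly equal quantiles (sizes differ by at
most one gene). Genes with no expression value are dropped by default
(configurable to zero-fill); zero-expressed genes are *kept* and fall into
the bottom quantile, since this stage applies no detectability filter. Each
category's territory is the per-base union of its gene spans minus the
blacklist; intergenic space is the genome minus all gene spans minus the
blacklist. Relative density and its binomial standard error are

```
relative_density_c = (k_c / L_c) / N      se_c = sqrt(p(1-p)/N) / L_c,  p = k_c/N
```

In the default `midpoint` mode a peak is assigned to the single category
containing its center, so `sum(k_c) = N` exactly — a conservation law the
tests assert. `any_overlap` mode, the literal reading of "peaks
overlapping a category", multi-counts boundary peaks and is provided for
comparison. Peaks whose center (midpoint mode) or span (any-overlap mode)
falls in the blacklist are excluded from `N` and all counts. A category
whose territory is erased (length 0) reports `NA` densities — undefined is
not zero. If user-supplied gene spans of different categories overlap a
center, the higher category wins deterministically; generated annotations
never overlap.

## Metagene profiles around TSS/TES

Only genes with detectable expression (value > 0) enter the profile, split
into three equal-sized classes by rank. The genome is scanned in fixed
1 kb windows; each window midpoint is assigned to the nearest gene *of the
class being profiled* — so intergenic windows contribute to each class
relative to that class's own genes, which is what lets the three curves
share a common distance axis. Inside a gene, the side is the nearer of
TSS/TES in transcription orientation and the offset is the distance to
that end (≥ 0); outside, the side is the flanked end and the offset is
negative. Everything is strand-aware; a reflection test (minus-strand gene
vs mirrored plus-strand gene) pins this down. Nearest-gene ties break by
smallest gene id, and an exact inside tie between the two ends goes to the
TSS.

Per (class, side, bin) the reported rate is the coverage-weighted mean
`sum(rate × bp) / sum(bp)` over contributing windows, with the covered
bases reported alongside. Window width, bin width (1 kb) and the 50 kb
distance cut-off are configurable defaults chosen at the scale of mammalian
genes; none of them affect the two identities the tests enforce — a
constant map yields exactly flat profiles, and with an unbounded distance
cut-off the coverage-weighted mean over all bins equals the global
length-weighted map mean.

## The synthetic generator and what it does (not) show

`synthetic_config()` describes a toy genome whose defaults are chosen to
resemble a mammalian landscape at 1/100 scale: 4 chromosomes × 5 Mb, 800
non-overlapping genes with log-normal lengths (median 8 kb; ~40% genic
fraction), log-normal expression with 20% silent genes, repeat families at
set genomic fractions (L1 15%, ERVK 4%, MIR 2.5%, Simple_repeat 2%, MaLR
1%), a 2% blacklist, 5% zero-coverage runs (log-normal lengths around
1.5 kb, so only some exceed the 1 kb callable threshold), and 2000
hotspots of ~300 bp. The planted-enrichment target family (MaLR) is kept
at a small genomic fraction on purpose: hotspots are placed by thinning
(max-factor rejection sampling), so a planted factor is exactly the ratio
of placement densities, but the acceptance of extra peaks near one family
renormalises the density everywhere else by `1/(1 + (f−1)q)` with `q` the
zone's share of the mask. At `q ≈ 1%` that renormalisation is second-order
and unplanted families remain NS at close to the nominal rate; at several
percent it would register as spurious depletion of the large families.

The recombination-map generator is deterministic given the annotation: a
piecewise-constant background multiplied by a TSS factor within ±1 kb of
every TSS and by a per-tertile suppression factor inside gene bodies
(defaults 1 / 0.8 / 0.5, mirroring the observed deficit of crossovers in
the bodies of highly expressed genes). Where the recovery experiments
quantify the gene-body factor they set the TSS factor to 1, because the
TSS zone overlaps the first kilobase of its own gene and would otherwise
confound the inside/outside contrast.

Everything is deterministic given the seed (the hotspot sampler uses an
offset stream so annotation and hotspots are independently reproducible),
and the generated files are valid inputs to every reader — a round-trip
property the tests exercise.

What passing these tests shows: the estimators are unbiased at planted
effect sizes, the null is correctly constrained and calibrated, and the
pipeline is deterministic. What they do not show: behaviour under
real-data features the generator omits — sequence content and motifs,
covariance between repeat density and gene density, non-uniform background
placement of hotspots, chromosome-scale rate variation, and the
heterozygosity-dependent detection power of NCO events (explicitly out of
scope).

## Problem sizes and budgets

The verification experiments are sized to run on a laptop-class single
core: 100 random instances for the brute-force overlap oracle, 1000
shuffles of a 200-peak set for conservation/containment plus 10,000 1-bp
placements for the uniformity chi-square, 500 null simulations × 5
families for the range-rule calibration (2000-peak sets), 50 small
replicate datasets for the unplanted-NS rate, and full-size (20 Mb, 2000-
or 5000-peak) datasets for the three recovery experiments. The standalone
`scripts/acceptance.R` recomputes the same quantities with 200 calibration
simulations and 30 replicates.

## Known limitations

* The density stage treats "transcript length" as the whole TSS→TES span,
  not exon unions; expression-weighted isoform structure is ignored.
* `any_overlap` mode breaks the `sum(k_c) = N` conservation by design;
  comparisons across modes should use the counts, not the totals.
* The profile stage assigns windows by midpoint; windows straddling a gene
  boundary contribute their whole coverage to the midpoint's bin.
* The shuffle treats the mask as the only constraint: it does not preserve
  per-chromosome peak counts, local GC or repeat context. Where the
  scientific question requires those constraints, the null is too liberal
  and the enrichment ratios should be read accordingly.
* Reported empirical p-values are one-sided and not multiplicity-adjusted;
  the range rule itself applies no correction across families.
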