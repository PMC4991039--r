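---
title: "Pseudo-testcross linkage mapping with ptcmap: models, filters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pseudo-testcross linkage mapping with ptcmap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ptcmap)
```

## The mapping problem

In an outbred F1 family — say, a cross between two heterozygous forest
trees — most SNP sites are heterozygous in exactly one parent. A marker of
type *ab×aa* (mother `ab`, father `aa`) transmits the maternal `a` or `b`
allele to each progeny with equal probability, so progeny genotypes
segregate 1:1 and carry information about *maternal* meiosis only; *aa×ab*
markers are the paternal mirror image. Each parent can therefore be mapped
exactly like a backcross parent. This is the pseudo-testcross strategy,
and it dictates the package's central constraint: maternal and paternal
markers are mapped separately, because a pair of markers informative for
different parents shares no recombination information.

ptcmap implements the full chain from genotype calls to ordered parental
maps, together with a meiosis simulator that generates families with known
truth, including two independently noisy "reference views" of the same
family (emulating genotypes called twice, once against each parent's rough
draft assembly).

## Two-point model

For two same-parent 1:1 markers, the four combined progeny classes reduce
to allele-concordant versus allele-discordant. With `n` co-observed
progeny and `m` discordant ones, the parental linkage phase is unknown, so
it is inferred by minimising the recombinant count:

* coupling if `m <= n - m` (recombinants `k = m`),
* repulsion otherwise (`k = n - m`),
* `m = n - m` is reported as `undetermined` with `r = 0.5`.

The maximum-likelihood recombination fraction is then `r̂ = k/n`, and the
support for linkage is the base-10 likelihood ratio against independence,

```
LOD = (n - k) log10(2(1 - r̂)) + k log10(2 r̂),
```

with `k log10(2r̂)` read as 0 when `k = 0`. Its expectation under a true
fraction `r`, `ELOD = n[(1-r) log10(2(1-r)) + r log10(2r)]`, is what makes
150 progeny a comfortable family size: at `r = 0.30` it already gives

```{r}
expected_lod(0.30, 150)
```

Distances are reported through the Kosambi mapping function
`d = 25 ln((1+2r)/(1-2r))` cM, so the largest distance a "moderately
linked" adjacent pair (`r = 0.30`) can span is

```{r}
kosambi_distance(0.30)
```

`estimate_rf()` is tested against a brute-force maximisation of the same
likelihood on a 0.0001-grid of `r` for every recombinant count up to
`n = 200`, and the Kosambi pair round-trips to 1e-9 relative over
0–200 cM.

## The filter cascade

All thresholds live in `filter_config()`, with defaults equal to the
protocol the package follows:

| stage | rule (default) |
|---|---|
| alignment records | drop if edit distance > 9, best score < 60, or second-best > best |
| SNP discovery | site MQ ≥ 20 and read depth ≥ 5 in either parent (union of parents) |
| genotype calls | missing unless DP ≥ 10 and GQ > 50 (strictly) |
| marker QC | drop if 1:1 chi-square p < .01 or missing fraction > 0.10 (strictly) |

Boundary semantics are deliberate and tested: GQ must *exceed* 50, while a
marker missing in exactly 10 % of progeny survives. The 1:1 test is the
plain goodness-of-fit statistic `(n_aa - n_ab)^2 / (n_aa + n_ab)` on 1 df
without a continuity correction — at family sizes around 150 the
correction is immaterial. Because the counts are discrete, the realised
size of the p < .01 rule at n = 150 is 1.11 %, not 1 % exactly; the
acceptance suite checks the simulated removal fraction against this exact
binomial size, not against the nominal level.

One wrinkle worth noting: the source protocol states the alignment rule
both as an absolute score floor (best ≥ 60) and, elsewhere, as a margin
(best at least 60 above second-best). `keep_alignment()` implements the
absolute reading — procedurally the clearer statement — and keeps both the
floor and the second-best comparison as separate configurable thresholds,
so the margin reading is a one-line configuration away.

Genotypes that are possible in the VCF but impossible under the cross
(a progeny homozygous for the allele the homozygous parent does not carry)
are coded missing rather than raising an error; only alleles outside the
site's ref/alt set are treated as input corruption.

## Cross-validation of two reference views

When the same family is called against two different draft references,
agreement between the two call sets is powerful quality evidence. Two loci
are "identical" when their coded genotype vectors have Hamming distance 0
across the progeny. Two decisions matter here:

* **Coding.** Comparison is on coded `aa`/`ab` vectors, never nucleotide
  genotypes: ref/alt labels are reference-specific, so nucleotide-level
  comparison destroys genuine matches. `venn_counts()` exposes both modes,
  and the coded-mode counts are provably never smaller.
* **Missing data.** The default policy compares co-observed progeny only
  and requires equality at all of them. With up to 10 % missingness per
  view, requiring equality at *all* positions (the `strict` policy, also
  available) would reject essentially every true match for reasons that
  have nothing to do with genotype disagreement.

Zero tolerance over ~150 progeny is a harsh test — a single discordant
call disqualifies a locus — and that is the point: it is the mechanism by
which two noisy datasets validate each other. At the simulator's default
inter-view error rate (0.002 per call per view) roughly half of the loci
survive, which is the retention regime dual-reference studies report.

After matching, `bin_markers()` collapses completely linked markers
(identical coded vectors) that sit within 1 kb of each other on one
contig into a single representative (the member with fewest missing
calls; ties to the smallest coordinate). Both conditions are required —
identical vectors alone, or adjacency alone, do not collapse anything.
For binning, "identical" is exact vector identity including the
missingness pattern; pairwise co-observed identity is not transitive and
would make the grouping ill-defined.

## Grouping and ordering

Linkage groups are connected components of the graph with an edge wherever
pairwise LOD clears a threshold (single linkage). The threshold is a
user choice (default 6); `select_threshold()` scans a range and picks the
smallest threshold producing a requested number of multi-marker groups,
which is how a 19-chromosome karyotype is dialled in when the group count
is known.

Within a group, markers are ordered by minimising the sum of adjacent
recombination fractions (SARF). `order_group()` uses greedy
nearest-neighbour construction from multiple random start markers, each
refined by a local search alternating best-improvement 2-opt segment
reversals with Or-opt relocations of segments of length 1–3; the best
order over all starts is returned, canonically oriented (first marker id
sorts before the last) with equal-SARF ties resolved lexicographically, so
results are reproducible. `brute_force_order()` provides the exact
optimum for groups of up to 10 markers; the test suite holds the heuristic
to the exhaustive optimum on 100 random instances of size up to 8.
Default restarts are `max(20, group size)` — cheap at realistic group
sizes and comfortably redundant for the local search.

`build_map()` turns adjacent fractions into Kosambi intervals and
cumulative positions, carrying the inferred phase of each adjacent pair.
An adjacent `r̂ = 0.5` is an error, not a 250-cM interval: it means the
chain is broken and grouping or ordering should be revisited. Pairs at
`r̂ = 0.5` are never mapped as distances.

## What the simulator does and does not emulate

`make_parent_spec()` lays out chromosomes with interleaved maternal and
paternal markers; per-interval recombination fractions are set so that
consecutive same-parent markers sit a requested Kosambi distance apart
(default 5 cM; the composite fraction over intervals is
`(1 - prod(1 - 2 r_k))/2`). Meioses are simulated with independent
recombination per interval — no crossover interference — because the
analysis chain estimates pairwise `r` and uses Kosambi purely as a
distance transform, so truth is naturally defined on `r`. Parents are
error-free and fully genotyped, mirroring the fact that parental sites
are filtered before progeny genotyping.

Noise is layered in the order real data acquires it: per-call missingness
and `aa↔ab` errors (`degrade()`), then per-view locus drops, independent
per-view call flips, view-specific ref/alt labels and contig coordinates,
and DP/GQ/MQ draws with configured fractions failing the thresholds
(`emit_dual_views()`). Output is plain VCF v4.2 with GT/DP/GQ and
INFO/MQ, re-imported through the same `read_family_vcf()` path real data
would use, so every run exercises the full contract. One master seed
derives fixed per-stage child seeds; identical configuration and seed
give byte-identical files.

Defaults where the protocol is silent are free parameters chosen once:
missingness 0.05 (half the QC budget), call error 0.005, inter-view flip
0.002, 2 % of calls failing DP/GQ, 1 % of sites failing MQ, 5 % locus
drop per view. Segregation distortion defaults to 0; when enabled it acts
as local viability selection against the `ab` class at a chosen fraction
of markers, which is sufficient to exercise the chi-square filter but is
not a mechanistic model of gametic selection.

The simulator does not model read-level data (no FASTQ or alignments),
crossover interference, polyploidy, genotyping-error correlation between
nearby markers, or fully informative *ab×ab* segregation — so passing
end-to-end tests demonstrates correctness of the mapping chain under
clean pseudo-testcross assumptions, not robustness to every pathology of
real sequencing data.

## Validation design and problem sizes

The package validates itself at three scales, chosen to keep the full
suite under a minute while leaving no stage untested:

* closed-form checks (expected LOD 5.36 at r = 0.30 and n = 150, Kosambi
  34.66 cM, chi-square boundary cases) and the published poplar map
  summary table bundled with the package, whose mean-interval, Pearson
  correlation, anchored-fraction and per-Mb arithmetic the reporting
  functions reproduce exactly;
* estimator-versus-oracle sweeps (grid likelihood maximisation for all
  counts up to n = 200; exhaustive SARF for 100 random groups of up to 8);
* an end-to-end clean run at full design scale — 19 chromosomes,
  20 markers per parent each, 150 progeny, noise off — which must recover
  19 maternal and 19 paternal groups, each mapping one-to-one onto a true
  chromosome with the exact marker order up to reversal, plus a smaller
  noisy run checking graceful behaviour away from the clean case.

One subtlety in "exact order recovery": with 150 progeny and ~5 cM
intervals, an interval occasionally shows zero recombinants by chance
(probability about 5e-4 per interval). The two flanking markers are then
genuinely unorderable from the data — any method can only tie them.
`order_agreement()` therefore treats marker pairs with zero observed
recombination as an unordered block when counting discordances;
misplacement of any resolvable pair still fails. A 1:1-filter calibration
run uses 5 000 independent single-marker meioses to compare the realised
removal fraction with the exact discrete test size.

## Known limitations

* Single-linkage grouping can chain two true chromosomes through one
  spurious high-LOD pair; at n = 150 the probability is negligible, but
  at small family sizes a threshold scan should be inspected rather than
  trusted blindly.
* The SARF criterion itself (not our optimiser) can prefer a wrong order
  when genotyping error is high, since errors inflate apparent adjacent
  recombination; the package tracks order agreement on noisy runs but
  does not claim exactness there.
* Multipoint likelihood ordering, EM over genotyping error, integrated
  (sex-averaged) maps and *ab×ab*/*ab×cd* bridge markers are out of
  scope: the model here maps each parent separately from 1:1 markers.
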