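---
title: "Models and methods behind chromoscope"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind chromoscope}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chromoscope)
```

chromoscope packages the statistical machinery used to validate
chromosome-scale genome scaffolds of the fungus gnat *Bradysia
coprophila*: an entropy score for inter-chromosomal gene shuffling
(EGGS), a long-range Hi-C interaction caller (SCOPE), polytene-map
distance expectations, and coverage utilities for centromere
localization. This vignette explains the models, their assumptions, the
parameters that matter, and the numerical choices the implementation
makes.

## EGGS: entropy of gene group shuffling

Single-copy orthologs (SCOs) are genes present exactly once in each of
two species. If chromosomes evolved without inter-chromosomal exchange,
the SCOs of a chromosome in species A would all sit on one counterpart
chromosome in species B; as translocations accumulate, SCOs scatter.
Counting SCOs over pairs of chromosomes $(i, j)$ — one from each
species — and normalizing yields a joint probability table $p(i, j)$
with marginals $p_A(i)$ and $p_B(j)$.

The Shannon entropy $H = -\sum p \log_2 p$ (in bits, with
$0 \log 0 = 0$) of the joint table is bounded by two analytic extremes
determined by the marginals alone:

* **minimum** — perfectly conserved gene sets, where knowing the
  chromosome in one species determines it in the other:
  $H_{\min} = \tfrac{1}{2}(H_A + H_B)$;
* **maximum** — independent assortment:
  $H_{\max} = H(p_A \otimes p_B) = H_A + H_B = 2 H_{\min}$.

The Min–Max Normalized Entropy is

$$\mathrm{MMNE} = \frac{H_{\mathrm{obs}} - H_{\min}}{H_{\max} - H_{\min}}
               = 1 - \frac{2\,\mathrm{MI}}{H_A + H_B},$$

where MI is the mutual information between the two chromosome
assignments. MMNE is 0 for fully conserved karyotypes and 1 for fully
shuffled ones; both identities are verified to $10^{-9}$ against an
independent mutual-information computation in the test suite.

Choices that matter:

* **Pseudo-count** (default 0.1) is added to *every* cell, including in
  self-comparisons. A consequence is that a species compared to itself
  scores slightly above 0 (about $2 \times 10^{-3}$ at 4 chromosomes
  with 1000 SCOs each); the package documents and tests this rather
  than special-casing it. Passing `pseudo_count = 0` recovers the exact
  zero.
* **Arm merging**: for species whose assemblies report chromosome arms
  (2L/2R, 3L/3R), counts are summed into whole chromosomes via the
  `arm_merge` map before normalization.
* **Counterpart mapping** (`counterpart_map()`) reports percentages
  from the *raw* counts, not the pseudo-counted ones, because it
  describes observed SCO fractions; ties are broken by declared
  chromosome-label order so output is deterministic. The default 20%
  reporting threshold keeps secondary counterparts that hold a
  substantial minority of a chromosome's SCOs.
* **Degenerate comparisons**: with a single effective chromosome on
  either side, $H_{\max} = H_{\min}$ and MMNE is undefined; `mmne()`
  raises an error instead of returning 0/0.
* **Clustering** of a pairwise MMNE matrix treats the scores as
  distances; the default linkage is average (UPGMA) and is a recorded
  parameter, since different linkages can regroup species whose scores
  are nearly tied.

A note on published, rounded tables: a printed 3-decimal joint table
need not sum to 1 (the bundled fungus-gnat example sums to 0.999, and
one of its printed marginals disagrees with its rounded row sum by one
unit in the third decimal). `joint_table_from_counts()` renormalizes,
so entropies computed from printed tables are self-consistent; fixtures
derived this way are labeled as coming from the rounded values.

## SCOPE: scatter clusters of paired ends

Hi-C read pairs mapping to the same chromosome form a scatter of
(mate 1, mate 2) positions. Loci that touch in three dimensions while
being megabases apart on the sequence — such as the three fold-back
regions (FBRs) that fold the polytene X chromosome back on itself —
appear as off-diagonal dots. SCOPE turns those dots into interval
calls:

1. **Filter** pairs to MAPQ $\ge$ 10 and inter-mate distance $\ge$
   1 Mb. The pair MAPQ is the *minimum* of the two mates' MAPQs — the
   conservative choice when a per-pair value is needed. Pairs are
   canonicalized to `pos_a <= pos_b`, so the density lives on the upper
   triangle and results do not depend on mate order or input order.
2. **Smooth** with a 2D binned kernel density estimate on an
   $m \times m$ grid spanning $[0, L]$ on both axes ($m = 1024$ gives
   68.9 kb bins on the 70.5 Mb X; $m = 2048$ gives 34.4 kb). Points are
   linear-binned onto bin centers and convolved with a separable
   Gaussian (SD = bandwidth, default 250 kb, truncated at 4 SDs,
   zero-padded at the borders), then normalized so the density sums
   to 1 over the grid.
3. **Threshold** at a high empirical quantile of all $m^2$ grid values
   (zeros included; linear-interpolation quantile). Bins *strictly*
   above the threshold are peaks, so a constant grid yields none.
4. **Cluster** the peak bins hierarchically (complete linkage by
   default, recorded as a parameter) on their genomic bin-center
   coordinates — not indices — so both axes share a scale; cut at `k`
   clusters.
5. **Summarize** each cluster: median/min/max per axis (median of an
   even-sized set is the midpoint of the central pair), the summit bin
   (maximal density; ties to the smaller row-major index), and the
   separation $|\mathrm{median}_y - \mathrm{median}_x|$.
6. **Filter by separation** ($\ge$ 5 Mb), keeping genuinely long-range
   locus pairs.
7. Optionally **subtract background**: a call is dropped when both of
   its anchors overlap the (padded) anchors of a call made from a
   genomic-DNA control — which carries structural-variation dots but no
   spatial-proximity signal — in either anchor order, or when either
   anchor overlaps a padded SV breakpoint interval. The default pad is
   one bin width.

The choice of `k` should reflect how many distinct features populate
the map: 12 suffices for the male X map (three FBR dots, one
breakpoint-pair dot, and the short-range features), while dot-rich maps
need more clusters to keep nearby dots from merging — the package's
SV-bearing test scenario uses `k = 14` for its 14 planted dots.

### Numerical notes on the KDE

Linear binning splits each point's mass between the two bracketing bin
centers per axis. For a point exactly *on* a bin center the binning is
exact, and the convolution (with truncation disabled) reproduces the
direct $O(Nm^2)$ Gaussian sum to floating-point accuracy — the test
suite exploits this for an exact oracle comparison, and checks
off-center inputs at the $O((\Delta/h)^2)$ tolerance linear binning
implies (about 1% at bandwidth ≈ 5 bins; in SCOPE's default geometry
the bandwidth is 3.6 bins). The implementation is also cross-checked
against an independent reference (`KernSmooth::bkde2D`) on aligned
grids. Kernel truncation at 4 SDs changes densities by less than
$e^{-8}$ relatively and keeps the convolution cost at
$O(m^2 \cdot \mathrm{taps})$.

## Polytene-map distance expectations

The historical polytene map of the X divides it into 14 zones of
visually similar length, each with sub-zones A, B and C — 42 sub-zones
in total. Assuming zones are also similar in nucleotide length, a
scaffold of length $L$ implies a sub-zone length of $L/42$
(1.678759 Mb for the 70,507,862 bp X) and an expected distance of
(sub-zone count) × (sub-zone length) between any two landmarks. The
scaffold length itself is recovered from the published assembly summary
of four chromosome-scale scaffolds: with four sequences the N50 is the
second-longest scaffold, so `total − max − min − N50` isolates the
remaining one, and `2·median − N50` provides an independent
cross-check.

Reported distances are rounded half-away-from-zero at 1 decimal place
(3 for sub-Mb values), matching how such tables are conventionally
printed. The expectation model deliberately ignores real zone-length
variation; observed deviations of ±1–2 Mb over tens of Mb are within
what the equal-length assumption can absorb.

## Genome tracks

Two coverage semantics coexist deliberately:

* `summed_alignment_depth()` sums the *full lengths* of all alignments
  overlapping each position (computed as width-weighted interval
  coverage, never per-position loops). Long satellite-family alignments
  thus dominate the signal, which is what makes the track spike at
  centromeres. Binned values are the mean of per-position values; the
  last partial bin is averaged over its true width.
* `binned_fraction_covered()` uses standard union coverage — duplicated
  intervals cannot push a bin's fraction past 1.

`locate_centromere()` median-smooths (default 3 bins) and takes the
leftmost argmax. `target_linked_profile()` counts, per bin, the mates
of pairs whose other mate falls in a target region, with bins anchored
at the target's boundaries; pairs entirely inside the target count once
in the target's own bin, so the total raw count equals the number of
selected pairs. With `log_scale = TRUE` values are
$\log_{10}(\mathrm{count} + 1)$, so 0 means no interactions.

## The synthetic-data generators

The generators produce inputs with the statistical structure the
analyses assume, at desk scale:

* **SCO tables**: each SCO keeps its counterpart chromosome with
  probability $1 - \theta$ and is otherwise reassigned uniformly
  (over all chromosomes, or over the others). At $\theta = 1$ with
  `uniform_any`, assignments are independent and MMNE approaches 1.
* **Hi-C pairs**: a mixture of (a) background — mate 1 uniform, and an
  inter-mate distance with density $\propto (d + d_0)^{-\alpha}$
  (defaults $\alpha = 1$, $d_0 = 10$ kb) truncated to the chromosome
  remaining downstream of mate 1, reproducing the qualitative decay of
  contact frequency with distance without the corner pile-up a fixed
  truncation would create; (b) planted loops — both ends at an anchor
  plus independent Gaussian jitter (150 kb default, giving FBR-scale
  dots); and (c) planted SV dots (10 kb jitter — "tiny" dots, an order
  of magnitude tighter than loop dots). Jitter is clipped at the
  chromosome bounds rather than resampled, which slightly inflates
  density at the extreme edges. A matched control
  (`simulate_control_pairs()`) zeroes the loop weights but keeps SV
  dots and background.
* **Repeat alignments**: midpoints at a planted centromere plus Laplace
  noise, lengths exponential.

The canonical X-chromosome condition (`sim_x_config()`) plants the
three FBR pair dots and the breakpoint-pair dot at coordinates
back-computed from the observed landmark distances, at weight 0.02
each, plus eight short-separation (< 5 Mb) dots standing in for the
small structural variants and shorter-range interactions that fill the
remaining peak clusters on the real map. All generators take explicit
seeds; multi-stream runs derive per-stream seeds deterministically from
one root seed (`derive_seed()`).

What the simulations do *not* model: restriction-fragment structure,
mappability and duplicate artifacts, inter-chromosomal contacts,
chromatin-compartment structure, and the empirical shape of real
contact-distance decay beyond a one-parameter power law. Passing tests
therefore demonstrate that the pipeline recovers planted structure
under its own assumptions — a correctness statement, not a guarantee
about noise regimes real libraries can present.

## Problem sizes and determinism

The bundled checks run at deliberately modest scale: 200,000 simulated
pairs on the full-length 70.5 Mb chromosome for SCOPE recovery (the
wide 1024² and narrow 2048² parameter sets both complete in seconds),
4 chromosomes × 1000 SCOs with 20 replicates per $\theta$ for the
entropy monotonicity checks, and 5000 repeat alignments for centromere
recovery. Identical configurations and seeds give byte-identical
outputs; shuffling input pair order changes nothing.

## Worked example

```{r example}
# entropy between two simulated species at a moderate shuffling rate
cfg <- sim_sco_config(c("X", "II", "III", "IV"), 1000, theta = 0.2,
                      seed = 7)
jt <- build_joint_table(simulate_sco_table(cfg))
mmne(jt)

# SCOPE on two small planted loops
hic <- simulate_hic_pairs(sim_hic_config("chrX", 2e7, 20000,
  loops = list(loop_spec(3e6, 1.5e7, 0.08),
               loop_spec(6e6, 1.8e7, 0.08)), seed = 11))
calls <- run_scope(hic, scope_params(grid_size = 256, k_clusters = 2))
as.data.frame(calls)[, c("anchor1_start", "anchor1_end",
                         "anchor2_start", "anchor2_end", "separation")]
```
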